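# Property-based drug-likeness rules: Rule-of-Five, the ring/rigid-bond
# (RNG/RGB) box classification, and single-descriptor threshold filters.

#' Lipinski Rule-of-Five with the one-violation allowance
#'
#' Violations are counted over MW > 500, AlogP > 5, N_HBDL > 5 and
#' N_HBAL > 10; a molecule is drug-like when it has at most one violation.
#' @param dv a descriptor vector (named numeric, e.g. from
#'   [compute_descriptors()]) containing `MW`, `AlogP`, `N_HBDL`, `N_HBAL`.
#' @return list with `violations` (0-4) and `druglike` (logical).
#' @export
rule_of_five <- function(dv) {
  need <- c("MW", "AlogP", "N_HBDL", "N_HBAL")
  miss <- setdiff(need, names(dv))
  if (length(miss)) stop("missing descriptor(s) for Rule-of-Five: ",
                         paste(miss, collapse = ", "))
  v <- sum(dv[["MW"]] > 500, dv[["AlogP"]] > 5, dv[["N_HBDL"]] > 5,
           dv[["N_HBAL"]] > 10)
  list(violations = as.integer(v), druglike = v <= 1L)
}

#' Ring-count / rigid-bond box classification
#'
#' RNG is the SSSR ring count; RGB (rigid bonds) is taken as heavy-atom bonds
#' minus rotatable bonds. A molecule falls in the non-drug-like box when
#' 0 <= RNG <= 2 and RGB <= 17, in the drug-like box when RNG >= 3 and
#' RGB >= 18, and otherwise in neither; the three outcomes are mutually
#' exclusive and exhaustive.
#' @param dv named numeric vector containing `N_Rings`, `N_Bonds`, `N_rot`.
#' @return one of `"druglike_box"`, `"nondruglike_box"`, `"neither"`.
#' @export
oprea_box <- function(dv) {
  need <- c("N_Rings", "N_Bonds", "N_rot")
  miss <- setdiff(need, names(dv))
  if (length(miss)) stop("missing descriptor(s) for box rule: ",
                         paste(miss, collapse = ", "))
  rng <- dv[["N_Rings"]]
  rgb <- dv[["N_Bonds"]] - dv[["N_rot"]]
  if (rng <= 2 && rgb <= 17) "nondruglike_box"
  else if (rng >= 3 && rgb >= 18) "druglike_box"
  else "neither"
}

#' Single-descriptor threshold filter
#'
#' @param descriptor_name one of the 60 descriptor names.
#' @param cutoff threshold in the descriptor's units.
#' @param direction `"below_is_positive"` (value < cutoff passes) or
#'   `"above_is_positive"` (value > cutoff passes); equality is always
#'   negative (strict comparison).
#' @return object of class `threshold_filter`.
#' @export
threshold_filter <- function(descriptor_name, cutoff,
                             direction = c("below_is_positive", "above_is_positive")) {
  direction <- match.arg(direction)
  if (!descriptor_name %in% descriptor_names())
    stop("unknown descriptor: ", descriptor_name)
  structure(list(descriptor_name = descriptor_name, cutoff = cutoff,
                 direction = direction), class = "threshold_filter")
}

#' @export
print.threshold_filter <- function(x, ...) {
  op <- if (x$direction == "below_is_positive") "<" else ">"
  cat(sprintf("<threshold_filter: %s %s %g>\n", x$descriptor_name, op, x$cutoff))
  invisible(x)
}

#' Apply a threshold filter to a descriptor vector
#'
#' @param dv named numeric vector (with optional `flags` attribute); a
#'   flagged-undefined or `NA` descriptor classifies as negative, with a
#'   warning.
#' @param filter a [threshold_filter()].
#' @return logical: does the molecule pass the filter?
#' @export
apply_threshold <- function(dv, filter) {
  nm <- filter$descriptor_name
  if (!nm %in% names(dv)) stop("descriptor not present: ", nm)
  val <- dv[[nm]]
  flagged <- nm %in% (attr(dv, "flags") %||% character())
  if (is.na(val) || flagged) {
    warning("descriptor ", nm, " undefined; classified negative")
    return(FALSE)
  }
  if (filter$direction == "below_is_positive") val < filter$cutoff
  else val > filter$cutoff
}
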