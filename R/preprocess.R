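#' Apply peak detection threshold and analysis range
#'
#' Retains exactly the peaks whose height is at least the peak detection
#' threshold and whose size lies inside the analysis range. Both
#' comparisons are inclusive: the PDT names the lowest acceptable peak
#' height, so a peak at exactly the threshold is kept. The filter can be
#' applied post hoc to already-exported peak tables and is idempotent.
#'
#' @param profile A [trf_profile()].
#' @param config A [detection_config()].
#' @return The filtered profile, with a provenance entry appended. An
#'   empty result is allowed and triggers a warning.
#' @export
apply_detection_threshold <- function(profile, config = detection_config()) {
  stopifnot(inherits(profile, "trf_profile"),
            inherits(config, "detection_config"))
  keep <- profile$peaks$height >= config$pdt &
    profile$peaks$size >= config$range_min &
    profile$peaks$size <= config$range_max
  n0 <- nrow(profile$peaks)
  profile$peaks <- profile$peaks[keep, , drop = FALSE]
  rownames(profile$peaks) <- NULL
  if (nrow(profile$peaks) == 0)
    warning("profile '", profile$profile_id,
            "' has no peaks left after detection filtering", call. = FALSE)
  add_provenance(profile, sprintf(
    "detection_filter(pdt=%g, range=[%g,%g]): %d -> %d peaks",
    config$pdt, config$range_min, config$range_max, n0, nrow(profile$peaks)))
}

#' Total fluorescence of a profile
#'
#' Total fluorescence (TF) is the sum of all peak heights, or of all peak
#' areas, of a profile. It is the proxy for the amount of DNA loaded on
#' the gel and the quantity equalized by [tfn_normalize()].
#'
#' @param profile A [trf_profile()].
#' @param basis `"height"` or `"area"`.
#' @return A single non-negative number; 0 for an empty profile.
#' @export
total_fluorescence <- function(profile, basis = c("height", "area")) {
  stopifnot(inherits(profile, "trf_profile"))
  basis <- match.arg(basis)
  sig <- profile$peaks[[basis]]
  if (basis == "area" && anyNA(sig))
    stop("profile '", profile$profile_id,
         "' has missing peak areas; total fluorescence on the area basis ",
         "is undefined", call. = FALSE)
  sum(sig)
}

#' Relative abundances within a profile
#'
#' The relative abundance of a T-RF is its peak height (or area) divided
#' by the sum of all peak heights (or areas) of the profile.
#'
#' @param profile A non-empty [trf_profile()].
#' @param basis `"height"` or `"area"`.
#' @return Numeric vector aligned with the profile's peak order, summing
#'   to 1.
#' @export
relative_abundance <- function(profile, basis = c("height", "area")) {
  stopifnot(inherits(profile, "trf_profile"))
  basis <- match.arg(basis)
  if (nrow(profile$peaks) == 0)
    stop("cannot compute relative abundances of an empty profile",
         call. = FALSE)
  sig <- profile$peaks[[basis]]
  if (basis == "area" && anyNA(sig))
    stop("profile '", profile$profile_id,
         "' has missing peak areas; relative abundance on the area basis ",
         "is undefined", call. = FALSE)
  sig / sum(sig)
}
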