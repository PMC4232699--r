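#' Normalization settings
#'
#' Configures the five evaluated normalization procedures. `TFN` is the
#' iterative total-fluorescence normalization: profiles are rescaled to
#' the lowest total fluorescence in the group, peaks falling below a
#' threshold after rescaling are removed, and the rescale/remove cycle is
#' repeated until the total fluorescence equals the minimum. `FPT`
#' removes, in a single pass, all T-RFs whose relative abundance lies
#' strictly below a fixed percentage threshold.
#'
#' The TFN threshold rule depends on the signal basis: with peak heights
#' the minimum allowed height is the peak detection threshold
#' (`"pdt"`); with peak areas it is the minimum observed area in the
#' whole dataset (`"global_min_area"`, procedure TFN-areas) or among the
#' replicates being normalized (`"local_min_area"`, procedure
#' TFN-areas-LT).
#'
#' @param method `"TFN"` or `"FPT"`.
#' @param basis `"height"` or `"area"`.
#' @param threshold_rule TFN only: `"pdt"`, `"global_min_area"` or
#'   `"local_min_area"`. Defaults to `"pdt"` for heights and
#'   `"global_min_area"` for areas.
#' @param fpt_fraction FPT only: relative abundance threshold in (0, 1);
#'   default 0.01 (1 percent).
#' @param tolerance Relative convergence tolerance for TF = TFmin.
#' @param max_iterations Iteration cap for the TFN loop.
#' @param destructive_removal If `TRUE`, peaks removed in a TFN iteration
#'   are discarded permanently. The default re-evaluates the original
#'   peak set under the cumulative factor each iteration, so a peak may
#'   re-enter - which is what makes the documented two-state oscillation
#'   possible.
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(method = c("TFN", "FPT"),
                                 basis = c("height", "area"),
                                 threshold_rule = NULL,
                                 fpt_fraction = 0.01,
                                 tolerance = 1e-9,
                                 max_iterations = 1000,
                                 destructive_removal = FALSE) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  if (method == "TFN") {
    if (is.null(threshold_rule))
      threshold_rule <- if (basis == "height") "pdt" else "global_min_area"
    threshold_rule <- match.arg(threshold_rule,
                                c("pdt", "global_min_area",
                                  "local_min_area"))
    if (basis == "height" && threshold_rule != "pdt")
      stop("invalid normalization_config: TFN on heights uses the peak ",
           "detection threshold (threshold_rule = 'pdt')", call. = FALSE)
    if (basis == "area" && threshold_rule == "pdt")
      stop("invalid normalization_config: TFN on areas requires an area ",
           "threshold rule ('global_min_area' or 'local_min_area')",
           call. = FALSE)
  }
  if (!is.numeric(fpt_fraction) || fpt_fraction <= 0 || fpt_fraction >= 1)
    stop("invalid normalization_config: 'fpt_fraction' must be in (0, 1)",
         call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("invalid normalization_config: 'tolerance' must be > 0",
         call. = FALSE)
  structure(list(method = method, basis = basis,
                 threshold_rule = threshold_rule,
                 fpt_fraction = fpt_fraction, tolerance = tolerance,
                 max_iterations = max_iterations,
                 destructive_removal = destructive_removal),
            class = "normalization_config")
}

# Named presets for the five evaluated procedures (internal helper,
# used by the treatment registry and the command line).
normalization_preset <- function(name) {
  switch(name,
    "tfn-heights" = normalization_config("TFN", "height"),
    "tfn-areas" = normalization_config("TFN", "area", "global_min_area"),
    "tfn-areas-lt" = normalization_config("TFN", "area", "local_min_area"),
    "fpt-heights" = normalization_config("FPT", "height"),
    "fpt-areas" = normalization_config("FPT", "area"),
    stop("unknown normalization preset '", name, "'", call. = FALSE))
}

#' Total fluorescence normalization (TFN)
#'
#' Rescales every profile in a group to the group's lowest total
#' fluorescence, TFmin. For a profile with total fluorescence TF above
#' TFmin, all signals are multiplied by TFmin/TF; peaks whose rescaled
#' signal falls below the minimum allowed value are removed, TF is
#' recomputed over the remaining peaks, and the process repeats until TF
#' equals TFmin (within `tolerance`). When the retained peak set
#' oscillates between two states - a peak near the threshold being
#' alternately included and excluded - the profile is taken as the
#' peak-wise average of the two states, with a peak absent from one state
#' contributing zero to its average. The minimum-TF profile is returned
#' unchanged.
#'
#' @param profiles List of [trf_profile()] objects (the dataset).
#' @param config A [normalization_config()] with `method = "TFN"`.
#' @param detection The [detection_config()] supplying the height
#'   threshold for TFN on peak heights.
#' @param groups Optional grouping (character/factor, one per profile):
#'   normalization and TFmin are computed within each group, e.g. per
#'   replicate pair. Default: all profiles form one group. With
#'   `threshold_rule = "global_min_area"` the area threshold is always
#'   the minimum over all profiles passed, regardless of grouping.
#' @return The normalized profiles, in input order.
#' @export
tfn_normalize <- function(profiles, config = normalization_config(),
                          detection = detection_config(), groups = NULL) {
  profiles <- as_profile_list(profiles)
  stopifnot(inherits(config, "normalization_config"))
  if (config$method != "TFN")
    stop("tfn_normalize() requires a TFN configuration", call. = FALSE)
  if (length(profiles) < 2)
    stop("tfn_normalize() needs at least two profiles", call. = FALSE)
  basis <- config$basis
  if (basis == "area") {
    all_areas <- unlist(lapply(profiles, function(p) p$peaks$area))
    if (anyNA(all_areas))
      stop("TFN on the area basis requires peak areas for every peak",
           call. = FALSE)
  }
  if (is.null(groups)) groups <- rep("all", length(profiles))
  if (length(groups) != length(profiles))
    stop("'groups' must have one entry per profile", call. = FALSE)
  threshold_global <- switch(config$threshold_rule,
    pdt = detection$pdt,
    global_min_area = min(unlist(lapply(profiles,
                                        function(p) p$peaks$area))),
    local_min_area = NA_real_)
  out <- profiles
  for (g in unique(groups)) {
    idx <- which(groups == g)
    tfs <- vapply(profiles[idx], total_fluorescence, numeric(1), basis)
    tfmin <- min(tfs)
    if (tfmin <= 0)
      stop("degenerate input: group '", g, "' has a profile with zero ",
           "total fluorescence", call. = FALSE)
    threshold <- if (config$threshold_rule == "local_min_area")
      min(unlist(lapply(profiles[idx], function(p) p$peaks$area)))
    else threshold_global
    for (i in idx) {
      out[[i]] <- tfn_one(profiles[[i]], tfmin, threshold, basis, config)
    }
  }
  out
}

# Normalize a single profile to tfmin (internal). Implements the
# iterative rescale/remove loop with two-state cycle averaging.
tfn_one <- function(profile, tfmin, threshold, basis, config) {
  sig0 <- profile$peaks[[basis]]
  tf0 <- sum(sig0)
  if (tf0 == tfmin)
    return(add_provenance(profile, sprintf(
      "tfn(%s): minimum-TF profile, unchanged (TF = %g)", basis, tf0)))
  fac <- 1
  tf <- tf0
  hist_keep <- list()
  hist_fac <- numeric()
  active <- rep(TRUE, length(sig0))   # destructive mode only
  for (iter in seq_len(config$max_iterations)) {
    fac <- fac * tfmin / tf
    scaled <- sig0 * fac
    keep <- active & scaled >= threshold
    if (!any(keep))
      stop("degenerate input: profile '", profile$profile_id,
           "' loses every peak during TFN", call. = FALSE)
    if (config$destructive_removal) active <- keep
    tf <- sum(scaled[keep])
    if (abs(tf - tfmin) / tfmin <= config$tolerance) {
      pk <- profile$peaks[keep, , drop = FALSE]
      pk$height <- pk$height * fac
      pk$area <- pk$area * fac
      res <- profile
      res$peaks <- pk
      rownames(res$peaks) <- NULL
      return(add_provenance(res, sprintf(
        "tfn(%s): TF %g -> %g in %d iteration(s), %d peak(s) removed",
        basis, tf0, tf, iter, sum(!keep))))
    }
    key <- paste(which(keep), collapse = ",")
    n <- length(hist_keep)
    if (n >= 2 && identical(key, hist_keep[[n - 1L]]) &&
        !identical(key, hist_keep[[n]])) {
      # two-state cycle: average the current state and the previous one
      prev_keep <- as.integer(strsplit(hist_keep[[n]], ",")[[1]])
      prev_fac <- hist_fac[n]
      w_cur <- ifelse(keep, fac, 0)
      w_prev <- rep(0, length(sig0))
      w_prev[prev_keep] <- prev_fac
      w <- (w_cur + w_prev) / 2
      sel <- w > 0
      pk <- profile$peaks[sel, , drop = FALSE]
      pk$height <- profile$peaks$height[sel] * w[sel]
      pk$area <- profile$peaks$area[sel] * w[sel]
      res <- profile
      res$peaks <- pk
      rownames(res$peaks) <- NULL
      return(add_provenance(res, sprintf(
        "tfn(%s): two-state cycle after %d iterations, averaged states (TF %g -> %g)",
        basis, iter, tf0, sum(pk[[basis]]))))
    }
    hist_keep[[n + 1L]] <- key
    hist_fac <- c(hist_fac, fac)
  }
  stop("TFN did not converge for profile '", profile$profile_id,
       "' within ", config$max_iterations, " iterations (last TF = ",
       format(tf, digits = 10), ", TFmin = ", format(tfmin, digits = 10),
       ") and no two-state cycle was detected", call. = FALSE)
}

#' Fixed percentage threshold (FPT) normalization
#'
#' Removes, in one pass, every T-RF whose relative abundance on the
#' configured basis is strictly below `fpt_fraction` (default 1 percent).
#' Relative abundances are computed once, on the input profile; surviving
#' signals are not rescaled and the threshold is not re-applied after
#' removal.
#'
#' @param profile A non-empty [trf_profile()].
#' @param config A [normalization_config()] with `method = "FPT"`.
#' @return The filtered profile. Removing every peak yields an empty
#'   profile with a warning.
#' @export
fpt_normalize <- function(profile, config = normalization_config("FPT")) {
  stopifnot(inherits(profile, "trf_profile"),
            inherits(config, "normalization_config"))
  if (config$method != "FPT")
    stop("fpt_normalize() requires an FPT configuration", call. = FALSE)
  ra <- relative_abundance(profile, config$basis)
  keep <- ra >= config$fpt_fraction
  n0 <- nrow(profile$peaks)
  profile$peaks <- profile$peaks[keep, , drop = FALSE]
  rownames(profile$peaks) <- NULL
  if (nrow(profile$peaks) == 0)
    warning("profile '", profile$profile_id,
            "' has no peaks left after FPT filtering", call. = FALSE)
  add_provenance(profile, sprintf(
    "fpt(%s, %g): %d -> %d peaks", config$basis, config$fpt_fraction,
    n0, nrow(profile$peaks)))
}
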