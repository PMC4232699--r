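#' Specification of a synthetic T-RF profile dataset
#'
#' Parameterizes a generative model of T-RFLP fingerprints with the noise
#' structure characterized on a 3730-class capillary instrument:
#'
#' * run-to-run size-estimation noise split into a per-profile
#'   systematic shift (uniform, the dominant component) and per-peak
#'   jitter (truncated normal); the defaults are jointly calibrated so
#'   loading duplicates show a mean absolute size difference of 0.21
#'   bases with a maximum below 1, about 95 percent of differences
#'   below 0.5, and roughly half of profile pairs carrying a detectable
#'   systematic shift;
#' * loading-dependent total fluorescence - the relative TF difference
#'   between successive loadings of the same digest is drawn directly
#'   (truncated normal, mean 17 percent, sd 7, max 33), plus
#'   concentration scaling and replicate-level yield variability;
#' * low-height artifact/noise peaks near the instrument baseline
#'   (20-30 fluorescence units) up to sub-threshold pull-up peaks.
#'
#' @param n_fragments True community richness (number of fragments).
#' @param true_sizes Optional fragment lengths in bases; drawn uniformly
#'   over `size_range` with spacing at least `min_spacing` when `NULL`.
#' @param true_abundances Optional unit-sum relative abundances of the
#'   base community; default is a geometric rank-abundance series with
#'   ratio 0.85, shuffled over the fragments.
#' @param sample_tilt_range Per-sample steepness tilt of the
#'   rank-abundance curve: each sample's abundances are the base
#'   abundances raised to a power drawn uniformly from this interval
#'   (then renormalized), so communities differ in evenness between
#'   samples. `c(1, 1)` disables the tilt.
#' @param sample_effect_sd Log-normal sd of per-sample, per-fragment
#'   abundance noise (compositional variability between samples); 0
#'   disables it.
#' @param base_signal Expected total fluorescence at concentration 1
#'   (fluorescence units).
#' @param jitter_sd,jitter_cap Size-estimation noise: normal sd and hard
#'   cap (bases); `jitter_cap` must be below 1.
#' @param shift_range Bounds of the uniform per-profile systematic size
#'   shift (bases).
#' @param loading_diff Numeric triple (mean, sd, max) of the relative TF
#'   difference between consecutive loadings of one digest.
#' @param replicate_cv Log-normal coefficient of variation of the
#'   replicate-level (extraction/PCR/digestion) yield multiplier.
#' @param noise_peak_rate Expected artifact peaks per profile (Poisson).
#' @param noise_height_range Artifact peak height bounds (fluorescence
#'   units).
#' @param width_slope Relative peak-width growth per base: peak area is
#'   height times (1 + width_slope * size), reflecting the broadening of
#'   peaks with migration time.
#' @param size_range Analysis range the fragments must fall in (bases).
#' @param min_spacing Minimum spacing between drawn true sizes (bases).
#' @param seed RNG seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_fragments = 40,
                           true_sizes = NULL,
                           true_abundances = NULL,
                           sample_tilt_range = c(0.5, 1.5),
                           sample_effect_sd = 0.6,
                           base_signal = 15000,
                           jitter_sd = 0.0593,
                           jitter_cap = 0.15,
                           shift_range = c(-0.3, 0.3),
                           loading_diff = c(mean = 0.17, sd = 0.07,
                                            max = 0.33),
                           replicate_cv = 0.15,
                           noise_peak_rate = 5,
                           noise_height_range = c(20, 100),
                           width_slope = 0.002,
                           size_range = c(50, 1020),
                           min_spacing = 3,
                           seed = 1) {
  if (!is.null(true_sizes)) {
    n_fragments <- length(true_sizes)
    if (any(true_sizes < size_range[1] | true_sizes > size_range[2]))
      stop("invalid synthetic_spec: true sizes must lie within the ",
           "size range", call. = FALSE)
    if (is.unsorted(true_sizes, strictly = TRUE))
      stop("invalid synthetic_spec: true sizes must be strictly increasing",
           call. = FALSE)
  }
  if (!is.null(true_abundances)) {
    if (length(true_abundances) != n_fragments)
      stop("invalid synthetic_spec: one abundance per fragment required",
           call. = FALSE)
    if (abs(sum(true_abundances) - 1) > 1e-9)
      stop("invalid synthetic_spec: true abundances must sum to 1",
           call. = FALSE)
  }
  if (jitter_cap >= 1)
    stop("invalid synthetic_spec: jitter_cap must be below 1 base",
         call. = FALSE)
  if (jitter_sd < 0 || replicate_cv < 0 || noise_peak_rate < 0)
    stop("invalid synthetic_spec: noise magnitudes must be >= 0",
         call. = FALSE)
  if (length(loading_diff) != 3 || any(loading_diff < 0) ||
      loading_diff[3] >= 1)
    stop("invalid synthetic_spec: loading_diff must be (mean, sd, max) ",
         "with max < 1", call. = FALSE)
  if (length(sample_tilt_range) != 2 || any(sample_tilt_range <= 0) ||
      sample_effect_sd < 0)
    stop("invalid synthetic_spec: sample_tilt_range must be positive ",
         "bounds and sample_effect_sd >= 0", call. = FALSE)
  structure(list(n_fragments = n_fragments, true_sizes = true_sizes,
                 true_abundances = true_abundances,
                 sample_tilt_range = sample_tilt_range,
                 sample_effect_sd = sample_effect_sd,
                 base_signal = base_signal, jitter_sd = jitter_sd,
                 jitter_cap = jitter_cap, shift_range = shift_range,
                 loading_diff = unname(loading_diff),
                 replicate_cv = replicate_cv,
                 noise_peak_rate = noise_peak_rate,
                 noise_height_range = noise_height_range,
                 width_slope = width_slope, size_range = size_range,
                 min_spacing = min_spacing, seed = seed),
            class = "synthetic_spec")
}

# Normal draws truncated at +/- cap by rejection (internal).
rnorm_trunc <- function(n, sd, cap) {
  if (sd == 0 || n == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > cap))
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

# One-sided truncated normal on [0, cap] (internal).
rnorm_trunc_pos <- function(n, mean, sd, cap) {
  if (n == 0) return(numeric())
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0 | x > cap))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a T-RF profile dataset with ground truth
#'
#' Generates profiles for a factorial design of samples, replicates and
#' repeated gel loadings. Each profile's observed peak sizes are the true
#' fragment sizes plus the profile's systematic shift plus per-peak
#' jitter; peak heights are true abundance times base signal times the
#' sample concentration times the replicate and loading multipliers;
#' areas are heights scaled by the size-dependent width factor; artifact
#' peaks with random sizes and low heights are appended. The ground
#' truth record maps every observed peak to its true fragment or flags
#' it as an artifact. Identical seeds give identical output; the global
#' RNG state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @param design List with `samples` (count or character vector),
#'   `replicates_per_sample`, `loadings_per_replicate` and
#'   `concentrations` (recycled over samples; relative DNA
#'   concentration, 1 = undiluted).
#' @return A list with `profiles` (named list of [trf_profile()]) and
#'   `truth` (fragments, per-profile parameters, and the per-peak map).
#' @export
simulate_dataset <- function(spec,
                             design = list(samples = 1,
                                           replicates_per_sample = 1,
                                           loadings_per_replicate = 2,
                                           concentrations = 1)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec$seed)
  samples <- design$samples
  if (is.numeric(samples)) samples <- sprintf("S%02d", seq_len(samples))
  n_rep <- design$replicates_per_sample %||% 1
  n_load <- design$loadings_per_replicate %||% 1
  conc <- rep_len(design$concentrations %||% 1, length(samples))
  lo <- spec$size_range[1]; hi <- spec$size_range[2]
  # community: spaced true sizes, geometric rank-abundance profile
  sizes <- spec$true_sizes
  if (is.null(sizes)) {
    margin <- max(1, spec$min_spacing / 2)
    sizes <- numeric(0)
    tries <- 0
    while (length(sizes) < spec$n_fragments) {
      cand <- stats::runif(1, lo + margin, hi - margin)
      if (!length(sizes) || min(abs(sizes - cand)) >= spec$min_spacing)
        sizes <- c(sizes, cand)
      tries <- tries + 1
      if (tries > 10000 * spec$n_fragments)
        stop("could not place ", spec$n_fragments,
             " fragments with spacing ", spec$min_spacing, call. = FALSE)
    }
    sizes <- sort(sizes)
  }
  ab <- spec$true_abundances
  if (is.null(ab)) {
    ab <- 0.85 ^ (seq_len(spec$n_fragments) - 1)
    ab <- sample(ab / sum(ab))
  }
  fragments <- data.frame(fragment = seq_len(spec$n_fragments),
                          true_size = sizes, true_abundance = ab)
  # per-sample community: steepness tilt plus log-normal noise on the
  # base abundances, renormalized (sum stays 1, so TF is unaffected)
  abundances <- vapply(seq_along(samples), function(s) {
    tilt <- stats::runif(1, spec$sample_tilt_range[1],
                         spec$sample_tilt_range[2])
    w <- ab ^ tilt *
      exp(stats::rnorm(spec$n_fragments, 0, spec$sample_effect_sd))
    w / sum(w)
  }, numeric(spec$n_fragments))
  if (is.null(dim(abundances)))
    abundances <- matrix(abundances, nrow = spec$n_fragments)
  colnames(abundances) <- samples
  profiles <- list()
  prof_rows <- list()
  peak_rows <- list()
  ld <- spec$loading_diff
  for (s in seq_along(samples)) {
    for (r in seq_len(n_rep)) {
      rep_mult <- exp(stats::rnorm(1, 0, spec$replicate_cv))
      load_mult <- 1
      for (l in seq_len(n_load)) {
        if (l > 1) {
          d <- rnorm_trunc_pos(1, ld[1], ld[2], ld[3])
          load_mult <- load_mult * (1 - d) ^ sample(c(1, -1), 1)
        }
        pid <- sprintf("%s_R%d_L%d", samples[s], r, l)
        shift <- stats::runif(1, spec$shift_range[1], spec$shift_range[2])
        mult <- conc[s] * rep_mult * load_mult
        jit <- rnorm_trunc(spec$n_fragments, spec$jitter_sd,
                           spec$jitter_cap)
        obs_size <- fragments$true_size + shift + jit
        height <- abundances[, s] * spec$base_signal * mult
        n_art <- stats::rpois(1, spec$noise_peak_rate)
        art_size <- stats::runif(n_art, lo, hi)
        art_height <- stats::runif(n_art, spec$noise_height_range[1],
                                   spec$noise_height_range[2])
        all_size <- c(obs_size, art_size)
        while (anyDuplicated(all_size)) {   # vanishingly rare
          art_size <- stats::runif(n_art, lo, hi)
          all_size <- c(obs_size, art_size)
        }
        all_height <- c(height, art_height)
        all_frag <- c(fragments$fragment, rep(NA_integer_, n_art))
        area <- all_height * (1 + spec$width_slope * all_size)
        ord <- order(all_size)
        profiles[[pid]] <- trf_profile(
          pid,
          data.frame(size = all_size[ord], height = all_height[ord],
                     area = area[ord]),
          sample_id = samples[s], replicate = sprintf("R%d", r),
          provenance = sprintf("simulate_dataset(seed=%d)", spec$seed))
        prof_rows[[pid]] <- data.frame(
          profile_id = pid, sample_id = samples[s],
          replicate = sprintf("R%d", r), loading = l,
          concentration = conc[s], shift = shift, multiplier = mult,
          stringsAsFactors = FALSE)
        peak_rows[[pid]] <- data.frame(
          profile_id = pid, size_observed = all_size[ord],
          fragment = all_frag[ord], artifact = is.na(all_frag[ord]),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- list(spec = spec, fragments = fragments,
                abundances = abundances,
                profiles = do.call(rbind, c(prof_rows,
                                            make.row.names = FALSE)),
                peaks = do.call(rbind, c(peak_rows,
                                         make.row.names = FALSE)))
  list(profiles = profiles, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a pipeline result against simulation ground truth
#'
#' Measures how well an analysis recovered the simulated community:
#' bin-to-fragment assignment accuracy (the fraction of fragment-derived
#' peaks placed in their fragment's plurality bin), the number of
#' artifact peaks that leaked into the alignment, the root-mean-square
#' error of estimated relative abundances against the truth, and the
#' per-profile error of the recovered systematic shift offsets (offsets
#' are relative, so errors are centered before comparison).
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param alignment A `trf_alignment` computed from the simulated
#'   profiles.
#' @param abundance Optional `trf_abundance` built from `alignment`.
#' @param correction Optional `shift_correction` from
#'   [correct_systematic_shift()].
#' @return A list with `assignment_accuracy`, `artifact_leaks`,
#'   `abundance_rmse` (or `NA`), `shift_error` (named vector, or `NULL`)
#'   and `max_shift_error`.
#' @export
evaluate_recovery <- function(truth, alignment, abundance = NULL,
                              correction = NULL) {
  stopifnot(inherits(alignment, "trf_alignment"))
  m <- alignment$members
  if (!all(m$profile_id %in% truth$peaks$profile_id))
    stop("alignment profiles do not match the ground truth record",
         call. = FALSE)
  key_truth <- paste(truth$peaks$profile_id,
                     round(truth$peaks$size_observed, 9))
  key_m <- paste(m$profile_id, round(m$size_original, 9))
  hit <- match(key_m, key_truth)
  if (anyNA(hit))
    stop("alignment contains peaks not present in the ground truth ",
         "record; was the alignment computed from these simulated ",
         "profiles?", call. = FALSE)
  frag <- truth$peaks$fragment[hit]
  artifact_leaks <- sum(is.na(frag))
  # plurality bin per fragment
  real <- !is.na(frag)
  acc <- NA_real_
  home <- NULL
  if (any(real)) {
    tab <- table(frag[real], m$bin_id[real])
    home <- apply(tab, 1, function(row)
      as.integer(colnames(tab)[which.max(row)]))
    acc <- mean(m$bin_id[real] == home[as.character(frag[real])])
  }
  abundance_rmse <- NA_real_
  if (!is.null(abundance)) {
    stopifnot(inherits(abundance, "trf_abundance"))
    if (nrow(abundance) != nrow(alignment$bins))
      stop("abundance matrix does not match the alignment's bins",
           call. = FALSE)
    # majority fragment per bin (NA when artifact-dominated)
    bin_frag <- rep(NA_integer_, nrow(alignment$bins))
    for (b in seq_len(nrow(alignment$bins))) {
      f <- frag[m$bin_id == alignment$bins$bin_id[b]]
      f <- f[!is.na(f)]
      if (length(f))
        bin_frag[b] <- as.integer(names(sort(table(f),
                                             decreasing = TRUE))[1])
    }
    errs <- c()
    for (p in colnames(abundance)) {
      sel <- !is.na(bin_frag) & abundance[, p] > 0
      if (!any(sel)) next
      s <- truth$profiles$sample_id[match(p, truth$profiles$profile_id)]
      if (is.na(s)) s <- p   # consensus profiles are named by sample
      if (!s %in% colnames(truth$abundances))
        stop("cannot map abundance column '", p,
             "' to a simulated sample", call. = FALSE)
      tr <- truth$abundances[bin_frag[sel], s]
      tr <- tr / sum(tr)
      est <- abundance[sel, p]
      est <- est / sum(est)
      errs <- c(errs, est - tr)
    }
    if (length(errs)) abundance_rmse <- sqrt(mean(errs ^ 2))
  }
  shift_error <- NULL
  max_shift_error <- NA_real_
  if (!is.null(correction)) {
    stopifnot(inherits(correction, "shift_correction"))
    off <- correction$per_profile_offset
    true_shift <- truth$profiles$shift[match(names(off),
                                             truth$profiles$profile_id)]
    resid <- off + true_shift
    shift_error <- resid - mean(resid)
    max_shift_error <- max(abs(shift_error))
  }
  list(assignment_accuracy = acc, artifact_leaks = artifact_leaks,
       abundance_rmse = abundance_rmse, shift_error = shift_error,
       max_shift_error = max_shift_error)
}
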