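#' Treatment configuration
#'
#' A treatment is a named composition of the processing stages: peak
#' detection threshold, optional normalization of replicate profiles,
#' replicate alignment with duplicate resolution, consensus profile
#' construction, optional normalization of consensus profiles, alignment
#' of the consensus profiles (moving-average or integer) with optional
#' systematic shift correction, classification, optional removal of
#' ambiguous bins, and finally the relative abundance and similarity
#' matrices.
#'
#' @param name Unique treatment name.
#' @param pdt Peak detection threshold (fluorescence units).
#' @param normalize_replicates `NULL`, or a normalization preset name
#'   (`"tfn-heights"`, `"tfn-areas"`, `"tfn-areas-lt"`, `"fpt-heights"`,
#'   `"fpt-areas"`) or [normalization_config()] applied to replicate
#'   profiles within each sample.
#' @param consensus Build consensus profiles from the replicates of each
#'   sample.
#' @param min_presence Bin presence rule for the consensus (see
#'   [build_consensus()]).
#' @param normalize_consensus Like `normalize_replicates`, applied to the
#'   consensus profiles across the whole dataset.
#' @param alignment `"moving_average"` or `"integer"`.
#' @param shift_correction Correct systematic size-estimation shifts
#'   before the final classification (moving-average alignment only).
#' @param drop_ambiguous Remove bins still classified as ambiguous.
#' @param basis `"height"` or `"area"` - the signal used for abundances
#'   and similarities.
#' @param noise_filter `NULL`, or the name of an external noise filter
#'   the input must already have passed through (`"abdo"` for the
#'   T-REX-style treatments; [run_treatment()] then requires
#'   `assume_prefiltered = TRUE`).
#' @param binning [binning_params()] for all alignment steps.
#' @return An object of class `treatment_config`.
#' @export
treatment_config <- function(name,
                             pdt = 50,
                             normalize_replicates = NULL,
                             consensus = TRUE,
                             min_presence = "all",
                             normalize_consensus = NULL,
                             alignment = c("moving_average", "integer"),
                             shift_correction = TRUE,
                             drop_ambiguous = TRUE,
                             basis = c("height", "area"),
                             noise_filter = NULL,
                             binning = binning_params()) {
  alignment <- match.arg(alignment)
  basis <- match.arg(basis)
  if (alignment == "integer" && shift_correction)
    stop("invalid treatment_config: integer alignment has no sub-base ",
         "size resolution, so shift correction cannot be combined with it",
         call. = FALSE)
  norm <- function(x) {
    if (is.null(x) || inherits(x, "normalization_config")) x
    else normalization_preset(x)
  }
  structure(list(name = name, pdt = pdt,
                 normalize_replicates = norm(normalize_replicates),
                 consensus = consensus, min_presence = min_presence,
                 normalize_consensus = norm(normalize_consensus),
                 alignment = alignment,
                 shift_correction = shift_correction,
                 drop_ambiguous = drop_ambiguous, basis = basis,
                 noise_filter = noise_filter, binning = binning),
            class = "treatment_config")
}

#' Registry of the nine named treatments
#'
#' The shipped presets combine PDT, alignment correction and
#' normalization the way the evaluated processing strategies do.
#' `PDT50 TFN-A` and `PDT50 TFN-H` normalize consensus profiles with
#' TFN on areas or heights; `PDT50 NoNorm` aligns and corrects without
#' normalizing; `PDT50 NoNorm NoAlCorr` also skips the shift correction;
#' `PDT100 TFN-H` raises the detection threshold; `PDT100 TFN-H RepNorm`
#' additionally normalizes the replicate profiles before the consensus.
#' The `TRex-A` and `TRex-H` presets reproduce only the downstream
#' composition of the T-REX-style analyses: they require input that has
#' already passed the external noise filter, average replicates instead
#' of intersecting them, and skip shift correction; `TRex-H Round-up`
#' additionally uses integer binning.
#'
#' @return Named list of [treatment_config()] objects.
#' @export
treatment_presets <- function() {
  p <- list(
    treatment_config("PDT50 TFN-A", pdt = 50,
                     normalize_consensus = "tfn-areas", basis = "area"),
    treatment_config("PDT50 TFN-H", pdt = 50,
                     normalize_consensus = "tfn-heights"),
    treatment_config("PDT50 NoNorm", pdt = 50),
    treatment_config("PDT50 NoNorm NoAlCorr", pdt = 50,
                     shift_correction = FALSE),
    treatment_config("PDT100 TFN-H", pdt = 100,
                     normalize_consensus = "tfn-heights"),
    treatment_config("PDT100 TFN-H RepNorm", pdt = 100,
                     normalize_replicates = "tfn-heights",
                     normalize_consensus = "tfn-heights"),
    treatment_config("TRex-A", pdt = 0, noise_filter = "abdo",
                     min_presence = 1, shift_correction = FALSE,
                     drop_ambiguous = FALSE, basis = "area"),
    treatment_config("TRex-H", pdt = 0, noise_filter = "abdo",
                     min_presence = 1, shift_correction = FALSE,
                     drop_ambiguous = FALSE),
    treatment_config("TRex-H Round-up", pdt = 0, noise_filter = "abdo",
                     min_presence = 1, alignment = "integer",
                     shift_correction = FALSE, drop_ambiguous = FALSE)
  )
  names(p) <- vapply(p, `[[`, character(1), "name")
  p
}

# Mean peak count and mean TF of a profile set (internal stage metric).
stage_metrics <- function(profiles, basis) {
  counts <- vapply(profiles, n_peaks, numeric(1))
  tfs <- vapply(profiles, function(p)
    if (nrow(p$peaks) == 0) 0 else total_fluorescence(p, basis),
    numeric(1))
  c(mean_n_trfs = mean(counts), mean_tf = mean(tfs))
}

#' Run a treatment pipeline end to end
#'
#' Applies the stages of a [treatment_config()] in order and returns the
#' relative abundance matrix, both similarity matrices, the final
#' alignment and a stage report recording the mean number of T-RFs and
#' mean total fluorescence after every stage.
#'
#' @param profiles Named list of replicate-level [trf_profile()]
#'   objects; replicates are grouped by their `sample_id`.
#' @param config A [treatment_config()].
#' @param assume_prefiltered Assert that the input already passed the
#'   external noise filter a `noise_filter` treatment requires.
#' @return A list of class `treatment_result`: `abundance`, `jaccard`,
#'   `bray_curtis`, `alignment`, `profiles` (the final profile set),
#'   `stages` (data frame), `config`.
#' @export
run_treatment <- function(profiles, config, assume_prefiltered = FALSE) {
  profiles <- as_profile_list(profiles)
  stopifnot(inherits(config, "treatment_config"))
  if (!is.null(config$noise_filter) && !assume_prefiltered)
    stop("treatment '", config$name, "' requires input pre-filtered by ",
         "the external noise filter '", config$noise_filter,
         "'; pass assume_prefiltered = TRUE if that has been done",
         call. = FALSE)
  basis <- config$basis
  detection <- detection_config(pdt = config$pdt)
  stages <- list()
  note <- function(stage, profs)
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, t(stage_metrics(profs, basis)),
      stringsAsFactors = FALSE)
  note("input", profiles)
  # 1. detection threshold and analysis range
  profiles <- lapply(profiles, apply_detection_threshold, detection)
  note(sprintf("pdt_%g", config$pdt), profiles)
  samples <- vapply(profiles, function(p) p$sample_id, character(1))
  # 2. normalization of replicate profiles (within each sample)
  if (!is.null(config$normalize_replicates)) {
    nc <- config$normalize_replicates
    if (nc$method == "TFN") {
      profiles <- tfn_normalize(profiles, nc, detection,
                                groups = samples)
    } else {
      profiles <- lapply(profiles, fpt_normalize, nc)
    }
    note("replicate_normalization", profiles)
  }
  # 3. replicate alignment + duplicate resolution, consensus per sample
  if (config$consensus) {
    cons <- lapply(unique(samples), function(s) {
      reps <- profiles[samples == s]
      if (length(reps) == 1) return(reps[[1]])
      al <- moving_average_bin(reps, config$binning)
      if (length(reps) == 2)
        al <- resolve_duplicate_ambiguity(al)
      build_consensus(reps, al, config$min_presence, profile_id = s)
    })
    names(cons) <- unique(samples)
    profiles <- cons
    note("consensus", profiles)
  }
  # 4. normalization of consensus profiles (dataset-wide)
  if (!is.null(config$normalize_consensus)) {
    nc <- config$normalize_consensus
    if (nc$method == "TFN") {
      profiles <- tfn_normalize(profiles, nc, detection)
    } else {
      profiles <- lapply(profiles, fpt_normalize, nc)
    }
    note("consensus_normalization", profiles)
  }
  # 5. final alignment (+ shift correction) and classification
  correction <- NULL
  if (config$alignment == "integer") {
    alignment <- integer_bin(profiles)
    alignment <- classify_bins(alignment,
                               config$binning$ambiguity_range)
  } else {
    alignment <- moving_average_bin(profiles, config$binning)
    alignment <- classify_bins(alignment)
    if (config$shift_correction && length(profiles) > 1) {
      corrected <- correct_systematic_shift(profiles, alignment,
                                            config$binning)
      profiles <- corrected$profiles
      alignment <- corrected$alignment
      correction <- corrected$correction
    }
  }
  # 6. drop bins still ambiguous
  if (config$drop_ambiguous)
    alignment <- drop_ambiguous_bins(alignment)
  aligned_counts <- table(factor(alignment$members$profile_id,
                                 levels = names(profiles)))
  aligned_profiles <- lapply(profiles, function(p) {
    keep_sizes <- alignment$members$size_original[
      alignment$members$profile_id == p$profile_id]
    p$peaks <- p$peaks[p$peaks$size %in% keep_sizes, , drop = FALSE]
    p
  })
  note("alignment", aligned_profiles)
  # 7. abundance and similarity matrices
  abundance <- build_abundance_matrix(profiles, alignment, basis)
  jac <- similarity_matrix(abundance, "jaccard")
  bc <- similarity_matrix(abundance, "bray_curtis")
  structure(list(abundance = abundance, jaccard = jac,
                 bray_curtis = bc, alignment = alignment,
                 profiles = profiles, correction = correction,
                 stages = do.call(rbind, stages), config = config),
            class = "treatment_result")
}

#' @export
print.treatment_result <- function(x, ...) {
  cat("<treatment_result> '", x$config$name, "': ",
      nrow(x$abundance), " bins x ", ncol(x$abundance),
      " profiles\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
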