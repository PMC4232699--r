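#' Detect a systematic size-estimation shift between two profiles
#'
#' Size estimates of the same fragment vary between electrophoresis runs,
#' and the variation is often systematic: all T-RFs of one profile are
#' estimated slightly longer than the corresponding T-RFs of another. A
#' pair is reported as shifted when, over the bins shared by the two
#' profiles, all nonzero size differences carry the same sign and at
#' least one difference is nonzero. Zero differences are sign-neutral;
#' identical estimates are not evidence of a shift.
#'
#' @param a,b Profile identifiers present in `alignment`.
#' @param alignment A `trf_alignment` containing both profiles.
#' @return A list of class `shift_report`: `pair`, `shared_bins`,
#'   `differences` (size of `b` minus size of `a`, per shared bin),
#'   `shifted`, `direction` (`"b_longer"`, `"a_longer"` or `NA`) and
#'   `mean_offset` (mean signed difference in bases).
#' @export
detect_pairwise_shift <- function(a, b, alignment) {
  stopifnot(inherits(alignment, "trf_alignment"))
  if (!all(c(a, b) %in% alignment$profile_ids))
    stop("profiles '", a, "' and '", b, "' must both be in the alignment",
         call. = FALSE)
  m <- alignment$members
  ma <- m[m$profile_id == a, c("bin_id", "size")]
  mb <- m[m$profile_id == b, c("bin_id", "size")]
  shared <- merge(ma, mb, by = "bin_id", suffixes = c("_a", "_b"))
  shared <- shared[order(shared$bin_id), , drop = FALSE]
  if (nrow(shared) == 0) {
    warning("profiles '", a, "' and '", b, "' share no alignment bins",
            call. = FALSE)
    return(structure(list(pair = c(a, b), shared_bins = 0L,
                          differences = numeric(), shifted = FALSE,
                          direction = NA_character_,
                          mean_offset = NA_real_),
                     class = "shift_report"))
  }
  d <- shared$size_b - shared$size_a
  nz <- d[d != 0]
  shifted <- length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  direction <- if (!shifted) NA_character_
  else if (all(nz > 0)) "b_longer" else "a_longer"
  structure(list(pair = c(a, b), shared_bins = nrow(shared),
                 differences = d, shifted = shifted,
                 direction = direction, mean_offset = mean(d)),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report> ", x$pair[1], " vs ", x$pair[2], ": ",
      x$shared_bins, " shared bins; ",
      if (x$shifted) paste0("systematic shift (", x$direction,
                            ", mean offset ",
                            format(x$mean_offset, digits = 3), " bases)")
      else "no systematic shift", "\n", sep = "")
  invisible(x)
}

#' Count systematically shifted profile pairs
#'
#' Applies [detect_pairwise_shift()] to every unordered pair of profiles
#' in the alignment. For n profiles there are n(n-1)/2 pairs.
#'
#' @param alignment A `trf_alignment` of at least two profiles.
#' @return A list with `total_pairs` and `shifted_pairs`.
#' @export
count_shifted_pairs <- function(alignment) {
  stopifnot(inherits(alignment, "trf_alignment"))
  ids <- alignment$profile_ids
  if (length(ids) < 2)
    stop("count_shifted_pairs() needs at least two profiles", call. = FALSE)
  total <- 0L
  shifted <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq.int(i + 1L, length(ids))) {
      total <- total + 1L
      rep <- suppressWarnings(detect_pairwise_shift(ids[i], ids[j],
                                                    alignment))
      if (rep$shifted) shifted <- shifted + 1L
    }
  }
  list(total_pairs = total, shifted_pairs = shifted)
}

#' Correct systematic shifts in fragment size estimation
#'
#' The correction assumes each profile's size estimates are offset from
#' the others by a constant number of bases. A T-RF present in all
#' profiles, in a bin classified as correct, serves as the reference: its
#' size is set to the same value in all profiles (the mean of its
#' observed sizes) and every other size in each profile is moved by that
#' profile's offset. Every eligible reference is tried; candidates are
#' scored by the sum, over unambiguously binned T-RFs, of the standard
#' deviation of the corrected member sizes, and the reference with the
#' lowest sum wins (ties go to the smaller mean size). The profiles are
#' then re-aligned on the corrected sizes and the new alignment is
#' re-classified.
#'
#' Corrected sizes are stored in a `size_corrected` column alongside the
#' original estimates, which are never overwritten; the correction is
#' relative to the profile set at hand.
#'
#' @param profiles The aligned profiles.
#' @param alignment A classified `trf_alignment` of those profiles, built
#'   on original sizes.
#' @param params [binning_params()] for the re-alignment.
#' @param allow_ambiguous_reference If `TRUE`, bins present in all
#'   profiles qualify as reference candidates regardless of status.
#' @return A list: `profiles` (with corrected sizes), `correction`
#'   (reference bin, per-profile offsets, score), and `alignment` (the
#'   re-binned, re-classified alignment on corrected sizes).
#' @export
correct_systematic_shift <- function(profiles, alignment,
                                     params = binning_params(),
                                     allow_ambiguous_reference = FALSE) {
  profiles <- as_profile_list(profiles)
  stopifnot(inherits(alignment, "trf_alignment"))
  if (!setequal(names(profiles), alignment$profile_ids))
    stop("the alignment must cover exactly the supplied profiles",
         call. = FALSE)
  if (anyNA(alignment$bins$status))
    alignment <- classify_bins(alignment, params$ambiguity_range)
  bins <- alignment$bins
  m <- alignment$members
  n_prof <- length(profiles)
  complete <- bins$bin_id[bins$n_members == n_prof]
  candidates <- if (allow_ambiguous_reference) complete
  else intersect(complete, bins$bin_id[bins$status == "correct"])
  if (length(candidates) == 0)
    stop("no reference candidate: no ", if (!allow_ambiguous_reference)
      "correct " else "", "bin has a member in every profile; ",
      "consider allow_ambiguous_reference = TRUE or more profiles",
      call. = FALSE)
  correct_ids <- bins$bin_id[bins$status == "correct"]
  ids <- names(profiles)
  # per-bin member sizes, indexed by profile, for the scoring loop
  score_candidate <- function(ref) {
    refm <- m[m$bin_id == ref, , drop = FALSE]
    common <- mean(refm$size)
    off <- stats::setNames(common - refm$size, refm$profile_id)[ids]
    corrected <- m$size + off[m$profile_id]
    sds <- tapply(corrected[m$bin_id %in% correct_ids],
                  m$bin_id[m$bin_id %in% correct_ids],
                  function(x) if (length(x) > 1) stats::sd(x) else 0)
    list(offsets = off, score = sum(sds))
  }
  scored <- lapply(candidates, score_candidate)
  scores <- vapply(scored, `[[`, numeric(1), "score")
  mean_sizes <- bins$mean_size[match(candidates, bins$bin_id)]
  best <- order(scores, mean_sizes)[1L]
  winner <- candidates[best]
  offsets <- scored[[best]]$offsets
  corrected_profiles <- lapply(profiles, function(p) {
    p$peaks$size_corrected <- p$peaks$size + offsets[[p$profile_id]]
    add_provenance(p, sprintf(
      "shift_correction(reference_bin=%d): offset %+0.4g bases",
      winner, offsets[[p$profile_id]]))
  })
  names(corrected_profiles) <- ids
  new_al <- moving_average_bin(corrected_profiles, params,
                               size_basis = "corrected")
  new_al <- classify_bins(new_al, params$ambiguity_range)
  correction <- structure(list(reference_bin = winner,
                               per_profile_offset = offsets,
                               score = scores[best],
                               candidate_bins = candidates,
                               candidate_scores = scores),
                          class = "shift_correction")
  list(profiles = corrected_profiles, correction = correction,
       alignment = new_al)
}

#' @export
print.shift_correction <- function(x, ...) {
  cat("<shift_correction> reference bin ", x$reference_bin,
      " (score ", format(x$score, digits = 4), ")\n", sep = "")
  cat("  offsets (bases):\n")
  print(round(x$per_profile_offset, 4))
  invisible(x)
}
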