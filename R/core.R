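#' Peak detection settings
#'
#' Holds the peak detection threshold (PDT) and the analysis range used to
#' filter raw peak tables. The PDT is the lowest acceptable peak height in
#' fluorescence units; peaks with a height equal to the threshold are kept.
#' The analysis range restricts fragment sizes to the interval over which
#' the size standard gives reliable estimates.
#'
#' @param pdt Minimum acceptable peak height (fluorescence units).
#'   Commonly 50 (intermediate) or 100 (strict).
#' @param range_min,range_max Analysis range bounds in bases (inclusive).
#' @return An object of class `detection_config`.
#' @examples
#' detection_config(pdt = 100)
#' @export
detection_config <- function(pdt = 50, range_min = 50, range_max = 1020) {
  if (!is.numeric(pdt) || length(pdt) != 1L || is.na(pdt) || pdt < 0)
    stop("invalid detection_config: 'pdt' must be a single number >= 0",
         call. = FALSE)
  if (!is.numeric(range_min) || !is.numeric(range_max) ||
      length(range_min) != 1L || length(range_max) != 1L ||
      is.na(range_min) || is.na(range_max) ||
      range_min <= 0 || range_min >= range_max)
    stop("invalid detection_config: requires 0 < range_min < range_max",
         call. = FALSE)
  structure(list(pdt = pdt, range_min = range_min, range_max = range_max),
            class = "detection_config")
}

#' Moving-average binning parameters
#'
#' Parameters of the moving-average alignment procedure. A bin is seeded
#' with the shortest unbinned fragment; all fragments at most `y` bases
#' longer join the bin, and the bin is then repeatedly extended with
#' fragments at most `z` bases longer than the current bin mean.
#' `ambiguity_range` is the inter-bin proximity below which a bin is
#' classified as ambiguous; it defaults to the seed window `y`.
#'
#' @param y Seed inclusion window (bases).
#' @param z Mean-relative extension window (bases); must not exceed `y`.
#' @param ambiguity_range Inter-bin proximity threshold (bases).
#' @return An object of class `binning_params`.
#' @export
binning_params <- function(y = 1, z = 0.5, ambiguity_range = y) {
  vals <- c(y = y, z = z, ambiguity_range = ambiguity_range)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0))
    stop("invalid binning_params: 'y', 'z' and 'ambiguity_range' must all be > 0",
         call. = FALSE)
  if (z > y)
    stop("invalid binning_params: 'z' must not exceed 'y' (z <= y)",
         call. = FALSE)
  structure(list(y = y, z = z, ambiguity_range = ambiguity_range),
            class = "binning_params")
}

#' Construct a T-RF profile
#'
#' A profile is the set of terminal restriction fragments (T-RFs) detected
#' for one loading of one sample: fragment size estimates in bases with the
#' corresponding peak heights and areas in fluorescence units. Peaks are
#' stored sorted by ascending size; duplicate sizes within a profile are a
#' read error. A profile may carry a parallel vector of shift-corrected
#' sizes (see [correct_systematic_shift()]); corrected sizes never
#' overwrite the original estimates.
#'
#' @param profile_id Unique profile label.
#' @param peaks A data frame with numeric columns `size`, `height` and
#'   optionally `area` (`NA` allowed for missing areas). A
#'   `size_corrected` column is accepted and preserved.
#' @param sample_id Source sample label (defaults to `profile_id`).
#' @param replicate Replicate / loading tag.
#' @param provenance Character vector logging the transformations applied.
#' @return An object of class `trf_profile`.
#' @examples
#' trf_profile("s1", data.frame(size = c(102.3, 240.8),
#'                              height = c(500, 120),
#'                              area = c(5200, 1100)))
#' @export
trf_profile <- function(profile_id, peaks, sample_id = profile_id,
                        replicate = "1", provenance = character()) {
  if (!is.character(profile_id) || length(profile_id) != 1L ||
      is.na(profile_id) || !nzchar(profile_id))
    stop("invalid profile: 'profile_id' must be a non-empty string",
         call. = FALSE)
  if (!is.data.frame(peaks))
    stop("invalid profile: 'peaks' must be a data frame", call. = FALSE)
  if (!all(c("size", "height") %in% names(peaks)))
    stop("invalid profile: 'peaks' requires columns 'size' and 'height'",
         call. = FALSE)
  if (!("area" %in% names(peaks)))
    peaks$area <- rep(NA_real_, nrow(peaks))
  peaks <- peaks[, intersect(c("size", "height", "area", "size_corrected"),
                             names(peaks)), drop = FALSE]
  peaks$size <- as.numeric(peaks$size)
  peaks$height <- as.numeric(peaks$height)
  peaks$area <- as.numeric(peaks$area)
  if (nrow(peaks) > 0) {
    if (anyNA(peaks$size) || any(peaks$size <= 0))
      stop("invalid profile '", profile_id,
           "': peak sizes must be positive numbers", call. = FALSE)
    if (anyNA(peaks$height) || any(peaks$height <= 0))
      stop("invalid profile '", profile_id,
           "': peak heights must be positive numbers", call. = FALSE)
    if (any(!is.na(peaks$area) & peaks$area <= 0))
      stop("invalid profile '", profile_id,
           "': peak areas must be positive where present", call. = FALSE)
    peaks <- peaks[order(peaks$size), , drop = FALSE]
    if (anyDuplicated(peaks$size))
      stop("invalid profile '", profile_id,
           "': duplicate peak sizes (sizes must be strictly increasing)",
           call. = FALSE)
  }
  rownames(peaks) <- NULL
  structure(list(profile_id = profile_id, sample_id = sample_id,
                 replicate = as.character(replicate), peaks = peaks,
                 provenance = as.character(provenance)),
            class = "trf_profile")
}

#' @export
print.trf_profile <- function(x, ...) {
  cat("<trf_profile> ", x$profile_id, " (sample ", x$sample_id,
      ", replicate ", x$replicate, ")\n", sep = "")
  cat("  peaks: ", nrow(x$peaks), sep = "")
  if (nrow(x$peaks) > 0)
    cat(", sizes ", format(min(x$peaks$size), digits = 6), "-",
        format(max(x$peaks$size), digits = 6), " bases", sep = "")
  cat("\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

# Append a provenance entry to a profile (internal).
add_provenance <- function(profile, msg) {
  profile$provenance <- c(profile$provenance, msg)
  profile
}

#' Number of peaks in a profile
#'
#' @param profile A [trf_profile()].
#' @return Integer peak count.
#' @export
n_peaks <- function(profile) {
  stopifnot(inherits(profile, "trf_profile"))
  nrow(profile$peaks)
}

# Validate a list of profiles and return it named by profile_id (internal).
as_profile_list <- function(profiles) {
  if (inherits(profiles, "trf_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) == 0 ||
      !all(vapply(profiles, inherits, logical(1), "trf_profile")))
    stop("expected a non-empty list of 'trf_profile' objects", call. = FALSE)
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  if (anyDuplicated(ids))
    stop("profile ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(profiles) <- ids
  profiles
}

# Sizes on the requested basis (internal). basis: "original" or "corrected".
profile_sizes <- function(profile, size_basis = "original") {
  if (size_basis == "original") return(profile$peaks$size)
  if (size_basis == "corrected") {
    if (is.null(profile$peaks$size_corrected))
      stop("profile '", profile$profile_id,
           "' has no corrected sizes; run correct_systematic_shift() first",
           call. = FALSE)
    return(profile$peaks$size_corrected)
  }
  stop("unknown size_basis: ", size_basis, call. = FALSE)
}

#' Construct an alignment from bin membership
#'
#' Internal constructor shared by the binning routines. `members` is a
#' data frame with one row per binned peak and columns `bin_id`,
#' `profile_id`, `size` (size on the alignment basis) and `size_original`.
#' Bins are renumbered in ascending order of their mean size and the
#' one-peak-per-profile invariant is enforced.
#'
#' @keywords internal
new_alignment <- function(members, profile_ids, params,
                          size_basis = "original", status = NULL) {
  stopifnot(is.data.frame(members),
            all(c("bin_id", "profile_id", "size", "size_original") %in%
                  names(members)))
  if (nrow(members) > 0) {
    dup <- duplicated(members[, c("bin_id", "profile_id")])
    if (any(dup))
      stop("invalid alignment: a profile may have at most one T-RF per bin",
           call. = FALSE)
  }
  if (nrow(members) == 0) {
    bins <- data.frame(bin_id = integer(), mean_size = numeric(),
                       n_members = integer(), status = character(),
                       stringsAsFactors = FALSE)
    return(structure(list(bins = bins, members = members,
                          profile_ids = profile_ids, params = params,
                          size_basis = size_basis),
                     class = "trf_alignment"))
  }
  means <- tapply(members$size, members$bin_id, mean)
  ord <- order(as.numeric(means))
  old_ids <- as.numeric(names(means))[ord]
  remap <- stats::setNames(seq_along(old_ids), old_ids)
  if (!is.null(status)) {
    stopifnot(length(status) == length(old_ids))
    status <- status[ord]
  } else {
    status <- rep(NA_character_, length(old_ids))
  }
  members$bin_id <- as.integer(remap[as.character(members$bin_id)])
  members <- members[order(members$bin_id, members$profile_id), , drop = FALSE]
  rownames(members) <- NULL
  bins <- data.frame(
    bin_id = seq_along(old_ids),
    mean_size = as.numeric(means)[ord],
    n_members = as.integer(table(members$bin_id)[as.character(seq_along(old_ids))]),
    status = status,
    stringsAsFactors = FALSE
  )
  structure(list(bins = bins, members = members,
                 profile_ids = profile_ids, params = params,
                 size_basis = size_basis),
            class = "trf_alignment")
}

#' Alignment bin summary
#'
#' @param alignment A `trf_alignment`.
#' @return Data frame with one row per bin: `bin_id`, `mean_size` (bases),
#'   `n_members`, `status` (`"correct"`, `"ambiguous"` or `NA` before
#'   classification).
#' @export
alignment_bins <- function(alignment) {
  stopifnot(inherits(alignment, "trf_alignment"))
  alignment$bins
}

#' Alignment membership table
#'
#' @param alignment A `trf_alignment`.
#' @return Data frame with one row per binned peak: `bin_id`, `profile_id`,
#'   `size` (on the alignment size basis) and `size_original`.
#' @export
alignment_members <- function(alignment) {
  stopifnot(inherits(alignment, "trf_alignment"))
  alignment$members
}

#' @export
print.trf_alignment <- function(x, ...) {
  n_amb <- sum(x$bins$status == "ambiguous", na.rm = TRUE)
  cat("<trf_alignment> ", nrow(x$bins), " bins over ",
      length(x$profile_ids), " profiles (", x$size_basis, " sizes)\n",
      sep = "")
  if (all(is.na(x$bins$status))) {
    cat("  status: unclassified\n")
  } else {
    cat("  status: ", sum(x$bins$status == "correct", na.rm = TRUE),
        " correct, ", n_amb, " ambiguous\n", sep = "")
  }
  invisible(x)
}

# Constructor for relative abundance matrices (internal): bins x profiles,
# each non-degenerate column sums to 1.
new_abundance_matrix <- function(values, mean_sizes, basis) {
  stopifnot(is.matrix(values))
  sums <- colSums(values)
  live <- sums > 0
  if (any(live) && any(abs(sums[live] - 1) > 1e-9))
    stop("invalid abundance matrix: profile columns must sum to 1",
         call. = FALSE)
  if (any(values < 0) || any(values > 1 + 1e-12))
    stop("invalid abundance matrix: values must lie in [0, 1]", call. = FALSE)
  structure(values, mean_sizes = mean_sizes, basis = basis,
            class = c("trf_abundance", class(values)))
}

# Constructor for similarity matrices (internal).
new_similarity_matrix <- function(values, metric) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12)
    stop("invalid similarity matrix: must be symmetric", call. = FALSE)
  if (any(abs(diag(values) - 1) > 1e-12))
    stop("invalid similarity matrix: diagonal must equal 1", call. = FALSE)
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("invalid similarity matrix: values must lie in [0, 1]", call. = FALSE)
  structure(values, metric = metric,
            class = c("trf_similarity", class(values)))
}
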