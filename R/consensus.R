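#' Build a consensus profile from replicates
#'
#' Combines replicate profiles into one consensus profile by keeping the
#' alignment bins represented in at least `min_presence` replicates and
#' averaging the size, height and area of the member T-RFs. With the
#' default `min_presence = "all"` only fragments observed in every
#' replicate are kept - the conservative rule normally used with two PCR
#' or loading replicates.
#'
#' @param replicates List of [trf_profile()] objects.
#' @param alignment A `trf_alignment` covering exactly those replicates.
#' @param min_presence `"all"` or an integer number of replicates a bin
#'   must reach.
#' @param profile_id Identifier for the consensus profile; defaults to
#'   the common `sample_id` of the replicates (or their ids joined by
#'   `"+"`).
#' @return A [trf_profile()] whose peaks are the bin-wise means. Averages
#'   are unweighted means over the members actually present, not over all
#'   replicates. Zero qualifying bins yield an empty profile with a
#'   warning.
#' @export
build_consensus <- function(replicates, alignment, min_presence = "all",
                            profile_id = NULL) {
  replicates <- as_profile_list(replicates)
  stopifnot(inherits(alignment, "trf_alignment"))
  if (!setequal(names(replicates), alignment$profile_ids))
    stop("the alignment must cover exactly the supplied replicates",
         call. = FALSE)
  n_rep <- length(replicates)
  if (identical(min_presence, "all")) min_presence <- n_rep
  if (!is.numeric(min_presence) || min_presence < 1 ||
      min_presence > n_rep)
    stop("'min_presence' must be \"all\" or an integer in [1, ",
         n_rep, "]", call. = FALSE)
  sample_ids <- unique(vapply(replicates, function(p) p$sample_id,
                              character(1)))
  if (is.null(profile_id))
    profile_id <- if (length(sample_ids) == 1) sample_ids
  else paste(names(replicates), collapse = "+")
  m <- alignment$members
  qual <- alignment$bins$bin_id[alignment$bins$n_members >= min_presence]
  if (length(qual) == 0) {
    warning("no alignment bin reaches min_presence = ", min_presence,
            "; consensus profile '", profile_id, "' is empty",
            call. = FALSE)
    empty <- data.frame(size = numeric(), height = numeric(),
                        area = numeric())
    return(trf_profile(profile_id, empty, sample_id = sample_ids[1],
                       replicate = "consensus",
                       provenance = sprintf(
                         "consensus(min_presence=%d) of: %s", min_presence,
                         paste(names(replicates), collapse = ", "))))
  }
  rows <- lapply(qual, function(b) {
    mb <- m[m$bin_id == b, , drop = FALSE]
    vals <- do.call(rbind, lapply(seq_len(nrow(mb)), function(k) {
      p <- replicates[[mb$profile_id[k]]]
      i <- match_size(p$peaks$size, mb$size_original[k])
      p$peaks[i, c("size", "height", "area"), drop = FALSE]
    }))
    data.frame(size = mean(vals$size), height = mean(vals$height),
               area = if (anyNA(vals$area)) NA_real_ else mean(vals$area))
  })
  peaks <- do.call(rbind, rows)
  trf_profile(profile_id, peaks, sample_id = sample_ids[1],
              replicate = "consensus",
              provenance = sprintf(
                "consensus(min_presence=%d) of: %s", min_presence,
                paste(names(replicates), collapse = ", ")))
}

# Locate a peak by its original size (internal); sizes are carried at
# full precision so an exact-with-tolerance match is reliable.
match_size <- function(sizes, target) {
  i <- which(abs(sizes - target) < 1e-9)
  if (length(i) != 1)
    stop("internal error: could not match peak of size ", target,
         " back to its profile", call. = FALSE)
  i
}
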