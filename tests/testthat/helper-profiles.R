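# Shared fixture builders. All fixtures are constructed in code.

make_profile <- function(id, sizes, heights = NULL, areas = NULL,
                         sample_id = id, replicate = "1") {
  if (is.null(heights)) heights <- rep(1000, length(sizes))
  if (is.null(areas)) areas <- heights * 10
  trf_profile(id, data.frame(size = sizes, height = heights, area = areas),
              sample_id = sample_id, replicate = replicate)
}

# Random small profile sets with sizes crowded into a narrow window so
# that binning decisions actually interact. Sizes are rounded to one
# decimal (like real size-caller output) but kept distinct per profile.
random_profile_set <- function(n_profiles, max_peaks_total, lo = 100,
                               hi = 103) {
  repeat {
    n_peaks <- sample.int(max_peaks_total, 1)
    owner <- sort(sample.int(n_profiles, n_peaks, replace = TRUE))
    sizes <- round(runif(n_peaks, lo, hi), 1)
    ok <- !any(vapply(split(sizes, owner), anyDuplicated, integer(1)) > 0)
    if (ok && length(unique(owner)) >= 1) {
      return(lapply(seq_len(n_profiles), function(i) {
        s <- sort(sizes[owner == i])
        if (length(s) == 0)
          return(NULL)
        make_profile(paste0("P", i), s)
      }))
    }
  }
}

# Canonical string form of a set of bins (sets of "profile@size" keys),
# order-independent, for comparing alignments across implementations.
bin_signature <- function(alignment) {
  m <- alignment_members(alignment)
  keys <- paste0(m$profile_id, "@", sprintf("%.6f", m$size_original))
  sets <- split(keys, m$bin_id)
  paste(sort(vapply(sets, function(s) paste(sort(s), collapse = "|"),
                    character(1))), collapse = " || ")
}
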