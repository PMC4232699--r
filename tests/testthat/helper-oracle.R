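# Independent oracle: a literal, deliberately naive re-execution of the
# published moving-average binning procedure, written against a flat
# peak table and sharing no code with the package implementation.
#
# peaks: data frame with integer column `profile` (input order rank),
# numeric `size` and unique integer `id`. Returns a list of sorted id
# vectors, one per bin. Tie-break rules match the package's documented
# choices: exact size ties processed in profile input order; when a
# profile has several candidates inside a window the one closest to the
# current reference (seed, then bin mean) wins, ties to the shorter.
oracle_moving_average <- function(peaks, y = 1, z = 0.5) {
  peaks$done <- FALSE
  bins <- list()
  repeat {
    todo <- peaks[!peaks$done, , drop = FALSE]
    if (nrow(todo) == 0) break
    todo <- todo[order(todo$size, todo$profile), , drop = FALSE]
    seed <- todo[1, ]
    bin <- seed$id
    peaks$done[peaks$id == seed$id] <- TRUE
    # the seed window: every T-RF at most y longer than the seed
    w <- peaks[!peaks$done & peaks$size <= seed$size + y, , drop = FALSE]
    if (nrow(w) > 0) {
      for (pr in unique(w$profile[order(w$size, w$profile)])) {
        in_bin <- peaks$profile[peaks$id %in% bin]
        if (pr %in% in_bin) next
        cand <- w[w$profile == pr, , drop = FALSE]
        cand <- cand[order(abs(cand$size - seed$size), cand$size), ,
                     drop = FALSE]
        bin <- c(bin, cand$id[1])
        peaks$done[peaks$id == cand$id[1]] <- TRUE
      }
    }
    # extension: grow by one T-RF within z of the mean, recompute, retry
    repeat {
      mu <- mean(peaks$size[peaks$id %in% bin])
      in_bin <- peaks$profile[peaks$id %in% bin]
      w <- peaks[!peaks$done & peaks$size <= mu + z &
                   !(peaks$profile %in% in_bin), , drop = FALSE]
      if (nrow(w) == 0) break
      winners <- do.call(rbind, lapply(split(w, w$profile), function(cc) {
        cc[order(abs(cc$size - mu), cc$size), , drop = FALSE][1, ]
      }))
      winners <- winners[order(winners$size, winners$profile), ,
                         drop = FALSE]
      bin <- c(bin, winners$id[1])
      peaks$done[peaks$id == winners$id[1]] <- TRUE
    }
    bins[[length(bins) + 1]] <- sort(bin)
  }
  bins
}

# Run both implementations on a profile list and compare bin sets.
oracle_agrees <- function(profiles, params = binning_params()) {
  profiles <- Filter(Negate(is.null), profiles)
  tab <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    data.frame(profile = i, label = profiles[[i]]$profile_id,
               size = profiles[[i]]$peaks$size)
  }))
  tab$id <- seq_len(nrow(tab))
  expected <- oracle_moving_average(tab, params$y, params$z)
  exp_sig <- paste(sort(vapply(expected, function(ids) {
    paste(sort(paste0(tab$label[tab$id %in% ids], "@",
                      sprintf("%.6f", tab$size[tab$id %in% ids]))),
          collapse = "|")
  }, character(1))), collapse = " || ")
  got_sig <- bin_signature(moving_average_bin(profiles, params))
  identical(exp_sig, got_sig)
}

# Brute-force reclassification oracle: a bin is ambiguous iff the
# smallest cross-bin peak distance involving it is within range.
oracle_classify <- function(alignment, range) {
  m <- alignment_members(alignment)
  bins <- alignment_bins(alignment)$bin_id
  vapply(bins, function(b) {
    mine <- m$size[m$bin_id == b]
    others <- m$size[m$bin_id != b]
    if (length(others) == 0) return("correct")
    if (min(abs(outer(mine, others, "-"))) <= range) "ambiguous"
    else "correct"
  }, character(1))
}
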