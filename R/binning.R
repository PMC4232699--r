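# Flatten a profile list into one peak table on the requested size basis
# (internal). `pid` is the profile input position, used only to break
# exact size ties deterministically.
pool_peaks <- function(profiles, size_basis = "original") {
  tabs <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    n <- nrow(p$peaks)
    data.frame(pid = rep.int(i, n),
               profile_id = rep.int(p$profile_id, n),
               size = profile_sizes(p, size_basis),
               size_original = p$peaks$size,
               height = p$peaks$height,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Align T-RF profiles by moving-average binning
#'
#' Implements the moving-average alignment procedure: the shortest
#' unbinned T-RF over all profiles seeds a new alignment bin; all T-RFs at
#' most `y` bases longer than the seed join it (at most one per profile);
#' the bin mean is then computed and the bin is repeatedly extended with
#' T-RFs at most `z` bases longer than the current mean, recomputing the
#' mean and re-searching after every addition, until no further T-RF
#' qualifies. The process restarts from the shortest remaining T-RF until
#' every peak is binned.
#'
#' A profile may contribute at most one T-RF to a bin. When a profile has
#' several candidates inside a window, the one closest to the current bin
#' mean wins, with ties going to the shorter fragment; exact size ties
#' across profiles are processed in profile input order.
#'
#' @param profiles List of [trf_profile()] objects (at least one peak in
#'   total).
#' @param params A [binning_params()].
#' @param size_basis `"original"` to bin the original size estimates,
#'   `"corrected"` to bin shift-corrected sizes.
#' @return A `trf_alignment` with unclassified bins (see
#'   [classify_bins()]).
#' @seealso [integer_bin()] for the simpler round-to-integer alternative.
#' @export
moving_average_bin <- function(profiles, params = binning_params(),
                               size_basis = c("original", "corrected")) {
  profiles <- as_profile_list(profiles)
  stopifnot(inherits(params, "binning_params"))
  size_basis <- match.arg(size_basis)
  pool <- pool_peaks(profiles, size_basis)
  if (is.null(pool) || nrow(pool) == 0)
    stop("moving_average_bin() needs at least one peak across the profiles",
         call. = FALSE)
  n <- nrow(pool)
  bin_of <- rep.int(NA_integer_, n)
  # process peaks in (size, input order); indexes into pool
  ord <- order(pool$size, pool$pid)
  size <- pool$size[ord]
  pid <- pool$pid[ord]
  bin_id <- 0L
  repeat {
    un <- which(is.na(bin_of))
    if (length(un) == 0) break
    bin_id <- bin_id + 1L
    seed <- un[1L]                      # shortest unbinned (ties: input order)
    bin_of[seed] <- bin_id
    seed_size <- size[seed]
    in_bin_pid <- pid[seed]
    # seed window: all unbinned T-RFs at most y longer than the seed,
    # one per profile (closest to the seed, ties to the shorter)
    win <- which(is.na(bin_of) & size <= seed_size + params$y)
    if (length(win)) {
      for (p in unique(pid[win])) {
        if (p %in% in_bin_pid) next
        cand <- win[pid[win] == p]
        pick <- cand[order(abs(size[cand] - seed_size), size[cand])][1L]
        bin_of[pick] <- bin_id
        in_bin_pid <- c(in_bin_pid, p)
      }
    }
    # extension: repeatedly admit T-RFs within z of the current bin mean,
    # recomputing the mean after every addition
    repeat {
      mu <- mean(size[bin_of == bin_id
                      & !is.na(bin_of)])
      elig <- which(is.na(bin_of) & size <= mu + params$z &
                      !(pid %in% in_bin_pid))
      if (length(elig) == 0) break
      # per-profile winner: closest to the mean, ties to the shorter;
      # then admit the shortest winner first
      best <- vapply(unique(pid[elig]), function(p) {
        cand <- elig[pid[elig] == p]
        cand[order(abs(size[cand] - mu), size[cand])][1L]
      }, integer(1))
      pick <- best[order(size[best], pid[best])][1L]
      bin_of[pick] <- bin_id
      in_bin_pid <- c(in_bin_pid, pid[pick])
    }
  }
  members <- data.frame(bin_id = bin_of,
                        profile_id = pool$profile_id[ord],
                        size = size,
                        size_original = pool$size_original[ord],
                        stringsAsFactors = FALSE)
  new_alignment(members, names(profiles), params, size_basis)
}

#' Classify alignment bins as correct or ambiguous
#'
#' A bin is classified as ambiguous if any of its T-RFs lies within the
#' alignment range of a T-RF in another bin; the relation is symmetric, so
#' both bins involved are flagged. All other bins are classified as
#' correct.
#'
#' @param alignment A `trf_alignment`.
#' @param ambiguity_range Inter-bin proximity threshold in bases
#'   (inclusive); defaults to the alignment's binning parameters.
#' @return The alignment with every bin's `status` set.
#' @export
classify_bins <- function(alignment, ambiguity_range = NULL) {
  stopifnot(inherits(alignment, "trf_alignment"))
  if (is.null(ambiguity_range))
    ambiguity_range <- alignment$params$ambiguity_range
  if (is.null(ambiguity_range) || !is.numeric(ambiguity_range) ||
      ambiguity_range <= 0)
    stop("classify_bins() needs a positive 'ambiguity_range'", call. = FALSE)
  m <- alignment$members
  if (nrow(m) == 0) return(alignment)
  amb <- rep(FALSE, nrow(alignment$bins))
  ord <- order(m$size)
  sz <- m$size[ord]
  bn <- m$bin_id[ord]
  for (i in seq_along(sz)) {
    j <- i + 1L
    while (j <= length(sz) && sz[j] - sz[i] <= ambiguity_range) {
      if (bn[j] != bn[i]) {
        amb[bn[i]] <- TRUE
        amb[bn[j]] <- TRUE
      }
      j <- j + 1L
    }
  }
  alignment$bins$status <- ifelse(amb, "ambiguous", "correct")
  alignment
}

#' Resolve ambiguous bins between two replicate profiles
#'
#' For an alignment of exactly two profiles, ambiguous bins are re-paired
#' by binning the T-RFs that are most similar in size. The moving-average
#' procedure works from shorter to longer fragments and can pair the
#' shorter T-RFs even when the longer ones match better; this routine
#' finds, within each connected cluster of mutually ambiguous bins, the
#' order-preserving pairing of the two profiles' T-RFs that maximizes the
#' number of matched pairs and, among those, minimizes the total absolute
#' size difference. Matched pairs may differ by at most the ambiguity
#' range; unmatched T-RFs get singleton bins. Statuses are recomputed.
#'
#' @param alignment A `trf_alignment` covering exactly two profiles.
#' @param ambiguity_range Pairing tolerance in bases; defaults to the
#'   alignment's binning parameters.
#' @return The corrected, re-classified alignment.
#' @export
resolve_duplicate_ambiguity <- function(alignment, ambiguity_range = NULL) {
  stopifnot(inherits(alignment, "trf_alignment"))
  if (length(alignment$profile_ids) != 2)
    stop("resolve_duplicate_ambiguity() applies to alignments of exactly ",
         "two profiles; for more profiles use correct_systematic_shift()",
         call. = FALSE)
  if (is.null(ambiguity_range))
    ambiguity_range <- alignment$params$ambiguity_range
  if (all(is.na(alignment$bins$status)))
    alignment <- classify_bins(alignment, ambiguity_range)
  amb_ids <- alignment$bins$bin_id[alignment$bins$status == "ambiguous"]
  if (length(amb_ids) == 0) return(alignment)
  m <- alignment$members
  # connected clusters of mutually ambiguous bins (within-range cross
  # peaks), via union-find over positions in amb_ids
  parent <- seq_along(amb_ids)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(amb_ids)) {
    sa <- m$size[m$bin_id == amb_ids[a]]
    for (b in seq_along(amb_ids)) {
      if (b <= a) next
      sb <- m$size[m$bin_id == amb_ids[b]]
      if (min(abs(outer(sa, sb, "-"))) <= ambiguity_range) {
        ra <- root(a); rb <- root(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp_of <- vapply(seq_along(amb_ids), root, integer(1))
  keep <- m[!(m$bin_id %in% amb_ids), , drop = FALSE]
  pids <- alignment$profile_ids
  next_bin <- if (nrow(keep)) max(keep$bin_id) else 0L
  out <- list(keep)
  for (cc in unique(comp_of)) {
    cluster_bins <- amb_ids[comp_of == cc]
    cm <- m[m$bin_id %in% cluster_bins, , drop = FALSE]
    a <- cm[cm$profile_id == pids[1], , drop = FALSE]
    b <- cm[cm$profile_id == pids[2], , drop = FALSE]
    a <- a[order(a$size), , drop = FALSE]
    b <- b[order(b$size), , drop = FALSE]
    pairing <- pair_nearest(a$size, b$size, ambiguity_range)
    rows <- list()
    used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
    for (k in seq_len(nrow(pairing))) {
      next_bin <- next_bin + 1L
      i <- pairing$i[k]; j <- pairing$j[k]
      used_a[i] <- TRUE; used_b[j] <- TRUE
      rows[[length(rows) + 1L]] <-
        rbind(transform(a[i, , drop = FALSE], bin_id = next_bin),
              transform(b[j, , drop = FALSE], bin_id = next_bin))
    }
    for (i in which(!used_a)) {
      next_bin <- next_bin + 1L
      rows[[length(rows) + 1L]] <- transform(a[i, , drop = FALSE],
                                             bin_id = next_bin)
    }
    for (j in which(!used_b)) {
      next_bin <- next_bin + 1L
      rows[[length(rows) + 1L]] <- transform(b[j, , drop = FALSE],
                                             bin_id = next_bin)
    }
    out <- c(out, rows)
  }
  members <- do.call(rbind, out)
  res <- new_alignment(members, pids, alignment$params, alignment$size_basis)
  classify_bins(res, ambiguity_range)
}

# Maximum-cardinality, minimum-total-difference order-preserving pairing of
# two sorted size vectors, pairs constrained to |a - b| <= range (internal).
# Returns a data frame of matched index pairs (i into a, j into b).
pair_nearest <- function(a, b, range) {
  na <- length(a); nb <- length(b)
  INF <- 1e18
  M <- matrix(0L, na + 1L, nb + 1L)   # matches
  C <- matrix(0, na + 1L, nb + 1L)    # total |difference| at that match count
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best_m <- M[i, j + 1L]; best_c <- C[i, j + 1L]; from <- 1L # skip a_i
      if (M[i + 1L, j] > best_m ||
          (M[i + 1L, j] == best_m && C[i + 1L, j] < best_c)) {
        best_m <- M[i + 1L, j]; best_c <- C[i + 1L, j]; from <- 2L # skip b_j
      }
      d <- abs(a[i] - b[j])
      if (d <= range) {
        mm <- M[i, j] + 1L; cc <- C[i, j] + d
        if (mm > best_m || (mm == best_m && cc < best_c)) {
          best_m <- mm; best_c <- cc; from <- 3L
        }
      }
      M[i + 1L, j + 1L] <- best_m
      C[i + 1L, j + 1L] <- best_c
    }
  }
  # traceback (preferring a match when it ties the optimum)
  i <- na; j <- nb
  pi <- integer(); pj <- integer()
  while (i > 0 && j > 0) {
    d <- abs(a[i] - b[j])
    if (d <= range && M[i + 1L, j + 1L] == M[i, j] + 1L &&
        abs(C[i + 1L, j + 1L] - (C[i, j] + d)) < 1e-12) {
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] &&
               C[i + 1L, j + 1L] == C[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  data.frame(i = pi, j = pj)
}

#' Integer (round-up/down) binning
#'
#' The simple alternative to moving-average binning: every T-RF size is
#' rounded to the nearest integer (halves round up) and all T-RFs sharing
#' a rounded size share a bin. Two T-RFs of size 134.4 and 134.6 bases end
#' up in different bins under this rule, which is why the moving-average
#' procedure is normally preferred; integer binning is provided as a
#' comparison treatment. Same-profile collisions keep the taller peak,
#' with a warning.
#'
#' @param profiles List of [trf_profile()] objects.
#' @return An unclassified `trf_alignment` whose params record
#'   `method = "integer"`.
#' @export
integer_bin <- function(profiles) {
  profiles <- as_profile_list(profiles)
  pool <- pool_peaks(profiles, "original")
  if (is.null(pool) || nrow(pool) == 0)
    stop("integer_bin() needs at least one peak across the profiles",
         call. = FALSE)
  pool$label <- floor(pool$size + 0.5)   # round half up
  drop <- logical(nrow(pool))
  for (key in unique(paste(pool$pid, pool$label))) {
    rows <- which(paste(pool$pid, pool$label) == key)
    if (length(rows) > 1) {
      keep <- rows[order(-pool$height[rows], pool$size[rows])][1L]
      drop[setdiff(rows, keep)] <- TRUE
      warning("profile '", pool$profile_id[rows[1]], "': ",
              length(rows), " peaks round to integer size ",
              pool$label[rows[1]], "; keeping the tallest", call. = FALSE)
    }
  }
  pool <- pool[!drop, , drop = FALSE]
  labels <- sort(unique(pool$label))
  members <- data.frame(bin_id = match(pool$label, labels),
                        profile_id = pool$profile_id,
                        size = pool$size,
                        size_original = pool$size_original,
                        stringsAsFactors = FALSE)
  new_alignment(members, names(profiles),
                list(method = "integer", ambiguity_range = NULL), "original")
}

#' Remove ambiguous bins from an alignment
#'
#' Bins that remain classified as ambiguous (even after shift correction)
#' are removed from further analysis, so that similarities between
#' profiles are never based on uncertain alignment binning.
#'
#' @param alignment A classified `trf_alignment`.
#' @return The alignment restricted to correct bins. Removing every bin
#'   yields an empty alignment with a warning.
#' @export
drop_ambiguous_bins <- function(alignment) {
  stopifnot(inherits(alignment, "trf_alignment"))
  if (anyNA(alignment$bins$status))
    stop("drop_ambiguous_bins() requires a classified alignment; ",
         "run classify_bins() first", call. = FALSE)
  n_amb <- sum(alignment$bins$status == "ambiguous")
  if (n_amb == 0) return(alignment)
  keep_ids <- alignment$bins$bin_id[alignment$bins$status == "correct"]
  message("drop_ambiguous_bins: removed ", n_amb, " of ",
          nrow(alignment$bins), " bins")
  members <- alignment$members[alignment$members$bin_id %in% keep_ids, ,
                               drop = FALSE]
  if (nrow(members) == 0)
    warning("all alignment bins were ambiguous; the alignment is empty",
            call. = FALSE)
  status <- alignment$bins$status[alignment$bins$status == "correct"]
  new_alignment(members, alignment$profile_ids, alignment$params,
                alignment$size_basis, status = status)
}
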