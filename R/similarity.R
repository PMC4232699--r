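#' Jaccard similarity of two presence/absence patterns
#'
#' The Jaccard coefficient puts equal weight on all T-RFs regardless of
#' abundance: shared T-RFs divided by the total number of distinct
#' T-RFs. Inputs are logical presence vectors over the same alignment
#' bins (or anything coercible to logical).
#'
#' @param a,b Logical presence vectors of equal length.
#' @return A fraction in \[0, 1\]. Two empty profiles are defined as
#'   identical (similarity 1) with a warning.
#' @export
jaccard_similarity <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("presence vectors must have equal length", call. = FALSE)
  union <- sum(a | b)
  if (union == 0) {
    warning("both profiles are empty; Jaccard similarity defined as 1",
            call. = FALSE)
    return(1)
  }
  sum(a & b) / union
}

#' Bray-Curtis similarity of two relative abundance vectors
#'
#' Takes the relative abundances of the T-RFs into consideration:
#' similarity is 1 minus half the sum of absolute abundance differences,
#' which for unit-sum vectors equals the sum of bin-wise minima.
#'
#' @param p,q Relative abundance vectors over the same bins, each summing
#'   to 1 (checked to 1e-6). Two all-zero vectors are treated as
#'   identical empty profiles (similarity 1, with a warning).
#' @return A fraction in \[0, 1\].
#' @export
bray_curtis_similarity <- function(p, q) {
  if (length(p) != length(q))
    stop("abundance vectors must have equal length", call. = FALSE)
  if (sum(p) == 0 && sum(q) == 0) {
    warning("both profiles are empty; Bray-Curtis similarity defined as 1",
            call. = FALSE)
    return(1)
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("Bray-Curtis similarity requires unit-sum abundance vectors",
         call. = FALSE)
  1 - 0.5 * sum(abs(p - q))
}

#' Relative abundance matrix over alignment bins
#'
#' Builds the bins-by-profiles matrix of relative abundances: for each
#' profile, the signal (height or area) of its member peak in each
#' retained bin, divided by the profile's total over the retained bins.
#' Abundances are therefore renormalized over the bins present in the
#' alignment, which is the peak set comparisons proceed on after
#' treatment (including removal of ambiguous bins).
#'
#' @param profiles The aligned profiles.
#' @param alignment A `trf_alignment` of those profiles.
#' @param basis `"height"` or `"area"`.
#' @return A `trf_abundance` matrix; rows are bins labeled by mean size
#'   (2 decimals), columns are profiles, each non-empty column sums to 1.
#' @export
build_abundance_matrix <- function(profiles, alignment,
                                   basis = c("height", "area")) {
  profiles <- as_profile_list(profiles)
  stopifnot(inherits(alignment, "trf_alignment"))
  basis <- match.arg(basis)
  if (!setequal(names(profiles), alignment$profile_ids))
    stop("the alignment must cover exactly the supplied profiles",
         call. = FALSE)
  ids <- alignment$profile_ids
  bins <- alignment$bins
  m <- alignment$members
  values <- matrix(0, nrow = nrow(bins), ncol = length(ids),
                   dimnames = list(sprintf("%.2f", bins$mean_size), ids))
  for (k in seq_len(nrow(m))) {
    p <- profiles[[m$profile_id[k]]]
    i <- match_size(p$peaks$size, m$size_original[k])
    sig <- p$peaks[[basis]][i]
    if (is.na(sig))
      stop("profile '", p$profile_id, "' has a missing ", basis,
           " for the peak at ", m$size_original[k], " bases", call. = FALSE)
    values[match(m$bin_id[k], bins$bin_id), m$profile_id[k]] <- sig
  }
  sums <- colSums(values)
  if (any(sums == 0))
    warning("profile(s) with no peaks in the alignment: ",
            paste(ids[sums == 0], collapse = ", "), call. = FALSE)
  values <- sweep(values, 2, ifelse(sums > 0, sums, 1), "/")
  new_abundance_matrix(values, bins$mean_size, basis)
}

#' Pairwise similarity matrix of aligned profiles
#'
#' Computes all pairwise Jaccard (presence = abundance > 0) or
#' Bray-Curtis similarities between the profile columns of an abundance
#' matrix.
#'
#' @param abundance A `trf_abundance` matrix from
#'   [build_abundance_matrix()].
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return A symmetric `trf_similarity` matrix with unit diagonal.
#' @seealso [write_similarity_matrix()] to export it, optionally as a
#'   distance matrix (1 - similarity).
#' @export
similarity_matrix <- function(abundance,
                              metric = c("jaccard", "bray_curtis")) {
  stopifnot(inherits(abundance, "trf_abundance"))
  metric <- match.arg(metric)
  ids <- colnames(abundance)
  n <- length(ids)
  values <- diag(nrow = n)
  dimnames(values) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- if (metric == "jaccard")
        jaccard_similarity(abundance[, i] > 0, abundance[, j] > 0)
      else {
        if (sum(abundance[, i]) == 0 || sum(abundance[, j]) == 0) {
          if (sum(abundance[, i]) == 0 && sum(abundance[, j]) == 0) 1
          else 0
        } else bray_curtis_similarity(abundance[, i], abundance[, j])
      }
      values[i, j] <- s
      values[j, i] <- s
    }
  }
  new_similarity_matrix(values, metric)
}
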