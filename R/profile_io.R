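#' Peak table dialect
#'
#' Describes the layout of a delimited peak table exported from
#' genotyping software. The canonical native format is tab-delimited with
#' header `sample_id  replicate  size  height  area`; exports from other
#' software are read by remapping the column names. Unknown columns are
#' ignored. A `NULL` column name marks the column as absent (allowed for
#' `replicate` and `area`).
#'
#' @param delimiter Field delimiter, `"\t"` or `","`.
#' @param sample_col,replicate_col,size_col,height_col,area_col Column
#'   names in the file header.
#' @param decimal Decimal mark, `"."` or `","` (for locale-exported
#'   tables).
#' @return An object of class `peak_table_dialect`.
#' @export
peak_table_dialect <- function(delimiter = "\t",
                               sample_col = "sample_id",
                               replicate_col = "replicate",
                               size_col = "size",
                               height_col = "height",
                               area_col = "area",
                               decimal = ".") {
  if (!delimiter %in% c("\t", ","))
    stop("invalid dialect: delimiter must be tab or comma", call. = FALSE)
  if (!decimal %in% c(".", ","))
    stop("invalid dialect: decimal mark must be '.' or ','", call. = FALSE)
  if (delimiter == "," && decimal == ",")
    stop("invalid dialect: comma decimals need a tab delimiter",
         call. = FALSE)
  for (col in list(sample_col, size_col, height_col))
    if (is.null(col) || !nzchar(col))
      stop("invalid dialect: sample, size and height columns must be named",
           call. = FALSE)
  structure(list(delimiter = delimiter, sample_col = sample_col,
                 replicate_col = replicate_col, size_col = size_col,
                 height_col = height_col, area_col = area_col,
                 decimal = decimal),
            class = "peak_table_dialect")
}

#' GeneMapper export dialect
#'
#' Preset for tab-delimited GeneMapper-style exports with columns
#' `Sample File`, `Size`, `Height` and `Area` and no replicate column.
#'
#' @return A [peak_table_dialect()].
#' @export
genemapper_dialect <- function() {
  peak_table_dialect(delimiter = "\t", sample_col = "Sample File",
                     replicate_col = NULL, size_col = "Size",
                     height_col = "Height", area_col = "Area")
}

#' Read a peak table into T-RF profiles
#'
#' Reads a delimited per-peak fragment table (one row per detected peak)
#' and returns one [trf_profile()] per distinct sample/replicate
#' identifier, with peaks sorted by ascending size. Rows with
#' non-numeric size, height or area are rejected with their row number;
#' duplicate (sample, size) rows are a data error. Blank areas are
#' accepted and flagged missing; area-based operations on such profiles
#' then raise an error.
#'
#' @param path Path to the file.
#' @param dialect A [peak_table_dialect()].
#' @return Named list of [trf_profile()] objects.
#' @export
read_peak_table <- function(path, dialect = peak_table_dialect()) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (col in c(sample = dialect$sample_col, size = dialect$size_col,
                height = dialect$height_col)) {
    if (!col %in% names(tab))
      stop("peak table format error: missing required column '", col,
           "'", call. = FALSE)
  }
  num <- function(x) {
    x <- trimws(x)
    if (dialect$decimal == ",") x <- gsub(",", ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  size <- num(tab[[dialect$size_col]])
  height <- num(tab[[dialect$height_col]])
  has_area <- !is.null(dialect$area_col) &&
    dialect$area_col %in% names(tab)
  area_raw <- if (has_area) trimws(tab[[dialect$area_col]])
  else rep("", nrow(tab))
  area <- num(area_raw)
  bad <- which(is.na(size) | is.na(height) |
                 (is.na(area) & nzchar(area_raw)))
  if (length(bad))
    stop("peak table data error: non-numeric size/height/area in row(s) ",
         paste(bad + 1L, collapse = ", "), " (counting the header as row 1)",
         call. = FALSE)
  sample <- trimws(tab[[dialect$sample_col]])
  replicate <- if (!is.null(dialect$replicate_col) &&
                   dialect$replicate_col %in% names(tab))
    trimws(tab[[dialect$replicate_col]]) else rep("1", nrow(tab))
  key <- paste(sample, replicate, sep = "\r")
  dup <- duplicated(data.frame(key, size))
  if (any(dup))
    stop("peak table data error: duplicate (sample, size) rows: ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "),
         call. = FALSE)
  profiles <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    s <- sample[rows[1]]; r <- replicate[rows[1]]
    pid <- if (identical(r, "1") && all(replicate == "1")) s
    else paste(s, r, sep = "_")
    trf_profile(pid,
                data.frame(size = size[rows], height = height[rows],
                           area = area[rows]),
                sample_id = s, replicate = r,
                provenance = paste0("read_peak_table(", basename(path), ")"))
  })
  names(profiles) <- vapply(profiles, function(p) p$profile_id,
                            character(1))
  profiles
}

#' Write T-RF profiles as a canonical peak table
#'
#' Writes the tab-delimited canonical format (`sample_id`, `replicate`,
#' `size`, `height`, `area`) readable by [read_peak_table()]. Values are
#' written at full precision so a write/read round trip reproduces the
#' profiles.
#'
#' @param profiles List of [trf_profile()] objects.
#' @param path Output path.
#' @export
write_peak_table <- function(profiles, path) {
  profiles <- as_profile_list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$peaks) == 0) return(NULL)
    data.frame(sample_id = p$sample_id, replicate = p$replicate,
               size = p$peaks$size, height = p$peaks$height,
               area = p$peaks$area, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(sample_id = character(), replicate = character(),
                       size = numeric(), height = numeric(),
                       area = numeric())
  utils::write.table(format(rows, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a relative abundance matrix
#'
#' Comma-delimited text with bins as rows (labeled by mean size, 2
#' decimals) and profiles as columns. Values are written with enough
#' precision that re-reading reproduces them to at least 6 decimals.
#'
#' @param matrix A `trf_abundance` from [build_abundance_matrix()].
#' @param path Output path.
#' @export
write_abundance_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "trf_abundance"))
  df <- data.frame(bin = rownames(matrix),
                   signif(unclass(matrix), 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an abundance matrix written by [write_abundance_matrix()]
#'
#' @param path Path to the file.
#' @param basis Signal basis label to attach (not stored in the file).
#' @return A `trf_abundance` matrix.
#' @export
read_abundance_matrix <- function(path, basis = "height") {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$bin
  new_abundance_matrix(values, as.numeric(df$bin), basis)
}

#' Write a similarity (or distance) matrix
#'
#' Writes the square comma-delimited matrix importable by ordination
#' software. With `as_distance = TRUE` every similarity v is replaced by
#' the distance 1 - v (e.g. the Jaccard distance).
#'
#' @param matrix A `trf_similarity` from [similarity_matrix()].
#' @param path Output path.
#' @param as_distance Write 1 - similarity instead of similarity.
#' @export
write_similarity_matrix <- function(matrix, path, as_distance = FALSE) {
  stopifnot(inherits(matrix, "trf_similarity"))
  values <- unclass(matrix)
  attr(values, "metric") <- NULL
  if (as_distance) values <- 1 - values
  df <- data.frame(profile = rownames(values), signif(values, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a similarity matrix written by [write_similarity_matrix()]
#'
#' @param path Path to the file.
#' @param metric Metric label to attach.
#' @return A `trf_similarity` matrix.
#' @export
read_similarity_matrix <- function(path, metric = "jaccard") {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$profile
  new_similarity_matrix(values, metric)
}

#' Write a plain-text alignment report
#'
#' Lists every alignment bin with its mean size, status and member
#' T-RFs, for manual inspection of the binning.
#'
#' @param alignment A `trf_alignment`.
#' @param path Output path.
#' @export
write_alignment_report <- function(alignment, path) {
  stopifnot(inherits(alignment, "trf_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("alignment of %d profiles, %d bins (%s sizes)",
                     length(alignment$profile_ids),
                     nrow(alignment$bins), alignment$size_basis), con)
  writeLines(paste("profiles:",
                   paste(alignment$profile_ids, collapse = ", ")), con)
  for (k in seq_len(nrow(alignment$bins))) {
    b <- alignment$bins[k, ]
    mm <- alignment$members[alignment$members$bin_id == b$bin_id, ,
                            drop = FALSE]
    writeLines(sprintf("bin %d: mean %.2f bases, %d member(s), %s",
                       b$bin_id, b$mean_size, b$n_members,
                       if (is.na(b$status)) "unclassified" else b$status),
               con)
    writeLines(sprintf("  %s: %.2f", mm$profile_id, mm$size), con)
  }
  invisible(path)
}
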