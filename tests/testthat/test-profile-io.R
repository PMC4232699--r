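write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the canonical peak table format reads into profiles", {
  path <- write_lines_tmp(c(
    "sample_id\treplicate\tsize\theight\tarea",
    "s1\t1\t102.3\t500\t5200",
    "s1\t1\t240.8\t120\t1100"))
  profs <- read_peak_table(path)
  expect_length(profs, 1)
  expect_equal(profs$s1$peaks$size, c(102.3, 240.8))
  expect_equal(profs$s1$peaks$area, c(5200, 1100))
})

test_that("interleaved, unsorted rows split by sample and sort by size", {
  path <- write_lines_tmp(c(
    "sample_id\treplicate\tsize\theight\tarea",
    "s2\t1\t300.5\t100\t900",
    "s1\t1\t240.8\t120\t1100",
    "s2\t1\t100.1\t700\t6800",
    "s1\t1\t102.3\t500\t5200"))
  profs <- read_peak_table(path)
  expect_setequal(names(profs), c("s1", "s2"))
  expect_equal(profs$s1$peaks$size, c(102.3, 240.8))
  expect_equal(profs$s2$peaks$size, c(100.1, 300.5))
})

test_that("the reader is insensitive to row order", {
  lines <- c("sample_id\treplicate\tsize\theight\tarea",
             sprintf("s%d\t1\t%.2f\t%d\t%d", rep(1:3, each = 4),
                     runif(12, 60, 900), sample(100:900, 12),
                     sample(1000:9000, 12)))
  p1 <- read_peak_table(write_lines_tmp(lines))
  p2 <- read_peak_table(write_lines_tmp(c(lines[1],
                                          sample(lines[-1]))))
  for (id in names(p1)) expect_equal(p1[[id]]$peaks, p2[[id]]$peaks)
})

test_that("format and data errors name the offender", {
  no_height <- write_lines_tmp(c("sample_id\tsize\tarea",
                                 "s1\t100.0\t900"))
  expect_error(read_peak_table(no_height), "height")
  bad_row <- write_lines_tmp(c("sample_id\treplicate\tsize\theight\tarea",
                               "s1\t1\t100.0\t500\t5000",
                               "s1\t1\tnot_a_number\t200\t2000"))
  expect_error(read_peak_table(bad_row), "row.*3")
  dup <- write_lines_tmp(c("sample_id\treplicate\tsize\theight\tarea",
                           "s1\t1\t100.0\t500\t5000",
                           "s1\t1\t100.0\t200\t2000"))
  expect_error(read_peak_table(dup), "duplicate")
  expect_error(read_peak_table("does/not/exist.tsv"), "not found")
})

test_that("the GeneMapper dialect and comma decimals are supported", {
  path <- write_lines_tmp(c(
    "Sample File\tSize\tHeight\tArea\tDye",
    "day1.fsa\t102,3\t500\t5200\tB",
    "day1.fsa\t240,8\t120\t1100\tB"))
  d <- genemapper_dialect()
  d$decimal <- ","
  profs <- read_peak_table(path, d)
  expect_equal(profs[["day1.fsa"]]$peaks$size, c(102.3, 240.8))
})

test_that("blank areas are read as missing", {
  path <- write_lines_tmp(c("sample_id\treplicate\tsize\theight\tarea",
                            "s1\t1\t100.0\t500\t",
                            "s1\t1\t200.0\t300\t2800"))
  profs <- read_peak_table(path)
  expect_equal(profs$s1$peaks$area, c(NA, 2800))
  expect_error(total_fluorescence(profs$s1, "area"), "missing")
})

test_that("profiles survive a write/read round trip", {
  profs <- list(a = make_profile("a", c(100.123456, 200.654321),
                                 heights = c(500.25, 300.75),
                                 sample_id = "a", replicate = "1"),
                b = make_profile("b", c(150.5, 250.5),
                                 heights = c(800, 100), sample_id = "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(profs, path)
  back <- read_peak_table(path)
  for (id in c("a", "b"))
    expect_equal(back[[id]]$peaks[, c("size", "height", "area")],
                 profs[[id]]$peaks[, c("size", "height", "area")],
                 tolerance = 1e-6)
})

test_that("abundance matrices round trip with unit column sums", {
  p1 <- make_profile("A", c(100, 200), heights = c(600, 400))
  p2 <- make_profile("B", 100, heights = 1000)
  al <- moving_average_bin(list(p1, p2))
  ab <- build_abundance_matrix(list(p1, p2), al)
  expect_equal(unname(ab[, "A"]), c(0.6, 0.4))
  expect_equal(unname(ab[, "B"]), c(1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_matrix(ab, path)
  txt <- read.csv(path, check.names = FALSE)
  expect_equal(colSums(txt[, -1]), c(A = 1, B = 1), tolerance = 1e-9)
  back <- read_abundance_matrix(path)
  expect_equal(unclass(back), unclass(ab), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("an empty alignment writes a header-only abundance table", {
  p1 <- make_profile("A", 100)
  p2 <- make_profile("B", 101.4)
  al <- classify_bins(moving_average_bin(list(p1, p2)), 1.5)
  empty <- suppressWarnings(suppressMessages(drop_ambiguous_bins(al)))
  ab <- suppressWarnings(build_abundance_matrix(list(p1, p2), empty))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_matrix(ab, path)
  expect_length(readLines(path), 1)
})

test_that("similarity matrices export as similarity or distance", {
  values <- diag(2)
  dimnames(values) <- list(c("A", "B"), c("A", "B"))
  sm <- trflptools:::new_similarity_matrix(values, "jaccard")
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(sm, path, as_distance = TRUE)
  d <- read.csv(path, check.names = FALSE)
  expect_equal(unname(as.matrix(d[, -1])), matrix(c(0, 1, 1, 0), 2))
  # round trip of the similarity form preserves symmetry
  write_similarity_matrix(sm, path)
  back <- read_similarity_matrix(path)
  expect_equal(unclass(back), values, ignore_attr = TRUE)
  # 1-profile matrix
  one <- trflptools:::new_similarity_matrix(matrix(1, 1, 1,
                                                   dimnames = list("A", "A")),
                                            "jaccard")
  write_similarity_matrix(one, path)
  expect_equal(unclass(read_similarity_matrix(path))[1, 1], 1)
})

test_that("alignment reports list bins, members and statuses", {
  al <- classify_bins(moving_average_bin(
    list(make_profile("P1", c(100.0, 101.2)), make_profile("P2", 100.4))))
  path <- withr::local_tempfile(fileext = ".txt")
  write_alignment_report(al, path)
  txt <- readLines(path)
  expect_match(txt, "bin 1: mean 100.20", all = FALSE)
  expect_match(txt, "ambiguous", all = FALSE)
  expect_match(txt, "P2: 100.40", all = FALSE)
})
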