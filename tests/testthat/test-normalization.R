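test_that("normalization configs validate basis/threshold combinations", {
  expect_error(normalization_config("TFN", "height", "global_min_area"),
               "peak *detection threshold|pdt")
  expect_error(normalization_config("TFN", "area", "pdt"), "area")
  expect_error(normalization_config(fpt_fraction = 1.5), "fpt_fraction")
  expect_silent(normalization_config("TFN", "area", "local_min_area"))
})

test_that("TFN rescales to the minimum TF, removing sub-threshold peaks", {
  # hand trace: P2 scales by 1500/2120, its 120-unit peak falls to 84.9
  # (< 100) and is removed; the survivor rescales to exactly 1500
  p1 <- make_profile("P1", c(100, 200), heights = c(1000, 500))
  p2 <- make_profile("P2", c(100, 200), heights = c(2000, 120))
  out <- tfn_normalize(list(p1, p2), normalization_config("TFN", "height"),
                       detection_config(pdt = 100))
  expect_equal(out$P1$peaks$height, c(1000, 500))   # min-TF: unchanged
  expect_equal(out$P2$peaks$size, 100)
  expect_equal(out$P2$peaks$height, 1500)
})

test_that("profiles with equal TF pass through unchanged", {
  p1 <- make_profile("P1", c(100, 200), heights = c(900, 600))
  p2 <- make_profile("P2", c(110, 210), heights = c(600, 900))
  out <- tfn_normalize(list(p1, p2), normalization_config("TFN", "height"),
                       detection_config(pdt = 100))
  expect_equal(out$P1$peaks, p1$peaks)
  expect_equal(out$P2$peaks, p2$peaks)
})

test_that("a two-state oscillation terminates in the averaged profile", {
  # hand trace: TFmin 1000, threshold 100. State A keeps only the 950
  # peak (the 105 peak scales to 99.5); state B keeps both. The states
  # alternate and the output is their peak-wise average, retaining the
  # averaged sub-threshold peak.
  pa <- make_profile("A", 100, heights = 1000)
  pb <- make_profile("B", c(100, 200), heights = c(950, 105))
  out <- tfn_normalize(list(pa, pb), normalization_config("TFN", "height"),
                       detection_config(pdt = 100))
  expect_equal(out$B$peaks$height,
               c((950 * 1000 / 1055 + 1000) / 2, 105 * (1000 / 950) / 2),
               tolerance = 1e-12)
  expect_equal(out$B$peaks$height, c(950.2369668246446, 55.2631578947),
               tolerance = 1e-9)
  expect_match(out$B$provenance, "cycle", all = FALSE)
})

test_that("TFN output TFs equal TFmin and peak counts never grow", {
  set.seed(31)
  cfg <- normalization_config("TFN", "height")
  det <- detection_config(pdt = 50)
  for (i in 1:15) {
    profs <- lapply(1:4, function(p) {
      n <- sample(5:15, 1)
      make_profile(paste0("P", p), sort(runif(n, 60, 1000)),
                   heights = runif(n, 55, 4000))
    })
    out <- tryCatch(tfn_normalize(profs, cfg, det), error = function(e) e)
    expect_false(inherits(out, "error"))
    tfs <- vapply(out, total_fluorescence, numeric(1))
    tfmin <- min(vapply(profs, total_fluorescence, numeric(1)))
    cycled <- vapply(out, function(p)
      any(grepl("cycle", p$provenance)), logical(1))
    expect_true(all(abs(tfs[!cycled] - tfmin) / tfmin <= 1e-9))
    expect_true(all(vapply(out, n_peaks, numeric(1)) <=
                      vapply(profs, n_peaks, numeric(1))))
    # idempotent on the non-cycled profiles
    out2 <- tfn_normalize(out, cfg, det)
    for (k in which(!cycled))
      expect_equal(out2[[k]]$peaks$height, out[[k]]$peaks$height,
                   tolerance = 1e-7)
  }
})

test_that("TFN area variants use the dataset or group minimum area", {
  mk <- function(id, areas) make_profile(id, seq(100, by = 50,
                                                 length.out = length(areas)),
                                         heights = areas / 10,
                                         areas = areas)
  # dataset minimum area = 200 (in group g2); local minimum in g1 = 500
  g1 <- list(mk("A", c(5000, 500)), mk("B", c(9000, 2000)))
  g2 <- list(mk("C", c(4000, 200)), mk("D", c(5000, 900)))
  all4 <- c(g1, g2)
  groups <- c("g1", "g1", "g2", "g2")
  glob <- tfn_normalize(all4, normalization_config("TFN", "area",
                                                   "global_min_area"),
                        groups = groups)
  loc <- tfn_normalize(all4, normalization_config("TFN", "area",
                                                  "local_min_area"),
                       groups = groups)
  # B scaled toward TF 5500; with the global rule its small peak
  # (2000 * 0.5 = 1000 >= 200) survives
  expect_equal(n_peaks(glob$B), 2)
  expect_equal(total_fluorescence(glob$B, "area"), 5500)
  # with the local rule the threshold is 500: 2000 * 0.5 = 1000 >= 500
  # still survives, but scaling is identical; check group TFs
  expect_equal(total_fluorescence(loc$D, "area"), 4200)
})

test_that("TFN on heights decouples peak count from pre-treatment TF", {
  # 51 digests of varying concentration, each loaded twice; before
  # treatment the number of observed T-RFs grows with total
  # fluorescence, because more of the low-abundance tail clears the
  # detection threshold. Normalizing every profile to the dataset
  # minimum TF cuts all profiles at the same effective abundance, so
  # the dependence collapses.
  set.seed(9)
  spec <- synthetic_spec(seed = 202)
  conc <- exp(rnorm(51, 0, 0.5))
  sim <- simulate_dataset(spec, list(samples = 51,
                                     replicates_per_sample = 1,
                                     loadings_per_replicate = 2,
                                     concentrations = conc))
  det <- detection_config(pdt = 50)
  filtered <- lapply(sim$profiles, apply_detection_threshold, det)
  tf_pre <- vapply(filtered, total_fluorescence, numeric(1))
  n_pre <- vapply(filtered, n_peaks, numeric(1))
  expect_gt(cor(tf_pre, n_pre), 0.3)   # more signal, more peaks
  out <- tfn_normalize(filtered, normalization_config("TFN", "height"),
                       det)
  n_post <- vapply(out, n_peaks, numeric(1))
  expect_lt(abs(cor(tf_pre, n_post)), 0.25)
  expect_lt(abs(cor(tf_pre, n_post)), cor(tf_pre, n_pre))
})

test_that("FPT removes strictly sub-threshold T-RFs in one pass", {
  p <- make_profile("p", c(100, 200, 300), heights = c(970, 25, 5))
  out <- fpt_normalize(p, normalization_config("FPT", "height"))
  expect_equal(out$peaks$height, c(970, 25))
  # exact 1% boundary is retained; signals are not rescaled
  q <- make_profile("q", c(100, 200), heights = c(990, 10))
  out2 <- fpt_normalize(q, normalization_config("FPT", "height"))
  expect_equal(out2$peaks$height, c(990, 10))
  # vanishing threshold is the identity
  tiny <- normalization_config("FPT", "height", fpt_fraction = 1e-12)
  expect_equal(fpt_normalize(p, tiny)$peaks, p$peaks)
  # every retained peak clears the threshold on the ORIGINAL profile
  set.seed(32)
  for (i in 1:10) {
    r <- make_profile("r", sort(runif(12, 60, 900)),
                      heights = runif(12, 1, 1000))
    cfg <- normalization_config("FPT", "height", fpt_fraction = 0.02)
    kept <- fpt_normalize(r, cfg)
    ra0 <- relative_abundance(r)
    expect_true(all(ra0[r$peaks$size %in% kept$peaks$size] >= 0.02))
  }
})

test_that("removing every peak is degenerate and warned about", {
  p <- make_profile("p", c(100, 200), heights = c(30, 40))
  cfg <- normalization_config("FPT", "height", fpt_fraction = 0.9)
  expect_warning(out <- fpt_normalize(p, cfg), "no peaks left")
  expect_equal(n_peaks(out), 0)
})
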