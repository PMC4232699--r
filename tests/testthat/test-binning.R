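test_that("moving-average binning follows the published trace", {
  # hand trace: seed 100.0, Y-window admits 100.4 (other profile);
  # 101.2 is excluded both by the one-per-profile rule and by being
  # further than Z from the bin mean 100.2
  al <- moving_average_bin(list(make_profile("P1", c(100.0, 101.2)),
                                make_profile("P2", 100.4)))
  bins <- alignment_bins(al)
  expect_equal(nrow(bins), 2)
  expect_equal(bins$mean_size, c(100.2, 101.2))
  m <- alignment_members(al)
  expect_setequal(m$size[m$bin_id == 1], c(100.0, 100.4))
  expect_equal(m$size[m$bin_id == 2], 101.2)
})

test_that("exact matches across profiles share bins; a single profile gets singleton bins", {
  al <- moving_average_bin(list(make_profile("A", c(100, 200)),
                                make_profile("B", c(100, 200))))
  expect_equal(alignment_bins(al)$n_members, c(2L, 2L))
  solo <- moving_average_bin(list(make_profile("A", c(100, 100.3, 100.6))))
  expect_equal(alignment_bins(solo)$n_members, rep(1L, 3))
})

test_that("binning partitions every peak exactly once", {
  set.seed(11)
  for (i in 1:30) {
    profs <- Filter(Negate(is.null), random_profile_set(3, 8))
    if (length(profs) == 0) next
    total <- sum(vapply(profs, n_peaks, numeric(1)))
    al <- moving_average_bin(profs)
    expect_equal(nrow(alignment_members(al)), total)
    expect_equal(sum(alignment_bins(al)$n_members), total)
    # each peak appears exactly once
    m <- alignment_members(al)
    expect_false(anyDuplicated(paste(m$profile_id, m$size)) > 0)
  }
})

test_that("binning is invariant to profile input order when sizes are distinct", {
  set.seed(12)
  for (i in 1:25) {
    repeat {
      profs <- Filter(Negate(is.null), random_profile_set(3, 7))
      sizes <- unlist(lapply(profs, function(p) p$peaks$size))
      if (length(profs) >= 2 && !anyDuplicated(sizes)) break
    }
    ref <- bin_signature(moving_average_bin(profs))
    perm <- sample(length(profs))
    expect_identical(bin_signature(moving_average_bin(profs[perm])), ref)
  }
})

test_that("binning matches a literal re-execution of the procedure", {
  set.seed(13)
  for (i in 1:200) {
    profs <- random_profile_set(sample(1:3, 1), 6)
    if (all(vapply(profs, is.null, logical(1)))) next
    expect_true(oracle_agrees(profs))
  }
})

test_that("classification flags bins with near neighbors, symmetrically", {
  al <- moving_average_bin(list(make_profile("P1", c(100.0, 101.2)),
                                make_profile("P2", 100.4)))
  al <- classify_bins(al, 1)
  expect_equal(alignment_bins(al)$status, c("ambiguous", "ambiguous"))
  far <- classify_bins(moving_average_bin(list(make_profile("A", c(100, 200)))), 1)
  expect_equal(alignment_bins(far)$status, c("correct", "correct"))
  single <- classify_bins(moving_average_bin(list(make_profile("A", 100))), 1)
  expect_equal(alignment_bins(single)$status, "correct")
})

test_that("classification agrees with the brute-force oracle", {
  set.seed(14)
  for (i in 1:30) {
    profs <- Filter(Negate(is.null), random_profile_set(3, 8))
    if (length(profs) == 0) next
    al <- classify_bins(moving_average_bin(profs), 1)
    expect_equal(alignment_bins(al)$status, unname(oracle_classify(al, 1)))
  }
})

test_that("duplicate ambiguity resolution pairs the most similar sizes", {
  # original binning pairs 100.0 with 100.8 (shortest first); the
  # resolution re-pairs 100.8 with 100.9 (difference 0.1 instead of 0.8)
  al <- moving_average_bin(list(make_profile("P1", c(100.0, 100.9)),
                                make_profile("P2", 100.8)))
  m0 <- alignment_members(al)
  expect_setequal(m0$size[m0$bin_id == 1], c(100.0, 100.8))
  res <- resolve_duplicate_ambiguity(al)
  m <- alignment_members(res)
  paired <- alignment_bins(res)$bin_id[alignment_bins(res)$n_members == 2]
  expect_length(paired, 1)
  expect_setequal(m$size[m$bin_id == paired], c(100.8, 100.9))
})

test_that("resolution leaves unambiguous alignments unchanged", {
  al <- classify_bins(moving_average_bin(
    list(make_profile("A", c(100, 200)), make_profile("B", c(100, 200)))))
  expect_identical(bin_signature(resolve_duplicate_ambiguity(al)),
                   bin_signature(al))
  same <- classify_bins(moving_average_bin(
    list(make_profile("A", 100), make_profile("B", 100))))
  expect_equal(nrow(alignment_bins(resolve_duplicate_ambiguity(same))), 1)
})

test_that("resolution preserves the peak partition and rejects >2 profiles", {
  set.seed(15)
  for (i in 1:20) {
    profs <- Filter(Negate(is.null), random_profile_set(2, 8))
    if (length(profs) != 2) next
    al <- moving_average_bin(profs)
    res <- resolve_duplicate_ambiguity(al)
    expect_equal(nrow(alignment_members(res)), nrow(alignment_members(al)))
  }
  al3 <- moving_average_bin(list(make_profile("A", 100),
                                 make_profile("B", 100),
                                 make_profile("C", 100)))
  expect_error(resolve_duplicate_ambiguity(al3), "systematic")
})

test_that("integer binning rounds to the nearest integer, halves up", {
  al <- integer_bin(list(make_profile("A", 134.4), make_profile("B", 134.6)))
  expect_equal(nrow(alignment_bins(al)), 2)
  al2 <- integer_bin(list(make_profile("A", c(99.5, 134.4)),
                          make_profile("B", c(100.0, 134.6))))
  # 99.5 rounds up to 100 and joins B's 100.0
  bins <- alignment_bins(al2)
  expect_equal(bins$n_members, c(2L, 1L, 1L))
  expect_warning(
    collide <- integer_bin(list(make_profile("A", c(133.6, 134.4),
                                             heights = c(10, 900)))),
    "keeping the tallest")
  expect_equal(alignment_members(collide)$size, 134.4)
})

test_that("dropping ambiguous bins keeps exactly the correct ones", {
  profs <- list(make_profile("P1", c(100.0, 101.2, 200, 300)),
                make_profile("P2", c(100.4, 200, 300)))
  al <- classify_bins(moving_average_bin(profs))
  expect_equal(sum(alignment_bins(al)$status == "ambiguous"), 2)
  dropped <- suppressMessages(drop_ambiguous_bins(al))
  expect_equal(nrow(alignment_bins(dropped)), 2)
  expect_true(all(alignment_bins(dropped)$status == "correct"))
  # idempotent: classifying and dropping again changes nothing
  again <- drop_ambiguous_bins(classify_bins(dropped))
  expect_identical(bin_signature(again), bin_signature(dropped))
  # all ambiguous -> empty alignment with a warning
  close_pair <- classify_bins(moving_average_bin(
    list(make_profile("A", 100), make_profile("B", 101.4))), 1.5)
  expect_warning(suppressMessages(drop_ambiguous_bins(close_pair)),
                 "empty")
  expect_error(drop_ambiguous_bins(moving_average_bin(
    list(make_profile("A", 100)))), "classified")
})
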