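test_that("length intervals are half-open and labelled by their lower edge", {
  expect_equal(bin_index(2.04), 2.0)
  expect_equal(bin_index(4.20), 4.2)
  expect_equal(bin_index(0.1), 0.1)    # [0.1, 0.2)
  expect_equal(bin_index(0.0999), 0.0)
  expect_equal(bin_index(c(1.95, 2.0, 2.1)), c(1.9, 2.0, 2.1))
})

test_that("window pooling averages counts over adjacent intervals", {
  # intervals 2.0/2.1/2.2 hold (1-focus, 2-focus) counts (3,0), (2,1),
  # (1,2); the 0.3 um window at 2.1 pools them: fraction 3/9
  foci <- c(replicate(3, list(A = 1.0), simplify = FALSE),
            replicate(2, list(A = 1.0), simplify = FALSE),
            list(list(A = c(0.5, 1.5))),
            list(list(A = 1.1)),
            replicate(2, list(A = c(0.5, 1.5)), simplify = FALSE))
  ds <- tiny_dataset(c(2.01, 2.02, 2.03, 2.11, 2.12, 2.13,
                       2.21, 2.22, 2.23), foci)
  dup <- duplication_frequency(ds, "A", min_cells = 1)
  expect_equal(dup$fraction[dup$center == 2.1], 3 / 9)
  expect_equal(dup$n_1focus[dup$center == 2.1], 6L)
})

test_that("all-single-focus channels give zero duplication everywhere", {
  ds <- tiny_dataset(rep(c(2.0, 3.0), each = 6),
                     replicate(12, list(A = 1.0), simplify = FALSE))
  dup <- duplication_frequency(ds, "A", min_cells = 1)
  expect_true(all(dup$fraction[!is.na(dup$fraction)] == 0))
  expect_error(duplication_frequency(ds, "missing"), "absent")
})

test_that("sliding-window duplication equals the brute-force oracle exactly", {
  sim <- sample_population(preset_scenario("WT", loci = c("L2_I", "ter_I")),
                           500, seed = 23)
  ds <- sim$dataset
  for (ch in c("L2_I", "ter_I")) {
    got <- duplication_frequency(ds, ch)
    want <- oracle_duplication(binning_length(ds), focus_count(ds, ch))
    expect_identical(got$center, want$center)
    expect_identical(got$n_1focus, want$n_1focus)
    expect_identical(got$n_2focus, want$n_2focus)
    expect_identical(got$fraction, want$fraction)
  }
})

test_that("duplication frequency is invariant under axis flips", {
  ds <- wt_sim()$dataset
  expect_identical(duplication_frequency(ds, "L3_I"),
                   duplication_frequency(flip_dataset(ds), "L3_I"))
})

test_that("position profiles report dominant-type percentiles", {
  # window at 2.0: three single-focus cells at 0.7, 0.8, 0.9
  ds1 <- tiny_dataset(c(2.0, 2.02, 2.04),
                      list(list(A = 0.7 * 2.0), list(A = 0.8 * 2.02),
                           list(A = 0.9 * 2.04)), oriented = TRUE)
  p1 <- position_profile(ds1, "A", min_cells = 1)
  expect_equal(p1$dominant_type[p1$center == 2.0], "one")
  expect_equal(p1$med[p1$center == 2.0], 0.8)
  # two 2-focus cells with sisters (0.1, 0.9), (0.2, 0.8)
  ds2 <- tiny_dataset(c(3.0, 3.02),
                      list(list(A = c(0.1, 0.9) * 3.0),
                           list(A = c(0.2, 0.8) * 3.02)),
                      oriented = TRUE)
  p2 <- position_profile(ds2, "A", min_cells = 1)
  i <- which(p2$center == 3.0)
  expect_equal(p2$dominant_type[i], "two")
  expect_equal(p2$lo_med[i], 0.15)
  expect_equal(p2$up_med[i], 0.85)
  expect_true(all(p2$lo_med[i] <= p2$up_med[i]))
})

test_that("profiles of unoriented datasets are empty and flagged", {
  ds <- tiny_dataset(c(2, 2), list(list(A = 1), list(A = 1)))
  p <- position_profile(ds, "A")
  expect_equal(nrow(p), 0L)
  expect_true(isTRUE(attr(p, "no_oriented_cells")))
})

test_that("profile medians equal the brute-force oracle exactly", {
  sim <- sample_population(preset_scenario("WT", loci = c("ori_I", "L4_I")),
                           400, seed = 31)
  ds <- refine_orientation(orient_cells(sim$dataset))
  ok <- ds$cells$orientation == "oriented"
  sub_ids <- ds$cells$cell_id[ok]
  for (ch in c("ori_I", "L4_I")) {
    got <- position_profile(ds, ch)
    f <- ds$foci[ds$foci$channel == ch & ds$foci$cell_id %in% sub_ids, ]
    i <- match(f$cell_id, ds$cells$cell_id)
    rel <- f$position_um / ds$cells$length_um[i]
    rel <- ifelse(ds$cells$polarity_flip[i], 1 - rel, rel)
    rel_list <- split(rel, factor(f$cell_id, levels = sub_ids))
    want <- oracle_profile_medians(binning_length(ds)[ok], rel_list)
    expect_identical(got$center, want$center)
    expect_identical(got$dominant_type, want$type)
    expect_identical(got$med, want$med)
    expect_identical(got$lo_med, want$lo)
    expect_identical(got$up_med, want$up)
  }
})

test_that("first crossing picks the smallest interval reaching the threshold", {
  dup <- data.frame(center = c(2.0, 2.1, 2.2),
                    fraction = c(0.1, 0.4, 0.6))
  expect_equal(first_crossing(dup, 0.5), 2.2)
  expect_equal(first_crossing(dup, 0.25), 2.1)
  expect_true(is.na(first_crossing(dup, 0.9)))
})

test_that("loci rank by crossing interval with genomic tie-breaks", {
  mk <- function(cross) data.frame(center = cross, fraction = 0.6)
  dups <- list(ter = mk(3.6), ori = mk(2.2), mid = mk(2.8))
  r <- rank_loci_by_duplication(dups)
  expect_equal(r$locus, c("ori", "mid", "ter"))
  expect_false(any(r$tied))
  # tied crossings are flagged and broken by distance from ori
  dups2 <- list(b = mk(2.2), a = mk(2.2))
  loci2 <- list(a = locus("a", "I", 100), b = locus("b", "I", 400))
  r2 <- rank_loci_by_duplication(dups2, loci = loci2)
  expect_equal(r2$locus, c("a", "b"))
  expect_true(all(r2$tied))
})

test_that("simulated duplication order follows the genetic map along each arm", {
  ds <- wt_sim()$dataset
  arms <- list(left = c("ori_I", "L1_I", "L2_I", "L3_I", "L4_I",
                        "L5_I", "ter_I"),
               right = c("ori_I", "R1_I", "R2_I", "R3_I", "R4_I",
                         "R5_I", "ter_I"))
  for (arm in arms) {
    cross <- sapply(arm, function(ch)
      first_crossing(duplication_frequency(ds, ch), 0.5))
    cross[is.na(cross)] <- Inf   # never crossed = later than any interval
    expect_false(is.unsorted(cross))
  }
})

test_that("duplication curves of non-terminus loci rise sharply", {
  ds <- wt_sim()$dataset
  for (ch in c("ori_I", "L2_I", "R3_I")) {
    dup <- duplication_frequency(ds, ch)
    lo <- dup$center[!is.na(dup$fraction) & dup$fraction <= 0.1]
    hi <- dup$center[!is.na(dup$fraction) & dup$fraction >= 0.8]
    expect_true(length(lo) > 0 && length(hi) > 0)
    expect_lte(min(hi) - max(lo[lo < min(hi)]), 0.6)
  }
})
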