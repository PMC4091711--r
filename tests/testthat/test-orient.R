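# dividing cells with stereotyped foci for pole-preference calls
pref_dataset <- function(rel_positions, n = 25, L = 4) {
  foci <- replicate(n, list(A = rel_positions * L), simplify = FALSE)
  tiny_dataset(rep(L, n), foci)
}

oriented_rel <- function(ds, channel) {
  f <- ds$foci[ds$foci$channel == channel, ]
  i <- match(f$cell_id, ds$cells$cell_id)
  rel <- f$position_um / ds$cells$length_um[i]
  ok <- ds$cells$orientation[i] == "oriented"
  ifelse(ok, ifelse(ds$cells$polarity_flip[i], 1 - rel, rel), NA_real_)
}

test_that("septum-proximal foci in dividing cells call a new-pole preference", {
  ds <- pref_dataset(0.48)
  p <- classify_pole_preference(ds, "A", dividing_length_threshold = 3.5)
  expect_equal(p$preference, "new_pole")
  expect_gt(p$margin, 0.4)
})

test_that("pole-proximal sister foci call an old-pole preference", {
  ds <- pref_dataset(c(0.05, 0.95))
  p <- classify_pole_preference(ds, "A", dividing_length_threshold = 3.5)
  expect_equal(p$preference, "old_pole")
})

test_that("the quarter position is the vote boundary and ties go old-pole", {
  ds <- pref_dataset(0.25)   # d_sept = d_pole exactly
  p <- classify_pole_preference(ds, "A", dividing_length_threshold = 3.5)
  expect_equal(p$preference, "old_pole")
})

test_that("too few dividing cells yields an ambiguous preference with a warning", {
  ds <- pref_dataset(0.05, n = 5)
  expect_warning(
    p <- classify_pole_preference(ds, "A", dividing_length_threshold = 3.5),
    "dividing cells")
  expect_equal(p$preference, "ambiguous")
})

test_that("cells orient by the weighted asymmetry score, invariant to storage axis", {
  # 30 dividing cells fix the old-pole preference of channel A; two
  # mirror-image probe cells carry a single polar focus
  lengths <- c(rep(4, 30), 3.0, 3.0)
  foci <- c(replicate(30, list(A = c(0.2, 3.8)), simplify = FALSE),
            list(list(A = 2.4),    # focus at 0.8 L: already oriented
                 list(A = 0.6)))   # same cell stored flipped
  ds <- tiny_dataset(lengths, foci)
  out <- orient_cells(ds, ambiguity_tolerance = 0.05)
  n <- nrow(out$cells)
  probe <- (n - 1):n
  expect_equal(out$cells$orientation[probe], rep("oriented", 2))
  expect_equal(out$cells$polarity_flip[probe], c(FALSE, TRUE))
  rel <- oriented_rel(out, "A")
  expect_equal(tail(rel, 2), c(0.8, 0.8))
})

test_that("cells symmetric about midcell are ambiguous; zero score is never flipped", {
  lengths <- c(rep(4, 30), 3.0)
  foci <- c(replicate(30, list(A = c(0.2, 3.8)), simplify = FALSE),
            list(list(A = 1.5)))   # exactly at midcell
  ds <- tiny_dataset(lengths, foci)
  out <- orient_cells(ds)
  expect_equal(out$cells$orientation[nrow(out$cells)], "ambiguous")
  expect_true(is.na(out$cells$polarity_flip[nrow(out$cells)]))
})

test_that("datasets with only ambiguous preferences are returned unoriented", {
  # votes split exactly 50/50: zero margin, preference ambiguous
  foci <- c(replicate(12, list(A = 4 * 0.48), simplify = FALSE),
            replicate(12, list(A = 4 * 0.05), simplify = FALSE))
  ds <- tiny_dataset(rep(4, 24), foci)
  expect_warning(out <- orient_cells(ds), "ambiguous")
  expect_true(all(out$cells$orientation == "unoriented"))
  expect_true(isTRUE(attr(out, "orientation_failed")))
})

test_that("template refinement rescues cells matching an asymmetric profile", {
  # channel A: old-pole preference from dividing cells; channel B: a
  # terminus-like locus at 0.12 in mid-size cells; probe cell has A
  # split symmetrically so only the B template can orient it
  lengths <- c(rep(4, 30), rep(3.0, 30), 3.0)
  foci <- c(replicate(30, list(A = c(0.2, 3.8)), simplify = FALSE),
            replicate(30, list(A = 2.55, B = 0.36), simplify = FALSE),
            list(list(A = c(0.6, 2.4), B = 0.36)))
  ds <- tiny_dataset(lengths, foci)
  out <- suppressWarnings(orient_cells(ds, ambiguity_tolerance = 0.05))
  last <- nrow(out$cells)
  expect_equal(out$cells$orientation[last], "ambiguous")
  ref <- refine_orientation(out, margin = 0.05)
  expect_equal(ref$cells$orientation[last], "oriented")
  expect_false(ref$cells$polarity_flip[last])
  # an exact mirror tie stays ambiguous: make the B template symmetric
  foci2 <- foci
  for (i in 31:60) foci2[[i]]$B <- 1.5          # B at midcell
  ds2 <- tiny_dataset(lengths, foci2)
  out2 <- suppressWarnings(orient_cells(ds2, ambiguity_tolerance = 0.05))
  ref2 <- refine_orientation(out2, margin = 0.05)
  expect_equal(ref2$cells$orientation[last], "ambiguous")
})

test_that("orientation of simulated populations matches ground truth", {
  sim <- wt_sim()
  ds <- wt_oriented()
  acc <- orientation_accuracy(ds, sim$truth)
  expect_gte(acc$accuracy, 0.95)
  expect_lte(acc$ambiguous_fraction, 0.15)
  # flipping every stored axis must give the identical oriented result;
  # the true flip indicator complements under storage reversal
  ds_flip <- refine_orientation(orient_cells(flip_dataset(sim$dataset)))
  truth_flip <- sim$truth
  truth_flip$cells$flipped <- !truth_flip$cells$flipped
  acc2 <- orientation_accuracy(ds_flip, truth_flip)
  expect_equal(acc2$accuracy, acc$accuracy)
  expect_equal(acc2$ambiguous_fraction, acc$ambiguous_fraction)
  expect_equal(sort(oriented_rel(ds_flip, "ori_I")),
               sort(oriented_rel(ds, "ori_I")), tolerance = 1e-12)
})

test_that("simulated ori and ter channels classify to the expected poles", {
  ds <- wt_sim()$dataset
  expect_equal(classify_pole_preference(ds, "ori_I")$preference,
               "old_pole")
  expect_equal(classify_pole_preference(ds, "ter_I")$preference,
               "new_pole")
})
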