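test_that("steady-state ages follow the exponential-population age law", {
  tau <- 55
  a <- steady_state_ages(1e5, tau, seed = 101)
  expect_true(all(a >= 0 & a < tau))
  F <- function(q) 2 * (1 - 2^(-q / tau))
  ks <- suppressWarnings(stats::ks.test(a, F))
  expect_gt(ks$p.value, 0.01)
  # median of f(a) is tau*log2(4/3) ~ 22.8 min
  expect_equal(stats::median(a), tau * log2(4 / 3), tolerance = 0.02)
})

test_that("replication times follow fork progression from the origins", {
  expect_equal(replication_time("ori_I"), 11)
  expect_equal(replication_time("ter_I"), 43, tolerance = 0.01)
  # dif-adjacent locus on chromosome I finishes at B + C
  gm <- vc_genome_map()
  dif_loc <- locus("dif1", "I", gm$chromosomes$I$dif_kb, gm)
  expect_equal(replication_time(dif_loc), 43)
  # chromosome II fires later, terminates with chromosome I
  expect_gt(replication_time("ori_II"), replication_time("ori_I"))
  expect_equal(replication_time("ter_II"), 43, tolerance = 0.01)
  # ectopic origin: zero distance means replication at initiation
  repl2 <- replication_model(extra_origins = list(I = 651))
  ect <- locus("ect", "I", 651)
  expect_equal(replication_time(ect, repl2), 11)
  # and an intermediate locus is reached by the nearer fork
  expect_lt(replication_time("L3_I", repl2, panel = vc_locus_panel()),
            replication_time("L3_I"))
})

test_that("sister homes follow the affine division mapping", {
  expect_equal(unname(sister_homes(0.8)), c(0.9, 0.1))
  expect_equal(unname(sister_homes(0.5)), c(0.75, 0.25))
})

test_that("division mapping is self-similar: daughters recover the mother's home", {
  # exact (bitwise) on dyadic homes, where every operation is exact
  for (h in (1:15) / 16) {
    homes <- sister_homes(h)
    expect_identical(daughter_coordinate(homes[["old"]], "old"), h)
    expect_identical(daughter_coordinate(homes[["new"]], "new"), h)
  }
  # and to machine precision everywhere
  set.seed(1)
  h <- stats::runif(100, 0.01, 0.99)
  expect_equal(unname(daughter_coordinate(sister_homes(h)[1:100], "old")),
               h, tolerance = 1e-14)
})

test_that("noiseless positions sit at homes before and after segregation", {
  scn <- preset_scenario("WT")
  # static locus, pre-duplication
  h <- scn$program$h_pre[scn$program$locus == "ori_I"]
  expect_equal(position_at_age("ori_I", 5, scn), h)
  # post-transition: exactly at sister homes
  pos <- position_at_age("ori_I", 50, scn, split_age = 16)
  expect_equal(pos, unname(sister_homes(h)))
  # midcell-early locus reaches 0.5 before duplicating
  row <- scn$program[scn$program$locus == "ter_I", ]
  expect_equal(position_at_age("ter_I", row$midcell_age_min + 1, scn),
               0.5)
  expect_equal(position_at_age("ter_I", 5, scn), row$h_pre)
})

test_that("focus state switches from one to two foci at the sampled split age", {
  scn <- preset_scenario("WT")
  set.seed(42)
  st_young <- focus_state("ori_I", 2, scn)
  expect_equal(st_young$count, 1L)
  set.seed(42)
  st_old <- focus_state("ori_I", 54.9, scn)
  expect_equal(st_old$count, 2L)
  expect_true(all(st_old$positions > 0 & st_old$positions < 1))
})

test_that("sampled populations are reproducible and have calibrated lengths", {
  scn <- preset_scenario("WT", loci = c("ori_I", "ter_I"))
  s1 <- sample_population(scn, 200, seed = 7)
  s2 <- sample_population(scn, 200, seed = 7)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$truth, s2$truth)
  s3 <- sample_population(scn, 200, seed = 8)
  expect_false(identical(s1$dataset$foci, s3$dataset$foci))

  L <- wt_sim()$dataset$cells$length_um
  expect_gte(mean(L >= 1.9 & L <= 4.3), 0.9)
})

test_that("the stored axis is flipped with probability one half", {
  scn <- preset_scenario("WT", loci = "ori_I")
  sim <- sample_population(scn, 1e4, seed = 5)
  expect_equal(mean(sim$truth$cells$flipped), 0.5, tolerance = 0.04)
})

test_that("terminus-class loci duplicate in the configured fraction of dividing cells", {
  sim <- wt_sim()
  ds <- sim$dataset
  thr <- stats::quantile(ds$cells$length_um, 0.9, names = FALSE)
  div <- ds$cells$cell_id[ds$cells$length_um >= thr]
  frac2 <- function(ch) {
    cnt <- focus_count(ds, ch)[match(div, ds$cells$cell_id)]
    mean(cnt == 2L)
  }
  # targets 50/40/10% at the moment of division; cells in the dividing
  # length decile are slightly younger, so allow a generous band
  expect_lt(frac2("ter_I"), 0.2)
  expect_gt(frac2("L5_I"), 0.25)
  expect_gt(frac2("R5_I"), 0.2)
  expect_lt(frac2("ter_I"), frac2("R5_I"))
  expect_lt(frac2("R5_I"), frac2("L5_I") + 0.05)
})

test_that("preset scenarios encode the perturbed positional programs", {
  h_of <- function(scn, loc) scn$program$h_pre[scn$program$locus == loc]
  wt <- preset_scenario("WT")
  expect_equal(h_of(wt, "ori_I"), 0.8)
  expect_equal(h_of(wt, "ori_II"), 0.55)
  expect_equal(h_of(wt, "ter_II"), 0.28)
  # homes decrease ori -> ter along the left replichore
  hs <- sapply(c("ori_I", "L1_I", "L2_I", "L3_I", "L4_I"),
               function(l) h_of(wt, l))
  expect_true(all(diff(hs) < 0))

  dp <- preset_scenario("delta_parS")
  expect_equal(h_of(dp, "ori_I"), 0.7)
  # terminus program pinned
  expect_equal(h_of(dp, "ter_I"), h_of(wt, "ter_I"))

  # parS displaced to 650 kb: the locus 170 kb away (L2, at 480 kb)
  # inherits a more polar home than ori, now 650 kb from the anchor;
  # ori gets the home of a locus at that distance from the WT anchor
  p650 <- preset_scenario("parS_displaced", parS_kb = 650)
  expect_gt(h_of(p650, "L2_I"), h_of(p650, "ori_I"))
  expect_equal(h_of(p650, "ori_I"),
               h_of(wt, "L3_I"), tolerance = 0.01)
  expect_error(preset_scenario("parS_displaced"), "parS_kb")
  expect_error(preset_scenario("nonsense"))
})

test_that("chromosome II ori-proximal loci split later than ori_I", {
  sim <- wt_sim()
  med_split <- function(ch) {
    tl <- sim$truth$loci
    stats::median(tl$t_split_min[tl$locus == ch])
  }
  expect_gt(med_split("ori_II"), med_split("ori_I"))
  expect_gt(med_split("R1_II"), med_split("ori_I"))
})
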