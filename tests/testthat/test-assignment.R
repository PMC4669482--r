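test_that("coverage summaries normalize by library size and union covered bases", {
  sc <- scaffold_set(lengths = c(s1 = 100L, s2 = 100L))
  # one A track: depth 20 on all of s1, nothing on s2 -> genome-wide mean 10
  trA <- flat_track("A1", sc, 20, ids = "s1")
  trA2 <- flat_track("A2", sc, 20, ids = "s1")
  trD <- flat_track("D1", sc, 10)   # uniform everywhere
  trD2 <- flat_track("D2", sc, 10)
  s <- summarize_coverage(list(trA, trA2, trD, trD2), fix_manifest(), sc)
  expect_equal(unname(s$per_dataset["s1", "A1"]), 2.0)  # 20 / 10
  expect_equal(unname(s$covered["s1", "A"]), 1.0)
  expect_equal(unname(s$covered["s2", "A"]), 0.0)       # absence = zero
  expect_equal(unname(s$per_dataset["s2", "A1"]), 0.0)
  expect_equal(unname(s$covered["s2", "union"]), 1.0)   # D tracks cover it
})

test_that("clade covered fraction uses the union of the clade's tracks", {
  sc <- scaffold_set(lengths = c(s1 = 100L))
  left <- coverage_track("A1", data.frame(scaffold_id = "s1", start = 0L,
                                          end = 50L, depth = 5), sc)
  right <- coverage_track("A2", data.frame(scaffold_id = "s1", start = 50L,
                                           end = 100L, depth = 5), sc)
  d <- flat_track("D1", sc, 1); d2 <- flat_track("D2", sc, 1)
  s <- summarize_coverage(list(left, right, d, d2), fix_manifest(), sc)
  expect_equal(unname(s$covered["s1", "A"]), 1.0)
})

test_that("three-criteria classifier labels At, Dt and ungrouped correctly", {
  # build a summary object by hand through tracks engineered per scaffold
  sc <- scaffold_set(lengths = c(at = 1000L, dt = 1000L, un = 1000L,
                                 flat = 1000L))
  mk <- function(id, d_at, d_dt, d_un, d_flat) {
    coverage_track(id, data.frame(
      scaffold_id = c("at", "dt", "un", "flat"), start = 0L, end = 1000L,
      depth = c(d_at, d_dt, d_un, d_flat)), sc)
  }
  # A-clade sees at+flat; D-clade sees dt+flat; un barely covered (depth 0 rows dropped)
  tracks <- list(mk("A1", 21, 0.1, 0, 10), mk("A2", 19, 0.1, 0, 10),
                 mk("A3", 20, 0.1, 0, 10),
                 mk("D1", 0.1, 20, 0, 10), mk("D2", 0.1, 21, 0, 10),
                 mk("D3", 0.1, 19, 0, 10))
  s <- summarize_coverage(tracks, fix_manifest(3, 3), sc)
  a <- assign_scaffolds(s)
  lab <- setNames(a$label, a$scaffold_id)
  expect_identical(unname(lab[c("at", "dt", "un", "flat")]),
                   c("At", "Dt", "ungrouped", "ungrouped"))
  # all-zero coverage fails criterion 1; equal coverage fails criterion 2
  expect_false(a$crit_coverage[a$scaffold_id == "un"])
  expect_true(a$crit_coverage[a$scaffold_id == "flat"])
  expect_false(a$crit_ratio[a$scaffold_id == "flat"])
})

test_that("t statistic and p-value equal the textbook two-sample computation", {
  # spec-derived example: A (2.1, 1.9, 2.0) vs D (0.10, 0.12, 0.08)
  o <- oracle_student_t(c(2.1, 1.9, 2.0), c(0.10, 0.12, 0.08))
  got <- allotetra:::.two_sample_t(c(2.1, 1.9, 2.0), c(0.10, 0.12, 0.08))
  expect_equal(got[1], unname(o["t"]), tolerance = 1e-12)
  expect_equal(got[2], unname(o["p"]), tolerance = 1e-12)
  expect_lt(o["p"], 0.01)
  expect_gt(log2(2.0 / 0.1), 2)
})

test_that("fewer than two replicates per clade demands an explicit opt-out", {
  sc <- scaffold_set(lengths = c(s1 = 100L))
  tr <- list(flat_track("A1", sc, 10), flat_track("D1", sc, 10),
             flat_track("D2", sc, 10))
  s <- summarize_coverage(tr, fix_manifest(1, 2), sc)
  expect_error(assign_scaffolds(s), "use_ttest")
  a <- assign_scaffolds(s, pipeline_config(use_ttest = FALSE))
  expect_identical(a$label, "ungrouped")  # ratio 0
})

test_that("labels partition the assembly and totals are exact", {
  p <- simulation_params(n_scaffolds = 30, scaffold_length_min = 50000,
                         scaffold_length_max = 80000, rng_seed = 2)
  sim <- simulate_tetraploid(p)
  a <- assign_scaffolds(summarize_coverage(sim$tracks, sim$manifest,
                                           sim$scaffolds))
  expect_equal(nrow(a), 30)
  expect_true(all(a$label %in% c("At", "Dt", "ungrouped")))
  rpt <- assignment_report(a, sim$scaffolds)
  expect_equal(sum(rpt$n_scaffolds[rpt$label != "total"]),
               rpt$n_scaffolds[rpt$label == "total"])
  expect_equal(sum(rpt$total_length[rpt$label != "total"]),
               rpt$total_length[rpt$label == "total"])
})

test_that("scaling all A-clade depths up never flips At toward Dt (monotonicity)", {
  p <- simulation_params(n_scaffolds = 20, scaffold_length_min = 50000,
                         scaffold_length_max = 80000, rng_seed = 3)
  sim <- simulate_tetraploid(p)
  base <- assign_scaffolds(summarize_coverage(sim$tracks, sim$manifest,
                                              sim$scaffolds))
  boosted <- lapply(sim$tracks, function(t) {
    m <- sim$manifest
    if (m$clade[m$dataset_id == t$dataset_id] == "A") {
      t$intervals$depth <- t$intervals$depth * 3
    }
    t
  })
  b <- assign_scaffolds(summarize_coverage(boosted, sim$manifest, sim$scaffolds))
  was_at <- base$label == "At"
  expect_false(any(b$label[was_at] == "Dt"))
})

test_that("swapping the A and D clades swaps At and Dt labels exactly", {
  p <- simulation_params(n_scaffolds = 24, scaffold_length_min = 50000,
                         scaffold_length_max = 80000, rng_seed = 4)
  sim <- simulate_tetraploid(p)
  a1 <- assign_scaffolds(summarize_coverage(sim$tracks, sim$manifest,
                                            sim$scaffolds))
  m2 <- sim$manifest
  m2$clade <- c(A = "D", D = "A", AD = "AD")[m2$clade]
  m2 <- dataset_manifest(as.data.frame(m2))
  a2 <- assign_scaffolds(summarize_coverage(sim$tracks, m2, sim$scaffolds))
  swap <- c(At = "Dt", Dt = "At", ungrouped = "ungrouped")
  expect_identical(unname(swap[a1$label]), a2$label)
  expect_equal(a2$log2_ratio, -a1$log2_ratio, tolerance = 1e-12)
})

test_that("N50 agrees with the exhaustive definition", {
  expect_equal(n50(c(8, 2)), 8)
  expect_equal(n50(numeric(0)), 0)
  withr::local_seed(7)
  for (i in 1:25) {
    lens <- sample(1:500, sample(1:20, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})
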