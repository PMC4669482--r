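small_params <- function(...) {
  simulation_params(n_scaffolds = 10, scaffold_length_min = 50000,
                    scaffold_length_max = 60000, ungrouped_fraction = 0,
                    depth_noise = "none", ...)
}

test_that("noise-free tetraploids have perfect clade-exclusive coverage", {
  sim <- simulate_tetraploid(small_params(rng_seed = 1))
  s <- summarize_coverage(sim$tracks, sim$manifest, sim$scaffolds)
  at <- names(sim$truth$scaffold_subgenome)[sim$truth$scaffold_subgenome == "At"]
  dt <- names(sim$truth$scaffold_subgenome)[sim$truth$scaffold_subgenome == "Dt"]
  expect_true(all(s$covered[at, "A"] == 1.0))
  expect_true(all(s$covered[at, "D"] == 0.0))
  expect_true(all(s$covered[dt, "D"] == 1.0))
  expect_true(all(s$covered[dt, "A"] == 0.0))
})

test_that("identical seeds reproduce simulations exactly; hybrids are counted", {
  p <- simulation_params(n_scaffolds = 12, n_hybrids = 2, rng_seed = 77)
  s1 <- simulate_tetraploid(p)
  s2 <- simulate_tetraploid(p)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth$junctions), 2)
  expect_equal(length(unique(s1$truth$junctions$scaffold_id)), 2)
  lens <- s1$scaffolds$lengths[s1$truth$junctions$scaffold_id]
  expect_true(all(s1$truth$junctions$position > 0 &
                    s1$truth$junctions$position < lens))
  expect_error(simulate_tetraploid(simulation_params(n_scaffolds = 3,
                                                     n_hybrids = 4)),
               "n_hybrids")

  e1 <- simulate_expression(p); e2 <- simulate_expression(p)
  expect_identical(e1, e2)
  l1 <- simulate_ltr_pairs(simulation_params(ltr_count = 5, rng_seed = 77))
  l2 <- simulate_ltr_pairs(simulation_params(ltr_count = 5, rng_seed = 77))
  expect_identical(l1, l2)
})

test_that("LTR pairs start identical at age 0 and diverge as K = 2rT", {
  z <- simulate_ltr_pairs(simulation_params(ltr_count = 5, ltr_true_ages = 0,
                                            rng_seed = 5))
  expect_identical(z$pairs$five_prime, z$pairs$three_prime)

  # 200 pairs at 3 Myr, r = 1.3e-8: expected K = 2 * 1.3e-8 * 3e6 = 0.078
  sim <- simulate_ltr_pairs(simulation_params(ltr_count = 200,
                                              ltr_true_ages = 3e6,
                                              rng_seed = 6))
  ks <- vapply(seq_len(200), function(i) {
    k2p_divergence(sim$pairs$five_prime[i], sim$pairs$three_prime[i])$K
  }, 0)
  expect_equal(mean(ks), 0.078, tolerance = 0.05)
})

test_that("simulated substitutions respect the transition:transversion ratio", {
  sim <- simulate_ltr_pairs(simulation_params(ltr_count = 150,
                                              ltr_true_ages = 3e6,
                                              ltr_ts_tv_ratio = 2,
                                              rng_seed = 8))
  counts <- vapply(seq_len(nrow(sim$pairs)), function(i) {
    k <- k2p_divergence(sim$pairs$five_prime[i], sim$pairs$three_prime[i])
    c(ts = k$P * k$sites, tv = k$Q * k$sites)
  }, c(ts = 0, tv = 0))
  ratio <- sum(counts["ts", ]) / sum(counts["tv", ])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("expression simulation plants the requested bias structure", {
  none <- simulate_expression(simulation_params(n_pairs = 50,
                                                bias_at_fraction = 0,
                                                bias_dt_fraction = 0,
                                                rng_seed = 3))
  expect_true(all(none$truth$class == "unbiased"))

  ex <- simulate_expression(simulation_params(n_pairs = 1000, rng_seed = 4))
  expect_equal(sum(ex$truth$class == "At-biased"), 300)
  expect_equal(sum(ex$truth$class == "Dt-biased"), 200)
  expect_equal(ncol(ex$matrix), 8)
  expect_true(all(c("FE", "FS") %in% colnames(ex$matrix)))
  expect_true(all(ex$matrix >= 0))
  # 4x effect with log2 threshold 1: planted biased pairs exceed it in expectation
  expect_gt(log2(simulation_params()$bias_effect_size), 1)
})

test_that("map simulation plants recoverable, rejectable and ambiguous markers", {
  p <- simulation_params(n_markers = 60, n_chromosomes = 2,
                         scaffolds_per_chromosome = 3,
                         map_scaffold_length = 10000,
                         frac_bad_markers = 0.1, frac_duplicated_markers = 0.1,
                         rng_seed = 10)
  mv <- simulate_map_and_vcf(p)
  tr <- mv$truth$marker_truth
  expect_equal(sum(tr$status == "mismatched"), 6)
  expect_equal(sum(tr$status == "duplicated"), 6)
  expect_true(any(grepl("^decoy", mv$scaffolds$ids)))
  # clean markers really are verbatim copies at the recorded offset/strand
  clean <- which(tr$status == "clean")[1:10]
  for (i in clean) {
    seg <- mv$markers$segment[mv$markers$marker_id == tr$marker_id[i]]
    sq <- as.character(Biostrings::subseq(
      mv$scaffolds$sequences[[tr$scaffold_id[i]]],
      start = tr$offset[i] + 1, width = nchar(seg)))
    if (tr$strand[i] == "-") sq <- rc(sq)
    expect_identical(sq, seg)
  }
  # mismatched markers differ from the reference at exactly 6 positions
  bad <- which(tr$status == "mismatched")[1]
  seg <- mv$markers$segment[mv$markers$marker_id == tr$marker_id[bad]]
  sq <- as.character(Biostrings::subseq(
    mv$scaffolds$sequences[[tr$scaffold_id[bad]]],
    start = tr$offset[bad] + 1, width = nchar(seg)))
  if (tr$strand[bad] == "-") sq <- rc(sq)
  expect_equal(sum(strsplit(sq, "")[[1]] != strsplit(seg, "")[[1]]), 6)
})

test_that("planted VCF alleles are lineage-exclusive by construction", {
  p <- simulation_params(n_lineage_sites = 40, n_shared_sites = 10,
                         n_markers = 20, n_chromosomes = 2,
                         scaffolds_per_chromosome = 2, rng_seed = 11)
  mv <- simulate_map_and_vcf(p)
  lin <- setNames(mv$manifest$clade, mv$manifest$dataset_id)
  truth <- mv$truth$lineage_snps
  key <- paste(mv$vcf$fix$contig, mv$vcf$fix$pos)
  for (i in seq_len(nrow(truth))) {
    row <- match(paste(truth$contig[i], truth$pos[i]), key)
    has_alt <- grepl("1", mv$vcf$gt[row, ])
    expect_true(all(has_alt == (lin[colnames(mv$vcf$gt)] == truth$lineage[i])))
  }
})

test_that("simulation writers emit files the io layer reads back", {
  sim <- simulate_tetraploid(small_params(rng_seed = 2))
  d <- withr::local_tempdir()
  write_tetraploid_simulation(sim, d)
  man <- read_manifest(file.path(d, "manifest.tsv"))
  expect_identical(man$dataset_id, sim$manifest$dataset_id)
  tr <- read_bedgraph(file.path(d, paste0(man$dataset_id[1], ".bedgraph")),
                      man$dataset_id[1], sim$scaffolds)
  expect_equal(tr$intervals, sim$tracks[[1]]$intervals)
})
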