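test_that("SNP segments are cut 100+1+100 with edge SNPs skipped", {
  withr::local_seed(1)
  ref <- fix_scaffolds(s1 = random_dna(300))
  snps <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = "c1",
                     cM = c(1, 2, 3), scaffold_id = "s1",
                     position = c(150L, 50L, 101L), stringsAsFactors = FALSE)
  expect_message(seg <- extract_segments(snps, ref), "skipped")
  expect_identical(seg$marker_id, c("m1", "m3"))
  expect_equal(nchar(seg$segment), c(201L, 201L))
  full <- as.character(ref$sequences[["s1"]])
  expect_identical(seg$segment[1], substr(full, 50, 250))
  expect_identical(seg$segment[2], substr(full, 1, 201))
  expect_error(extract_segments(transform(snps, scaffold_id = "sX"), ref),
               "absent")
})

planted_markers <- function(scaffolds, plants) {
  # plants: data.frame(marker_id, chromosome, cM, scaffold_id, offset, strand, n_mm)
  segs <- vapply(seq_len(nrow(plants)), function(i) {
    sq <- as.character(Biostrings::subseq(
      scaffolds$sequences[[plants$scaffold_id[i]]],
      start = plants$offset[i] + 1, width = 201))
    if (plants$strand[i] == "-") sq <- rc(sq)
    if (plants$n_mm[i] > 0) {
      ch <- strsplit(sq, "")[[1]]
      pos <- seq_len(plants$n_mm[i]) * 7
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      sq <- paste(ch, collapse = "")
    }
    sq
  }, "")
  allotetra:::add_order_index(
    data.frame(marker_id = plants$marker_id, chromosome = plants$chromosome,
               cM = plants$cM, segment = segs, stringsAsFactors = FALSE))
}

test_that("segment matching obeys the 196/201 rule and uniqueness", {
  withr::local_seed(2)
  sc <- fix_scaffolds(s1 = random_dna(5000), s2 = random_dna(5000))
  plants <- data.frame(
    marker_id = c("exact", "mm5", "mm6", "minus"),
    chromosome = "c1", cM = 1:4,
    scaffold_id = c("s1", "s1", "s2", "s2"),
    offset = c(1000L, 2000L, 1000L, 3000L),
    strand = c("+", "+", "+", "-"),
    n_mm = c(0L, 5L, 6L, 0L), stringsAsFactors = FALSE)
  mk <- planted_markers(sc, plants)
  hits <- match_segments(mk, sc)
  expect_setequal(hits$marker_id, c("exact", "mm5", "minus"))
  h <- hits[hits$marker_id == "exact", ]
  expect_identical(h$scaffold_id, "s1")
  expect_equal(h$start, 1000)
  expect_identical(h$strand, "+")
  expect_equal(h$matched, 201)
  expect_equal(hits$matched[hits$marker_id == "mm5"], 196)
  expect_identical(hits$strand[hits$marker_id == "minus"], "-")

  # duplicated plant -> dropped as non-unique
  dup_seq <- as.character(Biostrings::subseq(sc$sequences[["s1"]], 1001, 1201))
  sc2 <- fix_scaffolds(s1 = as.character(sc$sequences[["s1"]]),
                       s2 = paste0(random_dna(100), dup_seq, random_dna(100)))
  expect_message(h2 <- match_segments(mk[mk$marker_id == "exact", ], sc2),
                 "tied")
  expect_equal(nrow(h2), 0)
})

test_that("matcher equals the brute-force position scan", {
  withr::local_seed(3)
  sc <- fix_scaffolds(s1 = random_dna(3000), s2 = random_dna(3000))
  plants <- data.frame(
    marker_id = paste0("m", 1:4), chromosome = "c1", cM = 1:4,
    scaffold_id = c("s1", "s2", "s1", "s2"),
    offset = c(100L, 500L, 2500L, 1200L),
    strand = c("+", "-", "+", "-"),
    n_mm = c(0L, 3L, 5L, 1L), stringsAsFactors = FALSE)
  mk <- planted_markers(sc, plants)
  a <- match_segments(mk, sc)
  b <- match_segments_bruteforce(mk, sc)
  expect_equal(a[order(a$marker_id), ], b[order(b$marker_id), ],
               ignore_attr = TRUE)
})

test_that("anchoring requires 5 continuous map-order segments on one chromosome", {
  # 20 markers on c1; scaffold A holds map orders 10..14, scaffold B holds
  # 1,2,3,5,6 (longest run 3) -> only A anchors
  hits <- data.frame(
    marker_id = c(paste0("c1_", 10:14), paste0("c1_", c(1, 2, 3, 5, 6))),
    scaffold_id = rep(c("A", "B"), each = 5),
    start = c(seq(100, 500, by = 100), seq(500, 100, by = -100)),
    strand = "+", matched = 201L, unique = TRUE, stringsAsFactors = FALSE)
  markers <- data.frame(marker_id = paste0("c1_", 1:20), chromosome = "c1",
                        cM = 1:20, order_index = 1:20, segment = "N",
                        stringsAsFactors = FALSE)
  anc <- anchor_scaffolds(hits, markers)
  expect_identical(anc$scaffold_id, "A")
  expect_identical(anc$chromosome, "c1")
  expect_identical(anc$orientation, "+")
  expect_equal(anc$n_markers, 5)

  # decreasing scaffold coordinate with map order -> minus orientation
  hits$start[1:5] <- rev(hits$start[1:5])
  anc2 <- anchor_scaffolds(hits, markers)
  expect_identical(anc2$orientation, "-")

  # qualifying runs on two chromosomes -> rejected
  hits3 <- rbind(hits[1:5, ],
                 data.frame(marker_id = paste0("c2_", 1:5), scaffold_id = "A",
                            start = seq(1000, 1400, by = 100), strand = "+",
                            matched = 201L, unique = TRUE,
                            stringsAsFactors = FALSE))
  markers3 <- rbind(markers,
                    data.frame(marker_id = paste0("c2_", 1:5),
                               chromosome = "c2", cM = 1:5, order_index = 1:5,
                               segment = "N", stringsAsFactors = FALSE))
  expect_message(anc3 <- anchor_scaffolds(hits3, markers3), "rejected")
  expect_equal(nrow(anc3), 0)
})

test_that("pseudochromosome building concatenates, orients and gaps scaffolds", {
  sc <- fix_scaffolds(a = paste(rep("ACGTACGTAC", 10), collapse = ""),
                      b = paste(rep("AAAC", 25), collapse = ""))
  anchored <- data.frame(scaffold_id = c("a", "b"), chromosome = "c1",
                         position_cM = c(1, 2), orientation = c("+", "-"),
                         n_markers = 5L, cm_span = 1, stringsAsFactors = FALSE)
  built <- build_pseudochromosomes(anchored, sc)
  expect_equal(unname(built$sequences$lengths["c1"]), 300L)  # 100+100+100
  chr <- as.character(built$sequences$sequences[["c1"]])
  expect_identical(substr(chr, 101, 200), strrep("N", 100))
  expect_identical(substr(chr, 201, 204), "GTTT")  # revcomp of AAAC
  expect_identical(built$layout$chrom_start, c(0L, 200L))
  expect_error(build_pseudochromosomes(rbind(anchored, anchored[1, ]), sc),
               "more than once")
  empty <- build_pseudochromosomes(anchored[0, ], sc)
  expect_equal(nrow(empty$layout), 0)
})

test_that("map truth is recovered end to end on a small shredded genome", {
  p <- simulation_params(n_markers = 240, n_chromosomes = 2,
                         scaffolds_per_chromosome = 4,
                         map_scaffold_length = 12000,
                         frac_bad_markers = 0.05,
                         frac_duplicated_markers = 0.05, rng_seed = 31)
  mv <- simulate_map_and_vcf(p)
  hits <- suppressMessages(match_segments(mv$markers, mv$scaffolds))
  bad <- mv$truth$marker_truth$marker_id[mv$truth$marker_truth$status != "clean"]
  expect_false(any(hits$marker_id %in% bad))
  anc <- anchor_scaffolds(hits, mv$markers)
  m <- merge(anc, mv$truth$scaffold_truth, by = "scaffold_id")
  expect_true(all(m$chromosome.x == m$chromosome.y))
  expect_true(all(m$orientation.x == m$orientation.y))
  for (chr in unique(m$chromosome.y)) {
    d <- m[m$chromosome.y == chr, ]
    expect_equal(cor(d$position_cM, d$true_order, method = "kendall"), 1)
  }
})
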