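# Independent reference computations used to check the package's results.
# These deliberately re-derive everything from first principles.

# textbook two-sample t-test (equal-variance Student form)
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(t), df = nx + ny - 2)
  c(t = t, p = p)
}

# N50 by exhaustive definition: largest L with sum(lengths >= L) >= total/2
oracle_n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  }
  min(lengths)
}

# K2P closed form evaluated directly from proportions
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# connected components by naive union-find over an undirected edge list
oracle_components <- function(vertices, edges_from, edges_to) {
  parent <- setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (i in seq_along(edges_from)) {
    a <- find(edges_from[i]); b <- find(edges_to[i])
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  comp <- vapply(vertices, find, "")
  # canonical labels: integer rank of each root
  rank_of <- setNames(seq_along(sort(unique(comp))), sort(unique(comp)))
  setNames(as.integer(rank_of[comp]), vertices)
}

# build a scaffold_set with given sequences
fix_scaffolds <- function(...) {
  seqs <- c(...)
  scaffold_set(sequences = Biostrings::DNAStringSet(seqs))
}

# a uniform-depth coverage track over whole scaffolds
flat_track <- function(dataset_id, scaffolds, depth, ids = scaffolds$ids) {
  coverage_track(dataset_id,
                 data.frame(scaffold_id = ids, start = 0L,
                            end = unname(scaffolds$lengths[ids]),
                            depth = depth),
                 scaffolds)
}

# manifest with n replicates per clade
fix_manifest <- function(nA = 2, nD = 2, nAD = 0) {
  rows <- NULL
  for (cl in c("A", "D", "AD")) {
    n <- switch(cl, A = nA, D = nD, AD = nAD)
    if (n > 0) rows <- rbind(rows, data.frame(
      dataset_id = paste0(cl, seq_len(n)), clade = cl,
      line_label = paste0(cl, seq_len(n)), stringsAsFactors = FALSE))
  }
  dataset_manifest(rows)
}

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
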