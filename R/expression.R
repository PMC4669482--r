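#' Read an FPKM expression matrix
#'
#' TSV with a `gene` column then one column per tissue.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("expression table needs a 'gene' column")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  if (any(m < 0)) stop("FPKM values must be non-negative")
  rownames(m) <- df$gene
  m
}

#' Normalize expression profiles
#'
#' Per gene: log2(FPKM + 1), then z-score across tissues. Genes with zero
#' variance get an all-zero profile and are flagged in the
#' `"zero_variance"` attribute.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @return Normalized matrix with attribute `zero_variance` (character vector
#'   of flagged gene ids).
#' @export
normalize_profiles <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least 2 tissues")
  lg <- log2(matrix + 1)
  mu <- rowMeans(lg)
  sdev <- apply(lg, 1, stats::sd)
  flat <- sdev == 0
  z <- (lg - mu) / ifelse(flat, 1, sdev)
  z[flat, ] <- 0
  attr(z, "zero_variance") <- rownames(matrix)[flat]
  z
}

#' Seeded, permutation-invariant k-means on expression profiles
#'
#' Genes are sorted by id before a seeded initialization (k distinct genes
#' sampled as starting centers), so the result does not depend on input row
#' order. Lloyd iterations run to assignment stability or 300 iterations.
#'
#' @param normalized Normalized profile matrix (see [normalize_profiles()]).
#' @param k Number of clusters (2 <= k <= number of genes).
#' @param seed RNG seed.
#' @return List of class `"cluster_result"`: `cluster` (named integer vector),
#'   `k`, `seed`, `centers`, `tot_withinss`.
#' @export
kmeans_cluster <- function(normalized, k, seed = 1L) {
  n <- nrow(normalized)
  if (k > n) stop("k (", k, ") exceeds gene count (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  normalized <- normalized[order(rownames(normalized)), , drop = FALSE]
  fit <- withr::with_seed(as.integer(seed), {
    centers <- normalized[sample.int(n, k), , drop = FALSE]
    stats::kmeans(normalized, centers = centers, iter.max = 300,
                  algorithm = "Lloyd")
  })
  structure(list(cluster = stats::setNames(as.integer(fit$cluster),
                                           rownames(normalized)),
                 k = k, seed = as.integer(seed), centers = fit$centers,
                 tot_withinss = fit$tot.withinss),
            class = "cluster_result")
}

#' Read a homoeolog pair table
#'
#' TSV with `pair_id`, `at_gene`, `dt_gene`; each gene may belong to at most
#' one pair.
#'
#' @param path TSV path.
#' @return data.frame of pairs.
#' @export
read_homoeolog_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "at_gene", "dt_gene")
  if (!all(req %in% names(df))) stop("pairs need columns: ",
                                     paste(req, collapse = ", "))
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_ids")
  if (anyDuplicated(c(df$at_gene, df$dt_gene))) stop("a gene appears in >1 pair")
  df
}

# combined (At + Dt) FPKM per pair x tissue (internal)
.pair_combined <- function(matrix, pairs) {
  missing <- setdiff(c(pairs$at_gene, pairs$dt_gene), rownames(matrix))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  matrix[pairs$at_gene, , drop = FALSE] + matrix[pairs$dt_gene, , drop = FALSE]
}

#' Pairs highly and specifically expressed in a focal tissue
#'
#' A pair qualifies when its combined (At + Dt) FPKM in the focal tissue is at
#' least `expression_floor` and at least `specificity_factor` times the
#' combined expression in every other tissue.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param pairs Homoeolog pair data.frame.
#' @param focal_tissue Column name of the focal tissue.
#' @param config A [pipeline_config()].
#' @return The qualifying subset of `pairs`, with a `combined_focal` column.
#' @export
tissue_specific_pairs <- function(matrix, pairs, focal_tissue,
                                  config = pipeline_config()) {
  if (!focal_tissue %in% colnames(matrix)) stop("unknown tissue: ", focal_tissue)
  comb <- .pair_combined(matrix, pairs)
  focal <- comb[, focal_tissue]
  others <- comb[, setdiff(colnames(comb), focal_tissue), drop = FALSE]
  ok <- focal >= config$expression_floor &
    focal >= config$specificity_factor * apply(others, 1, max)
  out <- pairs[ok, , drop = FALSE]
  out$combined_focal <- focal[ok]
  rownames(out) <- NULL
  out
}

#' Call homoeolog expression bias in a focal tissue
#'
#' ratio = log2((FPKM_At + 1) / (FPKM_Dt + 1)); a pair is At-biased when
#' ratio >= `bias_log2_threshold`, Dt-biased when ratio <= -threshold,
#' otherwise unbiased.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param pairs Homoeolog pair data.frame.
#' @param focal_tissue Column name of the focal tissue.
#' @param config A [pipeline_config()].
#' @return data.frame `pair_id`, `tissue`, `at_fpkm`, `dt_fpkm`, `log2_ratio`,
#'   `class` in `{At-biased, Dt-biased, unbiased}`.
#' @export
call_bias <- function(matrix, pairs, focal_tissue, config = pipeline_config()) {
  if (!focal_tissue %in% colnames(matrix)) stop("unknown tissue: ", focal_tissue)
  missing <- !(pairs$at_gene %in% rownames(matrix) &
                 pairs$dt_gene %in% rownames(matrix))
  if (any(missing)) stop("gene missing from matrix for pair(s): ",
                         paste(utils::head(pairs$pair_id[missing], 5),
                               collapse = ", "))
  at <- matrix[pairs$at_gene, focal_tissue]
  dt <- matrix[pairs$dt_gene, focal_tissue]
  lr <- log2((at + 1) / (dt + 1))
  cls <- rep("unbiased", nrow(pairs))
  cls[lr >= config$bias_log2_threshold] <- "At-biased"
  cls[lr <= -config$bias_log2_threshold] <- "Dt-biased"
  data.frame(pair_id = pairs$pair_id, tissue = focal_tissue,
             at_fpkm = unname(at), dt_fpkm = unname(dt),
             log2_ratio = unname(lr), class = cls, stringsAsFactors = FALSE)
}

#' Per-group summed expression profiles
#'
#' Sums FPKM over the genes of each group in every tissue — e.g. to compare
#' the collective output of a clade of genes (such as a CesA phylogenetic
#' group) with that of another. Missing genes are an error; empty groups give
#' a zero row and are flagged with a message.
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param groups Named list of character vectors of gene ids.
#' @return Groups x tissues numeric matrix.
#' @export
group_expression_sum <- function(matrix, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- matrix(0, nrow = length(groups), ncol = ncol(matrix),
                dimnames = list(names(groups), colnames(matrix)))
  for (g in names(groups)) {
    genes <- groups[[g]]
    if (!length(genes)) { message("empty group: ", g); next }
    missing <- setdiff(genes, rownames(matrix))
    if (length(missing)) stop("group ", g, " references missing gene(s): ",
                              paste(missing, collapse = ", "))
    out[g, ] <- colSums(matrix[genes, , drop = FALSE])
  }
  out
}
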