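#' Kimura two-parameter divergence between two sequences
#'
#' Computes the transition proportion P (A<->G, C<->T), transversion
#' proportion Q, and the K2P-corrected divergence
#' K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#' Sequences of unequal length are first globally aligned with a fixed-score
#' Needleman-Wunsch (match +1, mismatch -1, gap open 4, gap extend 1, via
#' Biostrings). Columns containing a gap or an ambiguous base are excluded
#' (pairwise deletion). When 1 - 2P - Q <= 0 or 1 - 2Q <= 0 the distance is
#' saturated and `defined` is `FALSE`.
#'
#' @param a,b Character strings or `DNAString`s.
#' @return List of class `"k2p_result"`: `P`, `Q`, `sites` (compared sites),
#'   `K`, `defined`.
#' @export
k2p_divergence <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  plain <- c("A", "C", "G", "T")
  keep <- x %in% plain & y %in% plain
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  x <- x[keep]; y <- y[keep]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  K <- if (defined) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
  structure(list(P = P, Q = Q, sites = n, K = K, defined = defined),
            class = "k2p_result")
}

#' Insertion age from K2P divergence
#'
#' T = K / (2r): the two terminal repeats of an element are identical at
#' insertion and each accumulates substitutions at rate r per site per year,
#' so their divergence K grows at 2r per year.
#'
#' @param k2p A `"k2p_result"` (or a bare numeric K).
#' @param r Substitution rate per site per year.
#' @return List: `K`, `r`, `T_years`, `defined`. Undefined (saturated) K
#'   yields `T_years = NA` with `defined = FALSE`.
#' @export
insertion_age <- function(k2p, r = pipeline_config()$substitution_rate_r) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  if (is.numeric(k2p)) k2p <- list(K = k2p, defined = is.finite(k2p))
  if (!isTRUE(k2p$defined)) {
    return(list(K = k2p$K, r = r, T_years = NA_real_, defined = FALSE))
  }
  list(K = k2p$K, r = r, T_years = k2p$K / (2 * r), defined = TRUE)
}

#' Date a table of LTR pairs
#'
#' Applies [k2p_divergence()] and [insertion_age()] to every element.
#'
#' @param pairs data.frame with `element_id`, `five_prime`, `three_prime` and
#'   optionally `subgenome`.
#' @param r Substitution rate per site per year.
#' @return data.frame: `element_id`, `P`, `Q`, `sites`, `K`, `defined`,
#'   `T_years` (+ `subgenome` when present).
#' @export
ltr_ages <- function(pairs, r = pipeline_config()$substitution_rate_r) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    k <- k2p_divergence(pairs$five_prime[i], pairs$three_prime[i])
    a <- insertion_age(k, r)
    data.frame(element_id = pairs$element_id[i], P = k$P, Q = k$Q,
               sites = k$sites, K = ifelse(k$defined, k$K, NA_real_),
               defined = k$defined, T_years = a$T_years,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if ("subgenome" %in% names(pairs)) out$subgenome <- pairs$subgenome
  out
}

#' Binned insertion-age distribution per group
#'
#' Histograms of defined ages per subgenome (or any grouping), with the mode
#' bin per group. Bins are `[i*w, (i+1)*w)` from zero.
#'
#' @param ages data.frame from [ltr_ages()] with a grouping column.
#' @param bin_width Bin width in years (default 0.5 Myr).
#' @param group Name of the grouping column (default `"subgenome"`).
#' @return data.frame `group`, `bin_start`, `bin_end`, `count`, `is_mode`.
#'   Groups with no defined age are absent (a message notes them).
#' @export
age_distribution <- function(ages, bin_width = 5e5, group = "subgenome") {
  stopifnot(group %in% names(ages))
  ok <- ages[!is.na(ages$T_years), , drop = FALSE]
  dropped <- setdiff(unique(ages[[group]]), unique(ok[[group]]))
  if (length(dropped)) message("group(s) with no defined ages: ",
                               paste(dropped, collapse = ", "))
  if (!nrow(ok)) stop("no defined ages")
  out <- lapply(split(ok$T_years, ok[[group]]), function(tv) {
    b <- floor(tv / bin_width)
    tab <- table(b)
    data.frame(bin_start = as.numeric(names(tab)) * bin_width,
               bin_end = (as.numeric(names(tab)) + 1) * bin_width,
               count = as.integer(tab),
               is_mode = as.integer(tab) == max(as.integer(tab)))
  })
  out <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                            names(out), out))
  rownames(out) <- NULL
  out
}

#' Cluster LTR elements into families from reciprocal similarity
#'
#' Keeps only reciprocal edges (a hit in both directions at significance
#' <= `evalue_max`); families are the connected components of the reciprocal
#' graph. Elements without a reciprocal partner are singleton families.
#' Family ids are numbered deterministically by each family's smallest member
#' id.
#'
#' @param edges data.frame with `query`, `subject`, `evalue`.
#' @param elements Optional character vector of all element ids (so elements
#'   with no edges still receive singleton families).
#' @param evalue_max Significance cutoff, re-applied defensively.
#' @return data.frame `element_id`, `family` (integer id).
#' @export
cluster_families <- function(edges, elements = NULL, evalue_max = 1e-5) {
  edges <- edges[edges$evalue <= evalue_max & edges$query != edges$subject, ,
                 drop = FALSE]
  all_ids <- sort(unique(c(elements, edges$query, edges$subject)))
  dir_keys <- unique(paste(edges$query, edges$subject, sep = "\r"))
  parts <- if (length(dir_keys)) {
    m <- do.call(rbind, strsplit(dir_keys, "\r", fixed = TRUE))
    # reciprocal: both directions present; keep each undirected pair once
    recip <- paste(m[, 2], m[, 1], sep = "\r") %in% dir_keys
    m[recip & m[, 1] < m[, 2], , drop = FALSE]
  } else {
    matrix(character(0), ncol = 2)
  }
  if (nrow(parts)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = parts[, 1], to = parts[, 2]),
      directed = FALSE, vertices = all_ids)
  } else {
    g <- igraph::make_empty_graph(n = length(all_ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = all_ids)
  }
  comp <- igraph::components(g)$membership
  # renumber by smallest member id per component
  min_member <- tapply(names(comp), comp, min)
  fam_rank <- rank(min_member, ties.method = "first")
  data.frame(element_id = names(comp),
             family = as.integer(fam_rank[as.character(comp)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Solo + truncated to intact LTR ratio per group
#'
#' (solo + truncated) / intact from supplied counts; groups with zero intact
#' elements are flagged undefined.
#'
#' @param counts data.frame with `group`, `solo`, `truncated`, `intact`.
#' @return data.frame `group`, `ratio`, `defined`.
#' @export
solo_intact_ratio <- function(counts) {
  req <- c("group", "solo", "truncated", "intact")
  stopifnot(all(req %in% names(counts)))
  num <- counts[, c("solo", "truncated", "intact")]
  if (any(num < 0)) stop("counts must be non-negative")
  if (any(num != floor(num))) stop("counts must be integers")
  ratio <- ifelse(counts$intact > 0,
                  (counts$solo + counts$truncated) / counts$intact, NA_real_)
  data.frame(group = counts$group, ratio = ratio, defined = counts$intact > 0,
             stringsAsFactors = FALSE)
}

#' Read paired LTR sequences from FASTA
#'
#' Expects records named `<element_id>_5p` and `<element_id>_3p`.
#'
#' @param path FASTA path.
#' @return data.frame `element_id`, `five_prime`, `three_prime`.
#' @export
read_ltr_pairs <- function(path) {
  s <- read_fasta(path)
  nm <- s$ids
  id5 <- sub("_5p$", "", nm[grepl("_5p$", nm)])
  id3 <- sub("_3p$", "", nm[grepl("_3p$", nm)])
  ids <- intersect(id5, id3)
  orphan <- setdiff(union(id5, id3), ids)
  if (length(orphan)) stop("unpaired LTR records: ", paste(orphan, collapse = ", "))
  data.frame(element_id = ids,
             five_prime = as.character(s$sequences[paste0(ids, "_5p")]),
             three_prime = as.character(s$sequences[paste0(ids, "_3p")]),
             stringsAsFactors = FALSE)
}
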