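#' Window-level subgenome classification
#'
#' Tiles each scaffold with fixed windows (last window may be short) and
#' labels every window `A`, `D` or `ambiguous` from the pooled, library-size
#' normalized A- and D-clade depths, using the same log2-ratio threshold as
#' the scaffold classifier. This is the substrate for hybrid-scaffold
#' (inter-subgenome translocation) detection.
#'
#' @param tracks List of [coverage_track()] objects.
#' @param manifest A [dataset_manifest()].
#' @param scaffolds A [scaffold_set()].
#' @param config A [pipeline_config()]; `hybrid_window` sets the window size.
#' @param scaffold_ids Optional subset of scaffolds to scan.
#' @return data.frame with `scaffold_id`, `start`, `end` (0-based half-open),
#'   `mean_A`, `mean_D` (normalized), `log2_ratio`, `label`.
#' @export
window_classify <- function(tracks, manifest, scaffolds,
                            config = pipeline_config(), scaffold_ids = NULL) {
  ids <- vapply(tracks, function(t) t$dataset_id, "")
  clades <- stats::setNames(manifest$clade, manifest$dataset_id)[ids]
  if (!any(clades == "A") || !any(clades == "D")) {
    stop("need at least one A-clade and one D-clade track")
  }
  genome_len <- sum(as.numeric(scaffolds$lengths))
  gw_mean <- vapply(tracks, function(t) {
    iv <- t$intervals
    sum(iv$depth * (iv$end - iv$start)) / genome_len
  }, 0)
  if (any(gw_mean == 0)) stop("dataset with zero genome-wide coverage")

  if (is.null(scaffold_ids)) scaffold_ids <- scaffolds$ids
  w <- config$hybrid_window
  eps <- config$pseudocount

  by_scaf <- lapply(tracks, function(t) split(t$intervals, t$intervals$scaffold_id))

  res <- lapply(scaffold_ids, function(s) {
    len <- scaffolds$lengths[[s]]
    starts <- seq(0L, len - 1L, by = w)
    ends <- pmin(starts + w, len)
    nw <- length(starts)
    win <- IRanges::IRanges(start = starts + 1L, end = ends)
    depth <- matrix(0, nrow = nw, ncol = length(tracks))
    for (k in seq_along(tracks)) {
      iv <- by_scaf[[k]][[s]]
      if (is.null(iv) || !nrow(iv)) next
      ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
      hits <- IRanges::findOverlaps(ir, win)
      if (!length(hits)) next
      ov <- IRanges::width(IRanges::pintersect(ir[S4Vectors::queryHits(hits)],
                                               win[S4Vectors::subjectHits(hits)]))
      mass <- iv$depth[S4Vectors::queryHits(hits)] * ov
      agg <- tapply(mass, S4Vectors::subjectHits(hits), sum)
      depth[as.integer(names(agg)), k] <- as.numeric(agg)
    }
    depth <- sweep(depth / (ends - starts), 2, gw_mean, "/")
    mean_a <- rowMeans(depth[, clades == "A", drop = FALSE])
    mean_d <- rowMeans(depth[, clades == "D", drop = FALSE])
    lr <- log2((mean_a + eps) / (mean_d + eps))
    lab <- rep("ambiguous", nw)
    lab[lr > config$log2_ratio_min] <- "A"
    lab[lr < -config$log2_ratio_min] <- "D"
    data.frame(scaffold_id = s, start = starts, end = ends,
               mean_A = mean_a, mean_D = mean_d, log2_ratio = lr,
               label = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Call hybrid (At-Dt) scaffolds from window labels
#'
#' Consecutive windows of the same unambiguous label are merged into
#' segments; ambiguous windows neither break nor extend a segment. A junction
#' is emitted between each adjacent A-segment/D-segment pair whose flanking
#' segments are both at least `hybrid_min_segment` long. The junction is
#' reported as an interval — the gap between the last unambiguous window of
#' one side and the first of the other — because its position is only known
#' to window resolution.
#'
#' @param windows data.frame from [window_classify()].
#' @param config A [pipeline_config()].
#' @return data.frame with `scaffold_id`, `junction_start`, `junction_end`,
#'   `left_label`, `right_label`, `left_length`, `right_length`.
#' @export
call_hybrids <- function(windows, config = pipeline_config()) {
  empty <- data.frame(scaffold_id = character(0), junction_start = integer(0),
                      junction_end = integer(0), left_label = character(0),
                      right_label = character(0), left_length = integer(0),
                      right_length = integer(0), stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  out <- lapply(split(windows, windows$scaffold_id), function(wdf) {
    wdf <- wdf[order(wdf$start), , drop = FALSE]
    u <- wdf[wdf$label != "ambiguous", , drop = FALSE]
    if (nrow(u) < 2L) return(NULL)
    r <- rle(u$label)
    n_runs <- length(r$values)
    if (n_runs < 2L) return(NULL)
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1L) + 1L)
    seg_start <- u$start[first]
    seg_end <- u$end[last]
    seg_len <- seg_end - seg_start
    res <- NULL
    for (i in seq_len(n_runs - 1L)) {
      if (r$values[i] == r$values[i + 1L]) next
      if (seg_len[i] < config$hybrid_min_segment ||
          seg_len[i + 1L] < config$hybrid_min_segment) next
      res <- rbind(res, data.frame(
        scaffold_id = wdf$scaffold_id[1],
        junction_start = seg_end[i],
        junction_end = seg_start[i + 1L],
        left_label = r$values[i],
        right_label = r$values[i + 1L],
        left_length = seg_len[i],
        right_length = seg_len[i + 1L],
        stringsAsFactors = FALSE))
    }
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Project junctions onto reference chromosomes
#'
#' Each junction midpoint is projected through the alignment interval that
#' contains it by linear interpolation, strand-aware. Junctions not contained
#' in any alignment interval are reported with `projected = FALSE`.
#'
#' @param calls data.frame from [call_hybrids()].
#' @param alignments data.frame with columns `scaffold_id`, `scaffold_start`,
#'   `scaffold_end`, `ref_chrom`, `ref_start`, `ref_end`, `strand`
#'   (0-based half-open; scaffold and reference intervals of equal length).
#' @return data.frame: the calls plus `ref_chrom`, `ref_pos`, `projected`.
#' @export
project_junctions <- function(calls, alignments) {
  req <- c("scaffold_id", "scaffold_start", "scaffold_end",
           "ref_chrom", "ref_start", "ref_end", "strand")
  if (!all(req %in% names(alignments))) {
    stop("alignments need columns: ", paste(req, collapse = ", "))
  }
  for (s in unique(alignments$scaffold_id)) {
    a <- alignments[alignments$scaffold_id == s, , drop = FALSE]
    a <- a[order(a$scaffold_start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$scaffold_start[-1] < a$scaffold_end[-nrow(a)])) {
      stop("overlapping alignment intervals on scaffold ", s)
    }
  }
  mid <- floor((calls$junction_start + calls$junction_end) / 2)
  ref_chrom <- rep(NA_character_, nrow(calls))
  ref_pos <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- alignments[alignments$scaffold_id == calls$scaffold_id[i] &
                      alignments$scaffold_start <= mid[i] &
                      alignments$scaffold_end > mid[i], , drop = FALSE]
    if (!nrow(a)) next
    off <- mid[i] - a$scaffold_start[1]
    ref_chrom[i] <- a$ref_chrom[1]
    ref_pos[i] <- if (a$strand[1] == "-") a$ref_end[1] - off else a$ref_start[1] + off
  }
  cbind(calls, data.frame(ref_chrom = ref_chrom, ref_pos = ref_pos,
                          projected = !is.na(ref_pos), stringsAsFactors = FALSE))
}

#' Sub-telomeric enrichment of projected sites
#'
#' Tests whether projected translocation sites fall near chromosome ends more
#' often than expected under uniform placement. A site is terminal when it
#' lies within `terminal_fraction` of either chromosome end. The p-value is a
#' permutation test drawing uniform positions on the same chromosomes.
#'
#' @param sites data.frame with `ref_chrom` and `ref_pos` (projected sites).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param config A [pipeline_config()]; `terminal_fraction` sets the band.
#' @param n_permutations Number of permutations (0 = report observed only).
#' @param seed RNG seed for the permutations.
#' @return List with `n_sites`, `observed_fraction`, `expected_fraction`,
#'   `p_value` (NA when `n_permutations` is 0).
#' @export
subtelomeric_enrichment <- function(sites, chrom_lengths,
                                    config = pipeline_config(),
                                    n_permutations = 1000L, seed = 1L) {
  sites <- sites[!is.na(sites$ref_pos), , drop = FALSE]
  if (!nrow(sites)) stop("no projected sites")
  if (!all(sites$ref_chrom %in% names(chrom_lengths))) {
    stop("site on chromosome absent from chrom_lengths")
  }
  len <- chrom_lengths[sites$ref_chrom]
  f <- config$terminal_fraction
  is_term <- function(pos, len) pos < f * len | pos > (1 - f) * len
  obs <- mean(is_term(sites$ref_pos, len))
  p <- NA_real_
  if (n_permutations > 0L) {
    p <- withr::with_seed(seed, {
      perm <- vapply(seq_len(n_permutations), function(i) {
        mean(is_term(stats::runif(length(len), 0, len), len))
      }, 0)
      (1 + sum(perm >= obs)) / (n_permutations + 1)
    })
  }
  list(n_sites = nrow(sites), observed_fraction = obs,
       expected_fraction = 2 * f, p_value = p)
}
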