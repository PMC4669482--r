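#' Extract 201-bp SNP segments from a reference
#'
#' Each genetic-map SNP becomes a segment of 100 bp left flank + the SNP base
#' + 100 bp right flank (length `segment_length`). SNPs closer than 100 bp to
#' a sequence end are skipped with a logged count.
#'
#' @param snps data.frame with `marker_id`, `chromosome`, `cM`, `scaffold_id`,
#'   `position` (1-based SNP coordinate on the reference sequence).
#' @param reference A [scaffold_set()] with sequences.
#' @param config A [pipeline_config()].
#' @return data.frame of genetic-map markers: `marker_id`, `chromosome`, `cM`,
#'   `order_index` (rank of cM within chromosome), `segment`.
#' @export
extract_segments <- function(snps, reference, config = pipeline_config()) {
  if (is.null(reference$sequences)) stop("reference has no sequences")
  flank <- (config$segment_length - 1L) %/% 2L
  missing <- setdiff(unique(snps$scaffold_id), reference$ids)
  if (length(missing)) stop("reference sequence absent: ",
                            paste(missing, collapse = ", "))
  lens <- reference$lengths[snps$scaffold_id]
  ok <- snps$position - flank >= 1L & snps$position + flank <= lens
  if (any(!ok)) message(sum(!ok), " SNP(s) too close to a sequence end; skipped")
  snps <- snps[ok, , drop = FALSE]
  seg <- as.character(Biostrings::subseq(
    reference$sequences[snps$scaffold_id],
    start = snps$position - flank, end = snps$position + flank))
  out <- data.frame(marker_id = snps$marker_id,
                    chromosome = snps$chromosome,
                    cM = snps$cM,
                    segment = unname(seg),
                    stringsAsFactors = FALSE)
  add_order_index(out)
}

# order_index = rank of cM within chromosome, ties broken by input order
add_order_index <- function(markers) {
  markers$order_index <- NA_integer_
  for (chr in unique(markers$chromosome)) {
    i <- which(markers$chromosome == chr)
    markers$order_index[i] <- rank(markers$cM[i], ties.method = "first")
  }
  markers
}

#' Read a genetic-map marker table
#'
#' TSV with columns `marker_id`, `chromosome`, `cM`, `segment`. Segments must
#' all have length `segment_length`; the within-chromosome order index is
#' derived from cM.
#'
#' @param path TSV path.
#' @param config A [pipeline_config()].
#' @return Marker data.frame as from [extract_segments()].
#' @export
read_genetic_map <- function(path, config = pipeline_config()) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("marker_id", "chromosome", "cM", "segment")
  if (!all(req %in% names(m))) stop("map needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$marker_id)) stop("duplicate marker_ids")
  if (any(nchar(m$segment) != config$segment_length)) {
    stop("all segments must be ", config$segment_length, " bp")
  }
  m$segment <- toupper(m$segment)
  add_order_index(m)
}

#' Match map segments to scaffolds
#'
#' Ungapped scan of both strands of every scaffold for placements of each
#' segment with at most `segment_length - segment_min_match` mismatches
#' (196/201 default: at most 5). A marker with exactly one best placement
#' genome-wide is flagged unique; markers with no placement or with tied best
#' placements are dropped (counts logged).
#'
#' @param markers Marker data.frame (see [read_genetic_map()]).
#' @param scaffolds A [scaffold_set()] with sequences.
#' @param config A [pipeline_config()].
#' @return data.frame of retained hits: `marker_id`, `scaffold_id`, `start`
#'   (0-based), `strand`, `matched`, `unique` (all `TRUE` after filtering).
#' @export
match_segments <- function(markers, scaffolds, config = pipeline_config()) {
  if (is.null(scaffolds$sequences)) stop("scaffolds have no sequences")
  if (any(nchar(markers$segment) != config$segment_length)) {
    stop("segments must be exactly ", config$segment_length, " bp")
  }
  max_mm <- config$segment_length - config$segment_min_match
  subj <- scaffolds$sequences
  n_none <- 0L; n_tied <- 0L
  rows <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    pat <- Biostrings::DNAString(markers$segment[i])
    hits <- NULL
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::vmatchPattern(p, subj, max.mismatch = max_mm, fixed = TRUE)
      for (k in which(S4Vectors::elementNROWS(m) > 0)) {
        r <- m[[k]]
        mm <- Biostrings::neditStartingAt(p, subj[[k]], starting.at = IRanges::start(r),
                                          with.indels = FALSE)
        hits <- rbind(hits, data.frame(scaffold_id = names(subj)[k],
                                       start = IRanges::start(r) - 1L,
                                       strand = strand,
                                       matched = config$segment_length - mm,
                                       stringsAsFactors = FALSE))
      }
    }
    if (is.null(hits)) { n_none <- n_none + 1L; next }
    best <- hits[hits$matched == max(hits$matched), , drop = FALSE]
    if (nrow(best) > 1L) { n_tied <- n_tied + 1L; next }
    best$marker_id <- markers$marker_id[i]
    rows[[i]] <- best
  }
  if (n_none || n_tied) {
    message("segment matching dropped ", n_none, " marker(s) with no placement and ",
            n_tied, " with tied best placements")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(marker_id = character(0), scaffold_id = character(0),
                      start = integer(0), strand = character(0),
                      matched = integer(0), unique = logical(0),
                      stringsAsFactors = FALSE))
  }
  out$unique <- TRUE
  rownames(out) <- NULL
  out[, c("marker_id", "scaffold_id", "start", "strand", "matched", "unique")]
}

#' Brute-force segment matcher (reference oracle)
#'
#' Plain position-by-position mismatch count over both strands, identical in
#' contract to [match_segments()]. Quadratic and meant for small genomes
#' (tests, cross-checks); not for production use.
#'
#' @inheritParams match_segments
#' @return Same as [match_segments()].
#' @export
match_segments_bruteforce <- function(markers, scaffolds,
                                      config = pipeline_config()) {
  max_mm <- config$segment_length - config$segment_min_match
  L <- config$segment_length
  seqs <- lapply(as.character(scaffolds$sequences), function(s) {
    strsplit(s, "")[[1]]
  })
  revcomp_chr <- function(x) rev(chartr("ACGTN", "TGCAN", x))
  # mismatch count at every start position: one vectorized pass per pattern column
  scan_all <- function(sq, p) {
    npos <- length(sq) - L + 1L
    mm <- integer(npos)
    for (j in seq_len(L)) mm <- mm + (sq[j:(j + npos - 1L)] != p[j])
    mm
  }
  rows <- NULL
  for (i in seq_len(nrow(markers))) {
    pats <- list("+" = strsplit(markers$segment[i], "")[[1]])
    pats[["-"]] <- revcomp_chr(pats[["+"]])
    hits <- NULL
    for (sid in names(seqs)) {
      sq <- seqs[[sid]]
      if (length(sq) < L) next
      for (strand in c("+", "-")) {
        mm <- scan_all(sq, pats[[strand]])
        at <- which(mm <= max_mm)
        if (length(at)) {
          hits <- rbind(hits, data.frame(scaffold_id = sid, start = at - 1L,
                                         strand = strand, matched = L - mm[at],
                                         stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(hits)) next
    best <- hits[hits$matched == max(hits$matched), , drop = FALSE]
    if (nrow(best) > 1L) next
    best$marker_id <- markers$marker_id[i]
    rows <- rbind(rows, best)
  }
  if (is.null(rows)) {
    return(data.frame(marker_id = character(0), scaffold_id = character(0),
                      start = integer(0), strand = character(0),
                      matched = integer(0), unique = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows$unique <- TRUE
  rownames(rows) <- NULL
  rows[, c("marker_id", "scaffold_id", "start", "strand", "matched", "unique")]
}

#' Anchor scaffolds to chromosomes from segment hits
#'
#' "Continuous" segments are markers consecutive in within-chromosome map
#' order all hitting the same scaffold (`max_marker_gap` map positions without
#' a retained hit may be skipped when configured). A scaffold whose longest
#' run reaches `min_continuous_segments` is anchored to that run's chromosome;
#' scaffolds with qualifying runs on two chromosomes are rejected (logged).
#' Orientation is the sign of the correlation between map order and scaffold
#' coordinate over the run's hits; zero or undefined correlation gives
#' `unknown`. Position within the chromosome is the run's median cM.
#'
#' @param hits data.frame from [match_segments()].
#' @param markers Marker data.frame with `order_index`.
#' @param config A [pipeline_config()].
#' @return data.frame: `scaffold_id`, `chromosome`, `position_cM`,
#'   `orientation`, `n_markers`, `cm_span`, ordered by chromosome and
#'   position.
#' @export
anchor_scaffolds <- function(hits, markers, config = pipeline_config()) {
  empty <- data.frame(scaffold_id = character(0), chromosome = character(0),
                      position_cM = numeric(0), orientation = character(0),
                      n_markers = integer(0), cm_span = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  mk <- merge(hits, markers[, c("marker_id", "chromosome", "cM", "order_index")],
              by = "marker_id")
  best_runs <- NULL
  for (chr in unique(mk$chromosome)) {
    cm <- markers[markers$chromosome == chr, , drop = FALSE]
    cm <- cm[order(cm$order_index), , drop = FALSE]
    h <- mk[mk$chromosome == chr, , drop = FALSE]
    scaf_of <- stats::setNames(h$scaffold_id, h$marker_id)
    seq_scaf <- unname(scaf_of[cm$marker_id])  # NA where marker unplaced
    n <- length(seq_scaf)
    i <- 1L
    while (i <= n) {
      if (is.na(seq_scaf[i])) { i <- i + 1L; next }
      s <- seq_scaf[i]
      j <- i
      gap <- 0L
      last_hit <- i
      while (j < n) {
        nxt <- seq_scaf[j + 1L]
        if (!is.na(nxt) && nxt == s) {
          j <- j + 1L; last_hit <- j; gap <- 0L
        } else if (is.na(nxt) && gap < config$max_marker_gap) {
          j <- j + 1L; gap <- gap + 1L
        } else break
      }
      run_markers <- cm$marker_id[i:last_hit]
      run_markers <- run_markers[!is.na(seq_scaf[i:last_hit]) &
                                   seq_scaf[i:last_hit] == s]
      best_runs <- rbind(best_runs, data.frame(
        scaffold_id = s, chromosome = chr,
        n_markers = length(run_markers),
        first = i, last = last_hit,
        marker_ids = I(list(run_markers)),
        stringsAsFactors = FALSE))
      i <- last_hit + 1L
    }
  }
  if (is.null(best_runs)) return(empty)
  qual <- best_runs[best_runs$n_markers >= config$min_continuous_segments, ,
                    drop = FALSE]
  if (!nrow(qual)) return(empty)

  out <- NULL
  rejected <- character(0)
  for (s in unique(qual$scaffold_id)) {
    q <- qual[qual$scaffold_id == s, , drop = FALSE]
    if (length(unique(q$chromosome)) > 1L) { rejected <- c(rejected, s); next }
    q <- q[which.max(q$n_markers), , drop = FALSE]
    run_ids <- q$marker_ids[[1]]
    hh <- mk[mk$scaffold_id == s & mk$marker_id %in% run_ids, , drop = FALSE]
    ori <- "unknown"
    if (nrow(hh) >= 2L && stats::sd(hh$start) > 0) {
      r <- stats::cor(hh$order_index, hh$start, method = "spearman")
      if (!is.na(r) && r > 0) ori <- "+"
      if (!is.na(r) && r < 0) ori <- "-"
    }
    out <- rbind(out, data.frame(
      scaffold_id = s, chromosome = q$chromosome,
      position_cM = stats::median(hh$cM),
      orientation = ori, n_markers = q$n_markers,
      cm_span = diff(range(hh$cM)), stringsAsFactors = FALSE))
  }
  if (length(rejected)) {
    message("rejected ", length(rejected),
            " scaffold(s) with qualifying runs on multiple chromosomes: ",
            paste(rejected, collapse = ", "))
  }
  if (is.null(out)) return(empty)
  out <- out[order(out$chromosome, out$position_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build pseudochromosome sequences from anchored scaffolds
#'
#' Concatenates each chromosome's scaffolds in map order, reverse-complemented
#' when orientation is `-` (`unknown` is placed forward), separated by runs of
#' `gap_size` N bases. The layout table records every placement in 0-based
#' half-open pseudochromosome coordinates.
#'
#' @param anchored data.frame from [anchor_scaffolds()].
#' @param scaffolds A [scaffold_set()] with sequences.
#' @param config A [pipeline_config()]; `gap_size` sets the N gap.
#' @return List with `sequences` (a [scaffold_set()] of pseudochromosomes) and
#'   `layout` (data.frame `chromosome`, `scaffold_id`, `chrom_start`,
#'   `chrom_end`, `orientation`, `order`).
#' @export
build_pseudochromosomes <- function(anchored, scaffolds,
                                    config = pipeline_config()) {
  if (anyDuplicated(anchored$scaffold_id)) {
    stop("scaffold placed more than once: ",
         paste(unique(anchored$scaffold_id[duplicated(anchored$scaffold_id)]),
               collapse = ", "))
  }
  if (!nrow(anchored)) {
    return(list(sequences = NULL,
                layout = data.frame(chromosome = character(0),
                                    scaffold_id = character(0),
                                    chrom_start = integer(0), chrom_end = integer(0),
                                    orientation = character(0), order = integer(0),
                                    stringsAsFactors = FALSE)))
  }
  if (is.null(scaffolds$sequences)) stop("scaffolds have no sequences")
  gap <- strrep("N", config$gap_size)
  seq_out <- list()
  layout <- NULL
  for (chr in unique(anchored$chromosome)) {
    a <- anchored[anchored$chromosome == chr, , drop = FALSE]
    a <- a[order(a$position_cM), , drop = FALSE]
    pieces <- character(nrow(a))
    pos <- 0L
    for (i in seq_len(nrow(a))) {
      sq <- scaffolds$sequences[[a$scaffold_id[i]]]
      if (a$orientation[i] == "-") sq <- Biostrings::reverseComplement(sq)
      pieces[i] <- as.character(sq)
      layout <- rbind(layout, data.frame(
        chromosome = chr, scaffold_id = a$scaffold_id[i],
        chrom_start = pos, chrom_end = pos + length(sq),
        orientation = a$orientation[i], order = i, stringsAsFactors = FALSE))
      pos <- pos + length(sq) + config$gap_size
    }
    seq_out[[chr]] <- paste(pieces, collapse = gap)
  }
  rownames(layout) <- NULL
  list(sequences = scaffold_set(
         sequences = Biostrings::DNAStringSet(unlist(seq_out))),
       layout = layout)
}
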