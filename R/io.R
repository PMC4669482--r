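#' Scaffold sets
#'
#' A `scaffold_set` holds the assembly units the pipeline operates on: unique
#' ids, lengths in bp, and (optionally) the sequences themselves as a
#' [Biostrings::DNAStringSet]. Coverage-based stages only need lengths, so
#' length-only stubs are supported; sequence-level stages (segment matching,
#' pseudochromosome building, LTR work) require sequences.
#'
#' @param sequences A named [Biostrings::DNAStringSet], or `NULL`.
#' @param lengths Named integer vector of scaffold lengths; derived from
#'   `sequences` when those are given.
#' @return An object of class `"scaffold_set"` with elements `ids`, `lengths`
#'   (named) and `sequences` (`DNAStringSet` or `NULL`).
#' @export
scaffold_set <- function(sequences = NULL, lengths = NULL) {
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      sequences <- Biostrings::DNAStringSet(unlist(sequences))
    }
    ids <- names(sequences)
    if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
    lens <- stats::setNames(Biostrings::width(sequences), ids)
  } else {
    if (is.null(lengths) || is.null(names(lengths))) {
      stop("either named sequences or named lengths are required")
    }
    ids <- names(lengths)
    lens <- stats::setNames(as.integer(lengths), ids)
  }
  if (anyDuplicated(ids)) stop("duplicate scaffold ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(lens <= 0L)) stop("scaffold lengths must be positive")
  if (!is.null(sequences) && !identical(unname(lens),
                                        unname(Biostrings::width(sequences)))) {
    stop("length/sequence mismatch")
  }
  structure(list(ids = ids, lengths = lens, sequences = sequences),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("scaffold_set:", length(x$ids), "scaffolds,",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp",
      if (is.null(x$sequences)) "(length-only)" else "(with sequences)", "\n")
  invisible(x)
}

#' Read scaffolds from FASTA
#'
#' Ids are the first whitespace-delimited header token; sequences are
#' uppercased with IUPAC ambiguity codes preserved. Duplicate ids are an
#' error; an empty file yields an empty set with a warning.
#'
#' @param path FASTA file.
#' @return A [scaffold_set()].
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("no records in ", path)
    return(structure(list(ids = character(0),
                          lengths = stats::setNames(integer(0), character(0)),
                          sequences = Biostrings::DNAStringSet()),
                     class = "scaffold_set"))
  }
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  # readDNAStringSet already uppercases via the shared DNA alphabet
  scaffold_set(sequences = seqs)
}

#' Write scaffolds to FASTA
#'
#' @param scaffolds A [scaffold_set()] with sequences.
#' @param path Output path.
#' @export
write_fasta <- function(scaffolds, path) {
  if (is.null(scaffolds$sequences)) stop("scaffold_set has no sequences")
  Biostrings::writeXStringSet(scaffolds$sequences, path)
  invisible(path)
}

#' Dataset manifests
#'
#' The manifest assigns each sequencing dataset to a clade: `A` (A-genome
#' progenitor lines), `D` (D-genome progenitor lines) or `AD` (tetraploid).
#' At least two datasets per progenitor clade are needed for the replicate
#' t-test of the subgenome classifier.
#'
#' @param datasets data.frame with columns `dataset_id`, `clade`, `line_label`.
#' @return data.frame of class `"dataset_manifest"`.
#' @export
dataset_manifest <- function(datasets) {
  req <- c("dataset_id", "clade", "line_label")
  if (!all(req %in% names(datasets))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  }
  datasets <- as.data.frame(datasets)[, req]
  datasets$dataset_id <- as.character(datasets$dataset_id)
  datasets$clade <- as.character(datasets$clade)
  datasets$line_label <- as.character(datasets$line_label)
  if (anyDuplicated(datasets$dataset_id)) stop("duplicate dataset_ids in manifest")
  bad <- setdiff(unique(datasets$clade), c("A", "D", "AD"))
  if (length(bad)) stop("clade labels must be A, D or AD; found: ",
                        paste(bad, collapse = ", "))
  class(datasets) <- c("dataset_manifest", "data.frame")
  datasets
}

#' @rdname dataset_manifest
#' @param path TSV file with the manifest columns.
#' @export
read_manifest <- function(path) {
  dataset_manifest(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Coverage tracks
#'
#' Per-scaffold interval depth for one sequencing dataset, 0-based half-open.
#' Unlisted regions are implicitly depth 0. Intervals must lie within scaffold
#' bounds and not overlap within a scaffold.
#'
#' @param dataset_id Dataset the track belongs to.
#' @param intervals data.frame with `scaffold_id`, `start`, `end`, `depth`.
#' @param scaffolds Optional [scaffold_set()] to validate bounds against.
#' @return Object of class `"coverage_track"`.
#' @export
coverage_track <- function(dataset_id, intervals, scaffolds = NULL) {
  req <- c("scaffold_id", "start", "end", "depth")
  if (!all(req %in% names(intervals))) {
    stop("intervals need columns: ", paste(req, collapse = ", "))
  }
  intervals <- as.data.frame(intervals)[, req]
  intervals$scaffold_id <- as.character(intervals$scaffold_id)
  if (any(intervals$depth < 0)) stop("negative depth in track ", dataset_id)
  if (any(intervals$end <= intervals$start)) stop("empty/inverted interval in track ",
                                                  dataset_id)
  if (!is.null(scaffolds)) {
    unknown <- setdiff(unique(intervals$scaffold_id), scaffolds$ids)
    if (length(unknown)) stop("unknown scaffold_id in track ", dataset_id, ": ",
                              paste(unknown, collapse = ", "))
    lens <- scaffolds$lengths[intervals$scaffold_id]
    if (any(intervals$end > lens)) {
      i <- which(intervals$end > lens)[1]
      stop("interval beyond scaffold end in track ", dataset_id, " (",
           intervals$scaffold_id[i], ":", intervals$start[i], "-",
           intervals$end[i], ")")
    }
  }
  o <- order(intervals$scaffold_id, intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  ov <- intervals$scaffold_id[-1] == intervals$scaffold_id[-nrow(intervals)] &
    intervals$start[-1] < intervals$end[-nrow(intervals)]
  if (nrow(intervals) > 1L && any(ov)) {
    stop("overlapping intervals in track ", dataset_id)
  }
  rownames(intervals) <- NULL
  structure(list(dataset_id = dataset_id, intervals = intervals),
            class = "coverage_track")
}

#' Read a bedgraph coverage track
#'
#' 4-column bedgraph (contig, start, end, depth), 0-based half-open. `track`
#' and comment lines are skipped. Out-of-bounds intervals and unknown
#' scaffold ids are errors naming the offending line.
#'
#' @param path bedgraph file.
#' @param dataset_id Dataset id to attach to the track.
#' @param scaffolds [scaffold_set()] defining valid ids and bounds.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, dataset_id, scaffolds) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(coverage_track(dataset_id,
                          data.frame(scaffold_id = character(0), start = integer(0),
                                     end = integer(0), depth = numeric(0)),
                          scaffolds))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(fields) != 4L)) {
    stop("malformed bedgraph line ", which(keep)[which(lengths(fields) != 4L)[1]],
         " in ", path)
  }
  m <- do.call(rbind, fields)
  iv <- data.frame(scaffold_id = m[, 1],
                   start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]),
                   depth = as.numeric(m[, 4]),
                   stringsAsFactors = FALSE)
  lineno <- which(keep)
  unknown <- !(iv$scaffold_id %in% scaffolds$ids)
  if (any(unknown)) {
    stop("unknown scaffold_id '", iv$scaffold_id[unknown][1], "' at line ",
         lineno[unknown][1], " of ", path)
  }
  lens <- scaffolds$lengths[iv$scaffold_id]
  oob <- iv$start < 0L | iv$end > lens
  if (any(oob)) {
    stop("interval out of scaffold bounds at line ", lineno[oob][1], " of ", path)
  }
  coverage_track(dataset_id, iv, scaffolds)
}

#' Write a coverage track as bedgraph
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  utils::write.table(iv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tab-separated table I/O
#'
#' Writes records as a TSV with a header row and a deterministic column order;
#' character fields must be tab-free so the file round-trips losslessly
#' through [read_table_file()].
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param columns Column order (default: the data.frame's order).
#' @export
write_table_file <- function(records, path, columns = names(records)) {
  stopifnot(is.data.frame(records))
  if (!all(columns %in% names(records))) stop("schema names columns absent from records")
  records <- records[, columns, drop = FALSE]
  chr <- vapply(records, is.character, TRUE)
  if (any(vapply(records[chr], function(x) any(grepl("\t", x)), TRUE))) {
    stop("character fields must not contain tabs")
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_file
#' @return `read_table_file()` returns the data.frame.
#' @export
read_table_file <- function(path) {
  stopifnot(file.exists(path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Mean depth per scaffold for one track
#'
#' Mean depth averages over *all* bases of the scaffold (uncovered bases count
#' as depth 0): sum(depth x interval length) / scaffold length. This makes
#' coverage ratios robust to differences in covered fraction.
#'
#' @param track A [coverage_track()].
#' @param scaffolds A [scaffold_set()].
#' @return Named numeric vector over all scaffolds (0 where uncovered).
#' @export
track_mean_depth <- function(track, scaffolds) {
  iv <- track$intervals
  out <- stats::setNames(numeric(length(scaffolds$ids)), scaffolds$ids)
  if (nrow(iv)) {
    mass <- tapply(iv$depth * (iv$end - iv$start), iv$scaffold_id, sum)
    out[names(mass)] <- as.numeric(mass) / as.numeric(scaffolds$lengths[names(mass)])
  }
  out
}

# intervals with depth >= 1 as an IRanges per scaffold (internal)
covered_ranges <- function(intervals) {
  iv <- intervals[intervals$depth >= 1, , drop = FALSE]
  if (!nrow(iv)) return(list())
  split(IRanges::IRanges(start = iv$start + 1L, end = iv$end), iv$scaffold_id)
}
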