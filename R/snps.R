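#' Read variant sites and per-dataset allele support from a VCF
#'
#' Parses a multi-sample VCF (v4.x) with `vcfR` and reduces each genotype to
#' allele presence/absence: a sample supports the alternate allele when its
#' genotype contains a non-reference allele index. Tetraploid genotype calls
#' are handled transparently — dosage is ignored. A sample covers a site when
#' its genotype is called and, if a `DP` FORMAT field is present, its depth
#' is at least `min_presence_depth`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param config A [pipeline_config()].
#' @return List of class `"variant_sites"`: `sites` (data.frame `contig`,
#'   `pos` — 1-based as on disk — `ref`, `alt`), `alt_present` and `covered`
#'   (sites x samples logical matrices), `samples`.
#' @export
read_vcf_sites <- function(path, config = pipeline_config()) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  has_alt <- !is.na(gt) & grepl("[1-9]", gt)
  covered <- !is.na(gt) & !grepl("^\\.([/|].)*$", gt)
  fmt <- v@gt[, 1]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    covered <- covered & !is.na(dp) & dp >= config$min_presence_depth
  }
  list(sites = data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
       alt_present = has_alt, covered = covered,
       samples = colnames(gt)) |>
    structure(class = "variant_sites")
}

#' Partition SNPs into lineage-specific sets
#'
#' A site is lineage-L-specific iff an alternate allele is present in every
#' L-lineage dataset that covers the site (at least one must cover it) and
#' absent from every covering dataset of all other lineages. Datasets without
#' coverage at the site do not veto. Sites covered by no dataset are skipped
#' (logged). Lineages are the manifest clades; by construction the resulting
#' sets are pairwise disjoint.
#'
#' @param variants A `"variant_sites"` from [read_vcf_sites()].
#' @param manifest A [dataset_manifest()]; sample names must match
#'   `dataset_id`s.
#' @return data.frame `contig`, `pos`, `ref`, `alt`, `lineage` — one row per
#'   lineage-specific site.
#' @export
partition_lineage_specific <- function(variants, manifest) {
  samples <- variants$samples
  missing <- setdiff(samples, manifest$dataset_id)
  if (length(missing)) stop("VCF samples absent from manifest: ",
                            paste(missing, collapse = ", "))
  lin <- stats::setNames(manifest$clade, manifest$dataset_id)[samples]
  if (length(unique(lin)) < 2L) stop("need at least 2 lineages")
  pres <- variants$alt_present
  cov <- variants$covered
  uncovered <- rowSums(cov) == 0L
  if (any(uncovered)) message(sum(uncovered), " site(s) with no covering dataset skipped")
  out_lin <- rep(NA_character_, nrow(pres))
  for (L in unique(lin)) {
    inL <- lin == L
    covL <- cov[, inL, drop = FALSE]
    covO <- cov[, !inL, drop = FALSE]
    presL <- pres[, inL, drop = FALSE]
    presO <- pres[, !inL, drop = FALSE]
    spec <- rowSums(covL) > 0 &
      rowSums(presL & covL) == rowSums(covL) &
      rowSums(presO & covO) == 0L
    out_lin[spec & !uncovered] <- L
  }
  keep <- !is.na(out_lin)
  cbind(variants$sites[keep, , drop = FALSE],
        data.frame(lineage = out_lin[keep], stringsAsFactors = FALSE))
}

#' Summarize coding effects of lineage-specific SNPs
#'
#' Joins lineage-specific sites to a supplied effect annotation (SnpEff-style,
#' consumed not computed) and tallies per-lineage effect classes and affected
#' genes. A gene counts once per lineage regardless of how many of its sites
#' are hit; the affected-gene count uses non-synonymous sites, mirroring the
#' usual emphasis on protein-changing variation.
#'
#' @param ls_snps data.frame from [partition_lineage_specific()].
#' @param annotation data.frame with `contig`, `pos`, `effect`
#'   (`synonymous`, `non-synonymous`, anything else mapped to `other/none`)
#'   and optional `gene_id`. Sites without annotation are `other/none`.
#' @return List: `class_counts` (data.frame `lineage`, `effect`, `n`) and
#'   `affected_genes` (data.frame `lineage`, `n_genes`).
#' @export
effect_summary <- function(ls_snps, annotation = NULL) {
  df <- ls_snps
  df$effect <- "other/none"
  df$gene_id <- NA_character_
  if (!is.null(annotation) && nrow(annotation)) {
    if (!"gene_id" %in% names(annotation)) annotation$gene_id <- NA_character_
    key <- paste(df$contig, df$pos)
    akey <- paste(annotation$contig, annotation$pos)
    m <- match(key, akey)
    hit <- !is.na(m)
    eff <- annotation$effect[m[hit]]
    eff[!eff %in% c("synonymous", "non-synonymous")] <- "other/none"
    df$effect[hit] <- eff
    df$gene_id[hit] <- annotation$gene_id[m[hit]]
  }
  class_counts <- as.data.frame(table(lineage = df$lineage, effect = df$effect),
                                stringsAsFactors = FALSE)
  names(class_counts)[3] <- "n"
  ns <- df[df$effect == "non-synonymous" & !is.na(df$gene_id), , drop = FALSE]
  genes <- unique(ns[, c("lineage", "gene_id")])
  if (nrow(genes)) {
    affected <- as.data.frame(table(lineage = genes$lineage),
                              stringsAsFactors = FALSE)
    names(affected) <- c("lineage", "n_genes")
  } else {
    affected <- data.frame(lineage = character(0), n_genes = integer(0))
  }
  list(class_counts = class_counts, affected_genes = affected)
}

#' Windowed SNP density scan
#'
#' Tiles each contig with fixed windows (a contig shorter than one window is
#' a single short window), counts sites per window, and flags windows whose
#' z-score against the genome-wide window-count distribution is beyond
#' `density_z_threshold` as `low` or `high`. With no sites, or a degenerate
#' (zero-variance) count distribution, flags are suppressed.
#'
#' @param sites data.frame with `contig`, `pos` (1-based).
#' @param contig_lengths Named numeric vector.
#' @param config A [pipeline_config()]; `density_window`,
#'   `density_z_threshold`.
#' @return data.frame `contig`, `start`, `end` (0-based half-open), `count`,
#'   `density`, `z`, `flag` in `{low, high, normal}`.
#' @export
density_scan <- function(sites, contig_lengths, config = pipeline_config()) {
  w <- config$density_window
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  stray <- setdiff(unique(sites$contig), names(contig_lengths))
  if (length(stray)) stop("sites on unknown contig: ", paste(stray, collapse = ", "))
  win <- do.call(rbind, lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- seq(0, max(len - 1, 0), by = w)
    data.frame(contig = ct, start = starts, end = pmin(starts + w, len),
               stringsAsFactors = FALSE)
  }))
  win$count <- 0L
  if (nrow(sites)) {
    idx <- paste(sites$contig, floor((sites$pos - 1) / w))
    tab <- table(idx)
    wkey <- paste(win$contig, win$start / w)
    m <- match(names(tab), wkey)
    if (anyNA(m)) stop("site position beyond contig length")
    win$count[m] <- as.integer(tab)
  }
  win$density <- win$count / (win$end - win$start)
  mu <- mean(win$count); sdev <- stats::sd(win$count)
  if (nrow(sites) == 0L || is.na(sdev) || sdev == 0) {
    win$z <- NA_real_
    win$flag <- "normal"
    return(win)
  }
  win$z <- (win$count - mu) / sdev
  win$flag <- "normal"
  win$flag[win$z <= -config$density_z_threshold] <- "low"
  win$flag[win$z >= config$density_z_threshold] <- "high"
  win
}
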