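#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults reproduce the published analysis constants: a scaffold is assigned
#' to a subgenome when more than 40% of its bases are covered by progenitor
#' reads, the log2 ratio of mean A-clade to D-clade coverage exceeds 2, and a
#' Student's t-test across replicate libraries gives p < 0.01. Genetic-map
#' segments are 201 bp (100 bp each side of the SNP) and must align with at
#' least 196 matching bases; a scaffold needs at least 5 continuous segments to
#' be anchored. LTR insertion ages use T = K / (2r) with
#' r = 1.3e-8 substitutions per site per year. SNP density is scanned in 1 Mb
#' windows.
#'
#' @param covered_fraction_min Minimum union covered fraction (criterion 1).
#' @param log2_ratio_min Minimum |log2(mean A / mean D)| (criterion 2).
#' @param ttest_alpha Significance level for the replicate t-test (criterion 3).
#' @param use_ttest Apply criterion 3. Must be set to `FALSE` explicitly when a
#'   clade has fewer than two replicate datasets.
#' @param welch Use Welch's unequal-variance t-test instead of the classic
#'   Student's equal-variance test.
#' @param pseudocount Normalized-depth pseudocount added to both clade means in
#'   the log ratio so zero denominators stay finite.
#' @param mapq_min Mapping-quality filter applied upstream when converting
#'   alignments to coverage (documentation of provenance; coverage tracks are
#'   the pipeline's entry point).
#' @param substitution_rate_r Substitution rate per site per year used in
#'   T = K / (2r).
#' @param segment_length Genetic-map segment length in bp.
#' @param segment_min_match Minimum matching bases for a segment placement.
#' @param min_continuous_segments Minimum run of map-consecutive segments on
#'   one scaffold for anchoring.
#' @param max_marker_gap Number of intervening map-order markers without a
#'   retained hit that a run may skip (0 = strictly consecutive).
#' @param hybrid_window Window size in bp for hybrid-scaffold scanning.
#' @param hybrid_min_segment Minimum flanking segment length in bp on each side
#'   of a reported junction.
#' @param density_window Window size in bp for SNP density scanning.
#' @param density_z_threshold |z| beyond which a window is flagged low/high.
#' @param kmeans_k Default number of k-means clusters for expression profiles.
#' @param bias_log2_threshold |log2((At+1)/(Dt+1))| at or above which a
#'   homoeolog pair is called biased.
#' @param expression_floor Minimum combined FPKM in the focal tissue for a
#'   tissue-specific pair.
#' @param specificity_factor Fold by which the focal tissue must exceed every
#'   other tissue for a tissue-specific pair.
#' @param min_presence_depth Minimum read depth for a dataset to vote on allele
#'   presence/absence at a site.
#' @param terminal_fraction Fraction of each chromosome end treated as
#'   sub-telomeric in the enrichment test.
#' @param gap_size N-gap inserted between scaffolds in pseudochromosomes.
#' @param rng_seed Default seed for seeded operations.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(covered_fraction_min = 0.40,
                            log2_ratio_min = 2,
                            ttest_alpha = 0.01,
                            use_ttest = TRUE,
                            welch = FALSE,
                            pseudocount = 0.01,
                            mapq_min = 20L,
                            substitution_rate_r = 1.3e-8,
                            segment_length = 201L,
                            segment_min_match = 196L,
                            min_continuous_segments = 5L,
                            max_marker_gap = 0L,
                            hybrid_window = 10000L,
                            hybrid_min_segment = 50000L,
                            density_window = 1e6,
                            density_z_threshold = 2,
                            kmeans_k = 8L,
                            bias_log2_threshold = 1,
                            expression_floor = 5,
                            specificity_factor = 2,
                            min_presence_depth = 3L,
                            terminal_fraction = 0.10,
                            gap_size = 100L,
                            rng_seed = 1L) {
  cfg <- list(covered_fraction_min = covered_fraction_min,
              log2_ratio_min = log2_ratio_min,
              ttest_alpha = ttest_alpha,
              use_ttest = isTRUE(use_ttest),
              welch = isTRUE(welch),
              pseudocount = pseudocount,
              mapq_min = as.integer(mapq_min),
              substitution_rate_r = substitution_rate_r,
              segment_length = as.integer(segment_length),
              segment_min_match = as.integer(segment_min_match),
              min_continuous_segments = as.integer(min_continuous_segments),
              max_marker_gap = as.integer(max_marker_gap),
              hybrid_window = as.integer(hybrid_window),
              hybrid_min_segment = as.integer(hybrid_min_segment),
              density_window = density_window,
              density_z_threshold = density_z_threshold,
              kmeans_k = as.integer(kmeans_k),
              bias_log2_threshold = bias_log2_threshold,
              expression_floor = expression_floor,
              specificity_factor = specificity_factor,
              min_presence_depth = as.integer(min_presence_depth),
              terminal_fraction = terminal_fraction,
              gap_size = as.integer(gap_size),
              rng_seed = as.integer(rng_seed))
  pos <- c("covered_fraction_min", "log2_ratio_min", "ttest_alpha",
           "pseudocount", "substitution_rate_r", "segment_length",
           "segment_min_match", "min_continuous_segments", "hybrid_window",
           "hybrid_min_segment", "density_window", "density_z_threshold",
           "kmeans_k", "bias_log2_threshold", "terminal_fraction")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || !is.finite(cfg[[nm]]) ||
        cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a single positive number")
    }
  }
  if (cfg$segment_min_match > cfg$segment_length) {
    stop("segment_min_match must not exceed segment_length")
  }
  if (cfg$ttest_alpha >= 1 || cfg$covered_fraction_min >= 1 ||
      cfg$terminal_fraction >= 0.5) {
    stop("ttest_alpha and covered_fraction_min must be < 1; terminal_fraction < 0.5")
  }
  if (cfg$max_marker_gap < 0L || cfg$min_presence_depth < 0L || cfg$gap_size < 0L) {
    stop("max_marker_gap, min_presence_depth and gap_size must be non-negative")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a configuration file
#'
#' Accepts plain `key = value` (or `key: value`) lines; unknown keys are an
#' error, values are coerced to the type of the corresponding
#' [pipeline_config()] default.
#'
#' @param path Path to the config file.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- formals(pipeline_config)
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else {
      as.numeric(val)
    }
  }
  do.call(pipeline_config, args)
}
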