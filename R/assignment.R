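#' Summarize clade-structured coverage per scaffold
#'
#' For each scaffold and dataset the mean depth over all bases is computed and
#' library-size normalized by that dataset's genome-wide mean depth. Covered
#' fractions (proportion of bases with depth >= 1) are computed per clade on
#' the union of the clade's tracks, plus a progenitor union (A and D clades
#' together) used by the classifier's coverage criterion.
#'
#' @param tracks List of [coverage_track()] objects.
#' @param manifest A [dataset_manifest()].
#' @param scaffolds A [scaffold_set()].
#' @return Object of class `"coverage_summary"`: list with `per_dataset`
#'   (scaffolds x datasets matrix of normalized mean depths), `covered`
#'   (scaffolds x clades matrix plus a `union` column), `clade_means`
#'   (scaffolds x clades matrix), `manifest`, `scaffold_lengths`.
#' @export
summarize_coverage <- function(tracks, manifest, scaffolds) {
  ids <- vapply(tracks, function(t) t$dataset_id, "")
  if (anyDuplicated(ids)) stop("duplicate dataset_ids among tracks")
  missing <- setdiff(ids, manifest$dataset_id)
  if (length(missing)) stop("tracks not in manifest: ", paste(missing, collapse = ", "))
  clades <- stats::setNames(manifest$clade, manifest$dataset_id)[ids]
  if (!any(clades == "A") || !any(clades == "D")) {
    stop("need at least one A-clade and one D-clade track")
  }

  per_dataset <- do.call(cbind, lapply(tracks, function(t) {
    track_mean_depth(t, scaffolds)
  }))
  dimnames(per_dataset) <- list(scaffolds$ids, ids)
  genome_len <- sum(as.numeric(scaffolds$lengths))
  gw_mean <- colSums(per_dataset * as.numeric(scaffolds$lengths)) / genome_len
  if (any(gw_mean == 0)) {
    stop("dataset with zero genome-wide coverage: ",
         paste(ids[gw_mean == 0], collapse = ", "))
  }
  norm <- sweep(per_dataset, 2, gw_mean, "/")

  covered_union_frac <- function(track_subset) {
    per_scaf <- stats::setNames(numeric(length(scaffolds$ids)), scaffolds$ids)
    rng <- list()
    for (t in track_subset) {
      r <- covered_ranges(t$intervals)
      for (s in names(r)) rng[[s]] <- c(rng[[s]], list(r[[s]]))
    }
    for (s in names(rng)) {
      merged <- IRanges::reduce(do.call(c, rng[[s]]))
      per_scaf[s] <- sum(IRanges::width(merged)) / as.numeric(scaffolds$lengths[s])
    }
    per_scaf
  }
  clade_names <- intersect(c("A", "D", "AD"), unique(clades))
  covered <- do.call(cbind, lapply(clade_names, function(cl) {
    covered_union_frac(tracks[clades == cl])
  }))
  covered <- cbind(covered,
                   covered_union_frac(tracks[clades %in% c("A", "D")]))
  colnames(covered) <- c(clade_names, "union")

  clade_means <- do.call(cbind, lapply(clade_names, function(cl) {
    rowMeans(norm[, clades == cl, drop = FALSE])
  }))
  colnames(clade_means) <- clade_names
  structure(list(per_dataset = norm,
                 covered = covered,
                 clade_means = clade_means,
                 manifest = manifest[match(ids, manifest$dataset_id), ],
                 scaffold_lengths = scaffolds$lengths),
            class = "coverage_summary")
}

# classic equal-variance or Welch two-sample t-test via stats::t.test;
# returns c(t, p), NA-safe for degenerate inputs
.two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) return(c(NA_real_, NA_real_))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # both groups constant: zero pooled variance; identical means -> no evidence
    if (mean(x) == mean(y)) return(c(0, 1))
    return(c(Inf * sign(mean(x) - mean(y)), 0))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  c(unname(tt$statistic), tt$p.value)
}

#' Assign scaffolds to subgenomes
#'
#' Applies the three-criteria classifier to every scaffold: (1) more than
#' `covered_fraction_min` of the scaffold covered by progenitor shotgun reads
#' (union of A- and D-clade tracks); (2) |log2((mean_A + eps)/(mean_D + eps))|
#' greater than `log2_ratio_min`; (3) the A/D difference significant at
#' `ttest_alpha` by a Student's t-test over the per-dataset normalized mean
#' depths of the replicate libraries. A scaffold passing all three with a
#' positive ratio is `At`, with a negative ratio `Dt`, otherwise `ungrouped`.
#'
#' @param summary A `"coverage_summary"` from [summarize_coverage()].
#' @param config A [pipeline_config()].
#' @return data.frame with one row per scaffold: `scaffold_id`, `label`,
#'   `covered_fraction_union`, `mean_cov_A`, `mean_cov_D`, `log2_ratio`,
#'   `t_statistic`, `p_value`, `crit_coverage`, `crit_ratio`, `crit_ttest`.
#' @export
assign_scaffolds <- function(summary, config = pipeline_config()) {
  stopifnot(inherits(summary, "coverage_summary"))
  man <- summary$manifest
  a_cols <- man$dataset_id[man$clade == "A"]
  d_cols <- man$dataset_id[man$clade == "D"]
  if (config$use_ttest && (length(a_cols) < 2L || length(d_cols) < 2L)) {
    stop("fewer than 2 replicate datasets in a progenitor clade; the replicate ",
         "t-test (criterion 3) cannot run. Supply more datasets or set ",
         "use_ttest = FALSE in pipeline_config() explicitly.")
  }
  eps <- config$pseudocount
  mean_a <- summary$clade_means[, "A"]
  mean_d <- summary$clade_means[, "D"]
  lr <- log2((mean_a + eps) / (mean_d + eps))
  cov_u <- summary$covered[, "union"]

  if (config$use_ttest) {
    tp <- t(apply(summary$per_dataset, 1, function(v) {
      .two_sample_t(v[a_cols], v[d_cols], welch = config$welch)
    }))
  } else {
    tp <- matrix(NA_real_, nrow = nrow(summary$per_dataset), ncol = 2L)
  }

  crit_cov <- cov_u > config$covered_fraction_min
  crit_ratio_at <- lr > config$log2_ratio_min
  crit_ratio_dt <- lr < -config$log2_ratio_min
  crit_t <- if (config$use_ttest) !is.na(tp[, 2]) & tp[, 2] < config$ttest_alpha
            else rep(TRUE, length(lr))

  label <- rep("ungrouped", length(lr))
  label[crit_cov & crit_ratio_at & crit_t] <- "At"
  label[crit_cov & crit_ratio_dt & crit_t] <- "Dt"

  data.frame(scaffold_id = rownames(summary$per_dataset),
             label = label,
             covered_fraction_union = unname(cov_u),
             mean_cov_A = unname(mean_a),
             mean_cov_D = unname(mean_d),
             log2_ratio = unname(lr),
             t_statistic = tp[, 1],
             p_value = tp[, 2],
             crit_coverage = unname(crit_cov),
             crit_ratio = unname(crit_ratio_at | crit_ratio_dt),
             crit_ttest = unname(crit_t),
             stringsAsFactors = FALSE)
}

#' N50 of a set of lengths
#'
#' Largest length L such that lengths >= L sum to at least half the total.
#'
#' @param lengths Numeric vector of lengths.
#' @return The N50, or 0 for an empty vector.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Per-label assignment summary
#'
#' Scaffold counts, total lengths and N50 per label (`At`, `Dt`, `ungrouped`)
#' plus a `total` row; the per-label totals partition the assembly exactly.
#'
#' @param assignments data.frame from [assign_scaffolds()].
#' @param scaffolds A [scaffold_set()].
#' @return data.frame with columns `label`, `n_scaffolds`, `total_length`, `n50`.
#' @export
assignment_report <- function(assignments, scaffolds) {
  lens <- scaffolds$lengths[assignments$scaffold_id]
  out <- do.call(rbind, lapply(c("At", "Dt", "ungrouped"), function(lb) {
    l <- as.numeric(lens[assignments$label == lb])
    data.frame(label = lb, n_scaffolds = length(l),
               total_length = sum(l), n50 = n50(l))
  }))
  rbind(out, data.frame(label = "total", n_scaffolds = nrow(assignments),
                        total_length = sum(as.numeric(lens)),
                        n50 = n50(as.numeric(lens))))
}
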