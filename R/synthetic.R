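#' Simulation parameters
#'
#' All knobs of the synthetic allotetraploid generator, fully determined by
#' `rng_seed`. Defaults describe the study conditions the downstream stages
#' are validated against: 200 scaffolds with an even At/Dt split and 10%
#' ungrouped-truth, three replicate shotgun libraries per progenitor clade at
#' 20x mean depth with negative-binomial bin noise (dispersion 10), 1 kb LTR
#' pairs evolved under K2P at ts/tv 2 and r = 1.3e-8/site/year, a 5-chromosome
#' genetic map of 1,000 201-bp segments, and 1,000 homoeolog pairs with
#' 30% At- / 20% Dt-biased expression at 4-fold effect in the fibre
#' elongation (FE) tissue.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param at_fraction Fraction of grouped scaffolds that are At-truth.
#' @param ungrouped_fraction Fraction of (non-hybrid) scaffolds with
#'   ungrouped truth (repeat-rich, low mappability in every library).
#' @param scaffold_length_min,scaffold_length_max Scaffold length range (bp).
#' @param n_replicates_A,n_replicates_D,n_replicates_AD Datasets per clade.
#' @param depth_mean Mean mapped depth on a scaffold's own clade.
#' @param depth_noise One of `"none"`, `"poisson"`, `"negbin"`. `"none"`
#'   means pure mappability signal: exact `depth_mean` on-clade and exactly
#'   zero off-clade.
#' @param nb_dispersion Negative-binomial size parameter (Poisson is the
#'   dispersion -> Inf limit).
#' @param cross_mappability Fraction of bins receiving stray off-clade
#'   coverage under noisy models (conserved repeats); ignored when
#'   `depth_noise = "none"`.
#' @param ungrouped_covered_fraction Fraction of bins of an ungrouped-truth
#'   scaffold that are mappable at all; one mask shared by every library.
#' @param coverage_bin Bin size (bp) at which depth is simulated.
#' @param n_hybrids Number of At-Dt hybrid scaffolds (junction recorded).
#' @param hybrid_margin Minimum distance (bp) of a junction from either
#'   scaffold end.
#' @param n_markers,n_chromosomes,scaffolds_per_chromosome,map_scaffold_length
#'   Genetic-map simulation shape.
#' @param frac_bad_markers Fraction of markers with 6 planted mismatches
#'   (unmatchable under the 196/201 rule).
#' @param frac_duplicated_markers Fraction of markers whose segment is also
#'   planted in a decoy scaffold (non-unique, must be dropped).
#' @param n_lineage_sites,n_shared_sites Planted lineage-specific and shared
#'   SNP counts for the VCF.
#' @param ltr_count Number of LTR pairs per true age.
#' @param ltr_length LTR length in bp (>= 50).
#' @param ltr_ts_tv_ratio Transition:transversion ratio of the K2P process.
#' @param ltr_true_ages True insertion ages in years.
#' @param ltr_rate Substitution rate per site per year.
#' @param n_pairs Homoeolog pairs for the expression simulation.
#' @param tissues Tissue panel (8 columns including FE and FS).
#' @param bias_tissue Focal tissue carrying the planted bias.
#' @param bias_at_fraction,bias_dt_fraction Planted bias fractions.
#' @param bias_effect_size Fold change of the biased copy.
#' @param pair_noise_sdlog Within-pair log-normal noise (sd of log FPKM).
#' @param rng_seed Seed; identical params + seed give identical output.
#' @return Validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_scaffolds = 200L,
                              at_fraction = 0.5,
                              ungrouped_fraction = 0.10,
                              scaffold_length_min = 120000L,
                              scaffold_length_max = 200000L,
                              n_replicates_A = 3L,
                              n_replicates_D = 3L,
                              n_replicates_AD = 0L,
                              depth_mean = 20,
                              depth_noise = c("negbin", "poisson", "none"),
                              nb_dispersion = 10,
                              cross_mappability = 0.02,
                              ungrouped_covered_fraction = 0.2,
                              coverage_bin = 2000L,
                              n_hybrids = 0L,
                              hybrid_margin = 55000L,
                              n_markers = 1000L,
                              n_chromosomes = 5L,
                              scaffolds_per_chromosome = 8L,
                              map_scaffold_length = 25000L,
                              frac_bad_markers = 0.05,
                              frac_duplicated_markers = 0.05,
                              n_lineage_sites = 1000L,
                              n_shared_sites = 1000L,
                              ltr_count = 200L,
                              ltr_length = 1000L,
                              ltr_ts_tv_ratio = 2,
                              ltr_true_ages = c(1e6, 2e6, 3e6),
                              ltr_rate = 1.3e-8,
                              n_pairs = 1000L,
                              tissues = c("root", "stem", "leaf", "flower",
                                          "ovule", "seed", "FE", "FS"),
                              bias_tissue = "FE",
                              bias_at_fraction = 0.30,
                              bias_dt_fraction = 0.20,
                              bias_effect_size = 4,
                              pair_noise_sdlog = 0.15,
                              rng_seed = 1L) {
  p <- as.list(environment())
  p$depth_noise <- match.arg(depth_noise)
  fr <- c(p$at_fraction, p$ungrouped_fraction, p$cross_mappability,
          p$ungrouped_covered_fraction, p$frac_bad_markers,
          p$frac_duplicated_markers, p$bias_at_fraction, p$bias_dt_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$bias_at_fraction + p$bias_dt_fraction > 1) {
    stop("bias fractions must sum to at most 1")
  }
  counts <- c(p$n_scaffolds, p$n_replicates_A, p$n_replicates_D,
              p$n_replicates_AD, p$n_hybrids, p$n_markers, p$n_chromosomes,
              p$scaffolds_per_chromosome, p$n_lineage_sites, p$n_shared_sites,
              p$ltr_count, p$n_pairs)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (p$n_hybrids > p$n_scaffolds) stop("n_hybrids exceeds n_scaffolds")
  if (p$ltr_length < 50L) stop("ltr_length must be at least 50 bp")
  if (p$scaffold_length_min < 2 * p$hybrid_margin && p$n_hybrids > 0) {
    stop("scaffold_length_min must be at least 2 * hybrid_margin for hybrids")
  }
  if (p$bias_tissue %in% p$tissues == FALSE) stop("bias_tissue not in tissues")
  if (any(p$ltr_true_ages < 0) || p$ltr_rate <= 0) {
    stop("ltr ages must be non-negative and ltr_rate positive")
  }
  p$rng_seed <- as.integer(p$rng_seed)
  structure(p, class = "simulation_params")
}

# manifest implied by the replicate counts (internal)
.sim_manifest <- function(params) {
  rows <- NULL
  for (cl in c("A", "D", "AD")) {
    nrep <- params[[paste0("n_replicates_", cl)]]
    if (nrep > 0) {
      rows <- rbind(rows, data.frame(
        dataset_id = paste0(cl, "_rep", seq_len(nrep)),
        clade = cl,
        line_label = paste0(cl, seq_len(nrep)),
        stringsAsFactors = FALSE))
    }
  }
  dataset_manifest(rows)
}

# one vector of bin depths under the configured noise model (internal)
.bin_depth <- function(n, mean, params) {
  switch(params$depth_noise,
         none = rep(mean, n),
         poisson = stats::rpois(n, mean),
         negbin = stats::rnbinom(n, mu = mean, size = params$nb_dispersion))
}

#' Simulate a synthetic allotetraploid with coverage truth
#'
#' Generates scaffolds (length-only stubs), one coverage track per dataset
#' and the full ground truth. At-truth scaffolds are fully mappable in
#' A-clade and AD-clade libraries and (near-)unmappable in D-clade libraries,
#' and vice versa; ungrouped-truth scaffolds expose only a shared low
#' fraction of mappable bins to every library (repeat-rich sequence); hybrid
#' scaffolds switch clade signal at a recorded junction.
#'
#' @param params A [simulation_params()].
#' @return List: `scaffolds` ([scaffold_set()]), `tracks` (list of
#'   [coverage_track()]), `manifest`, `truth` (list with
#'   `scaffold_subgenome` — named vector in `{At, Dt, ungrouped}` — and
#'   `junctions` data.frame `scaffold_id`, `position`, `left_label`,
#'   `right_label`).
#' @export
simulate_tetraploid <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$rng_seed, {
    n <- params$n_scaffolds
    ids <- sprintf("scaf_%04d", seq_len(n))
    lens <- as.integer(round(stats::runif(n, params$scaffold_length_min,
                                          params$scaffold_length_max)))
    scaffolds <- scaffold_set(lengths = stats::setNames(lens, ids))

    hyb_idx <- if (params$n_hybrids > 0) sample.int(n, params$n_hybrids) else integer(0)
    rest <- setdiff(seq_len(n), hyb_idx)
    n_un <- round(length(rest) * params$ungrouped_fraction)
    un_idx <- if (n_un > 0) sample(rest, n_un) else integer(0)
    grouped <- setdiff(rest, un_idx)
    n_at <- round(length(grouped) * params$at_fraction)
    at_idx <- if (n_at > 0) sample(grouped, n_at) else integer(0)
    dt_idx <- setdiff(grouped, at_idx)

    truth_label <- rep("ungrouped", n)
    truth_label[at_idx] <- "At"
    truth_label[dt_idx] <- "Dt"
    names(truth_label) <- ids

    junctions <- NULL
    hyb_left <- stats::setNames(rep(NA_character_, n), ids)
    hyb_pos <- stats::setNames(rep(NA_integer_, n), ids)
    for (i in hyb_idx) {
      pos <- as.integer(round(stats::runif(1, params$hybrid_margin,
                                           lens[i] - params$hybrid_margin)))
      left <- sample(c("At", "Dt"), 1)
      right <- if (left == "At") "Dt" else "At"
      hyb_left[i] <- left
      hyb_pos[i] <- pos
      junctions <- rbind(junctions, data.frame(
        scaffold_id = ids[i], position = pos, left_label = left,
        right_label = right, stringsAsFactors = FALSE))
    }
    if (is.null(junctions)) {
      junctions <- data.frame(scaffold_id = character(0), position = integer(0),
                              left_label = character(0), right_label = character(0),
                              stringsAsFactors = FALSE)
    }

    manifest <- .sim_manifest(params)
    bin <- params$coverage_bin
    noisy <- params$depth_noise != "none"

    # per-scaffold bin structure and shared masks
    bin_starts <- lapply(lens, function(L) seq(0L, L - 1L, by = bin))
    un_mask <- lapply(seq_len(n), function(i) {
      if (truth_label[i] == "ungrouped" && !(i %in% hyb_idx)) {
        stats::runif(length(bin_starts[[i]])) < params$ungrouped_covered_fraction
      } else NULL
    })

    tracks <- lapply(seq_len(nrow(manifest)), function(k) {
      clade <- manifest$clade[k]
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        st <- bin_starts[[i]]
        en <- pmin(st + bin, lens[i])
        nb <- length(st)
        if (i %in% hyb_idx) {
          left_on <- (hyb_left[i] == "At" && clade %in% c("A", "AD")) ||
            (hyb_left[i] == "Dt" && clade %in% c("D", "AD"))
          right_on <- (hyb_left[i] == "At" && clade %in% c("D", "AD")) ||
            (hyb_left[i] == "Dt" && clade %in% c("A", "AD"))
          is_left <- st < hyb_pos[i]
          on <- ifelse(is_left, left_on, right_on)
        } else if (truth_label[i] == "At") {
          on <- rep(clade %in% c("A", "AD"), nb)
        } else if (truth_label[i] == "Dt") {
          on <- rep(clade %in% c("D", "AD"), nb)
        } else {
          on <- un_mask[[i]]
        }
        depth <- numeric(nb)
        depth[on] <- .bin_depth(sum(on), params$depth_mean, params)
        if (noisy && any(!on)) {
          stray <- which(!on)[stats::runif(sum(!on)) < params$cross_mappability]
          depth[stray] <- .bin_depth(length(stray), params$depth_mean, params)
        }
        keep <- depth > 0
        if (any(keep)) {
          rows[[i]] <- data.frame(scaffold_id = ids[i], start = st[keep],
                                  end = en[keep], depth = depth[keep],
                                  stringsAsFactors = FALSE)
        }
      }
      coverage_track(manifest$dataset_id[k], do.call(rbind, rows), scaffolds)
    })

    list(scaffolds = scaffolds, tracks = tracks, manifest = manifest,
         truth = list(scaffold_subgenome = truth_label, junctions = junctions))
  })
}

# evolve a character vector of bases for t years under K2P (internal)
.evolve_k2p <- function(bases, t_years, rate, tstv) {
  alpha <- rate * tstv / (tstv + 1)
  beta <- rate / (2 * (tstv + 1))
  e1 <- exp(-4 * beta * t_years)
  e2 <- exp(-2 * (alpha + beta) * t_years)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1   # each of the two transversion targets
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  u <- stats::runif(length(bases))
  out <- bases
  hit_ts <- u < p_ts
  hit_tv1 <- !hit_ts & u < p_ts + p_tv
  hit_tv2 <- !hit_ts & !hit_tv1 & u < p_ts + 2 * p_tv
  out[hit_ts] <- ts_partner[bases[hit_ts]]
  out[hit_tv1] <- vapply(bases[hit_tv1], function(b) tv_partner[[b]][1], "")
  out[hit_tv2] <- vapply(bases[hit_tv2], function(b) tv_partner[[b]][2], "")
  out
}

#' Simulate LTR pairs diverged at known ages
#'
#' Each element starts as two identical terminal repeats that independently
#' accumulate substitutions under the exact continuous-time K2P process with
#' the configured transition:transversion ratio, so the expected corrected
#' divergence is K = 2 r T and the K2P estimator recovers the planted age.
#'
#' @param params A [simulation_params()]; `ltr_count` pairs are generated per
#'   entry of `ltr_true_ages`.
#' @return List: `pairs` (data.frame `element_id`, `five_prime`,
#'   `three_prime`) and `truth` (data.frame `element_id`, `true_age`).
#' @export
simulate_ltr_pairs <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$rng_seed + 1L, {
    ages <- rep(params$ltr_true_ages, each = params$ltr_count)
    ids <- sprintf("ltr_%05d", seq_along(ages))
    five <- character(length(ids)); three <- character(length(ids))
    for (i in seq_along(ids)) {
      anc <- sample(c("A", "C", "G", "T"), params$ltr_length, replace = TRUE)
      five[i] <- paste(.evolve_k2p(anc, ages[i], params$ltr_rate,
                                   params$ltr_ts_tv_ratio), collapse = "")
      three[i] <- paste(.evolve_k2p(anc, ages[i], params$ltr_rate,
                                    params$ltr_ts_tv_ratio), collapse = "")
    }
    list(pairs = data.frame(element_id = ids, five_prime = five,
                            three_prime = three, stringsAsFactors = FALSE),
         truth = data.frame(element_id = ids, true_age = ages,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a homoeolog expression matrix with planted bias
#'
#' Unbiased pairs share a log-normal pair-tissue mean with small within-pair
#' noise; biased pairs have the At (or Dt) copy multiplied by
#' `bias_effect_size` in the focal tissue, where their baseline expression is
#' drawn high (they model the tissue-specific pairs of interest).
#'
#' @param params A [simulation_params()].
#' @return List: `matrix` (genes x tissues FPKM), `pairs` (data.frame
#'   `pair_id`, `at_gene`, `dt_gene`), `truth` (data.frame `pair_id`,
#'   `tissue`, `class` in `{At-biased, Dt-biased, unbiased}` for the focal
#'   tissue).
#' @export
simulate_expression <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$rng_seed + 2L, {
    np <- params$n_pairs
    tis <- params$tissues
    pair_id <- sprintf("pair_%04d", seq_len(np))
    at_gene <- sprintf("At_g%04d", seq_len(np))
    dt_gene <- sprintf("Dt_g%04d", seq_len(np))

    n_at <- round(np * params$bias_at_fraction)
    n_dt <- round(np * params$bias_dt_fraction)
    lab <- rep("unbiased", np)
    idx <- sample.int(np, n_at + n_dt)
    lab[idx[seq_len(n_at)]] <- "At-biased"
    if (n_dt > 0) lab[idx[n_at + seq_len(n_dt)]] <- "Dt-biased"

    base <- matrix(stats::rlnorm(np * length(tis), meanlog = log(20), sdlog = 1),
                   nrow = np, dimnames = list(pair_id, tis))
    focal <- params$bias_tissue
    biased <- lab != "unbiased"
    base[biased, focal] <- stats::rlnorm(sum(biased), meanlog = log(50),
                                         sdlog = 0.5)
    noise <- function() matrix(exp(stats::rnorm(np * length(tis), 0,
                                                params$pair_noise_sdlog)),
                               nrow = np)
    at_m <- base * noise()
    dt_m <- base * noise()
    at_m[lab == "At-biased", focal] <- at_m[lab == "At-biased", focal] *
      params$bias_effect_size
    dt_m[lab == "Dt-biased", focal] <- dt_m[lab == "Dt-biased", focal] *
      params$bias_effect_size

    m <- rbind(at_m, dt_m)
    rownames(m) <- c(at_gene, dt_gene)
    list(matrix = m,
         pairs = data.frame(pair_id = pair_id, at_gene = at_gene,
                            dt_gene = dt_gene, stringsAsFactors = FALSE),
         truth = data.frame(pair_id = pair_id, tissue = focal, class = lab,
                            stringsAsFactors = FALSE))
  })
}

# plant k mismatches into a segment string (internal)
.mutate_segment <- function(seg, k) {
  ch <- strsplit(seg, "")[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate a genetic map, shredded scaffolds and a multi-lineage VCF
#'
#' Builds `n_chromosomes` chromosomes from ordered, randomly oriented
#' scaffolds, plants `n_markers` 201-bp SNP segments at known scaffold
#' offsets (a fraction with 6 mismatches that must be rejected under the
#' 196/201 rule, and a fraction duplicated into a decoy scaffold that must be
#' dropped as non-unique), and emits a VCF with planted lineage-specific and
#' shared alternate alleles across the manifest's datasets.
#'
#' @param params A [simulation_params()].
#' @return List: `scaffolds` ([scaffold_set()] with sequences, including
#'   decoys), `markers` (genetic-map data.frame), `manifest`, `vcf`
#'   (list `fix`, `gt`, `samples` — see [write_vcf()]), and `truth` (list
#'   `marker_truth`, `scaffold_truth`, `lineage_snps`, `shared_snps`).
#' @export
simulate_map_and_vcf <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$rng_seed + 3L, {
    n_chr <- params$n_chromosomes
    spc <- params$scaffolds_per_chromosome
    slen <- params$map_scaffold_length
    chr_names <- sprintf("chr%02d", seq_len(n_chr))

    scaffold_truth <- NULL
    stored <- list()
    chrom_seq <- list()
    piece_map <- list()  # per chromosome: data.frame(scaffold_id, piece_start, ori)
    for (c_i in seq_len(n_chr)) {
      pieces <- character(spc)
      pm <- NULL
      pos <- 0L
      for (s_i in seq_len(spc)) {
        sid <- sprintf("map_scaf_%02d_%02d", c_i, s_i)
        sq <- paste(sample(c("A", "C", "G", "T"), slen, replace = TRUE),
                    collapse = "")
        ori <- sample(c("+", "-"), 1)
        stored[[sid]] <- sq
        pieces[s_i] <- if (ori == "+") sq else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
        pm <- rbind(pm, data.frame(scaffold_id = sid, piece_start = pos,
                                   piece_end = pos + slen, ori = ori,
                                   stringsAsFactors = FALSE))
        scaffold_truth <- rbind(scaffold_truth, data.frame(
          scaffold_id = sid, chromosome = chr_names[c_i], true_order = s_i,
          orientation = ori, stringsAsFactors = FALSE))
        pos <- pos + slen
      }
      chrom_seq[[chr_names[c_i]]] <- paste(pieces, collapse = "")
      piece_map[[chr_names[c_i]]] <- pm
    }

    # distribute markers over chromosomes
    per_chr <- rep(params$n_markers %/% n_chr, n_chr)
    extra <- params$n_markers %% n_chr
    if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
    markers <- NULL
    marker_truth <- NULL
    k <- 0L
    for (c_i in seq_len(n_chr)) {
      chr <- chr_names[c_i]
      pm <- piece_map[[chr]]
      chr_len <- spc * slen
      # centers at least 100 bp from every piece boundary
      centers <- sort(sample(setdiff(seq(100L, chr_len - 101L),
                                     unlist(lapply(pm$piece_start, function(p) {
                                       seq(max(0L, p - 100L), p + 100L)
                                     }))),
                             per_chr[c_i]))
      cseq <- chrom_seq[[chr]]
      for (ct in centers) {
        k <- k + 1L
        seg <- toupper(substr(cseq, ct - 100L + 1L, ct + 101L))
        piece <- pm[pm$piece_start <= ct & pm$piece_end > ct, ]
        op <- ct - piece$piece_start
        if (piece$ori == "+") {
          off <- op - 100L; strand <- "+"
        } else {
          off <- slen - op - 101L; strand <- "-"
        }
        markers <- rbind(markers, data.frame(
          marker_id = sprintf("mk_%05d", k), chromosome = chr,
          cM = ct / 1e4, segment = seg, stringsAsFactors = FALSE))
        marker_truth <- rbind(marker_truth, data.frame(
          marker_id = sprintf("mk_%05d", k), chromosome = chr,
          scaffold_id = piece$scaffold_id, offset = off, strand = strand,
          status = "clean", stringsAsFactors = FALSE))
      }
    }

    nm <- nrow(markers)
    n_bad <- round(nm * params$frac_bad_markers)
    n_dup <- round(nm * params$frac_duplicated_markers)
    flag <- sample.int(nm, n_bad + n_dup)
    bad_i <- flag[seq_len(n_bad)]
    dup_i <- if (n_dup > 0) flag[n_bad + seq_len(n_dup)] else integer(0)
    for (i in bad_i) {
      markers$segment[i] <- .mutate_segment(markers$segment[i], 6L)
      marker_truth$status[i] <- "mismatched"
    }
    decoy <- NULL
    if (length(dup_i)) {
      marker_truth$status[dup_i] <- "duplicated"
      pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
      decoy <- paste(vapply(dup_i, function(i) {
        paste0(pad(50L), markers$segment[i], pad(50L))
      }, ""), collapse = "")
      stored[["decoy_01"]] <- decoy
    }
    markers <- add_order_index(markers)
    marker_truth$order_index <- markers$order_index

    scaffolds <- scaffold_set(
      sequences = Biostrings::DNAStringSet(unlist(stored)))

    # ---- VCF with planted lineage-specific and shared alleles ----
    manifest <- .sim_manifest(params)
    samples <- manifest$dataset_id
    lin <- manifest$clade
    sids <- setdiff(names(stored), "decoy_01")
    n_sites <- params$n_lineage_sites + params$n_shared_sites
    site_scaf <- sample(sids, n_sites, replace = TRUE)
    site_pos <- integer(n_sites)
    for (s in unique(site_scaf)) {
      i <- which(site_scaf == s)
      site_pos[i] <- sample.int(slen, length(i))
    }
    o <- order(site_scaf, site_pos)
    site_scaf <- site_scaf[o]; site_pos <- site_pos[o]
    spec_lineage <- rep(NA_character_, n_sites)
    if (params$n_lineage_sites > 0) {
      spec_lineage[sample.int(n_sites, params$n_lineage_sites)] <-
        sample(c("A", "D"), params$n_lineage_sites, replace = TRUE)
    }
    ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    gt <- matrix("0/0", nrow = n_sites, ncol = length(samples),
                 dimnames = list(NULL, samples))
    for (i in seq_len(n_sites)) {
      carriers <- if (is.na(spec_lineage[i])) rep(TRUE, length(samples))
                  else lin == spec_lineage[i]
      gt[i, carriers] <- "1/1"
    }
    fix <- data.frame(contig = site_scaf, pos = site_pos, ref = ref,
                      alt = unname(alt), stringsAsFactors = FALSE)
    spec <- !is.na(spec_lineage)
    list(scaffolds = scaffolds, markers = markers, manifest = manifest,
         vcf = list(fix = fix, gt = gt, samples = samples, depth = 20L),
         truth = list(marker_truth = marker_truth,
                      scaffold_truth = scaffold_truth,
                      lineage_snps = cbind(fix[spec, , drop = FALSE],
                                           lineage = spec_lineage[spec]),
                      shared_snps = fix[!spec, , drop = FALSE]))
  })
}

#' Write a minimal multi-sample VCF
#'
#' Emits VCF v4.2 with GT and DP FORMAT fields — the on-disk form consumed by
#' [read_vcf_sites()].
#'
#' @param vcf List with `fix` (data.frame `contig`, `pos`, `ref`, `alt`),
#'   `gt` (sites x samples character matrix of genotypes), `samples`, and
#'   `depth` (constant DP to report, default 20).
#' @param path Output path.
#' @export
write_vcf <- function(vcf, path) {
  depth <- if (is.null(vcf$depth)) 20L else vcf$depth
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vcf$samples), collapse = "\t"))
  body <- apply(cbind(vcf$fix$contig, vcf$fix$pos, ".", vcf$fix$ref,
                      vcf$fix$alt, ".", "PASS", ".", "GT:DP",
                      matrix(paste0(vcf$gt, ":", depth), nrow = nrow(vcf$gt))),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a tetraploid simulation to disk
#'
#' Emits the exact on-disk formats the readers consume: one bedgraph per
#' dataset, the manifest TSV, a scaffold length table, and truth TSVs.
#'
#' @param sim Result of [simulate_tetraploid()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tetraploid_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_file(as.data.frame(sim$manifest), file.path(dir, "manifest.tsv"))
  write_table_file(data.frame(scaffold_id = sim$scaffolds$ids,
                              length = unname(sim$scaffolds$lengths)),
                   file.path(dir, "scaffolds.tsv"))
  for (t in sim$tracks) {
    write_bedgraph(t, file.path(dir, paste0(t$dataset_id, ".bedgraph")))
  }
  write_table_file(data.frame(scaffold_id = names(sim$truth$scaffold_subgenome),
                              subgenome = unname(sim$truth$scaffold_subgenome)),
                   file.path(dir, "truth_subgenome.tsv"))
  write_table_file(sim$truth$junctions, file.path(dir, "truth_junctions.tsv"))
  invisible(dir)
}
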