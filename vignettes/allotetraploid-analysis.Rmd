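---
title: "Subgenome assignment and genome dynamics in allotetraploid assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome assignment and genome dynamics in allotetraploid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allotetra)
```

# The problem

Allotetraploid species — tetraploid cotton is the motivating case — carry two
complete parental genomes, an A-derived (At) and a D-derived (Dt) subgenome,
that diverged for millions of years before being reunited by hybridization
and genome doubling. A shotgun assembly of such a genome yields scaffolds of
unknown parentage. Because reads from an extant diploid progenitor map almost
exclusively to the subgenome it gave rise to, clade-structured shotgun
coverage is an effective classifier of scaffold origin, and downstream
questions — where did translocations between subgenomes occur, how do the
subgenomes' transposon loads and insertion histories differ, which
homoeologous gene copies diverged in expression — all build on that
assignment.

`allotetra` implements this pipeline end to end, starting from coverage
tracks (bedgraph), a dataset manifest, a genetic-map marker table, LTR pair
sequences, a multi-sample VCF and an FPKM matrix. Read mapping, variant
calling, repeat identification and synteny detection are deliberately
upstream of the package: it consumes their standard outputs.

# Subgenome assignment

For scaffold $s$ and sequencing dataset $d$, the mean depth is
$\bar{c}_{sd} = \sum_i \mathrm{depth}_i \cdot \ell_i / L_s$, averaged over
**all** bases of the scaffold including uncovered ones. "Average base-pair
coverage" is ambiguous between covered-bases-only and all-bases averaging;
we chose all-bases because it makes the A:D ratio robust to differences in
covered fraction. Depths are library-size normalized by each dataset's
genome-wide mean, so libraries of different size are comparable; this
normalization can be disabled.

A scaffold is called **At** when all three of the following hold, **Dt**
under the mirrored ratio, and **ungrouped** otherwise:

1. *Covered fraction*: more than 40% of its bases carry depth ≥ 1 in the
   union of all progenitor (A- and D-clade) tracks. The union reading treats
   "covered by A1, A2 or D5 reads" literally as any-of.
2. *Ratio*: $\log_2\frac{\bar{c}_A + \epsilon}{\bar{c}_D + \epsilon} > 2$,
   where $\bar{c}_A$ pools all A-clade datasets equally (the A-genome lines
   are highly correlated with each other, and pooling uses every replicate
   rather than privileging one line) and $\epsilon = 0.01$ normalized-depth
   units keeps zero denominators finite.
3. *Significance*: a classic equal-variance Student's two-sample t-test on
   the per-dataset normalized means of the two clades gives $p < 0.01$.
   Welch's form is available by flag. At least two replicate datasets per
   clade are required; with fewer, the user must disable the criterion
   explicitly rather than have it silently skipped.

Tetraploid (AD-clade) tracks are carried through all summaries for display
but never used in classification. All thresholds live in
`pipeline_config()`.

# Hybrid scaffolds and translocations

Scaffolds assembled across an At–Dt junction — candidate inter-subgenome
translocations — switch clade signal along their length. The published
analyses show such scaffolds but name no algorithm, so the segmentation here
is this package's own reconstruction, and is stated as such:

* windows (default 10 kb; any size) are labelled A, D or ambiguous by the
  same pooled log2-ratio rule as whole scaffolds;
* consecutive same-label windows merge into segments; ambiguous windows
  neither break nor extend a segment;
* a junction is emitted between adjacent A/D segments when both flanks are
  at least `hybrid_min_segment` (default 50 kb) long, and is reported as an
  *interval* — the gap between the last unambiguous window of one side and
  the first of the other — because its position is only known to window
  resolution.

Scanning runs on all scaffolds; callers typically report the ungrouped
subset separately, where genuine hybrids are expected to land (a hybrid
fails the whole-scaffold ratio criterion). Junction midpoints are projected
onto a reference through user-supplied alignment intervals by strand-aware
linear interpolation, and `subtelomeric_enrichment()` tests whether
projected sites concentrate in the outer `terminal_fraction` (default 10%)
of each chromosome arm against a uniform permutation null. Distinguishing
biological translocation from assembly chimerism requires paired-end or PCR
evidence and is out of scope.

# Pseudochromosome anchoring

Genetic-map markers are 201-bp segments: 100 bp each side of a mapped SNP
(`extract_segments()` enforces the arithmetic and skips SNPs within 100 bp
of a sequence end). Matching is ungapped over both strands with at most 5
mismatches — the 196-of-201 minimum implies substitutions only, so indels
are not tolerated, and a marker is retained only with a unique best
placement genome-wide. A vectorized brute-force scanner
(`match_segments_bruteforce()`) with the identical contract serves as a
cross-check.

"At least 5 continuous SNP segments" is interpreted as *consecutive in
within-chromosome map order*, not physical distance; the definition is not
spelled out in the source analyses, so the package makes this reading
explicit and lets `max_marker_gap` tolerate missing markers when desired
(default 0, strict). A scaffold with qualifying runs on two chromosomes is
rejected. Orientation comes from the sign of the rank correlation between
map order and scaffold coordinate over the run's hits — monotone increasing
is `+`, decreasing `-`, undecidable `unknown` (placed forward). The original
third criterion also allowed consistency with a second tetraploid assembly;
cross-assembly tie-breaking is reduced here to the single-chromosome rule.
`build_pseudochromosomes()` concatenates anchored scaffolds in map order
with 100-N gaps and emits an AGP-like layout table.

# LTR insertion dating

The two terminal repeats of a retrotransposon are identical upon insertion;
their subsequent divergence dates it. With transition proportion $P$ and
transversion proportion $Q$ over compared sites,

$$K = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q), \qquad
T = \frac{K}{2r}, \quad r = 1.3\times10^{-8}\ \text{site}^{-1}\,\text{yr}^{-1}.$$

Columns containing gaps or ambiguous bases are excluded (pairwise deletion);
whether the original distance computation used only ungapped columns is
unstated, so pairwise deletion is this package's documented choice.
Unequal-length pairs pass through a built-in global aligner (match +1,
mismatch −1, gap open 4, extend 1) so the module is self-contained;
pre-aligned input bypasses it. Saturated pairs ($1-2P-Q \le 0$ or
$1-2Q\le0$) are *flagged undefined, not clamped* — clamping would silently
pile mass at the oldest age bin and bias the insertion-time distribution.
Age histograms default to 0.5 Myr bins (configurable; the published
histogram granularity is not stated numerically).

Family clustering keeps only reciprocal similarity edges (both directions
present at e-value ≤ 10⁻⁵, re-filtered defensively) and takes connected
components, numbered deterministically by smallest member id. Solo/truncated
to intact ratios are computed from supplied counts; element identification
itself is upstream.

# Lineage-specific SNPs and density scanning

A site is lineage-L-specific iff an alternate allele is present in **every**
L dataset covering the site (at least one must) and absent from **every**
covering dataset of all other lineages; datasets without coverage do not
veto. "Absent" means no alternate support in a covering dataset, with
coverage gated at `min_presence_depth` (default 3) — the source analyses do
not state their exact rule, so this one is explicit and configurable.
Tetraploid genotype calls are reduced to allele presence/absence; dosage is
ignored. The resulting lineage sets are pairwise disjoint by construction.

Density scanning tiles contigs with 1 Mb windows and z-scores each window's
SNP count against the genome-wide window distribution, flagging
$|z| \ge 2$ windows low or high. The published low-density (candidate
selective sweep) regions were identified descriptively; the z-score rule is
this package's operationalization.

# Homoeolog expression bias

Profiles are normalized per gene as z-scored $\log_2(\mathrm{FPKM}+1)$
across tissues (zero-variance genes get flagged all-zero profiles).
K-means runs on sorted gene ids with a seeded initialization, so results
are deterministic and invariant to input row order; k defaults to 8, one
per tissue column, since no k is stated in the source analyses.

A pair is *highly and specifically expressed* in a focal tissue when its
combined (At + Dt) FPKM is ≥ 5 and ≥ 2× the combined expression of every
other tissue — the published counts depend on unstated thresholds, so both
knobs are explicit. Bias is
$\mathrm{ratio} = \log_2\frac{\mathrm{FPKM}_{At}+1}{\mathrm{FPKM}_{Dt}+1}$
in the focal tissue with |ratio| ≥ 1 called biased; the pseudocount keeps
low-expression pairs conservative. `group_expression_sum()` adds FPKM over
gene groups per tissue, e.g. to show that many individually weak members of
a gene-family clade collectively match the output of a strong one.

# The synthetic tetraploid

Every stage is validated against `simulate_*()` generators whose defaults
*are* the study conditions of the package's acceptance checks; they are not
tuning knobs.

* **Coverage** is simulated directly as binned depth tracks (2 kb bins), not
  as reads — the classifier consumes coverage, and read simulation would
  re-introduce the upstream aligner stack. Homoeolog divergence is expressed
  purely through clade-differential mappability; actual bases are only
  emitted where they matter (marker segments, LTRs, map scaffolds).
* 200 scaffolds of 120–200 kb; three replicate libraries per progenitor
  clade at mean depth 20. Bin noise is negative binomial with dispersion 10
  (Poisson is the dispersion→∞ limit); overdispersion is the realistic
  failure mode for the replicate t-test, and no noise model is stated in
  the source, so this is an assumption of the generator, not a claim about
  the data. Under `depth_noise = "none"` the signal is pure mappability:
  exact `depth_mean` on-clade, exactly zero off-clade. Noisy modes add
  stray off-clade coverage to 2% of bins (conserved repeats).
* **Ungrouped-truth scaffolds** expose one shared low-mappability mask
  (20% of bins) to *every* library — repeat-rich regions are common to all
  libraries, and per-dataset independent masks would let the union covered
  fraction creep above the 40% criterion.
* **Hybrids** switch clade signal at a junction placed at least 55 kb from
  either end, so both flanks can satisfy the 50 kb minimum segment.
* **LTR pairs** evolve under the exact continuous-time K2P transition
  matrix at ts/tv 2 ($\alpha = 4\beta$), so expected divergence is exactly
  $2rT$ and the estimator is consistent; 200 pairs per age at 1 kb give
  mean recovered ages within a few percent of 1, 2 and 3 Myr.
* **The genetic map** shreds 5 chromosomes into 8 × 25 kb scaffolds with
  random orientations, plants 1,000 markers at known offsets, corrupts 5%
  with exactly 6 mismatches (just beyond the 196/201 rule) and duplicates
  another 5% into a dedicated decoy scaffold (so duplicates can never
  corrupt other planted markers).
* **Expression**: unbiased pairs share a log-normal pair-tissue mean
  (meanlog = log 20, sdlog = 1) with small within-pair noise
  (sdlog 0.15, so the unbiased log2-ratio has sd ≈ 0.3 and essentially
  never crosses the bias threshold); biased pairs draw a high focal-tissue
  baseline (meanlog = log 50, sdlog = 0.5) and multiply one copy by 4.
  The high baseline reflects what the biased pairs model — tissue-specific,
  highly expressed pairs — and keeps the +1 pseudocount from eroding the
  planted effect.

What passing these checks does **not** show: real libraries have GC- and
mappability-structured coverage, correlated errors between libraries of the
same line, index hopping and mapping ambiguity in repeat-rich regions none
of which the generator emulates; real genetic maps contain genotyping
errors and segregation distortion beyond the two planted corruption modes;
real FPKM matrices have replicate-level and length-dependent noise. The
generator demonstrates correctness of the decision rules, not robustness to
every artefact of real data.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; VCF and map
  positions convert at the file boundary.
* The log-ratio pseudocount (0.01), bias pseudocount (+1 FPKM) and the
  N-gap (100) are configurable; defaults are reported in output.
* Zero-coverage scaffolds summarize to zeros (not errors) and fail
  criterion 1; a both-clades-constant t-test degenerates to p = 1 on equal
  means rather than erroring.
* Orientation with a single supporting hit, or zero coordinate spread, is
  `unknown` and placed forward.
* Windows shorter than one window size become a single short window; the
  last window of a tiling may be short and density uses per-bp rates.
* Empty inputs return typed empty tables, never NULL.

# Problem sizes

The bundled checks run the generator at 200 scaffolds / 6 libraries, 1,000
markers over a 1 Mb shredded genome, 600 LTR pairs, 2,000 VCF sites and
1,000 expression pairs — sizes chosen so the whole validation suite
completes in a few minutes on one core while keeping every estimate's
sampling error far from its acceptance margin.

# Known limitations

* The t-test has 2–4 degrees of freedom with typical replicate counts;
  criterion 3 is the binding constraint at low depth, and Welch's form is
  advisable when library variances differ grossly.
* Segment matching tolerates substitutions only; markers spanning indels or
  assembly gaps are dropped rather than recovered.
* Junction localization is window-resolution; PET-style read-pair evidence
  (out of scope) is accepted only as an annotation table.
* Bias calls are per focal tissue with a fixed fold threshold; they are a
  classification, not a differential-expression test with error control.
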