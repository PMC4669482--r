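# allotetra

Analysis of allotetraploid genome assemblies — organisms such as tetraploid
cotton that carry two complete, diverged parental genomes (an A-like and a
D-like progenitor) in one nucleus. Given a scaffold-level assembly and shotgun
coverage tracks from the progenitor diploids and the tetraploid itself,
`allotetra`:

* **assigns scaffolds to parental subgenomes** (At / Dt / ungrouped) with a
  three-criteria classifier,
* **detects inter-subgenome hybrid scaffolds** (putative At–Dt translocations),
  localizes their junctions, projects them onto a reference and tests
  sub-telomeric enrichment,
* **anchors scaffolds into pseudochromosomes** from a genetic map of 201-bp
  SNP segments,
* **dates LTR retrotransposon insertions** from 5'/3' terminal-repeat
  divergence under the Kimura two-parameter model, and clusters elements into
  families from reciprocal similarity,
* **partitions lineage-specific SNPs** from a multi-sample VCF and scans
  windowed SNP density for low/high-density regions,
* **classifies homoeologous gene-pair expression bias** from an FPKM matrix,
  with seeded k-means profile clustering and group-summed profiles.

A synthetic-tetraploid generator with complete ground truth
(`simulate_tetraploid()`, `simulate_map_and_vcf()`, `simulate_ltr_pairs()`,
`simulate_expression()`) makes every stage testable without external data.

## The models at the core

**Subgenome assignment.** For each scaffold, per-dataset mean depth is
library-size normalized; the scaffold is assigned to At iff

1. more than 40% of its bases are covered by progenitor shotgun reads
   (union of the A- and D-clade tracks),
2. log2((mean_A + ε)/(mean_D + ε)) > 2, and
3. the A/D difference is significant (p < 0.01, Student's two-sample t-test)
   across the replicate libraries of each clade,

and to Dt under the mirrored ratio condition; anything else is *ungrouped*.

**LTR insertion dating.** For a pair of terminal repeats with transition
proportion P and transversion proportion Q,

    K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q),   T = K / (2r)

with r = 1.3 × 10⁻⁸ substitutions per site per year. Saturated pairs
(1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) are flagged undefined rather than clamped.

**Anchoring.** Map segments (100 bp + SNP + 100 bp) are matched to scaffolds
ungapped on both strands requiring ≥ 196/201 matching bases and a unique best
placement; a scaffold is anchored when at least 5 map-consecutive segments hit
it and only one chromosome qualifies.

## Worked example

```r
library(allotetra)

p   <- simulation_params(n_scaffolds = 40, scaffold_length_min = 60000,
                         scaffold_length_max = 90000, rng_seed = 7)
sim <- simulate_tetraploid(p)
s   <- summarize_coverage(sim$tracks, sim$manifest, sim$scaffolds)
a   <- assign_scaffolds(s)
table(truth = sim$truth$scaffold_subgenome[a$scaffold_id], called = a$label)
#>            called
#> truth       At Dt ungrouped
#>   At        18  0         0
#>   Dt         0 18         0
#>   ungrouped  0  0         4
assignment_report(a, sim$scaffolds)
#>       label n_scaffolds total_length   n50
#> 1        At          18      1359841 78811
#> 2        Dt          18      1316712 70867
#> 3 ungrouped           4       314282 85411
#> 4     total          40      2990835 74714
```

All 40 scaffolds are recovered with their true subgenome; the report gives
per-label counts, total lengths and N50. Dating a constructed LTR pair:

```r
k <- k2p_divergence(strrep("A", 100),
                    paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85)))
k$K                    # 0.1701812  (P = 0.10, Q = 0.05)
insertion_age(k)$T_years / 1e6   # 6.55 Myr at r = 1.3e-8
```

See `vignettes/allotetraploid-analysis.Rmd` for the full methods account.

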