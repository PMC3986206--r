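---
title: "Methods: germplasm curation and diversity analysis in corecurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm curation and diversity analysis in corecurator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corecurator)
```

corecurator analyzes biallelic SNP genotypes of inbred accessions from a
germplasm collection. This vignette documents the statistical models, the
parameters that matter, the synthetic-data generator the tests rely on, and
the numerical and design choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Data model

Calls are stored as an accessions × markers matrix over {0, 1, NA}. Inbred
lines are treated as haplotypes: a heterozygous raw call is a genotyping
artifact on this material and `mask_heterozygotes()` converts flagged calls
to missing. Readers for plain matrix TSV, HapMap and VCF flag heterozygotes
at parse time; multi-allelic VCF records are dropped with a count.

`qc_filter()` removes markers with missing fraction above
`max_marker_missing` (default 0.10) **first**, then accessions above
`max_accession_missing` (default 0.10) computed over the surviving markers.
Marker-first ordering is deliberate: a high-missingness marker is an
assay-level failure and should not count against the accessions carrying it.
The single fixed pass is idempotent at realistic missingness (a few
percent); it is not a fixpoint iteration.

## Duplicate detection

Genebanks accumulate re-accessioned duplicates. Two accessions are
considered genetically identical when their simple-matching similarity over
co-observed markers is exactly 1 and they co-observe at least
`min_overlap_fraction` (default 0.5) of the panel; missing calls never count
as matches or mismatches. Duplicate sets are connected components of the
resulting graph rather than cliques: exact-match edges are transitive in
practice on well-genotyped material, and a component containing a
conflicting pair is still reported as one set for the curator to inspect.
`resolve_duplicates()` retains one member per set (`keep-most-complete` by
default) and flags sets whose members disagree on origin metadata.

## Population structure

Admixture inference itself is out of scope: membership (Q) matrices and
log-probability series are consumed from external tools. The bespoke parts
are:

* **Δk.** For each interior k, the second difference of LnP(D) is computed
  per run, its absolute value averaged over runs, and divided by the
  standard deviation of LnP(D) at k across runs. Runs are aligned by index;
  zero standard deviation with a nonzero second difference yields `Inf`
  rather than an error, so a degenerate series is visible instead of fatal.
* **Assignment.** An accession is assigned to its arg-max subpopulation only
  when the coefficient strictly exceeds 0.8; the boundary value 0.8 itself
  is "admixed". The strict reading was chosen once and is asserted in tests.
* **PCA.** Missing calls are mean-imputed per marker, columns centered, no
  variance scaling — the common convention for genotype PCA, recorded here
  because the choice affects score scales. Component signs are fixed by
  making each component's largest-magnitude loading positive, so results are
  invariant to accession order. The one-marker-per-bin thinning helper
  (`thin_one_per_bin()`, least-missing marker per identical map position) is
  available for parity with structure-inference workflows that thin.

## Per-SNP Φ_PT divergence

For one marker with calls dropped where missing, the one-level AMOVA on
squared differences of 0/1 alleles gives `SS_total`, `SS_within` (around
group means), mean squares, and the sample-size coefficient
`n0 = (N − Σn_g²/N)/(g − 1)`. The variance components are `V_WP = MS_within`
and `V_AP = (MS_among − MS_within)/n0`, and `Φ_PT = V_AP/(V_AP + V_WP)` with
negative `V_AP` clamped to zero; the unclamped ratio is retained as
`phi_raw`. Only groups with at least two observed calls enter; markers with
fewer than two qualifying groups are skipped with a reason, and monomorphic
markers (zero total variance) are reported as undefined rather than zero —
they carry no information about differentiation, and treating them as zero
would bias every summary toward zero.

Permutation p-values shuffle group labels jointly across accessions and use
the add-one estimator `(1 + #{Φ*_perm ≥ Φ*_obs})/(1 + B)`, which cannot be
zero. Permuted statistics are compared on the unclamped scale: clamping
creates a point mass at zero under the null and would make the test
conservative beyond its intrinsic discreteness. Within one scan a single set
of permutations is reused across markers (and regenerated per scan), which
is what makes a 1,000-marker × 1,000-permutation scan affordable and makes
per-marker p-values comparable.

Two estimators summarize a scan: the per-marker ratio (what the scan plots)
and the multilocus ratio of sums `ΣV_AP / Σ(V_AP + V_WP)`
(`phi_pt_overall()`). Only the latter is consistent for the generating
differentiation level: markers drifted toward fixation in both groups have
per-marker ratios near zero and drag the mean of ratios well below the
generating F (brute-force checks in the test suite put the mean of ratios
near 0.30 at F = 0.5, while the ratio of sums sits at F). One-vs-rest
contrasts pool all non-focal groups and display `Φ_PT^10`, which spreads the
top of the scale so strongly differentiated markers stand out.

## Linkage disequilibrium

`pair_r2()` implements `r² = D²/(p_A(1−p_A) p_B(1−p_B))` with `D = p_AB −
p_A p_B` on pairwise-complete haplotypes, and `pair_fisher_p()` the
two-sided exact test (point-probability method) on the 2×2 joint-call
table.

The genome-wide significance threshold follows the unlinked-pair logic:
sample `n_pairs` (default 100,000) random inter-chromosomal pairs among
markers with MAF ≥ 0.05, shift r² by ε = 10⁻⁶, power-transform toward
normality, and take the parametric percentile `mean + z₉₉·sd`
back-transformed. The default exponent is the Wilson–Hilferty cube root: the
null r² between unlinked markers is asymptotically χ²₁/n, whose classical
normalizing power is 1/3, and in repeated simulations the cube root keeps
the fresh-pair exceedance of the 99th-percentile threshold near its nominal
1% (1.2–1.6% across seeds in the acceptance checks). The full Box–Cox MLE
exponent is available (`transform = "boxcox-mle"`) but optimizes
whole-distribution normality rather than tail fit and measurably
overshoots the threshold (exceedance 0.3–0.7%); that is why it is not the
default.

`decay_profile()` bins intra-chromosomal pairs by map distance (default
1 cM bins to 20 cM) per chromosome, reporting empty bins with `n = 0`.

The structure-corrected LD scan regresses each response marker M0 on one
regressor marker at a time within a half-open distance window `[lo, hi)`
(defaults 1–2 and 4–5 cM), with the first 11 principal components as
covariates, and reports the likelihood-ratio p-value of the regressor. The
LRT was preferred to the Wald test because it stays usable near separation;
complete separation triggers a Firth-type penalized fit (Jeffreys-prior
score adjustment, written in-package since no penalized-logistic package is
a dependency) flagged in the output, and non-convergence flags the pair
rather than failing the scan. Pairs are generated once with M0 the leftmost
marker, avoiding double counting; −log10(p) is capped at 320 to keep output
finite. The same fitter accepts an explicit pair list, which is how
unlinked pairs are pushed through it for calibration.

## Q+K association scan

The mixed model is `y = μ + Q*α + xβ + u + e`, `u ~ (0, σ²_g K)`,
`e ~ (0, σ²_e I)`. `Q*` drops the last membership column (rows sum to one,
so the full matrix is collinear with the intercept); any residual collinear
column is dropped with a message. Kinship is the centered cross-product on
mean-imputed calls, `K = (X − p)(X − p)′ / Σ p(1−p)`, over markers with
MAF > 0.01; the formula and marker count are recorded on the object.

Variance components are estimated once on the no-marker model — the
EMMAX/P3D approach — by a one-dimensional REML profile over
δ = σ²_e/σ²_g on the eigenbasis of K, after which every marker is tested by
generalized least squares with a Wald t-test (df = n − p − 1). Per-marker
REML is available behind `per_marker_reml = TRUE` but is not the default;
at these sample sizes the P3D approximation is standard practice and two
orders of magnitude faster. With K = I and no Q the scan reduces exactly to
per-marker ordinary least squares, which the tests assert. Binary traits
are fitted as 0/1 quantitative responses, the convention of the mixed-model
GWAS tools this follows. Multiple testing uses Benjamini–Hochberg q-values
(`stats::p.adjust`; an independent step-up oracle re-derives them in the
tests), and `manhattan_table()` orders results deterministically (chromosome,
position, marker id) with strict q < 0.05 significance flags and unmapped
markers emitted last.

## Mini-core selection

Per-marker PIC uses the gene-diversity form `1 − Σp_i²` (maximum 0.5 for
biallelic markers), with the full Botstein form available behind
`form = "botstein"`; outputs record which form was used. Frequencies are
computed over the observed calls of the current subset only, and a marker
that is all-missing within a subset is excluded from that subset's average
rather than counted as zero.

`rank_accessions()` repeatedly removes the accession whose removal yields
the highest post-removal average PIC, recording the trajectory down to a
retained set of 2 so a complete ranking exists even past the diversity
peak. Ties are broken by lexicographic accession id — required for
determinism, since any other order would make rankings depend on input
order. The engine maintains per-marker allele and observation counts so a
candidate evaluation is an O(markers) vector update; a naive
full-recomputation oracle lives in the test suite and the two must agree
exactly. The peak size is the retained-set size at the trajectory maximum
(largest size if tied). Trajectories typically rise to the peak and fall
after it; with missing data the rise can contain dips of order 10⁻⁴
(removing an accession changes denominators marker-by-marker), which is why
the tests assert monotonicity only up to that noise while the post-peak
decrease is strict. `select_minicore()` warns when the requested size is
below the peak: below it, every further exclusion discards diversity.
Group-restricted rankings simply re-run the procedure on one group's rows,
with frequencies computed within the group.

## Synthetic data generator

The generator emulates the structure of a genotyped inbred core collection
and is the substrate for every calibration test:

* **Map.** Seven chromosomes of 145, 181, 164, 130, 185, 139 and 169 cM
  (1,113 cM total, matching a barley consensus map's proportions); markers
  apportioned by length (largest remainder) and placed uniformly.
* **Structure.** Five subpopulations by default with pure-accession counts
  40/55/55/41/17 plus 164 admixed accessions — one fifth of a
  ~1,860-accession collection at the same proportions. Subpopulation allele
  frequencies follow the Balding–Nichols model
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` around an ancestral frequency drawn
  uniformly from (0.1, 0.5); F defaults to 0.15 for the four large
  subpopulations and 0.25 for the small, most diverged one. Admixed ancestry
  rows are symmetric Dirichlet(1.5), under which most admixed accessions
  have maximum membership below 0.8.
* **LD.** A first-order copy chain: with probability `exp(−d/λ)` (λ = 2 cM
  by default) a call copies the same accession's call at the previous
  marker. This produces distance-decaying r² at desk scale without
  coalescent machinery. It also attenuates *per-marker* differentiation
  (each marker's effective frequencies mix with its neighbor's), so
  calibration tests that compare Φ_PT to the generating F switch the chain
  off — their oracle is the plain Balding–Nichols draw.
* **Duplicates and missingness.** Duplicate sets are row copies made before
  missingness, which is then applied independently per copy at 2% — so
  duplicates are identical on co-observed calls but not bitwise-identical
  rows, like real re-genotyped material.
* **Phenotypes.** `y = Σ effect·call + ε`, missing calls mean-imputed for
  simulation, with ε scaled so the realized genetic-variance fraction
  equals the requested heritability; binary traits threshold at the median.

What the generator does **not** model: coalescent-accurate haplotype
structure, ascertainment bias of array SNP panels, genotyping error beyond
missingness, and inbreeding short of complete homozygosity. Passing tests
therefore demonstrate correctness and calibration of the algorithms under a
clean structured-population model, not robustness to array ascertainment or
partial heterozygosity in real collections.

## Problem sizes and calibration conditions

The acceptance checks run at fixed desk-scale sizes chosen once: duplicate
recovery on 20 simulations of 300 accessions × 2,000 markers; Φ_PT
calibration at F = 0.5 with 100 + 100 accessions × 500 independent markers;
permutation calibration on 1,000 null markers × 999 permutations with
100 + 100 accessions (smaller groups make the permutation null visibly
discrete and conservative); mini-core quality on 20 simulations of 300
accessions × 500 markers against 1,000 random subsets; GWAS power on 20
seeds of 500 accessions × 2,000 markers with three planted QTL scaled to
equal ≥10% variance shares, with genomic inflation assessed as the mean λ_GC
over five permuted-phenotype scans (a single scan's median-based λ on 2,000
LD-correlated markers varies by ±0.1 on its own); LD threshold calibration
on 10,000 fitted and 10,000 fresh unlinked pairs; and the
structure-corrected LD comparison on ten strongly diverged two-population
simulations (F = 0.5), because mild five-way structure produces no
measurable confounded association between unlinked markers — there would be
nothing for the principal components to remove.

## Pipeline

`run_pipeline()` executes simulate/load → QC → dedup → structure → Φ_PT →
LD → GWAS → mini-core from a single YAML config with all defaults filled by
`validate_config()` (unknown keys are rejected by name; violations are
reported together). Each stage derives its seed from the global seed by a
stable hash of the stage name, so inserting a stage never perturbs another
stage's randomness; every output file is a TSV recorded in a manifest with
its MD5 hash, and a rerun with the same config is byte-identical.

## Known limitations

* Φ_PT here is the one-level, binary-distance (haploid) form; hierarchical
  AMOVA and heterozygous genotypes are out of scope.
* The LD threshold's parametric percentile assumes the transformed null is
  near-normal; for very small panels (few hundred pairs) the empirical
  quantile is the safer choice.
* The P3D approximation holds variance components fixed across markers; for
  traits with very large single-QTL effects per-marker REML (provided) is
  more accurate.
* Mini-core ranking is greedy; it is exactly the stepwise-removal procedure,
  not a guaranteed global optimum over all subsets of a given size.
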