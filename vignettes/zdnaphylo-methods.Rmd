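---
title: "Methods: Z-DNA motif density and its phylogenetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-DNA motif density and its phylogenetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdnaphylo)
```

## The problem

Z-DNA is a left-handed double-helical conformation favoured by tracts of
alternating purine/pyrimidine sequence — (CG)n, (TG)n/(CA)n and similar
repeats. Such tracts are mutagenic hotspots and candidate regulatory
elements, and their genome-wide density varies strongly among species.
`zdnaphylo` provides the full computational chain needed to study that
variation comparatively:

1. detect Z-DNA-prone motifs and perfect short tandem repeats (STRs) in
   genome assemblies;
2. summarize them as per-species densities (motifs/Mb);
3. profile motif positions in the 10-kb windows upstream of start codons
   and test for positional enrichment;
4. model density evolution on a phylogeny (BM/OU/EB/Pagel's lambda),
   reconstruct ancestral densities, and regress densities on life-history
   traits with phylogenetic generalized least squares (PGLS).

Every stage can be exercised on synthetic genomes, annotations, trees and
traits with known ground truth, generated by the package itself.

## Motif definitions

**Z-DNA.** A Z-DNA-prone motif is a *maximal* tract in which every
adjacent base pair alternates purine (A/G) and pyrimidine (C/T), with
A–T adjacencies excluded by default (ApT/TpA steps have poor Z-forming
energetics) and with a minimum length of 10 nt. Maximality means the
tract cannot be extended in either direction and remain valid, so hits
never overlap. Any non-ACGT symbol (assembly gaps `N`; lowercase bases
when soft-masked scanning is disabled) terminates a tract. All
thresholds live in `scan_params()`:

| parameter | default | meaning |
|---|---|---|
| `zdna_min_len` | 10 nt | minimum Z-tract length |
| `zdna_allow_at_steps` | `FALSE` | permit A/T adjacencies |
| `str_unit_min`, `str_unit_max` | 2, 6 bp | primitive STR unit range |
| `str_min_copies` | 3 | minimum complete copies |
| `str_min_len` | 10 nt | minimum STR tract length |
| `include_softmasked` | `TRUE` | scan lowercase bases |

**STR.** A short tandem repeat is a maximal perfect tandem array of a
*primitive* unit (one that is not itself a repetition of a shorter
string) of 2–6 bp, with at least 3 full copies spanning at least 10 nt.
A partial trailing copy extends the reported tract but not the copy
count; the unit is reported in leftmost phase. The two scanners are
independent by design: a (TG)19 tract is both a Z-DNA motif and an STR,
and is reported by both, because the downstream analyses treat the two
densities as separate traits.

The defaults follow the conventions of the non-B DNA motif search tools
used in this field; since published descriptions do not pin down every
threshold, all of them are exposed and the scanners are validated not
against a tool but against brute-force oracles (every substring of every
sequence up to length 10, exhaustively, plus random 2-kb sequences).

## Densities and the upstream profile

Density is simply `count * 1e6 / genome_size_bp`, with the genome size
taken over all assembly symbols including `N` runs (an `ungapped` option
excludes them; the default matches the convention of dividing by total
assembly length).

For promoter analysis, each gene contributes a 10-kb window upstream of
its start codon (`start_codon` features, else the 5'-most CDS; for
multi-transcript genes the 5'-most start codon). A motif is assigned to
a gene when its *anchor* falls in the window. On the plus strand the
anchor is the motif stop. On the minus strand the published procedure
("the stop site ... within 10 kb upstream") is ambiguous: we default to
the *oriented* reading — the motif end nearest the gene in transcription
direction, i.e. the genomic start — and provide `convention = "genomic"`
for the literal reading; the two differ by at most one motif length.
Windows truncated at contig edges are kept without renormalization and
the affected genes are flagged. Distances are binned at 1 kb into k = 10
bins by default; both are configurable (`--window-kb`, `--bin-kb`). The
printed degrees of freedom in the motivating analysis imply one extra
region beyond the ten 1-kb bins, which is not defined in the text, so k
is left configurable rather than hard-coded at 11.

Counts per bin, summed over genes, give one row of the species × region
matrix. The test battery is:

* **Lilliefors** normality per region: `D = sup |F_n - Phi|` with
  estimated mean/sd, p-value from a seeded Monte-Carlo null at the same
  n (10,000 replicates by default). A Monte-Carlo reference is used
  because the classical KS distribution does not apply once parameters
  are estimated.
* **Friedman** test across regions with species as blocks, with the
  standard tie correction; p from the upper chi-squared tail with
  k − 1 df. At the study sizes (~150 blocks) the chi-squared reference
  is excellent; at toy sizes (4 blocks) it is known to deviate from the
  exact permutation null by more than 0.01, which is why the test suite
  validates the *statistic* through the exhaustive permutation
  distribution rather than asserting agreement of approximate and exact
  p-values.
* **Nemenyi** all-pairs comparisons:
  `q = |Rbar_i - Rbar_j| / sqrt(k(k+1)/(12n))` referred to the
  studentized range with infinite df (validated against numerical
  quadrature of the tail integral).

The top-5% gene selection ranks genes by upstream motif count, takes
`m = ceiling(0.05 G)` genes, and then includes every gene tied with the
m-th count — a tie-inclusive superset, so the exported list is never
smaller than 5% and every excluded gene is strictly below the threshold.

## Trait-evolution models

All comparative machinery is implemented from first principles on the
`phylo` edge matrix. With `C` the matrix of root-to-MRCA depths
(`bm_covariance()`), tip depths `t_i` and tree height `T`:

* **BM**: `V = C`.
* **Pagel's lambda**: off-diagonals scaled by `lambda` in [0, 1].
* **OU** (fixed root, ultrametric tree, attraction `alpha`):
  `V_ij = exp(-alpha (t_i + t_j - 2 t_a)) (1 - exp(-2 alpha t_a)) /
  (2 alpha)`, with `t_a` the MRCA depth. The non-stationary fixed-root
  form matches the default of the standard fitting tools; a stationary
  variant is deliberately not offered.
* **EB** (early burst, rate `exp(r t)`, `r <= 0`):
  `V_ij = (exp(r t_a) - 1) / r`, continuously extended to `t_a` at
  `r = 0` (computed with `expm1` for stability).

`fit_continuous()` profiles the root state and rate analytically
(`mu = (1'V^-1 x)/(1'V^-1 1)`, `sigma^2 = Q/n`) and optimizes the single
shape parameter by bounded scalar search restarted on 5 subintervals
(log scale for `alpha`). Bounds: `lambda` in [0, 1], `alpha` in
`(1e-8/T, 50/T]`, `r` in `[ln(1e-5)/T, 0]` — common practice, exposed as
arguments. AICc uses k = 2 (BM) or 3 parameters; ties below 1e-6 go to
the model with fewer parameters. A numerically constant trait returns a
documented degenerate boundary fit (`sigma2 = 0`, infinite likelihood)
rather than an optimizer failure.

Ancestral states under BM use the re-rooting construction: the estimate
at node v is the BM root-state MLE of the tree re-rooted at v, with the
re-rooted covariance assembled from patristic distances
(`C_v[i,j] = (d(v,i) + d(v,j) - d(i,j))/2`). This equals the GLS
conditional mean given the tips, which the test suite verifies against a
dense joint-covariance oracle on random trees.

## PGLS, bootstrap and the correlation call

`pgls_fit()` estimates `beta = (X'V^-1 X)^-1 X'V^-1 y` at each candidate
shape parameter via a Cholesky whitening and QR solve, maximizing the ML
profile likelihood over the shape. Standard errors use the unbiased
residual variance `RSS_gls/(n - p - 1)` with t-tests on `n - p - 1` df,
while AICc is ML-based; this reproduces conventional PGLS t-tests
alongside information-criterion selection. `R^2` compares the full
model's GLS residual sum of squares with the intercept-only model *at
the same fitted shape*; the adjusted version
`1 - (1 - R^2)(n-1)/(n-p-1)` can be negative. With `model = "auto"` the
BM, OU and lambda fits are compared by AICc per trait pair before
reporting, mirroring per-pair model selection.

The bootstrap is parametric — `y*` is simulated from the fitted model
(`X beta_hat` plus Gaussian noise with covariance
`sigma2_ML V(theta_hat)`) and the same model is refitted — matching the
bootstrap semantics of the standard phylogenetic regression tools.
Bootstrap refits use a slightly coarser 2-interval shape search, since
replicate estimates only feed quantile summaries. Two traits are called
correlated only when the slope p-value is below 0.05 *and* the adjusted
R² exceeds 0.1; the R² gate makes the rule conservative, and simulation
under the null (no slope, BM residuals, 100 species) shows a call rate
well below 5%.

Trait handling: durations can be mass-adjusted as residuals of
`log10(duration) ~ log10(mass)` (ordinary least squares) — the standard
allometric adjustment, chosen because the motivating analyses import
pre-adjusted durations without printing a formula; precomputed adjusted
traits can be supplied directly and bypass this step. Mass-like traits
are log10-transformed by the package's own default in the examples,
while densities (motifs/Mb) are used untransformed. Species lacking data
for a trait pair are pruned (with correct branch-length collapsing)
before fitting.

## Synthetic data: what it does and does not emulate

The generators provide machine-readable truth for every stage:

* `sim_genome()` draws an i.i.d. background at a chosen GC content
  (42% by default, a typical avian value), then — in `planted_only`
  mode — *scrubs* it by rejection: any tract the scanners would report
  is broken by re-drawing a base, iterating until the background is
  motif-free. Planted payloads (pure alternating dinucleotide tandems
  for Z-DNA; non-Z-forming units such as GAT/AAG for STR-only tracts)
  are inserted with guard bases chosen so tracts cannot extend into the
  background, and a verification scan confirms the emitted truth table
  is exactly what the scanners must report. Contigs are capped at 5 Mb
  in this mode; `oracle` mode skips scrubbing and defines truth as the
  scan of the emitted sequence.
* `sim_annotation()` writes UCSC-style GTF with `start_codon`/`CDS`
  features on both strands and can place a chosen motif into a chosen
  upstream distance bin of each gene.
* `sim_yule_tree()` is a pure-birth simulator: while k lineages exist
  the next split arrives at rate `k * birth_rate`; after the n-th tip
  the tree is extended by one further waiting time, giving expected
  height `sum_{k=2..n} 1/(k lambda)`. Pure birth is the simplest
  ultrametric generator; the tree input is pluggable everywhere.
* `sim_trait()`/`sim_regression_dataset()` draw from the exact model
  covariances via Cholesky factors.

Deliberately *not* emulated: isochore/GC heterogeneity, interspersed
repeats, assembly gaps (beyond optional N runs) and annotation errors.
Passing tests therefore demonstrate algorithmic correctness — that the
pipeline recovers what is truly in the sequence and the model — not that
any particular biological claim transfers to real genomes.

## Numerical choices and problem sizes

* Coordinates are 1-based inclusive in every serialized output
  (GTF/nBMST convention); interval arithmetic is done vectorized on
  encoded integer sequences.
* Covariance factorizations use Cholesky decompositions; OU terms are
  computed with `expm1` so the `alpha -> 0` limit is stable; trees are
  treated as ultrametric when the tip-depth spread is below 1e-6 of the
  height.
* Validation scales, chosen to make the simulation studies decisive
  while keeping a full run on a laptop CPU comfortable: exhaustive
  scanner equivalence over all sequences up to length 10 plus 1,000
  random 2-kb sequences; 12 planted genomes of 0.5 Mb; lambda and slope
  recovery on 200-tip Yule trees with 200 replicates; OU-vs-BM/EB
  identification on 100 replicates; decision-rule calibration on 1,000
  null datasets of 100 species. The acceptance script
  (`scripts/acceptance.R`) re-runs the same pipeline at moderately
  reduced replicate counts and records every quantity it computes.

## Known limitations

* The Z-DNA criterion is purely sequence-based; no energetic scoring
  (Z-Hunt-style) and no other non-B classes (G4, cruciform, triplex).
* OU fitting assumes an ultrametric tree and a fixed root; EB is
  offered for trait fits but not as a PGLS correlation structure.
* The Friedman/Nemenyi chi-squared and studentized-range references are
  asymptotic in the number of blocks; exact small-sample p-values are
  out of scope (the tests quantify this at toy sizes).
* Gene identifiers are taken at face value from one annotation; mapping
  across annotation sources is out of scope, and GO enrichment is left
  to external services consuming the exported gene list.
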