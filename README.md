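# zdnaphylo

Comparative genomics of Z-DNA-prone motifs: scan genomes for Z-DNA
tracts and short tandem repeats (STRs), turn counts into per-species
densities, profile motif positions upstream of start codons, and model
the evolution of those densities across a phylogeny.

**Who it is for.** Researchers asking how non-B DNA motif content varies
across a clade (the motivating use case is birds): does density carry
phylogenetic signal, which trait-evolution model explains it, what did
ancestral genomes look like, and is density correlated with life-history
traits once shared ancestry is accounted for?

## What it computes

* **Z-DNA motifs** — maximal tracts of alternating purine/pyrimidine
  sequence (A–T steps excluded), at least 10 nt by default. **STRs** —
  maximal perfect tandem arrays of a primitive 2–6 bp unit, ≥ 3 copies,
  ≥ 10 nt. Both serialized in an nBMST-style TSV.
* **Densities** — motifs per Mb, `count * 10^6 / genome size`.
* **Promoter profile** — counts per 1-kb bin in the 10-kb window
  upstream of each start codon; Lilliefors (Monte-Carlo), Friedman and
  Nemenyi tests across regions; tie-inclusive top-5% gene lists.
* **Phylogenetic comparative methods, from first principles** — BM, OU
  (fixed root), early-burst and Pagel's λ covariances; profiled ML
  fitting with AICc selection (`fitContinuous`-style); BM ancestral
  states via re-rooted GLS (`fastAnc`-style); PGLS with per-pair model
  selection, parametric bootstrap, and the decision rule
  *correlated ⇔ p < 0.05 and adjusted R² > 0.1* (`phylolm`-style).
* **Synthetic data** — seeded generators for genomes with planted
  motifs (exact truth tables), GTF annotations with controlled upstream
  placements, Yule trees, and traits drawn from the model covariances.

## Worked example

```r
library(zdnaphylo)

## 1. scan a sequence: a (TG)19 tract flanked by poly-A and poly-C,
##    followed by a (GAT)6 microsatellite
p <- scan_params()
pen <- paste0(strrep("A", 30), strrep("TG", 19), strrep("C", 30),
              strrep("GAT", 6))
rbind(scan_zdna(pen, "chr13", p), scan_str(pen, "chr13", p))
#>   seq_id start stop length motif_class unit copies
#> 1  chr13    31   69     39        ZDNA          NA
#> 2  chr13    31   68     38         STR   TG     19
#> 3  chr13    99  116     18         STR  GAT      6
```

The (TG)19 tract is reported by both scanners (the classes are analyzed
as separate traits); the Z-DNA tract runs one base further because the
final G→C step still alternates, while the poly-A flank cannot extend it
(A–T steps are excluded and G→A does not alternate).

```r
## 2. model density evolution on a 12-species tree
tr <- sim_yule_tree(12, 1, seed = 42, tip_prefix = "sp")
x  <- sim_trait(tr, "OU", sigma2 = 900, mu = 150, shape = 3, seed = 43)
best <- select_model(lapply(c("BM", "OU", "EB"),
                            function(m) fit_continuous(tr, x, m)))
best
#> Trait-evolution fit: OU model, n = 12 tips
#>   sigma2 = 6665.77, root state = 145.803
#>   shape parameter = 25.2219
#>   logLik = -46.3305, k = 3, AICc = 101.6611

## 3. regress a trait on density with PGLS (+ model selection)
d <- sim_regression_dataset(tr, beta = c(120, 6), model = "BM",
                            sigma2 = 25, seed = 44)
X <- cbind(intercept = 1, log_mass = d$x); rownames(X) <- names(d$x)
pgls_fit(tr, d$y, X, model = "auto")
#> PGLS fit (BM model), n = 12, predictors = 1
#>        term estimate std_error t_value    p_value
#> 1 intercept 122.7811    4.4499 27.5919 9.0637e-11
#> 2  log_mass   7.4761    2.1241  3.5197 5.5412e-03
#>   R2 = 0.55334, adj R2 = 0.50867, logLik = -40.8676, AICc = 90.7353
#>   correlated (p < 0.05 & adj R2 > 0.1): TRUE
```

The AICc-selected OU fit recovers an attraction parameter of the right
order (true α = 3 on a tree of height ≈ 2 is hard to pin down at 12
tips — the printed 25.2 illustrates why the package validates parameter
recovery at 200 tips), and the PGLS slope estimate 7.48 ± 2.12 covers
the simulated slope of 6 with a positive correlation call.

## Command line

A launcher script is installed at `inst/cli/zdnaphylo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/zdnaphylo.R", package="zdnaphylo"))')" \
    scan --fasta genome.fa --out out_scan
```

Subcommands: `scan`, `density`, `promoter`, `phylosignal`, `pgls`,
`simulate`, `report`. Every output directory receives a `manifest.json`
with resolved parameters, input checksums, the seed and the tool
version; all randomness flows from one `--seed`.

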