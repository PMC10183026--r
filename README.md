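# eamlr

Gene-level case-control analysis of coding-variant deleteriousness, for
exome studies of complex disease — including cohorts too small for
conventional genome-wide association, such as sex-separated strata.

Instead of counting rare alleles, each gene's coding variation in each
individual is collapsed into the *EA probability*

$$pEA = 1 - \prod_{j=1}^{k}\bigl(1 - EA_j/100\bigr)^{zygo_j},$$

where $EA_j \in [0, 100]$ is the precomputed Evolutionary Action
deleteriousness score of variant $j$ and $zygo_j$ is 1 (heterozygous) or
2 (homozygous/hemizygous).  Silent-only genotypes score 0; stop/frameshift
carriers score 1.  Six features per gene cross dominant/recessive
inheritance with EA thresholds {1, 30, 70}.  Every gene is then scored
independently by the mean Matthews correlation coefficient (MCC) of nine
classifiers under stratified 10-fold cross-validation, with permutation
or parametric p-values and Benjamini–Hochberg FDR ($q < 0.01$).

Around that core the package provides:

* a stacked risk classifier (random forest + ridge logistic + AdaBoost,
  decision-tree meta learner) versus an APOE-genotype + age baseline,
  compared by t-test on per-fold ROC AUCs;
* a down-sampling robustness harness (top-K overlap with hypergeometric
  p-values, Kendall tau) that also accepts external rankings;
* network diffusion (random walk with restart) of candidate gene sets,
  scored against degree-matched random sets by prioritization AUC and
  z-score;
* an analytic single-variant GWAS power comparator;
* a fully seeded synthetic exome-cohort simulator with planted
  (optionally sex-specific) risk genes, so the whole pipeline is testable
  without access-controlled data.

See `vignettes/eaml-methods.Rmd` for the models, assumptions and design
choices.

## Worked example

Simulate a 250/250 case-control cohort with three planted dominant risk
genes (carrier odds ratio 3, carrier frequency 0.1), then rank all genes:

```r
library(eamlr)

cfg <- simConfig(n_genes = 100, n_cases = 250, n_controls = 250,
                 planted = plantedGenes(3, beta = log(3),
                                        carrier_freq = 0.1))
cohort <- simulateCohort(cfg, seed = 42)
cohort
#> EamlCohort: 500 samples ( 250 cases / 250 controls ), 33501 variant
#> records over 104 genes

rk <- eamlRank(cohort, cv = cvConfig(k = 10, seed = 42),
               method = "parametric")
head(rk[, c("gene", "mean_mcc", "p", "q", "rank", "n_carriers")])
#>     gene   mean_mcc            p           q rank n_carriers
#> 1 RISK01 0.22137831 9.536188e-05 0.009822274    1         72
#> 2   APOE 0.15045726 5.610669e-03 0.288949437    2        201
#> 3 RISK03 0.12198325 1.989882e-02 0.683192757    3        102
#> 4  G0063 0.09798415 4.933105e-02 0.833478031    4        215
#> 5  G0099 0.09652520 5.189126e-02 0.833478031    5        367
#> 6  G0057 0.08925510 6.625726e-02 0.833478031    6        406
attr(rk, "significant")
#> [1] "RISK01"
```

Two planted genes and the APOE-like covariate gene head the ranking:
`mean_mcc` is each gene's cross-validated case/control discrimination
averaged over the nine classifiers, `q` the BH-adjusted p-value from the
robust genome-wide z mode, and `n_carriers` the number of samples with
any qualifying variant.  At this modest sample size one of the three
planted genes clears the stringent $q < 0.01$ line — exactly the regime
in which conventional single-variant association is powerless:

```r
assocPower(powerParams(n_cases = 250, n_controls = 250))
#> [1] 0.002565807   # i.e. ~0 power at alpha = 5e-6
```

A command-line front end over the same functions is installed as
`exec/eaml` (subcommands `rank`, `risk`, `downsample`, `diffuse`,
`power`, `simulate`).

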