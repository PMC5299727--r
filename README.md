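# DMVarSel

Bayesian variable selection for Dirichlet-Multinomial (DM) regression of
microbiome count tables on sample-level covariates.

Given an $n \times J$ taxa abundance table $\mathbf{Y}$ and an
$n \times P$ covariate matrix $\mathbf{X}$, the package models
$\mathbf{y}_i \sim \mathrm{DM}(\boldsymbol\gamma_i)$ with the log-linear
link

$$\log \gamma_{ij} = \alpha_j + \sum_{p=1}^{P} \beta_{pj} x_{ip},$$

and places spike-and-slab priors on the coefficients,

$$\beta_{pj} \mid \xi_{pj} \sim \xi_{pj}\,\mathcal{N}(0, r^2) +
(1-\xi_{pj})\,\delta_0, \qquad \xi_{pj} \sim \mathrm{Bernoulli}(m),$$

where $m = a/(a+b)$ arises from a Beta$(a,b)$ hyperprior integrated out
analytically. A stochastic-search Metropolis-within-Gibbs sampler
(compiled inner loop with incremental likelihood updates and
component-wise adaptive proposals) explores the $2^{P \times J}$ model
space; associations are selected from the marginal posterior probabilities
of inclusion (PPIs) by the median probability model (PPI > 0.5) or by
thresholding the estimated Bayesian false discovery rate
$\widehat{\mathrm{FDR}}(c) = \sum (1-\mathrm{PPI})\,D / \sum D$.

The DM likelihood handles the two defining nuisances of microbiome counts
— compositionality and overdispersion (variance inflation by
$(y_+ + \gamma_+)/(1+\gamma_+)$) — while the sparse prior controls
multiplicity across all taxa-covariate pairs jointly. Intended users:
statisticians and computational biologists associating taxa abundances
with clinical, dietary or functional-pathway covariates.

The package also ships the overdispersed benchmark generator
(`simulateDMData()`), selection-performance metrics (accuracy, FPR, FNR,
Matthews correlation, ROC/AUC), preprocessing for real tables (prevalence
filter, correlation-clustering covariate reduction, standardization), TSV
/ JSON I/O, and a thin command-line front end
(`inst/scripts/dmvarsel`, subcommands
`simulate | preprocess | fit | select | score`).

## Worked example

Simulate the benchmark scenario (100 samples, 50 taxa, 50 covariates, 25
true associations, overdispersion $\psi = 0.01$), fit, and score the
median-model selection against the generating truth:

```r
library(DMVarSel)

sim   <- simulateDMData(seed = 2)                 # data + ground truth
dat   <- standardizeCovariates(sim$data)
chain <- fitDMRegression(dat,
           hyper   = DMHyperParams(),             # r2 = s2 = 10, m = 0.01
           control = DMSamplerControl(nIterations = 5000, thin = 5,
                                      seed = 1002))
chain
#> DMChain: 1000 stored draws (thin 5), P = 50 covariates x J = 50 taxa
#>   model size: median 22 [15, 28]
#>   acceptance: alpha 0.239, add 0.000848, delete 0.0949

ppi <- computePPI(chain)                          # burn-in: first half
scoreSelection(medianModel(ppi), sim$truth@xiTrue, ppi)
#>   granularity   ACC FPR FNR       MCC       AUC
#> 1     overall 0.998   0 0.2 0.8935251 0.9726869
#> 2        taxa 0.980   0 0.2 0.8846517        NA
```

This replicate recovers 20 of the 25 planted associations with zero false
positives among the 2,475 null pairs (FPR = 0, overall MCC 0.89, AUC
0.97). The five misses all belong to one rare relevant taxon whose counts
barely inform its coefficients — the typical failure mode; replicates
without such a taxon recover everything, which is why FNR is the most
variable number across replicates. Selections, PPIs and coefficient
summaries are exported with `selectAssociations()` / `selectionTable()`,
and `convergenceSummary()` reports Geweke diagnostics for the model-size
and coefficient traces.

For real data, the typical pipeline is

```r
x <- readDMExperiment("counts.tsv", "covariates.tsv")
x <- filterPrevalence(x, 0.05)
x <- decorrelateCovariates(x, cut = 0.5)$data
x <- standardizeCovariates(x)
chain <- fitDMRegression(x)          # 10,000 iterations, thin 5
sel   <- selectAssociations(chain, method = "fdr", alphaLevel = 0.1)
```

See `vignettes/dm-variable-selection.Rmd` for the model, the sampler, the
generator's assumptions and the package's design choices.

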