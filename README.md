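# errmix

Model-based clustering for observations measured with *known*,
*observation-specific* error covariances.

## The problem

Clustering is routinely applied to summary statistics — per-gene
log-fold-change estimates from RNA-seq regressions, per-site or per-subject
effect estimates — and each such point comes with an estimation-error
covariance that can often be computed (for maximum-likelihood estimates, by
inverting the observed information matrix). Those covariances typically vary
by orders of magnitude across observations, yet a standard Gaussian mixture
ignores them: two genes with identical log fold changes always land in the
same cluster, however noisy their estimates. For differential-expression
style questions that is clearly wrong — a moderate fold change with a tiny
standard error means something different from the same fold change with a
huge one.

## The model

errmix fits a G-component Gaussian finite mixture in which every
observation's known error covariance Λᵢ adds to the component covariance:

    yᵢ = wᵢ + εᵢ,   wᵢ | k ~ N_d(μₖ, Σₖ),   εᵢ ~ N_d(0, Λᵢ)
    ⇒  yᵢ | k ~ N_d(μₖ, Σₖ + Λᵢ)

with mixing proportions τₖ and unconstrained component covariances. Fitting
is by EM: the E step computes membership probabilities
zᵢₖ ∝ τₖ N_d(yᵢ; μₖ, Σₖ + Λᵢ); the M step has a closed form for τₖ, profiles
μₖ out as a precision-weighted mean, and optimizes each Σₖ numerically
(L-BFGS-B on a log-diagonal Cholesky parameterization, with the analytic
profile gradient). Because the decision boundary between two clusters
depends on Λ, every distinct error covariance has its own boundary — points
with equal coordinates but different uncertainties can be clustered
differently, and classification uncertainty properly grows with Λᵢ.

Alongside the core fit the package provides the error-free mixture baseline
(`gmm_fit()`, the Λ ≡ 0 reduction through the same EM loop), the
precision-weighted k-means comparator (`kerror_fit()`), BIC model selection
(`bic_scan()`), two-group decision-boundary extraction
(`decision_boundary()`, `conic_coefficients()`), partition-agreement
statistics with permutation tests (`adjusted_rand_index()`,
`ari_permutation_test()`, `paired_ari_test()`), and seeded simulation
designs with ground truth (`sim_bernoulli_errors()`, `sim_uniform_errors()`,
`sim_error_sweep()`). Fits are tibble-friendly: `tidy()`, `glance()`,
`augment()`, and `autoplot()` methods are provided, and a thin command-line
wrapper (`inst/cli/errmix.R`, subcommands `fit`, `simulate`, `evaluate`,
`bic-scan`, `boundary`, `kerror`) covers scripted use.

## Worked example

```r
library(errmix)

sim <- sim_bernoulli_errors(n = 300, eta = 0.5, seed = 7)   # half the points carry Λ = 36·I
fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
glance(fit)
#>   method     G     n     d logLik    df    BIC n_iter converged
#> 1 errmix     2   300     2 -2040.    11 -4143.     67 TRUE

tidy(fit)
#>   component weight  mu_1    mu_2 sigma_1_1 sigma_1_2 sigma_2_2
#> 1         1  0.341 -1.64 -0.0860      72.8    -22.4       58.2
#> 2         2  0.659  7.55 -0.350       18.6      3.14      17.4

fit0 <- gmm_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
c(errmix = adjusted_rand_index(sim$truth$label, fit$hard_labels),
  gmm    = adjusted_rand_index(sim$truth$label, fit0$hard_labels))
#>    errmix       gmm
#> 0.2804951 0.1966749

label_crosstab(fit0, fit)$n_disagree
#> [1] 53
```

The generator plants two overlapping components (means 8 units apart,
covariances 64·I and 16·I) and attaches the error covariance to a random
half of the points. Modelling the errors recovers a noticeably better
partition (adjusted Rand index 0.28 vs 0.20 against the ground truth), and
the two methods assign 53 of 300 points differently — mostly points near
the boundary whose error covariances pull their memberships toward the
mixing weights. `autoplot(fit, boundaries = TRUE)` draws the two decision
boundaries (one per distinct error covariance) with points sized by
classification uncertainty.

The methods vignette (`vignettes/error-aware-clustering.Rmd`) documents the
model, the numerical choices, what the simulation designs do and do not
emulate, and known limitations.

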