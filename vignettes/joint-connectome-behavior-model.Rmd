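---
title: "A joint latent-space model of brain connectomes and behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint latent-space model of brain connectomes and behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(latentconn)
library(dplyr)
```

## The model

`latentconn` fits a joint Bayesian generative model that links a subject's
functional connectome to a latent behavioural construct. For subject
$j = 1, \dots, N$ with a symmetric $V \times V$ Fisher-z connectivity
matrix $C_j$ and $P$ behavioural indicators $b_{j,1}, \dots, b_{j,P}$
(all indicators of one unidimensional category, e.g. a sociability or
negative-emotion battery):

$$
c_{x,y,j} = d_j + \gamma_{x,j}\,\gamma_{y,j} + f_{x,y,j},
\qquad f_{x,y,j} \sim \mathrm{N}(0, \tau^2), \quad x < y,
$$

$$
b_{j,p} = e_p + \kappa_j + v_{j,p},
\qquad v_{j,p} \sim \mathrm{N}(0, \sigma^2),
$$

$$
(\gamma_{1,j}, \dots, \gamma_{V,j}, \kappa_j)^\top
  \;\overset{iid}{\sim}\; \mathrm{MVN}\big((m, 0)^\top,\ \Sigma\big).
$$

Each node has a scalar latent position $\gamma_{x,j}$; expected edge
weights are the pairwise products of positions (a rank-1 eigenmodel), on
top of a per-subject intercept $d_j$. All indicators of the category load
with unit weight on a single latent score $\kappa_j$ with per-indicator
intercepts $e_p$. The $(V{+}1) \times (V{+}1)$ covariance $\Sigma$ couples
the node positions to the behaviour score; its last column,
$\Sigma[x, V{+}1]$, is the **node-behaviour covariance** — the per-node
biomarker strength the package reports, with positive and negative values
marking nodes whose latent involvement tracks the behaviour in opposite
directions.

### The latent mean pattern

The latent prior carries an estimated mean pattern $m$ (length $V$) for
the node positions; the mean of $\kappa$ is fixed at 0 so that behaviour
means live in the $e_p$ intercepts. This term represents the population
connectivity backbone: the component of latent structure that all
subjects share, from which individual subjects deviate. It is not
optional decoration; it is what makes the model identified enough to
predict:

* The edge likelihood only sees products $\gamma_x \gamma_y$, so it is
  exactly invariant under $\gamma_j \to -\gamma_j$ for any single subject.
  Under a zero-mean latent prior, a subject whose behaviour is missing has
  an exactly symmetric posterior under the joint reflection
  $(\gamma_j, \kappa_j) \to -(\gamma_j, \kappa_j)$; a correctly mixing
  sampler would then average its predicted score to zero, and no method
  could do better (the information is simply absent: under a zero-mean
  generator the third moment
  $\mathrm{E}[\gamma_x \gamma_y \kappa]$ vanishes, so edges carry no
  linear behavioural signal at all). A nonzero backbone breaks the
  symmetry: the reflected configuration $-\gamma_j \approx -(m + \delta_j)$
  is far from the prior mean and becomes improbable, so each subject's
  orientation — and with it the transductive prediction — is identified.
* Fitting a zero-mean model to data that does have a backbone forces
  $\Sigma$ to absorb $m m^\top$, and a weakly identified shift direction
  between the $e_p$ intercepts and the $\kappa$ mean then leaks
  $m \cdot \overline{\kappa}$ into the reported cross-covariances. With
  the mean estimated and $\Sigma$ formed from centred latent rows, that
  leak disappears.

With centred data (no backbone) the posterior of $m$ concentrates at
zero and the model reduces to the plain zero-mean form.

### Priors

All priors are weakly informative and conjugate, so the sampler is pure
Gibbs: $d_j \sim \mathrm{N}(0, 100)$, $e_p \sim \mathrm{N}(0, 100)$,
$m_x \sim \mathrm{N}(0, 100)$, $\tau^2, \sigma^2 \sim
\mathrm{InvGamma}(2, 1)$ (prior mean 1), and $\Sigma \sim
\mathrm{InvWishart}(V + 3, I_{V+1})$ (prior mean $I$). These are set in
`prior_spec()` and can be changed there.

## The sampler

`gibbs_sweep()` performs one blocked sweep:

1. Each node column of $\Gamma$ from its exact Gaussian conditional (the
   rank-1 term is bilinear, so fixing all other columns makes the
   conditional Gaussian), vectorized over subjects.
2. A per-subject sign-flip Metropolis proposal $\gamma_j \to -\gamma_j$,
   accepted by the latent prior ratio (the edge likelihood is
   sign-invariant). With the backbone estimated this is an ordinary
   mode-hopping move that rescues subjects from a misaligned orientation.
3. $\kappa_j$ from its Gaussian conditional. Subjects whose behaviour
   row is entirely missing draw from the $\Gamma$-conditional alone —
   this is the transductive prediction mechanism.
4. Conjugate draws for $d$, $e$; then an interweaving recentering step
   that samples the near-flat direction $(\kappa + c,\ e - c)$ from its
   exact Gaussian conditional (the behaviour likelihood sees only
   $e_p + \kappa_j$, and without this step that direction mixes very
   slowly).
5. The latent mean $m$ (conjugate MVN), $\tau^2$ and $\sigma^2$
   (conjugate inverse-gamma), and $\Sigma$ (conjugate inverse-Wishart on
   the centred latent rows).

Every conditional has been validated with a Geweke joint-distribution
check (`geweke_check()`): the marginal-conditional sampler (exact prior
and likelihood draws) and the successive-conditional sampler (data draw
then one Gibbs sweep) must produce the same joint distribution, compared
on variance-stabilised functionals ($\log\tau^2$, $\log\sigma^2$, the
latent cross-correlation) because the raw inverse-gamma and
inverse-Wishart priors have heavy tails. The `z` statistics stay well
inside $\pm 4$ at $2 \times 10^4$ draws.

### Initialization, restarts and residual non-identifiability

Chains start from a spectral initialization: each subject's rank-1 eigen
fit of $C_j$, with subject signs aligned iteratively to the sample mean
pattern. A global reflection (all subjects and the cross block together)
remains an exact symmetry class; retained draws are sign-aligned to a
common orientation (as in mixture relabeling), and the reported vector is
oriented so that the summed covariance over its highest-magnitude decile
is non-negative. The posterior also has occasional locally stable but
inferior modes, so the standard fitting protocol (`latentsna()`) runs
`n_inits` restarts from jittered starting points and keeps the chain with
the highest mean retained log posterior; `fit_predict()` instead scores
restarts by predictive correlation in the test sample, reproducing the
protocol of choosing the best of ten random initializations by test-set
fit (an "honest" `selection = "logpost"` mode that never touches test
behaviour is available behind a flag).

### Convergence diagnostics

`gelman_rubin()` implements the standard potential-scale-reduction
statistic over parallel chains; single runs report the split-chain
variant per parameter, and `latentsna()` adds cross-restart diagnostics
after orientation alignment. Well-mixed runs in the package's validation
suite have mean $\widehat{R} < 1.05$.

## The synthetic-data generator

`simulate_dataset()` runs the generative equations forward under a
`simulation_design()`: planted biomarker nodes receive a chosen
cross-covariance with $\kappa$ (all other cross entries 0; node-node
off-diagonals of $\Sigma$ are 0), noise variances, intercept spreads and
a backbone scale. The defaults are the package's standard validation
conditions: $V = 30$ nodes, $N = 150$ subjects, $P = 4$ indicators,
$\tau^2 = \sigma^2 = 0.5$, 10 biomarker nodes with cross-covariance 0.3,
and `mu_scale = 1` for the backbone. The backbone scale was chosen once
on realism grounds — real Fisher-z connectomes have a strong shared
positive/negative structure whose per-edge means are comparable to the
inter-subject variation, which corresponds to per-node latent means of
about one latent standard deviation — and recovery quality is
essentially identical between `mu_scale` 0.5 and 1.

`simulate_conditions()` emulates a multi-condition scanning study: one
shared behaviour draw and one shared backbone, with each condition's
latent deviations drawn from its own conditional distribution given the
shared $\kappa$, so conditions differ only in how much behavioural signal
their connectomes carry.

`theoretical_ceiling()` gives the closed-form maximum correlation
between any connectome-based predictor and one behavioural indicator in
the noiseless-connectome limit,
$\sqrt{\Sigma_{\kappa\gamma} \Sigma_{\gamma\gamma}^{-1}
\Sigma_{\gamma\kappa}} \big/ \sqrt{\Sigma_{\kappa\kappa} + \sigma^2}$
(unchanged by the backbone, which shifts only the latent mean). It is the
oracle against which the prediction pipeline is checked.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring parcels, heavy-tailed motion artefacts, site effects,
non-Gaussian behavioural scales, and diagnosis-structured heterogeneity.
Passing the package's tests therefore demonstrates internal correctness
of the machinery under its own generative assumptions, not performance on
any particular real dataset.

## The comparative pipeline

A study-style analysis runs as:

```{r pipeline, eval = FALSE}
designs <- list(
  Rest = simulation_design(V = 20, N = 120, P = 3, biomarker_nodes = 1:10,
                           cross_cov = 0.27, condition = "Rest", seed = 1),
  Task = simulation_design(V = 20, N = 120, P = 3, biomarker_nodes = 1:10,
                           cross_cov = 0.12, condition = "Task", seed = 1))
multi <- simulate_conditions(designs, seed = 11)

cmp <- compare_conditions(multi$connectomes, multi$behavior,
                          n_repeats = 5,
                          config = mcmc_config(n_burn = 300, n_samples = 500,
                                               n_inits = 1, seed = 21),
                          category = "Demo")

fit_condition_regression(cmp$accuracy, "Demo", reference = "Rest")

covs <- average_covariances(cmp$cv$Rest$covariances)
sel <- select_top_nodes(covs)
count_by_system(sel, synthetic_atlas(20))
```

* **Splits.** `make_split()` draws 90/10 train/test partitions
  (`round(0.9 N)` training subjects, half-up); repeated cross-validation
  uses independent random splits with seeds `base + repeat`, following
  the protocol of repeating the split-and-fit steps rather than
  partitioned folds. All conditions and all baselines see identical
  partitions.
* **Transductive fitting.** Connectomes of *all* subjects enter the fit;
  test subjects' behaviour is masked to missing, and their scores are
  predicted as the posterior mean of $e_p + \kappa_j$.
* **Accuracy** is the Pearson correlation between predicted and observed
  scores in the test sample; constant vectors yield an undefined-accuracy
  flag (`NA`) that is excluded from averages.
* **Condition regression.** `fit_condition_regression()` regresses
  per-indicator, per-repeat accuracy on condition dummies; with dummies
  only, coefficients are exactly the condition-minus-reference mean
  accuracies. Observations are pooled over indicators and repeats within
  a category; $R^2$ is defined as 0 when the total sum of squares is 0.
* **Biomarkers.** Per-fold node covariances are averaged
  (`average_covariances()`), the top 10 positive and top 10 negative
  nodes selected (`select_top_nodes()`; ties broken by lower node index,
  zeros belong to neither list, fewer than 10 strictly-signed entries
  yield a shorter list), mapped to functional systems
  (`count_by_system()`, all systems reported including zero counts), and
  profiled as edge highlights among the top-5 signed node groups
  (`top_edges()`). Descriptions of circle-plot displays alternately call
  their elements nodes or edges; the implementation selects node groups
  and reports the within-group edges, which covers both readings.
* **Baselines.** `cpm_train()`/`cpm_crossval()` implement connectome-based
  predictive modelling: row-wise upper-triangle-with-diagonal edge
  vectorization, per-edge correlation screening at p < 0.001 (p-values
  from the t transform of the correlation), sign-split strength sums, and
  a linear fit on the two strengths (single-strength fallback when one
  set is empty; a combined-difference mode is available).
  `ridge_baseline()` wraps an L2-penalized fit with the penalty chosen by
  internal cross-validation on the training set only. Structurally
  constant features (the zero diagonal) are dropped from screening with a
  warning.

## Numerical choices and degenerate inputs

* SPD checks accept a smallest eigenvalue down to $-10^{-8}$ times the
  largest, and a $10^{-8}$ ridge is added before Cholesky factorization.
* `build_sigma()` rejects cross-covariances beyond the SPD bound
  $\sqrt{\sigma_\gamma^2 \sigma_\kappa^2 / n_{\text{biomarkers}}}$ with
  the bound printed in the error.
* The sampler aborts with the iteration index if any monitored quantity
  becomes non-finite.
* Thinning defaults to 1; traces are stored in memory.
* All randomized steps take explicit seeds and are byte-reproducible.

## Problem sizes used in validation

The validation suite and the acceptance script run entirely on synthetic
data at desk scale, chosen so the full pipeline exercises every stage:
recovery at $V = 30$, $N = 150$, $P = 4$ with 1000 burn-in + 2000
retained sweeps and two restarts per fit; the comparative experiments at
$V = 20$, $N = 120$--$200$ with 300--400 burn-in + 500--600 retained
sweeps; the Geweke check at $V = 4$, $N = 8$ with $2\times10^4$ draws.
The protocol defaults in `mcmc_config()` (5000 burn-in, 15,000 samples,
10 restarts) match the full-study settings and are what an analysis of a
real cohort would use.

## Known limitations

* With few indicators (small $P$) the split of behavioural variance
  between $\kappa$ and $\sigma^2$ is weakly identified; at
  $N \approx 100$, $P = 3$ the posterior for $\sigma^2$ can sit tens of
  percent above the generating value while $\tau^2$ and the covariance
  ranking remain accurate. More indicators or larger cohorts tighten it.
* The latent space is one-dimensional by design; connectomes with strong
  multi-factor structure are summarized only through their leading
  rank-1 component plus noise.
* Selection of restarts by test-sample fit reproduces the stated
  protocol but has a leakage flavour; use `selection = "logpost"` for a
  strictly honest variant.
* The averaged condition violates the rank-1 generative form (a mean of
  rank-1 matrices is generally rank-2), which is precisely why its
  predictive accuracy drops — the same mechanism the comparative study
  reports on real data.
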