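---
title: "Models and methods: phylogenetic coevolution of religious and political authority"
author: "coevauth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coevauth)
```

# The scientific problem

Across societies, religious authority (a right to manage relations between
people and supernatural agents) and political authority (a right to manage
relations among people) are plainly intertwined, but how the two institutions
have shaped each other over millennia is contested. The tractable setting is a
sample of related societies — here, Austronesian-speaking societies whose
genealogy is approximated by a time-scaled language phylogeny — with each
society scored on two four-level ordinal scales (0 absent, 1 sublocal, 2
local, 3 supralocal) plus a four-state classification of how the two forms of
authority are structured (0 none, 1 combined in one office, 2 partly
independent, 3 independent).

`coevauth` implements the three analyses such data support, plus a
synthetic-data generator that reproduces their statistical structure so the
entire pipeline is testable without any external download:

1. a **bivariate ordinal phylogenetic mixed model** estimating per-trait
   phylogenetic signal and the phylogenetic and residual correlations between
   the two authority traits (`fit_signal_model`);
2. a **dynamic coevolutionary model** in which each trait is a latent
   continuous variable evolving under a bivariate Ornstein–Uhlenbeck (OU)
   process with cross-trait selection, observed ordinally, with a spatial
   Gaussian-process control (`fit_coevolution`);
3. **constrained four-state Markov models** of the authority-structure trait,
   compared by stepping-stone marginal likelihoods and Bayes factors
   (`fit_multistate_mcmc`, `stepping_stone_logml`, `compare_models`).

# Model 1: signal and correlation on the liability scale

Each trait \(d\) has a latent liability per society,
\[
z_d = a_d + e_d,\qquad
(a_1, a_2) \sim N\!\big(0,\; B \otimes C\big),\qquad
(e_{1i}, e_{2i}) \sim N\!\big(0,\; R\big)\ \text{iid over societies},
\]
where \(C\) is the tree's Brownian covariance normalized by its largest
diagonal entry (so all quantities are invariant to a common rescaling of
branch lengths), \(B\) is a 2×2 between-trait covariance built from per-trait
phylogenetic variances \(\sigma_d^2\) and the phylogenetic correlation
\(\rho_{phylo}\), and \(R\) has unit variances and residual correlation
\(\rho_{resid}\). The observed level is \(y_d = k\) iff
\(c_{d,k} < z_d \le c_{d,k+1}\) for ordered cutpoints \(c_d\) (probit link; a
logit-style analysis can be emulated by rescaling, but probit is used
throughout for coherence with the coevolution model). Phylogenetic signal is
the liability-scale variance partition
\[
\lambda_d = \frac{\sigma_d^2}{\sigma_d^2 + 1},
\]
not a branch-length (Pagel) transform: this matches the "proportion of
variance captured by phylogeny" reading and keeps the bivariate model
coherent.

Priors are generic and weakly regularizing: half-normal(0, 1) on the
phylogenetic SDs, LKJ(2) on both correlations, and N(0, 2) on cutpoints.
Posterior draws are pooled over trees drawn at random from the supplied
posterior sample (10 at desk scale, 100 at paper scale).

**Sampler.** In the eigenbasis of \(C\) both the marginal liability
likelihood and the conditional of the phylogenetic effects factor into
independent 2×2 problems, so all parameter updates cost O(n): the
variance/correlation block moves by adaptive random-walk Metropolis against
the liability marginal (with the phylogenetic effects then redrawn exactly,
i.e. a collapsed update), liabilities and cutpoints have truncated-normal
full conditionals, and two per-trait "ridge" moves (a joint rescaling of
liabilities, effects, cutpoints and SD; a joint translation) traverse the
stiff cutpoint-scale direction of the posterior. Convergence is summarized by
split R-hat (threshold 1.05 for this model) and autocorrelation-based ESS.

**What iid (star-tree) data can and cannot show.** When \(C = I\) the
likelihood is exactly constant along the ridge that trades \(\sigma^2\)
against the cutpoint scale, so the posterior of \(\lambda\) there is
determined by the priors and the cutpoint volume factor, not by the data; an
exact importance-sampling oracle in the test suite puts its median near 0.46
at n = 120. A posterior median of \(\lambda\) near zero should therefore not
be expected on structureless data under weakly regularizing priors — the
informative statements are the HPDI reaching 0 and the contrast with data
simulated with genuine signal, both of which the test suite checks.

# Model 2: dynamic coevolution

The pair of latent authority levels \(\eta(t) \in \mathbb{R}^2\) follows the
OU stochastic differential equation
\[
d\eta = (A\eta + b)\,dt + S\,dW,
\]
with strictly negative diagonal \(A_{dd}\) (autoregressive selection toward
the equilibrium), off-diagonal \(A_{de}\) (cross-trait selection: the
influence of trait \(e\) on trait \(d\)'s equilibrium), drift intercept
\(b\), and diffusion \(S\). Along a branch of length \(t\),
\[
\eta_{child} \mid \eta_{parent} \sim N\!\big(M\eta_{parent} + m,\; V\big),
\quad M = e^{At},\ m = A^{-1}(M - I)b,\
\mathrm{vec}(V) = (A \oplus A)^{-1}\big(e^{(A\oplus A)t} - I\big)\mathrm{vec}(SS^\top),
\]
(`ou_transition`); the root is drawn from the stationary law with
\(\theta^* = -A^{-1}b\) and \(V_\infty\) solving
\(A V + V A^\top + SS^\top = 0\) (`stationary_moments`). Because the root is
stationary, every node is marginally stationary and the joint tip covariance
has closed form \( \mathrm{Cov}(\eta_i, \eta_j) = e^{A t_i} V_\infty
e^{A^\top t_j}\) with \(t_i, t_j\) the times back to the pair's MRCA — the
exact marginalization of all internal nodes. For 2×2 systems all matrix
exponentials use the closed form \(e^{At} = \alpha(t) I + \beta(t) A\), which
remains exact for defective (repeated-eigenvalue) selection matrices such as
the recovery truth below.

Tip liabilities add a spatial Gaussian process per trait (squared-exponential
kernel on great-circle km, haversine distances on the IUGG mean radius
6371.0088 km) to control for spatial proximity — amplitude 0 switches it off
— and are thresholded with unit probit noise at cutpoints whose middle value
is anchored at 0.

**Identifiability anchoring.** The latent scale and location are fixed by
\(S = I\) and \(c_2 = 0\) per trait; with these, \( (A, b,\) remaining
cutpoints\()\) are locally identified (the test suite checks a negative
definite Hessian at simulated truth).

**Effect sizes.** The headline quantity is the change in one trait's
equilibrium per robust unit of the other,
\[
\Delta\theta_{d \leftarrow e} = -\frac{A_{de}}{A_{dd}} \cdot \mathrm{MAD}_e,
\]
with the MAD (unscaled `median(|x - median(x)|)`, no 1.4826 factor — note
\(\Delta\theta\) scales linearly in this choice) of the posterior-mean tip
liabilities of the conditioning trait, computed once per fit. Summaries are
the posterior median, 95% HPDI, the posterior probability of a positive
value, and a Savage–Dickey doubled-natural-log Bayes factor against 0
(Gaussian KDE with Silverman bandwidth at 0, for both the posterior and a
simulated prior of \(\Delta\theta\)).

Priors: N(0,1) on off-diagonal selection and drift, \(-\exp(N(0,1))\) on
diagonal selection, ordered N(0,2) on the free cutpoints, half-normal(0,1) on
GP amplitudes and log-normal(log 1000, 1) on GP lengthscales in km.

**Sampler.** The probit liabilities \(u\) are Gaussian given the parameters
with covariance \(\Sigma(A) + I\) (the tip latents integrate out), so the
parameter updates are collapsed: the equilibrium \(\theta\) (hence
\(b = -A\theta\)) has an exact Gaussian full conditional; the selection
matrix and GP block move by adaptive RWM against the \(u\)-marginal;
per-trait scale moves rescale \((u, c)\) jointly with a similarity transform
of \(A\) whose diagonal absorbs the fixed unit diffusion; and the tip latents
are redrawn exactly afterwards by a Matheron update. Convergence threshold
for this model: split R-hat \(\le 1.01\) on all reported parameters.

**Ancestral states.** For a posterior subsample, internal-node latents are
conditioned on that draw's tip liabilities (joint Gaussian under the OU; the
GP contributes only at tips), sampled, and converted to level probabilities
\(\Phi(c_{k+1} - \eta) - \Phi(c_k - \eta)\), which sum to one per draw;
per-node medians are reported. Named clades (e.g. proto-language nodes) are
selected as MRCAs of user-supplied taxon sets, since Newick carries no node
labels.

# Model 3: sequential evolution of the authority structure

The four-state structure trait evolves by a continuous-time Markov chain with
rate matrix \(Q\) and transition probabilities \(e^{Qt}\). Five model
structures are compared: the full model (12 free ordered rates), weak/strong
differentiation (forbidding q02, q03 and additionally q13), and weak/strong
unification (forbidding q01, q02 and additionally q31). Tip-state likelihoods
use Felsenstein pruning (post-order partial likelihoods, uniform root
frequencies by default, with a stationary-of-Q option); the hot path is
compiled, with one eigendecomposition of \(Q\) and one batched product
covering all branches, and a scaling-and-squaring fallback for defective
generators.

Free rates get the hyperprior \(rate_j \sim \mathrm{Exp(mean} = m)\),
\(m \sim U(0, 10)\) — mirroring an exponential hyperprior spanning 0–10, with
"mean" chosen as the hyperparameter's meaning; prior ranges were
sanity-checked against multistart maximum-likelihood fits
(`max_likelihood_fit`). Fixed-structure models with this hyperprior replace
reversible-jump averaging: the inference target is the five-way comparison,
which fixed structures express exactly. Tree uncertainty enters by treating
the tree index as a sampled nuisance variable with a uniform prior over the
posterior sample (Metropolis move); the paper-scale preset mirrors the
original run lengths (1e8 iterations, 10% burn-in, 100 stones × 1e5
iterations), and all analyses default to three independent replicate chains.

Marginal likelihoods use stepping-stone sampling: stones at powers
\(\beta_k = (k/K)^{1/0.3}\) (Beta(0.3, 1) quantiles), one chain per stone
warm-started from the previous stone, and the log-sum-exp identity
\(\log p(y) = \sum_k \log \mathrm{mean}_j L_j^{\beta_{k+1}-\beta_k}\).
Desk-scale defaults are K = 20 stones × 2,000 sampled iterations per stone:
on the conjugate-normal toy this reproduces the analytic marginal to within
0.1, and on 200-tip tree data the replicate SD (~0.7 log units) is far below
the 2-unit decision margin on the doubled-log Bayes-factor scale, so
additional stone iterations buy nothing at this problem size. Support is read
off the conventional scale (0–2 "not worth more than a bare mention", 2–6
"positive", 6–10 "strong", ≥10 "very strong").

# The synthetic-data generator

`synthetic_dataset()` draws one complete study-shaped dataset: a birth–death
tree conditioned on the number of surviving societies (default pure birth),
rescaled to unit root depth so OU rates are comparable across replicates
(configurable); uniform coordinates in a Pacific-style box with antimeridian
wrapping; two coevolving ordinal traits from the OU model; and a structure
trait from a CTMC. Generator defaults are the fixed conditions of the
parameter-recovery study:

* selection \(A = \begin{pmatrix} -1 & 0.8 \\ 0 & -1 \end{pmatrix}\) (unit
  autoregressive selection, cross-trait selection 0.8 of religious on
  political, none in reverse), drift \(b = 0\), \(S = I\), cutpoints
  \((-1, 0, 1)\), spatial GP off (amplitude 0). On unit-depth trees these
  produce informative but far-from-deterministic ordinal data — all four
  levels typically occupied.
* structure-trait truth (strong differentiation): differentiating moves at
  rate 2, direct reversals at rate 1, skip-down reversals at 0.5; on a
  unit-depth 200-tip tree (total length ≈ 40) this yields dozens of realized
  changes, enough to separate the model families without saturating.
* the signal-model generator uses \(\sigma^2 = 1.5\) per trait
  (\(\lambda = 0.6\)), \(\rho_{phylo} = 0.8\), \(\rho_{resid} = 0.2\),
  cutpoints \((-1.2, 0, 1.2)\); the no-signal null sets \(\sigma^2 = 0\).

What the generator does *not* emulate: horizontal transmission or contact
(beyond the additive spatial GP), observation error in the ethnographic
coding, non-ultrametric trees, or correlation between the coevolving traits
and the structure trait (which in real data are logically coupled). Passing
recovery tests therefore demonstrates correctness of the inference machinery
under the model's own assumptions, not robustness to their violation.

# Scaled-down study sizes

All replicated experiments in the test suite are desk-scale versions of the
full designs, chosen to keep a complete run on a single CPU comfortable
while retaining statistical power: 20 replicates × 60 tips for the
coevolution recovery and null-calibration studies (full 100-replicate
configuration available through `recovery_experiment`'s arguments), 20
replicates × 120 tips for signal recovery, 20 replicates × 200 tips per
direction for the model-comparison study, and single-tree desk presets for
the example fits. The paper-scale presets (`scale = "paper"`) restore 100
tree draws and the original Multistate run lengths.

# Numerical choices and degenerate inputs

* Matrix exponentials: eigendecomposition fast path with an SVD conditioning
  check and `Matrix::expm` (scaling-and-squaring) fallback; for 2×2 the
  \(\alpha I + \beta A\) closed form with series handling of the
  repeated-eigenvalue limit.
* Tree covariances are jittered by 1e-8 on the diagonal; zero-length pendant
  branches (present in posterior tree samples) are therefore admissible.
* Truncated-normal draws use inverse-CDF sampling with tail safeguards;
  degenerate cutpoint windows (possible with empty categories) fall back to
  the current value, which always lies in the admissible interval.
* HPDIs use the sorted-window method; R-hat is split-R-hat (optionally
  rank-normalized); ESS uses Geyer's initial monotone sequence.
* Stepping-stone accumulation is entirely in the log domain (log-sum-exp).
* Constant ordinal columns are rejected with an informative error by the
  fitting functions; the generator can produce them (degenerate cutpoints)
  and the validation report flags out-of-range codes.

# Known limitations

* The coevolution surface is bivariate (D = 2); the OU machinery is written
  for general D but only the bivariate path is exercised and optimized.
* \(\lambda\) on structureless data is prior-dominated (see above); report
  intervals, not point estimates, for weakly identified variance shares.
* The Savage–Dickey Bayes factor depends on the KDE bandwidth at 0
  (Silverman default, configurable); for densities with little mass near 0
  it is reported as +Inf with a warning.
* Tree-sample pooling treats trees as exchangeable draws; no attempt is made
  to weight trees by their posterior probability beyond their frequency in
  the sample.
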