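---
title: "Data-driven treatment selection in seamless phase II/III trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven treatment selection in seamless phase II/III trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamsel)
```

## The design problem

A seamless phase II/III trial runs in two stages. In stage one, patients are
randomized to a control $T_0$ or one of $k$ experimental treatments
$T_1,\dots,T_k$; at an interim analysis one experimental treatment $T_I$ is
selected and continues, with the control, into stage two; the final analysis
must control the familywise type I error rate across all $k$ null hypotheses
$H_{0i}:\theta_i \le 0$ in the strong sense, where
$\theta_i = \mu_{B,i} - \mu_{B,0}$ is treatment $i$'s effect on the primary
("final") endpoint.

When the final endpoint needs long follow-up, the interim dataset is
unbalanced in an interesting way: a rapidly observable early endpoint is
available on $N_1$ patients per group, while the final endpoint is available
on only $n_1 \le N_1$ of them. `seamsel` models the two endpoints of a
patient as bivariate normal,

$$
\begin{pmatrix} X_{ij} \\ Y_{ij} \end{pmatrix} \sim
N\!\left(\begin{pmatrix}\mu_{b,i}\\ \mu_{B,i}\end{pmatrix},
\begin{pmatrix}\sigma_0^2 & \rho_w\sigma_0\sigma \\
\rho_w\sigma_0\sigma & \sigma^2\end{pmatrix}\right),
$$

with patients independent, common SDs across arms, and within-patient
correlation $\rho_w$ — the individual-level surrogacy of the early endpoint.
Group-level surrogacy (whether the $\mu_{b,i}$ order the arms the same way
as the $\mu_{B,i}$) is a separate, and in practice separately uncertain,
property; the tension between the two kinds of surrogacy is exactly what the
selection rules below trade off.

## The two base selection rules

**Early-endpoint rule.** Select the arm maximizing
$\tilde Z_i = (\bar X_i - \bar X_0)\sqrt{N_1/2}/\sigma_0$ (`early_z()`,
`select_friede()`). This uses the $N_1$ early observations only. Its
selection probability is driven entirely by the early-endpoint effects: with
close final effects but well-separated early effects it confidently picks
the early winner — which may be the wrong arm on the final endpoint.

**Efficient-score rule.** Select the arm maximizing the standardized score
statistic $S_i = \hat\theta_i\sqrt{I}$ (`score_statistics_known()`,
`select_stallard()`), where

$$
\hat\theta_i = (\bar Y_i^{(n_1)} - \bar Y_0^{(n_1)}) - \gamma\left[
(\bar X_i^{(n_1)} - \bar X_0^{(n_1)}) - (\bar X_i^{(N_1)} - \bar X_0^{(N_1)})
\right], \qquad \gamma = \rho_w\,\sigma/\sigma_0 ,
$$

is the regression-adjusted effect estimate using every stage-1 observation,
and

$$
I = \left[\,2\sigma^2\!\left(\frac{1-\rho_w^2}{n_1} +
\frac{\rho_w^2}{N_1}\right)\right]^{-1}
$$

is its exact information (`score_information()`). The adjustment shrinks the
interim final-endpoint comparison by what the paired early values say about
the luck of the $n_1$ subsample. At $\rho_w = 0$ nothing is borrowed and
$S_i$ is the final-endpoint statistic on $n_1$ patients; at $n_1 = N_1$ the
early data add nothing. The gain over the naive comparison is driven by
$\rho_w^2$ — individual-level surrogacy — and is immune to discordant group
effects because $E[S_i] = \theta_i\sqrt I$ regardless of the $\mu_{b,i}$.

With $\sigma_0,\sigma,\rho_w$ unknown, `score_statistics_estimated()`
replaces $\gamma$ by a pooled within-arm least-squares slope over the paired
patients, the residual variance $(1-\rho_w^2)\sigma^2$ by the pooled residual
mean square (one pooled slope, so the residual degrees of freedom are
$(k+1)(n_1-1)-1$), and $\sigma_0^2$ by the pooled variance of all $N_1$
early values per arm. A pooled (rather than per-arm) slope matches the
common-covariance model and keeps the estimate usable at interim sample
sizes as small as $n_1 = 4$.

Both statistic families have unit variances and pairwise correlation $1/2$
(the shared control), so the probability that arm $i$ is selected is a
$(k-1)$-dimensional multivariate normal orthant probability of the
differences — `friede_selection_prob()` and `stallard_selection_prob()`.

## The data-driven rule

Neither base rule dominates: which one selects the best arm more often
depends on the unknown effects and on $\rho_w$. `select_data_driven()`
therefore applies both rules to the interim data; if they agree, done. If
they disagree, it estimates the full endpoint model from the interim data
(`estimate_model()`: pooled SDs, pooled paired correlation clipped to
$\pm 0.99$), plugs the estimates into each rule's analytic selection
probability *for that rule's own candidate*, and follows the rule that is
more confident. An exact probability tie — a measure-zero event — goes to
the score-rule candidate, which uses more of the data; argmax ties go to the
lowest arm index. Both tie-breaks are deterministic, making every analysis
reproducible.

Because the data-driven rule is a deterministic function of stage-1 data,
the closed-testing analysis below retains strong familywise error control
unchanged.

## Agreement between the rules and the sign of $\rho_w$

Both marginal selection probabilities are unchanged when $\rho_w$ flips
sign (the early rule ignores it; the score rule depends on $\rho_w^2$ only).
The *joint* behaviour is not: the two statistic vectors share the early
data, with cross-covariance
$\mathrm{Cov}(S_i, \tilde Z_j) = \rho_w\sigma\sqrt{I}\,(1+1[i=j])/\sqrt{2N_1}$,
which carries the sign of $\rho_w$. `joint_selection_prob()` builds the
$2(k-1)$-dimensional normal law of both difference vectors and returns the
full 2×2 agreement table; at $\rho_w < 0$ the rules disagree far more often,
which widens the gap between the data-driven rule and either base rule:

```{r agreement}
neg <- agreement_example(-0.9)
joint_selection_prob(1, neg$model, neg$design)
pos <- agreement_example(0.9)
joint_selection_prob(1, pos$model, pos$design)
```

At $|\rho_w| = 1$ the joint law is degenerate: each score difference is an
affine function of its early difference. Full agreement at $\rho_w = +1$
requires the cutoffs to coincide, i.e. $\theta_i = (\sigma/\sigma_0)\,
\delta_i$; under the global null this holds, and at $\rho_w = -1$ the two
rules then *never* agree, so the at-least-one-selects probability doubles
from $1/3$ to $2/3$ in the three-arm null configuration.

## Confirmatory analysis

The final analysis (`closed_test()`) follows the closure principle. For each
nonempty $S \subseteq \{1..k\}$:

* stage-1 p-value: Dunnett test of $Z^{max} = \max_{i\in S} Z_{i,1}$, where
  $Z_{i,1}$ uses **all** $N_1$ stage-1 final observations (complete by the
  final analysis) — this keeps stage-1 and stage-2 statistics independent;
* stage-2 p-value: $p_I = 1 - \Phi(Z_{I,2})$ if $I \in S$, else $1$ (no
  stage-2 evidence is claimed against hypotheses not carried forward);
  $Z_{I,2}$ uses only the $n_2$ per-group stage-2 patients;
* combination: $C(p_1, p_2) = 1 - \Phi(w_1\Phi^{-1}(1-p_1) +
  w_2\Phi^{-1}(1-p_2))$ with pre-specified weights, $w_1^2 + w_2^2 = 1$.

$H_{0i}$ is rejected at one-sided level $\alpha$ iff every $S \ni i$ has
$C \le \alpha$. Subset enumeration is exhaustive ($2^k - 1$ tests), which is
cheap for the intended $k \le 10$ and refused above $k = 20$.

The default weights satisfy $w_j^2 \propto$ stagewise per-group sample size
($N_1$ and $n_2$). "Weights proportional to planned sample size" admits two
readings; the squares-proportional convention is the one under which the
combination is an exact level-$\alpha$ test, and literal proportionality
followed by normalization yields the identical pair, so nothing is lost.
Users may override with any normalized pair. All z statistics treat $\sigma$
as known (the estimated-parameter path exists for the selection rule, where
no error-rate guarantee is at stake, not for the confirmatory test).

## Numerical choices

All orthant probabilities go through `mvn_orthant()`:

* difference vectors from a shared control have compound-symmetric
  correlation $1/2$; for any compound-symmetric rectangle the probability
  reduces exactly to a one-dimensional Gaussian integral (condition on the
  shared factor), evaluated by adaptive quadrature to ~1e-10 — fast enough
  to sit inside simulation loops;
* general full-rank covariances use the deterministic Miwa algorithm
  (4097 grid steps, ~1e-6 absolute accuracy) up to dimension 8, and
  seed-fixed quasi-Monte-Carlo integration above that, so every reported
  probability is reproducible to printed precision;
* rank-deficient covariances (the $|\rho_w| = 1$ joint laws; duplicated
  coordinates) are handled by *interval reduction*: a coordinate perfectly
  correlated with an earlier one contributes an exact interval constraint on
  its representative, and the reduced full-rank rectangle is integrated as
  above. This is exact, whereas truncating to an eigen-subspace would turn
  the orthant into a general polytope and require a different integrator.

Estimated correlations are clipped at $\pm 0.99$ (configurable) so plug-in
information stays finite; plug-in selection probabilities inherit whatever
noise $n_1$ leaves in the estimates, which is the price of the data-driven
rule's adaptivity and is visible in its operating characteristics rather
than hidden.

## The simulator and what it does (not) emulate

`simulate_stage1()` / `simulate_stage2()` draw exactly from the model above:
balanced arms, common variances, bivariate-normal endpoints, independent
patients, stage-2 patients independent of stage 1. Reproducibility is
by construction: a master seed plus replicate id and stage tag are mapped
through a fixed Lehmer-step scheme (`substream_seed()`) to per-use
Mersenne-Twister seeds, so `(seed, replicate)` pins down a trial exactly,
across runs and platforms. The generator does **not** emulate staggered
accrual, dropout, missing early values, variance heterogeneity across arms,
or non-normal endpoints — passing operating-characteristic checks here says
nothing about those complications; the pairing of the first $n_1$ patients
per arm is a labelling convention, harmless because enrollment order is
exchangeable under the model.

`run_scenario()` applies all requested rules to the *same* stage-1 dataset
per replicate (a paired comparison, and the only way the agreement
decomposition of the data-driven rule's selections is well defined), shares
stage-2 data between rules that select the same arm, and reports selection
probability, power in the strict sense (select arm 1 *and* reject
$H_{01}$), the at-least-one-rule upper bound and the two-rule average
benchmark. The standalone score rule in the scenario engine uses the
*estimated* scores — the version a trial without known nuisance parameters
would run, and the same statistics the data-driven rule adjudicates
between. Cross-validation against the analytic (known-parameter)
probabilities is done by `simulate_selection_batch()`, which reduces
patient-level draws to the per-arm sufficient statistics chunk-wise and
makes $10^6$ replicates practical.

Problem sizes used in the shipped checks: the three-arm reference design
($N_1 = 32$, $n_1 = 4$, $n_2 = 64$, $\alpha = 0.025$) with 10,000 replicates
for error-rate checks and $10^6$ replicates for validating the analytic
probabilities; the packaged worked example below is analytic and instant.

## Worked example

The packaged hypertension dose-finding example (`hypertension_example()`)
has four dose regimens against placebo, final-endpoint (8-week diastolic
blood pressure reduction) effects $(1.0, 0.6, 3.9, 1.1)$ mmHg, early
(4-week) effects $(2.3, 3.4, 3.8, 1.9)$ mmHg, $\sigma_0 = \sigma = 10$ mmHg
and $\rho_w = 0.9$:

```{r example}
worked_example("i")    # interim at N1 = 45, n1 = 10
worked_example("ii")   # earlier interim: N1 = 25, n1 = 5
```

Both rules favour DR3 at either interim timing, more confidently at the
later look; DR2 — strong at 4 weeks, weak at 8 — is where the two rules
part company, and only the score rule discounts it.

## Known limitations

Balanced allocation and common variances are assumed throughout; a single
arm is selected, designs have exactly two stages and one early endpoint;
the confirmatory test has no small-sample $t$ version (known-$\sigma$ z
statistics); no futility stopping, sample-size re-estimation, or
post-selection estimation/confidence intervals. Power is estimated by
simulation only — the joint selection-and-rejection probability has no
tractable closed form, unlike the selection probabilities themselves.
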