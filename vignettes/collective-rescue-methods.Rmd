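---
title: "Models and methods: conformist social learning in risky bandits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: conformist social learning in risky bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Trial-and-error learners in risk-heterogeneous environments acquire a
systematic bias: after an unlucky draw from a high-variance option they
sample it less, never correct the underestimate, and settle on the safe
alternative even when the risky one is better on average — the *hot stove
effect*. Conformist ("copy-the-majority") social learning is usually viewed
as a bias amplifier, yet groups of such learners can *escape* learnt risk
aversion. This package implements, end to end, the modelling toolkit for
studying that collective behavioural rescue: an agent-based simulator, a
reduced population-dynamics model, a synthetic-experiment generator, and
hierarchical Bayesian inference with model comparison.

# The learning model

Each agent keeps a value estimate $Q_{i}$ per option, starting at
$Q_{i,1}=0$, updated only for the chosen option by the Rescorla–Wagner rule
$Q_{i,t+1} = (1-\alpha) Q_{i,t} + \alpha \pi_t$ with learning rate
$\alpha \in [0,1]$ and realised payoff $\pi_t$. The asocial choice rule is
softmax with inverse temperature $\beta \ge 0$. Social information is the
vector of counts $N_{i,t-1}$ of group members' choices on the previous
trial. Under *decision biasing*, the net choice probability is the mixture

$$P_{i,t} = (1-\sigma)\,
  \frac{e^{\beta Q_{i,t}}}{\sum_j e^{\beta Q_{j,t}}} + \sigma\,
  \frac{(N_{i,t-1}+0.1)^{\theta}}{\sum_j (N_{j,t-1}+0.1)^{\theta}},$$

with copying weight $\sigma \in [0,1]$ and conformity exponent $\theta$
(conformist above 1, none at 0, anti-conformist below 0). The 0.1 smoothing
keeps never-chosen options defined and lets them attract anti-conformists.
The first trial is always asocial. The product $\alpha(\beta+1)$ indexes
susceptibility to the hot stove effect; on the two-option Gaussian task the
asocial indifference boundary is $\beta = (2-\alpha)/\alpha$, i.e.
$\alpha(\beta+1) = 2$.

**Value shaping.** The alternative social mechanism moves learning rather
than choice. Its exact functional form varies across implementations in
this literature; the package adopts a documented variant: after the RW update,
every option's value gains $\sigma\,(S_i - 1/K)$ where $S_i$ is the
conformity weight above and $K$ the number of options — a zero-sum nudge of
values towards the social frequency, with choice by plain softmax. It
reduces exactly to asocial learning at $\sigma = 0$. This is the package's
own design choice, not a claim about any other implementation.

**Payoff scaling.** The experimental tasks pay in points (50–550). Fitted
inverse temperatures of 3–4 are only dimensionally sensible if values are
O(1), so point-valued presets carry `payoff_scale = 0.01`: payoffs are
divided by 100 before entering the learning rule, while session tables
record raw points. The scale is configurable per task.

# The simulator

`run_session()` advances all group members synchronously; choices at trial
$t$ use counts from $t-1$; payoffs are drawn privately from the chosen
option only (no forgone payoffs, no externalities). Displayed counts
*exclude* the focal agent's own previous choice by default
(`exclude_self = TRUE`): the experimental display shows what others did,
and exclusion makes a group of one informationally asocial. A flag restores
self-inclusion. All randomness flows through R's global RNG, consumed in a
fixed (trial, member) order inside the compiled engine, so a session is
bit-reproducible from its seed; per-agent substreams would add machinery
without adding reproducibility once the iteration order is fixed.

Sweeps (`sweep_parameter_grid()`), heterogeneous compositions
(`run_heterogeneous()`, non-focal defaults $\alpha=0.5$, $\beta=7$,
$\sigma=0.3$, $\theta=2$ — a composition known to rescue), and horizon
comparisons (`compare_horizons()`) are thin front ends over the same
engine. Replicate counts per sweep cell default to 1000 (a full-scale
heterogeneous-group study uses 20000 replications); tests run a few
hundred.
"Second half" always means $t > \lfloor T/2 \rfloor$ — trials 76–150 at
$T = 150$, 36–70 at $T = 70$.

# The population-dynamics model

The reduced model tracks a population of $N$ individuals choosing risky
(R) or safe (S) with a positive or negative attitude towards R. A fraction
$e$ of risky choosers ends up enchanted ($N_{R+} = e N_R$); $e$ proxies the
risk premium. Individuals move towards their preferred option at rate
$p_h$ and against it at rate $p_l$ ($0 \le p_l \le p_h \le 1$); social
influence mixes each rate with the frequency term
$N_i^{\theta}/(N_R^{\theta}+N_S^{\theta})$ with weight $\sigma$ (raw
densities here, no smoothing — densities are continuous and the empty
population is excluded). The state vector is $(N_R, N_{S-}, N_{S+})$ with
$N_{R\pm}$ derived algebraically, so the three-equation system conserves
$N$ by construction. At $\sigma = 0$ the equilibrium bias has the closed
form

$$N_R^{\star} - N_S^{\star} = \frac{-n\,(p_h-p_l)\,\{(1-e)p_h - e p_l\}}
  {(p_h+p_l)\,\{(1-e)p_h + e p_l\}},$$

zero on the neutral curve $e = p_h/(p_h+p_l)$; this closed form is the
oracle against which the integrator is verified.

Numerical choices: `lsoda` integration in chunks of 50 time units with
`rtol = atol = 1e-10`, convergence declared when $\max |d/dt| < 10^{-8}$,
giving up (flagged, not silent) at $t_{\max} = 10^4$. Equilibria closer
than 0.1 individuals are merged. Stability is probed by re-integrating from
$\pm 0.5$-individual perturbations along $N_R$ (the safe remainder
redistributed proportionally) — a basin check that avoids symbolic
Jacobians and mirrors how the bifurcation structure is scanned from many
initial conditions, $N_R(0) \in \{0,\dots,N\}$ with the safe population
split evenly between attitudes (the even split is one choice among several
defensible ones and is adopted throughout).

# The synthetic experiment generator

`generate_experiment()` stands in for the human study: four task presets
(1-risky-1-safe positive and negative risk premium, 1-risky-3-safe,
2-risky-2-safe; 70 trials; safe arms carry Gaussian noise with s.d. 5),
group sizes drawn uniformly from 2–8 (realised size distributions in
online group studies depend on recruitment flow; uniform is a stated
default, not a claim), an individual condition with $\sigma = 0$, and an optional
per-trial dropout hazard that truncates subjects independently of
behaviour, so the $\ge 35$-completed-rounds inclusion rule
(`apply_inclusion_filter()`) induces no selection on parameters.

Individual parameters come from the generative hierarchy
$\alpha_i = \mathrm{logit}^{-1}(\mu_\alpha + v_\alpha z)$,
$\beta_i = e^{\mu_\beta + v_\beta z}$,
$\sigma_i = \mathrm{logit}^{-1}(\mu_\sigma + v_\sigma z)$,
$\theta_i = \mu_\theta + v_\theta z$, $z \sim N(0,1)$.
`example_group_globals()` carries location estimates representative of
hierarchical fits to human group play on the positive-RP two-option task
($\mu_\alpha = -2.2$, $\mu_\beta = 1.4$, $\mu_\sigma = -2.4$,
$\mu_\theta = 1.4$). The spreads are a package design choice, made
once: $(v_\alpha, v_\beta, v_\sigma, v_\theta) =
(1, 0.75, 1.5, 2)$. The reasoning: a Fisher-information estimate shows the
per-subject likelihood for $\theta$ has a standard deviation of 1.5 or
more even for strongly social subjects in 70-trial sessions, so a
population whose true $\theta$ spread is much below 2 cannot support
individual-level recovery of the social parameters at all; the chosen
spreads put the population in the recoverable regime while keeping every
parameter in a human-plausible range ($\theta_i$ roughly $-2.5$ to $5.5$,
$\sigma_i$ mostly below 0.4, $\beta_i$ about 1–18).

What the generator does *not* emulate: the recruiting platform, lobby and
waiting-room mechanics, payment, instruction screens, or any within-session
adaptation of social learning. Passing tests therefore certify the
inference machinery on data whose generative process is exactly the fitted
model family — they do not certify the model against human behaviour.

# Hierarchical Bayesian inference

`fit_hierarchical()` fits the non-centred hierarchy above, with
group-condition subjects carrying all four blocks and individual-condition
subjects fixed at $\sigma = 0$ (an all-individual dataset drops the social
block). Priors are package choices: $\mu \sim N(0, 2)$ on each transformed scale, scales
half-Student-t(4, 0, 1), $z_i \sim N(0,1)$. $\theta$ is unbounded — no
positivity constraint.

The sampler is an adaptive random-walk Metropolis-within-Gibbs, written in
C++: component-wise subject-effect updates (two sweeps per iteration),
random-walk updates of each global, and an ancillarity–sufficiency
interweaving step — a centred-parameterisation refresh of each
$(\mu, v)$ pair holding the individual effects fixed (conjugate normal for
$\mu$, Metropolis on $\log v$), which decorrelates the globals from the
subject effects. Proposal scales adapt only during warmup
(Robbins–Monro towards 0.44 acceptance). Defaults are 4 chains of
1000 + 1000; "reduced" runs (tests, recovery experiments) use 2 chains of
2000 warmup + 3000 draws — a random-walk sampler needs several-fold more
iterations than a gradient-based one for comparable effective sample
sizes, and these sizes keep a 60-subject fit around a minute. Convergence
is summarised by split-$\widehat{R}$ and an initial-positive-sequence ESS
on the globals; the fit is flagged converged only when all
$\widehat{R} < 1.01$ and ESS $\ge 500$, and is returned either way with
its diagnostics.

Likelihoods replay each subject's own payoffs and displayed counts; a
choice probability that underflows to zero raises an error rather than
being clipped. Per-subject WAIC is on the deviance scale,
$-2(\mathrm{lppd} - p_{\mathrm{waic}})$ (both the lppd and deviance
scales appear in the literature; deviance is chosen and documented). Random-effects model
selection approximates each subject's log evidence by $-\mathrm{WAIC}/2$,
estimates the Dirichlet posterior over model frequencies by the standard
variational fixed point, and computes exceedance probabilities by
Monte-Carlo over that Dirichlet. "Mean $\alpha$"-style summaries are
posterior means of the per-subject transformed parameters (mean of the
transform, not transform of the mean). Recovery correlations are
computed on the sampling scales — $\mathrm{logit}\,\alpha$,
$\log \beta$, $\mathrm{logit}\,\sigma$, $\theta$ — because raw-scale
Pearson correlation for a lognormal parameter like $\beta$ is dominated by
tail draws and is unstable across Monte-Carlo replications; the
transformed-scale estimator measures the same recovery property
stably.

# Problem sizes

The package's own verification runs use: 2000 learners over 5000 trials
for the indifference-boundary and choice-shift checks; 21 social-weight
values times 21 initial conditions for the bifurcation scan; 500 random
parameter draws for the integrator-versus-closed-form oracle; 1000
replicate groups for the rescue and risk-premium comparisons; and 60
subjects (10 groups of 6, 70 trials) with the reduced MCMC settings for
parameter and model recovery. These sizes were chosen so each check is
statistically decisive for its stated tolerance.

# Known limitations

* The value-shaping variant is one documented formulation; others exist
  in the literature.
* Whether displayed counts should include the focal agent's own previous
  choice is a design fork in group-bandit software; the package defaults
  to exclusion and exposes the flag.
* Individual-level recovery of $\sigma$ and especially $\theta$ is
  information-limited in 70-trial sessions when most subjects copy rarely;
  recovery correlations at $n = 60$ subjects carry sampling noise of
  roughly $\pm 0.1$.
* Mixed-logit (GLMM) analyses of human experimental datasets are out of
  scope.
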