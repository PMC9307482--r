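---
title: "Methods: clone fitness inference from longitudinal VAF trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone fitness inference from longitudinal VAF trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(clonefit)
library(dplyr)
```

clonefit analyses clonal hematopoiesis from longitudinal targeted
deep-sequencing data: repeated blood draws from the same individuals, each
assayed at ~2000x depth over a panel of myeloid driver genes, yielding for
every somatic variant a time series of variant allele frequencies (VAFs).
This vignette documents the statistical model, the reasoning behind every
default, and the known limitations.

## 1. The birth-death clone model

A mutant hematopoietic stem-cell clone of size $n(t)$ cells follows a linear
birth-death process with birth rate $b = \lambda + s$ and death rate
$d = \lambda$ per cell per year, where $\lambda$ is the symmetric division
rate of wild-type stem cells (default $\lambda = 1$/yr) and $s$ is the
clone's *fitness*: its net growth advantage per year. Conditional on
$n(t_1) = n_1$, after an interval $\Delta t$:

$$
\mathbb{E}[n_2] = n_1 e^{s\Delta t}, \qquad
\mathrm{Var}[n_2] = n_1 \frac{2\lambda + s}{s}
  e^{s\Delta t}\left(e^{s\Delta t} - 1\right)
$$

with the $s \to 0$ limit $\mathrm{Var}[n_2] = 2\lambda n_1 \Delta t$ (the
neutral process is a martingale). `clone_transition()` moment-matches a
negative-binomial distribution to these two moments; `simulate_clone()`
provides the exact Gillespie oracle against which the approximation is
tested (the acceptance suite checks both moments across a grid of
$s$, $\Delta t$, $n_1$ within Monte-Carlo error).

A heterozygous clone of $n$ cells among $N_w$ wild-type stem cells has VAF

$$
v = \frac{n}{2\,(N_w + \sum_j n_j)},
$$

summing over all clones in that individual: clones *share* the pool, so one
expanding clone depresses every other clone's VAF. VAF saturates at 0.5.
With deterministic growth from a single cell at age $t_0$ the VAF follows a
logistic curve, $v(t) = 1/(2 + 2 N_w e^{-s (t - t_0)})$, reaching
VAF 0.25 at $t_0 + \ln(N_w)/s$.

## 2. Joint inference of fitness and pool size

`infer_posterior()` computes the joint posterior of the per-clone fitnesses
and the shared pool size $N_w$ on a grid:

* $s$: uniform prior on a grid from 0 to 1 in steps of 0.005 per year;
* $N_w$: log-uniform prior on 25 log-spaced points from $10^3$ to $10^6$;
* the likelihood of one clone's trajectory is a hidden-Markov forward pass
  over a 200-point logit-spaced latent VAF grid, with negative-binomial
  transitions (cell-boundary CDF differences) and binomial read emissions.

Because time of acquisition never enters the transition densities, fitness
and pool size are estimated without estimating $t_0$. Point estimates are
posterior modes (MAP); intervals are the narrowest contiguous 90% grid
windows (`credible_interval()`).

Why a grid rather than MCMC: with at most 8 variants per individual the
grid posterior is exact up to discretization, deterministic, and directly
testable. Convergence was checked by doubling the latent-grid resolution;
the relevant bias mode is a *coarse* latent grid, whose cell width at
VAF 0.05-0.1 can exceed the binomial sampling noise at 2000x and inflate
small fitness estimates — hence the 200-point default.

Shared-pool competition is a genuine prediction of the model: a fit clone's
VAF can *decline* when a fitter clone expands in the same individual, and
the joint inference still attributes positive fitness to it. Fitness is not
sign-tied to the VAF gradient.

```{r inference-demo}
# one simulated participant: clone with s = 0.25 against a 1e5-cell pool
sc <- sim_scenario(clones = tibble(s = 0.25, n0 = 8000), seed = 42)
sim <- simulate_cohort(sc)
fit <- infer_posterior(sim$cohort,
                       config = inference_config(
                         s_grid = seq(0, 0.5, 0.01),
                         n_w_grid = 10^seq(3, 6, length.out = 7),
                         latent_points = 100))
tidy(fit)
```

## 3. LiFT: separating clones from sequencing artifacts

Recurrent sequencing artifacts produce flat, low-VAF trajectories that a
naive VAF threshold happily calls "CHIP". LiFT (`lift_classify()`) compares
two generative models per trajectory by marginal likelihood:

* **artifact**: a constant proportion $\theta$, integrated over a Beta
  prior moment-matched to the cohort's synonymous variants
  (`calibrate_noise()`); recurrent variants (seen in more than one person)
  use a beta-binomial read model with overdispersion $\rho$ estimated from
  the synonymous trajectories, singletons use a binomial;
* **clonal**: the full birth-death HMM above, marginalized over $s$ and
  $N_w$.

A trajectory is called *fit* when the Bayes factor is at least 4
(inclusive). Candidates must have at least two timepoints, a maximum VAF
above 1%, and a non-synonymous consequence; synonymous variants are never
classified — they are the noise-calibration set.

**Limitation (by design of the calibration):** $\rho$ is estimated from
synonymous reads. If true artifacts are substantially *more* overdispersed
than the synonymous background ($\rho \gtrsim 0.002$), the clonal model —
whose $N_w$ grid extends down to $10^3$, where birth-death process noise is
large — can absorb the extra wiggle and win the comparison. LiFT's
false-positive guarantee therefore holds for artifacts whose overdispersion
resembles the calibration set; strongly overdispersed artifact classes need
either a richer noise model or blacklisting upstream.

## 4. Clonal structures

When one person carries several driver mutations, the mutations may sit in
one clone (shared latent trajectory) or in distinct clones (independent
trajectories competing for the pool). `select_structure()` enumerates all
set partitions of the individual's fit variants (capped at 8 variants,
Bell(8) = 4,140 partitions), scores each by its marginal likelihood under
the shared-pool model, applies a prior penalty of $\kappa = 0.5$ per merge
(multi-mutation clones are rarer a priori), and returns the best partition.
Nested (subclonal) structures are deliberately out of scope: the model's
state is the flat clone list.

## 5. Clinical forecasting

`predict_vaf_band()` propagates a clone observed at VAF $v_0$ with fitness
$s$ forward $\Delta t$ years: invert the VAF map for the clone size, apply
the birth-death moments, map back by the delta method, and add binomial
sampling variance at the follow-up depth.

`referral_time()` answers "how long until growth is confidently
measurable?". Its default *growth* criterion requires the expected VAF
growth to exceed `sd_multiplier` (default 2) standard deviations of that
growth, combining birth-death process noise with the propagated binomial
uncertainty of the initially measured clone size. Under the defaults
($\lambda = 1$/yr, $N_w = 10^5$, depth 2000), a clone at 1% VAF with
$s = 0.10$/yr becomes measurable in about 0.53 years — roughly 6-7 months.

An alternative *band* criterion instead requires the full predictive band
(including the follow-up assay's own sampling noise) to clear the baseline
sampling band. It is far more conservative — at 2000x the per-assay
sampling noise (VAF SD ~0.002) dwarfs months of growth at $s = 0.1$
(ΔVAF ~0.0006), stretching referral times to years. Both criteria are
config-exposed; the default is the growth criterion because a
sampling-noise-dominated criterion makes the answer a statement about the
assay, not the clone.

```{r forecast-demo}
referral_time(v0 = 0.01, s = 0.10)            # years, growth criterion
referral_time(v0 = 0.01, s = 0.10, criterion = "band")
min_detectable_fitness(v0 = 0.01, dt = 3)     # 3 years of follow-up
```

## 6. The simulator and its scope

`sim_scenario()` / `simulate_cohort()` generate seeded synthetic cohorts:
exact Gillespie latent clone paths (shared pool per participant), binomial
reads at negative-binomially distributed depths, flat artifact trajectories
with beta-binomial overdispersion, and binomial synonymous trajectories.
Every generated cohort ships with a ground-truth table, which is what the
acceptance battery scores against (coverage of credible intervals, LiFT
sensitivity/false-positive rate, structure recovery).

The generator is a *test harness*, not a biological claim: it simulates
exactly the model class the inference assumes, plus the artifact classes
described above. It does not simulate copy-number events, mosaic LOH
(which push VAF above 0.5 and violate the heterozygous VAF map), sample
swaps, or depth-dependent error profiles.

## 7. Known limitations

* **Heterozygous-only VAF map.** VAF is capped at 0.5; variants with LOH or
  copy-number amplification violate the map and should be QC'd out.
* **Overdispersed artifacts** beyond the synonymous calibration level can
  evade LiFT (section 3).
* **Flat clone list.** No subclonal nesting; partitions only.
* **Two timepoints minimum.** Cross-sectional fitness estimation is out of
  scope.
* **Referral-time criterion.** The growth criterion's exact variance
  decomposition is one of several defensible choices; the band criterion is
  provided as the conservative alternative, and `forecast_config()` exposes
  all assumptions ($\lambda$, $N_w$, depth, SD multiplier).
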