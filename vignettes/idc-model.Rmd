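---
title: "Modeling interdomain conjugation in crossfeeding batch cocultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interdomain conjugation in crossfeeding batch cocultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcsim)
```

## The system

Interdomain conjugation (IDC) is the transfer of plasmid DNA from bacterial
donors to yeast recipients through a type IV secretion system. `idcsim`
models a batch coculture of an *E. coli* donor and an *S. cerevisiae*
recipient engineered as crossfeeders: the bacterium is a leucine auxotroph
that overproduces tryptophan, the yeast a tryptophan auxotroph that
overproduces leucine, so media leucine/tryptophan levels ("%LW", fractions
of the defined 100% molarities L = 762, W = 245, U = 178, H = 95.4 µM) tune
the steady-state donor-to-recipient ratio. Wells (200 µL) grow for 24 h, are
sampled, then diluted 1:10 into fresh media (180 µL fresh + 20 µL culture)
for up to 6–12 days; 100 µL is plated on transconjugant-selective agar each
day. Bacteria adhere to yeast-wall mannoproteins via type I fimbriae,
forming mixed clumps; free mannose saturates the fimbriae and prevents
clumping.

## The deterministic model

State (per well): free and clumped donors ($B_f$, $B_c$), recipients
($Y_f$, $Y_c$) and transconjugants ($T_f$, $T_c$); amino acids $n_L, n_W,
n_U, n_H$ (µM); glucose $n_G$ (g/L); and a bookkeeping integral of all
conjugation events. For each population $X$ with required-nutrient set
$R(X)$:

$$\frac{dX}{dt} = \mu_X \Big[\prod_{a \in R(X)} \frac{n_a^{\mathrm{eff}}}{K_{X,a}+n_a^{\mathrm{eff}}}\Big]\frac{n_G}{K_G+n_G}\,X \;-\; d_X X \;+\; \text{(clump, transfer terms)}$$

* **Growth and resources.** Multiplicative Monod kinetics on every required
  amino acid and on glucose; first-order death $d_X$; consumption is
  growth-coupled ($u_{X,a}$ µM per new cell); overproducers secrete at a
  constant per-cell rate ($\sigma_L$, $\sigma_W$). Wild-type yeast release a
  small basal leucine flux $\sigma_{L,\mathrm{basal}}$ — the mechanism
  behind the observed commensal benefit (secretion vs lysate) is unresolved
  experimentally, and the model represents it as the simplest constant
  per-cell rate.
* **Clumping.** Free cells join the clumped phase by mass action with the
  partner species total ($k_a$, 1/(cell·h)) and leave at $k_d$ (1/h), so a
  yeast cell can carry several bacteria, as micrographs of such aggregates
  show. Mannose forces $k_a = 0$; a mid-experiment mannose switch also
  releases all clumped cells instantaneously, reflecting the fast disruption
  of existing aggregates. Clump exchange conserves each population's total.
  An earlier 1:1-pair formulation was discarded: it forces donors ≈
  recipients inside the clumped compartment, which caps the achievable
  mannose suppression of IDC near $\gamma_c/2\gamma$ and cannot reproduce
  the observed ≥10-fold effect at the fitted transfer terms.
* **Conjugation.** The transfer term $\gamma$ is the fractional occurrence
  of transfer per donor–recipient collision per hour. Default collision
  normalization is per total cell: rate $= \gamma D R / N_{\mathrm{tot}}$
  within each compartment (free cells use $\gamma$, clumped cells
  $\gamma_c$), which reproduces the textbook worked example — 1000 donors,
  1000 recipients, $\gamma = 0.004$ → 2 new transconjugants per unit step.
  The Levin-style mass-action form ($\gamma' D R / V$) is available as a
  configuration mode. Transconjugants never re-donate.
* **Proximity benefit.** Clumped auxotrophic bacteria perceive, on top of
  the bulk concentration, a local standing pool
  $P\,\sigma\,(\text{partners})\,\tau_{loc}$ of each amino acid their
  partners secrete. $P$ multiplies the secretion term only — it models extra
  local access, not extra bulk secretion. Locally supplied intake is booked
  against the partner-secretion source rather than the bulk pool (bulk share
  $n_a / n_a^{\mathrm{eff}}$), so bulk nutrients cannot be driven negative.
* **Payloads.** A rescue plasmid restores uracil/histidine prototrophy in
  transconjugants; the CRISPR cutter destroys the recipient's episomal URA3
  plasmid so transconjugants become uracil auxotrophs (terminal at 0% U);
  the oriT-less control contributes exactly zero transfer.

## Parameter defaults and units

Counts are cells per 200 µL well, amino acids well-average µM, glucose g/L,
time hours. Kinetic defaults are order-of-magnitude reconstructions from
cell composition and minimal-media physiology, fixed once:

| Parameter | Default | Basis |
|---|---|---|
| $\mu_B$, $\mu_Y$ | 0.50, 0.35 /h | typical minimal-media max rates |
| $d_X$ | 0.005 /h | slow starvation death |
| $K_{X,a}$ | 10 µM (0.1 g/L glucose) | µM-range amino-acid uptake affinity |
| $u_{B,L}$ | 6e-7 µM/cell | leucine content of an *E. coli* cell in a 200 µL well |
| $u_{Y,W}$ | 1.7e-6 µM/cell | tryptophan content of a yeast cell |
| $u_{B,G}$, $u_{Y,G}$ | 1e-8, 2e-7 g/L/cell | yields ≈ 2e9 bacteria or 1e8 yeast per well at 2% glucose |
| $\sigma_L$ | 5e-8 µM/h/cell | overproducer crossfeeding is real but modest: a day of secretion ≈ a low-% media dose |
| $\sigma_W$ | 1e-9 µM/h/cell | auxotrophic yeast gain little from overproducing bacteria |
| $\sigma_{L,\mathrm{basal}}$ | 1e-9 µM/h/cell | "low but significant" wild-type release; puts the clumped-commensalism threshold near $P \sim 50$ |
| $k_a$, $k_d$ | 2e-7 /(cell·h), 0.5 /h | pervasive clumping at typical densities, minutes-scale turnover |
| $\gamma$, $\gamma_c$ | 2e-5, 3e-4 | centers of the fitted bands (free 7e-6–4e-5; clumped 2e-4–4e-4) |
| $P$ | 1 | no proximity benefit unless configured (sweeps explore up to ~300) |

Numerical choices: `lsoda` (stiff-capable, adaptive) with rtol 1e-8 / atol
1e-6 cells for reference runs and 1e-6 / 1e-3 inside sweeps and fitting
loops; components are clipped at zero after integration with the largest
clip magnitude recorded; right-hand sides are evaluated in compiled code
with an R reference implementation tested for agreement.

## The staged calibration

Fitting mirrors the experimental logic: clump-free conditions first, then
transfer terms.

1. **Growth parameters** ($\mu_B$, $\mu_Y$, $u_{B,L}$, $u_{Y,W}$) are fit to
   mannose-arm data with the reduced two-population model (total bacteria,
   total yeast, no clump/transfer terms), by iterated Latin hypercube
   sampling: 3 rounds × 500 samples, keep the best 10%, shrink each range to
   the keepers' span (log-space for log-scaled parameters). Shrinking never
   expands a range and never excludes the incumbent best.
2. **Free transfer term** $\gamma$ is fit to the mannose-arm CFU tables
   (3 rounds × 100 samples; a one-dimensional search does not need 500).
3. **Clumped transfer term** $\gamma_c$ is fit to the mannose-free CFU
   tables with $\gamma$ fixed at its stage-2 estimate.

Estimator details that matter, and why:

* Traces are rolling-mean smoothed (9 points ≈ 2 h, segmented at the daily
  dilution boundaries so the 10× drops are not smeared) before post-day-1
  max-normalization: the maximum of ~600 readings at 5% CV is an
  extreme-value statistic biased several percent high, which otherwise
  drags stage-1 toward spuriously peaky growth.
* The trace error is evaluated on the post-day-1 window, the domain the
  normalization itself defines.
* Daily absolute counts are the only anchor for absolute abundance
  (normalized traces carry none), so the count stream is weighted by the
  ratio of trace points to count points — per-stream balance, as in a joint
  likelihood over two instruments.
* Transfer stages pool every informative media arm's CFU table; the
  collapsed 0% LW arm is excluded from calibration because its post-day-1
  normalizer is itself noise.
* Failed solves score +Inf rather than being discarded, preserving each
  round's Latin structure. Sensitivity ranking is the magnitude of the
  Spearman correlation between sampled values and errors, ties broken
  alphabetically.

## What the synthetic data emulate — and what they do not

The generator produces plate-reader traces (per-cell yield × species total ×
mean-one lognormal noise, 5% CV), daily flow-like counts, Poisson CFU
platings of 100 µL with the counting conventions (500 = lawn, counts ≥ 200
flagged as estimates, zeros floored at 0.1 only for log display, serial
1:10–1:10⁴ dilutions when plates would saturate), and two-channel colony
textures whose expected colocalization (Li's ICQ) is monotone in a mixing
parameter ρ, with ρ = ±1 hitting the analytic anchors ±0.5 exactly.

They do not emulate: growth-phase-dependent fluorescence yields, instrument
drift or well-position effects, stochastic single-cell "jackpot" events,
spatial colony structure beyond statistical texture, or clump-size
distributions. Passing recovery tests therefore shows the estimation
machinery is consistent under the model's own assumptions with realistic
measurement noise — not that the model is identifiable from any real
dataset.

## Quantification conventions

* Post-day-1 normalization divides each reading by the per-channel maximum
  at t ≥ 24 h across an experiment's wells (configurable to per-well);
  readings before the cutoff may exceed 1. The 24 h cutoff is calendar-day
  phrasing and is kept fixed even if day length varies.
* D:R is the ratio of per-species max-normalized counts; zero recipients
  flag a missing value rather than producing infinities.
* The D:R–IDC relationship is fit as a Gaussian-family identity-link GLM of
  log10(IDC) on log10(D:R) — ordinary least squares on the log-log scale —
  with points at the detection limits (0.1 floor, 500 lawn cap) excluded
  and counted; base-10 logs match decade-scaled plots.
* Li's ICQ is the fraction of mean-centered intensity products that are
  positive, minus ½; zero products count as non-positive (this keeps the
  identical/complementary image pair exactly antisymmetric at ±0.5);
  masking is optional and off by default.
* Fold decrease is reported verbatim as −(normalized monoculture)/(normalized
  coculture); the sign convention yields negative values by construction and
  interpretation is left to the caller.

## Problem sizes

The packaged analyses use 6-day protocols on a 15-minute grid (577 points),
parameter sweeps on 5–10-point log grids, 128–256 px colony rasters, and a
pseudo-experiment of one pairing × three %LW levels × two mannose arms for
calibration; recovery is assessed over 10 seeded staged fits. These sizes
were chosen so every analysis runs comfortably on a laptop while leaving the
estimator enough data to resolve the transfer terms within their fitted
bands.

## Known limitations

* Deterministic continuous populations cannot collapse to true extinction;
  rescue outcomes that are stochastic in experiments (all-or-nothing
  replicates) appear as smooth intermediate states here.
* The absolute transconjugant scale at the default transfer terms exceeds
  typical plate counts; the published headline fits were obtained against
  wet data unavailable here, so transfer-term inference is validated by
  recovery on synthetic data instead.
* Whether secretion is biomass- or growth-coupled is not experimentally
  resolved; the model fixes per-cell constant secretion.
* The collision normalization behind the per-total-cell transfer form is a
  reconstruction that reproduces the published worked example; the
  mass-action alternative is retained as a mode.
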