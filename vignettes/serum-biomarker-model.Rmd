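---
title: "A dynamic serum biomarker model for growing brain tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic serum biomarker model for growing brain tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfapsim)
```

## The problem

Glial fibrillary acidic protein (GFAP) is an astrocyte-specific intermediate
filament. It does not occur outside the central nervous system, so its
appearance in blood indicates astrocyte injury together with a compromised
blood-brain barrier (BBB) — precisely the situation in a growing
glioblastoma (GBM), whose hallmarks include a necrotic core and vascular
damage. A serum GFAP assay is therefore a candidate liquid biopsy for
astrocytic tumours, and the practical question is quantitative: *at what
tumour volume does serum GFAP first exceed a diagnostic cut-off, and which
tumour and patient characteristics move that volume?*

`gfapsim` answers this with a deliberately small mechanistic model: two
Gompertzian growth laws (tumour and necrotic core), a production term that
ties GFAP release to necrotic cell death, a saturable BBB transfer fraction,
and a one-compartment blood model with first-order elimination. Everything
downstream — detection volumes, sensitivity sweeps, detection boundaries,
virtual cohorts — is built from these four pieces.

## The model

**Growth.** Tumour volume follows a Gompertz law from a single cell,

$$V_T(t) = V_{T\max}\, \exp\!\big(\ln(V_{T0}/V_{T\max})\, e^{-R_T t}\big),$$

which solves $dV/dt = R_T \ln(V_{T\max}/V)\, V$ with $V_T(0) = V_{T0}$.
Necrosis begins when the tumour reaches an onset volume $V_{n0}$, at the
onset time $T_{n0} = V_T^{-1}(V_{n0})$, and the necrotic core then follows
its own Gompertz law on the shifted clock $t - T_{n0}$, growing from a
single necrotic cell towards its plateau $V_{N\max}$. Both inverses are
available in closed form (`onset_time()`), so onset times are always derived
from volumes, never configured directly.

**Production.** Each dying cell releases a mass $Q_N$ of GFAP, so the
production rate is $U_T(t) = Q_N\, dN_N/dt$ with $N_N = V_N \delta_N$. For
Gompertz growth the derivative is analytic:
$U_T = Q_N R_N \ln(N_{N\max}/N_N)\, N_N$. Production is zero before onset,
peaks when the core passes $V_{N\max}/e$, and vanishes again at the plateau
— late-stage serum levels can therefore *fall*, which is why the
concentration-volume relationship is only invertible on its rising limb.

**Transfer.** The fraction $K_T$ of released GFAP that reaches blood is zero
while the BBB is intact and rises as a Hill function once the tumour passes
the transfer onset volume $V_{k0}$:

$$K_T(t) = K_{\min} + (K_{\max}-K_{\min})\,
  \frac{t^h}{K_{1/2}^h + t^h}, \qquad t \ge T_{k0}.$$

The Hill clock is absolute model time (days since the single-cell origin),
which puts the half-saturation constant $K_{1/2}$ on the same axis as the
onset time $T_{k0}$ and makes the admissibility condition $K_{1/2} > T_{k0}$
directly comparable. BBB damage and necrosis are assumed to start together
($T_{n0} = T_{k0}$, i.e. $V_{k0} = V_{n0}$ in every default scenario),
because necrosis follows from hypoxia and hypoxia from failing vasculature.

**Serum compartment.** The blood mass $Q_p$ obeys

$$\frac{dQ_p}{dt} = K_T(t)\,U_T(t) + K_H U_H - \gamma\, Q_p,
  \qquad C = Q_p / V_p.$$

Healthy tissue contributes a constant input $K_H U_H$; only the product is
identifiable and it is rederived from the healthy steady state as
$K_H U_H = C_H \gamma V_p$. Simulations start at that steady state,
$Q_p(0) = C_H V_p$ — patients have baseline GFAP before they have tumours.

## Parameters

`default_parameters()` returns population-average values; `parameter_ranges()`
the reported spread used by sweeps and the cohort sampler.

| symbol | meaning | default | range | units |
|---|---|---|---|---|
| $R_T$ | tumour growth rate | 0.008 | 0.004–0.01 | day$^{-1}$ |
| $R_N$ | necrotic growth rate | 0.009 | 0.005–0.01 | day$^{-1}$ |
| $V_{T\max}$ | tumour plateau | 158 | 72–164 | ml |
| $V_{N\max}$ | necrotic plateau | 150 | 70–159 | ml |
| $V_{n0} = V_{k0}$ | onset volumes | 0.5 | 0.1–20 | ml |
| $h$ | Hill coefficient | 7 | 3–9 | — |
| $K_{\max}$ | max transfer fraction | 0.5 | 0.3–0.8 | — |
| $K_{1/2}$ | half-saturation time | 225 | 100–300 | days |
| $\gamma$ | blood elimination rate | 0.7 | 0.5–1 | day$^{-1}$ |
| $C_H$ | healthy baseline | 0.012 | 0–0.11 | ng ml$^{-1}$ |
| $Q_N$ | GFAP per dying cell | $3.1\times10^{-4}$ | 1.3–5.7 $\times10^{-4}$ | ng |
| $\delta_T$, $\delta_N$ | cell densities | $5.714\times10^7$, $4.8\times10^7$ | fixed | cells ml$^{-1}$ |

Initial volumes are one cell: $V_{T0} = 1/\delta_T$, and by analogy
$V_{N0} = 1/\delta_N$ for the first necrotic cell (no measured value exists
for the necrotic seed; one cell is the smallest physical choice and keeps
the two growth laws symmetric).

### The distribution volume

The blood distribution volume $V_p$ never appears in the reported averages,
yet every concentration scales with $1/V_p$. Because of that strict scaling
a single headline observation identifies it, so we fix it once by
calibration: `calibrate_distribution_volume()` finds the $V_p$ at which the
all-average simulation first crosses 0.12 ng ml$^{-1}$ at a tumour volume of
26 ml. Detection volume is monotone increasing in $V_p$ (more dilution means
a later crossing), so the root is unique; it sits near 1489 ml, and the root
search runs over [200, 6000] ml to bracket it comfortably. The result is
frozen as the package default and treated as a constant everywhere —
recalibrating per analysis would silently absorb model error into $V_p$.
Physically, ~1.5 l is below a typical adult plasma volume; it is best read
as an *effective* distribution volume that also soaks up any constant losses
not modelled explicitly (e.g. glymphatic clearance of interstitial GFAP).

## Numerical choices

* The growth laws and their inverses are evaluated in closed form; grids are
  only for export and inspection.
* The serum ODE is linear with a smooth forcing except at the single switch
  point $T_{n0}$. Before it the compartment sits at its exact steady state,
  so integration (`deSolve::lsoda`, rtol $10^{-8}$) starts *at* the switch,
  which is also where the integrator restarts — the discontinuity is never
  stepped over. Halving the tolerances moves no reported concentration by
  more than 0.01% (tested).
* Threshold crossings are located with the root-finding integrator
  `deSolve::lsodar` (rtol $10^{-10}$) on $C(t) - \theta$, i.e. event location
  inside the solver rather than interpolation on an output grid; the tumour
  volume at the crossing then comes from the closed-form growth curve.
* Sweep grids default to 11 points per axis over the published ranges
  (1331-point factorial for the transfer-fraction trio, 121 for the
  patient-baseline pair). A denser grid can only widen a reported spread —
  a tested monotone property — and 11 per axis resolves the smooth response
  surfaces well while keeping the full factorial to well under two minutes.
* The necrotic volume is defensively capped at the tumour volume when edge
  combinations from sweeps would momentarily violate containment; production
  uses the uncapped closed-form derivative.

## Design decisions in the open

* **Necrosis growth sign.** The necrosis law is used in the same growing
  form as the tumour law, $\exp(\ln(V_{N0}/V_{N\max})\, e^{-R_N (t-T_{n0})})$;
  with a positive sign in the inner exponential the expression would decay
  away from its plateau rather than grow towards it, contradicting the
  intended Gompertzian behaviour.
* **Hill form.** The transfer fraction uses the standard saturating Hill
  form with $K_{1/2}^h$ in the denominator, so that $K_T \to K_{\max}$ and
  half-saturation occurs exactly at $t = K_{1/2}$ (tested).
* **Strict vs. structural validation.** The admissibility condition
  $K_{1/2} > T_{k0}$ is part of the model's motivation but late-onset
  scenarios of real interest (onset at 20–50 ml) violate it. Structural
  invariants (positivity, containment $V_{N\max} < V_{T\max}$, fraction
  bounds) are always enforced; $K_{1/2} > T_{k0}$ only in `strict` mode,
  which the cohort sampler uses.
* **No-necrosis sentinel.** Setting $V_{n0} \ge V_{T\max}$ makes the onset
  unreachable ($T_{n0} = \infty$): production stays zero and the serum stays
  at $C_H$. This is the supported way to represent a tumour that never
  develops a necrotic core.

## The cohort sampler

`sample_cohort(n, seed)` draws each ranged parameter independently and
uniformly within its published range (no joint distribution has been
reported), ties $V_{k0} = V_{n0}$, and rejects draws that fail strict
validation. Rejection makes the *accepted* marginals non-uniform for the
constrained parameters: slow-growing tumours with late onsets are culled by
$K_{1/2} > T_{k0}$, so accepted cohorts over-represent faster growth,
earlier onsets and longer half-times. That is a property of the constraint
set, not a sampling bug, and the test suite pins down its direction.

What the generator emulates is parameter heterogeneity *between* patients
under the published ranges. What it does not emulate: within-tumour
heterogeneity (the model is well-mixed by construction), GFAP expression
loss in high-grade disease (production per dying cell is constant), assay
noise, and any correlation structure between parameters beyond the
admissibility constraints. Tests that pass on these cohorts therefore
validate the machinery and the stated constraints, not the realism of any
individual virtual patient.

## Worked analyses

The average tumour, and how the detection volume moves with the necrosis
rate:

```{r}
p <- default_parameters()
detect(p, 0.12)
detect(load_parameters(list(R_N = 0.013)), 0.12)
```

A coarse transfer-fraction sweep (the full 11^3 factorial is the default):

```{r}
kt_sweep(c(0.3, 0.55, 0.8), c(100, 200, 300), c(3, 6, 9))
```

The steady-state detection boundary: with a barely compromised barrier
(small $K$) only very high production rates are detectable, and
$K \cdot U^\ast$ is constant along the boundary:

```{r}
detection_boundary(c(0.1, 0.2, 0.4), 0.12, p)
```

## Known limitations

* The model is deterministic and well-mixed; it predicts population-average
  kinetics, not the measured serum noise of an individual assay.
* Production is tied exclusively to necrosis. GFAP from peripheral damage
  around non-astrocytic tumours is only representable through the static
  $(K_T, U_T)$ boundary analysis, not as a dynamic mechanism.
* $V_p$ is an effective, calibrated constant; all absolute concentrations
  inherit its uncertainty, although threshold *ratios* and sweep spreads are
  much less sensitive to it.
* Several published scenario values could not be reconciled with the printed
  equations under any onset or clock convention we tried (the calibration
  target and the late/slow-necrosis scenarios agree well; the low-threshold
  and rapid-necrosis scenarios do not). The package implements the equations
  as printed and reports what they produce; the acceptance script makes the
  comparison explicit rather than tuning parameters to match.
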