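---
title: "Modelling glucose regulation in a pancreas-liver MPS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose regulation in a pancreas-liver MPS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotwin)
```

## The system and the model

A pancreas-liver microphysiological system (MPS) co-cultures pancreatic
islets and HepaRG/stellate-cell liver spheroids in two 300 µl medium
compartments connected by a recirculating microfluidic loop (mean flow
4.94 µl/min). Glucose dosed with the medium is taken up by the liver
spheroids, partly in proportion to the insulin secreted by the islets;
the islets in turn respond to the circulating glucose concentration.
Over a two-week culture the system can develop a diabetes-like
phenotype: glucose tolerance and the insulin response both decline.

`glucotwin` implements a coupled fast/slow ODE model of this loop:

**Fast states (hours).** Glucose amounts $NG_{m,liver}$,
$NG_{m,pancreas}$ (mmol) and insulin amounts $NI_{m,liver}$,
$NI_{m,pancreas}$ (mIU) in the medium of each compartment. The liver
removes glucose at rate
$V_{HepaRG}\,(E_{G0} + S_I(t)\,I_{liver})\,G_{liver}$ — an
insulin-independent disposal $E_{G0}$ plus an insulin-dependent term
governed by the insulin sensitivity $S_I(t)$ — and eliminates insulin
at rate $V_{HepaRG}\,k_{elim}\,I_{liver}$. The islets secrete insulin
at rate $V_\beta(t)\,\sigma(t)\,G^2/(EC50_I^2+G^2)$. The flow $Q$
exchanges both species between compartments
($Q\,(C_{other}-C_{self})$). Endogenous glucose production is retained
as a parameter but fixed to zero: the observed glucose levels fall
below normoglycemia in this system, which a nonzero production term
would prevent.

**Slow states (weeks).** The integral of excess glucose
$G_{int}(t)=\int \max(G_{liver}-5.5,\,0)\,dt$ drives the loss of
insulin sensitivity; a first-order average $G_{slow}$ of pancreatic
glucose (time scale $\tau_{slow}$) drives Topp-type beta-cell volume
dynamics $\dot V_\beta = k_v(-d_0 + r_1 G_{slow} - r_2
G_{slow}^2)V_\beta$, whose growth law changes sign at roughly 5.6 and
13.9 mmol/L — death below normoglycemia, adaptation at moderate
hyperglycemia, glucotoxic decline beyond.

**Structural hypotheses.** Three variants of the time-dependent terms:

* **H1** (hyperglycemia alone):
  $S_I = S_{I0}\,(1 - I_{max,Si}\,G_{int}/(EC50_{Si}+G_{int}))$ and
  $\sigma(t)=\sigma_{max}(1 - t^2/(\alpha+t^2))$.
* **H2** (hyperglycemia plus an additional diabetogenic factor): the H1
  $S_I$ multiplied by $1 - I_{max,add}\,t^2/(EC50_{add}^2+t^2)$.
* **LOW_HCT** (physiological hydrocortisone): the additional factor is
  absent and $\sigma(t)=\sigma_{max}$ — the declines are attributed to
  the supra-physiological hydrocortisone of the standard medium, so
  removing it removes them. The hyperglycemia term on $S_I$ is
  retained.

Time is carried as an explicit state (`t_state`) so the autonomous
formulation survives the hard solver restarts at protocol events.

The measured observable is the pooled sample: 15 µl drawn from each
compartment, giving the sample-volume-weighted mean concentration. The
printed form of this pooling expression is typographically ambiguous
(taken literally it is dimensionally inconsistent); we implement the
volume-weighted mean, which coincides with the intended value for the
equal 15 µl draws.

## Units and parameters

Hours, litres, mmol (glucose) and mIU (insulin) everywhere inside the
model; conversions (e.g. insulin doses in nM via 1 mIU/L = 6.00 pmol/L,
`nM_to_mIU()`) happen at I/O boundaries only.

The chip geometry is fixed by the platform. The kinetic constants are
documented assumptions shipped in
`inst/extdata/default_parameters.yaml`: the reference values for this
model family are published outside this package, so the defaults were
chosen once, at design time, to reproduce the qualitative on-chip
phenomenology — an 11 mM load cleared to roughly half within 48 h early
in co-culture with an insulin response of tens of mIU/L, and a blunted
late response under the diseased condition. Choices that matter:

* `E_G0 = 0.3/h` — insulin-stimulated uptake dominates basal disposal.
  This is what makes $S_{I0}$ identifiable from a GTT curve; if basal
  disposal dominated, the insulin dependence of glucose clearance (and
  with it the whole hypothesis-discrimination logic) would be invisible.
* `EC50_Si = 600 mmol·h/L` — hyperglycemia-driven resistance
  half-saturates after about five days of continuous 11 mM exposure,
  i.e. it develops over the culture weeks. A much smaller value would
  saturate the exposure law within a single 48-h window, making the
  hyperglycemic and normoglycemic arms indistinguishable by day 13 and
  the two hypotheses structurally unidentifiable.
* `I_max_additional = 0.995`, `EC50_additional = 30 h` — the additional
  diabetogenic factor is *strong*: by day 13 hepatic insulin
  sensitivity is essentially gone, which is the regime in which a large
  spiked insulin dose visibly fails to accelerate glucose clearance (as
  observed in the validation experiment this package replays).
* `alpha = 168² h²` — the secretion capacity halves after one week,
  placing the decline of the insulin response in the middle of the
  15-day protocol.
* `sigma_max = 4e5 mIU/L/h` (per unit beta-cell volume, with
  $V_\beta(0) = 8.8\times10^{-9}$ L) — yields an early insulin response
  peaking near 50-80 mIU/L.

Every default is overridable (`default_parameters()`,
`update_parameters()`), and parameter files round-trip through YAML.

## Protocols as events

Medium exchanges replace the full compartment volume, so they are
instantaneous state resets, not finite-rate dosing; the continuous
dosing input of the RHS is kept at zero in all shipped protocols. The
model clock starts at the day-1 GTT exchange (the model's initial
conditions apply the day-1 offsets there), so `gtt_protocol()` places
exchanges at 0, 48, 96, ... h and GTT windows at (day−1)·24 h with
samples at +0, 8, 24, 48 h. The day-1 and day-13 offset parameters
absorb measured exchange errors and apply at the corresponding GTT
exchanges only. A sample coinciding with an event is drawn post-event
(fresh medium) when it is the window's 0-h draw, and pre-event when it
is a trailing 48-h draw that collides with the next scheduled exchange.
The day-13 insulin dose is added with the fresh medium of that
exchange, to both compartments (a liver-only mode exists for
sensitivity analysis).

Integration is adaptive LSODA with rtol 1e-8 / atol 1e-10 and a hard
restart at every event. The RHS is compiled (C); the exported
`ode_rhs()` is the R reference implementation, and the test suite holds
both to a third, independently transcribed copy of the equations.

## Calibration and uncertainty

**SEM preprocessing.** With 2-6 replicate circuits, measured SEMs
underestimate the real uncertainty. Two corrections, in order: SEMs
below 5% of their mean (or exactly zero, which would give a residual
infinite weight) are replaced by the largest measured SEM of the
dataset — across signals by default, per signal via `per_signal = TRUE`,
which is the right choice whenever the signals span orders of magnitude
(a 24 nM insulin spike is 4000 mIU/L against glucose at 11 mmol/L).
Then the magnitude of the measured t = 0 deviation from the nominal
dose is added to every SEM of that GTT window. Calibration and
validation windows are preprocessed separately: they are distinct
experiments, and the calibration floor must not see the later
validation data.

**Cost and acceptance.** The weighted least-squares cost
$V(p)=\sum_i\sum_t (y_i(t)-\hat y_i(t,p))^2/\mathrm{SEM}_i(t)^2$ is
compared against the $\chi^2_{0.95}$ quantile with degrees of freedom
equal to the number of residuals (the printed thresholds 37.65 and
12.59 back-solve to df 25 and 6 at $\alpha=0.05$; df is an explicit
override to match any convention).

**Acceptable-set search.** Seeded simulated annealing: log-scale
random-walk proposals for positive parameters (linear for sign-free
offsets), geometric cooling $T_k = T_0\,0.95^k$, multiple restarts with
log-uniform re-initialisation, followed by a Nelder-Mead polish from
the best point. Every cost evaluation — not only accepted moves — that
passes the $\chi^2$ gate joins the acceptable set, which is the model's
uncertainty representation. Prediction envelopes simulate the optimum
plus, per free parameter, the members attaining its minimum and maximum
($2n_{free}+1$ simulations; a full-ensemble mode exists behind a flag).
Default budgets are 5 restarts × 2000 evaluations; the self-validation
studies use 2 × 120 (see below).

**Workflows.** `test_hypothesis()` accepts a hypothesis when *any*
acceptable member explains the validation data (the ensemble is the
model's uncertainty); `design_discriminating_dose()` picks the smallest
dose whose glucose envelopes separate by more than the average
calibration SEM (glucose only drives the decision);
`predict_low_hct()` re-optimises exactly `S_I0` and `sigma_max` against
an early low-hydrocortisone GTT, switches the model to `LOW_HCT`, and
emits an out-of-sample envelope for the late response. When the
baseline fit fails its $\chi^2$ gate the prediction is still emitted,
flagged unreliable. For the envelope-based workflows the H2 calibration
pools both glucose arms into one cost with shared kinetics and
arm-specific dosing.

## Synthetic studies

`generate_gtt_study()` simulates each arm's protocol under sealed true
parameters (donor variability enters as multipliers on `S_I0` and
`sigma_max`, the two constants re-calibrated per donor), draws
replicate circuits with independent multiplicative Gaussian noise
(assay-CV style; an absolute-noise mode exists), truncates negative
draws at zero with a logged count, and emits the mean/SEM table in the
calibration schema. The ground truth is sealed (`unseal()`) so pipeline
code cannot read it by accident. Measurement-noise distributions are
not characterised for this platform; multiplicative Gaussian is an
assumption.

`generate_endpoint_matrix()` draws nested random effects
(lab → study → circuit) plus residual noise around a per-timepoint
trend, giving endpoint matrices whose ICC(2,1) behaviour is controlled
by the variance components.

The in-silico study replicas fix their conditions once:

* `discrimination_study()` — two arms, 3 circuits, 5% noise, day-13
  spike of 24 nM, truth H2 with the strong additional factor and
  day-1 offsets (0.4 mmol/L, 2 mIU/L); calibration on days 1-9 with
  the donor pair {`S_I0`, `sigma_max`} free. The structural resistance
  kinetics stay fixed during calibration: they are the hypotheses under
  test, and freeing them would let H1 imitate H2's time-driven decline
  through its exposure-driven one. 5% noise is the level the SEM
  preprocessing itself treats as the minimum realistic uncertainty.
* `recovery_study()` — one hyperglycemic arm, 4 circuits, 10%
  noise, donor-shifted truth, same free pair; reports relative errors.
* `low_hct_study()` — high-HCT calibration (both arms, days 1 and 13)
  followed by a low-HCT prediction scored by whether the day-13 glucose
  AUC of the noiseless truth falls inside the envelope's AUC band
  (baseline: 6 circuits, matching the larger early-window replication
  of the corresponding experiment).

Search budgets in these replicas (2 restarts × 120 evaluations plus
polish, ~500 ODE simulations per fit) were sized so a full replica set
runs in minutes on one core; the two-parameter donor calibration is
well inside what this budget resolves.

## What the synthetic validation does and does not show

Passing these studies shows the machinery is self-consistent: the
fitter finds parameters the generator hid, the $\chi^2$ gate separates
structurally wrong models from right ones *under the model's own noise
assumptions*, and the envelope covers what it should. It does not show
that the model family describes a real chip: real measurement noise is
not exactly multiplicative Gaussian, real donor variability touches
more than two constants, and the kinetic defaults are assumptions, not
fitted values. Conclusions about a real system require calibrating
against measured GTT tables via `read_gtt_table()`.

## Numerical choices and degenerate inputs

* LSODA, rtol 1e-8 / atol 1e-10; halving the tolerances moves pooled
  outputs by well under 1e-6 relative.
* Exchanges reset amounts exactly; slow states are never touched by
  events.
* `G_int` uses `max(G − 5.5, 0)`: continuous, kink handled by the
  adaptive solver.
* All-zero SEMs are an error (the floor is undefined); zero SEMs among
  nonzero ones are floored.
* An empty acceptable set yields a flagged ensemble carrying the best
  found vector; envelopes refuse flagged ensembles, except the low-HCT
  workflow, which emits a flagged single-member prediction.
* Ties in `design_discriminating_dose()` break toward the smallest
  dose.
* ICC requires a complete matrix (no imputation); the `n_c` in its
  denominator is the number of timepoints (standard ICC(2,1)); a
  literal mode using the total observation count is provided for
  comparison. CVs use the sample (n−1) standard deviation. Endpoint
  data are not log-transformed before ICC/CV.

## Known limitations

No spatial modelling of spheroids, no hydrocortisone pharmacokinetics
(HCT enters only through the structural variants), no evaporation or
sampling-volume depletion, no profile-likelihood or MCMC uncertainty
(the acceptable-set heuristic is the method under study), and no
identifiability analysis beyond what the synthetic replicas expose.
The insulin dose reported for the discriminating experiment differs
between sections of the source study (24 nM vs 23 nM); the dose is
always an explicit user input here.
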