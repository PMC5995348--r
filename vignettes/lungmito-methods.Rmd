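---
title: "Modeling the bioenergetics of isolated lung mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the bioenergetics of isolated lung mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmito)
```

## The model

`lungmito` simulates an isolated-lung-mitochondria experiment as a
three-compartment reaction/transport network: the extra-mitochondrial
buffer, the inter-membrane space (IMS) and the matrix. The outer membrane
is porous, so every small metabolite shares a single buffer/IMS state;
cytochrome c (too large for the porins) lives only in the IMS. The state
vector holds 37 metabolite concentrations, the matrix and buffer proton
concentrations, and the inner-membrane potential $\Delta\Psi_m$ — forty
states, plus two more when the rhodamine-123 probe is attached.

Fifteen reactions (ten TCA-cycle steps: PDH, CITS, CITDH, AKGDH, SCAS,
NDK, SUCDH, FH, MDH, GOT; and respiratory complexes I–V) and ten transport
processes (DCC for succinate and malate, OME, TCC, PYRH, PIC, ANT, GLUH,
GAE, and the GHK proton leak) connect the states. Every enzymatic and
carrier flux uses one generalized random-ordered rapid-equilibrium law
with a Haldane thermodynamic constraint:

$$
J \;=\; \frac{V_{maxf}}{\prod_i K_{S_i}^{\alpha_i}}\;
\frac{\prod_i [S_i]^{\alpha_i} \;-\; \prod_j [P_j]^{\beta_j}/K'_{eq}}
     {\prod_i \left(1+[S_i]^{\alpha_i}/K_{S_i}^{\alpha_i}\right)
      \prod_j \left(1+[P_j]^{\beta_j}/K_{P_j}^{\beta_j}\right)}
$$

so the flux is exactly zero when the reaction quotient equals the apparent
equilibrium constant, positive below it, and saturates at $V_{maxf}$. When
a substrate and product form a cofactor pair sharing one binding site
(NAD/NADH, FAD/FADH2, CoA thioesters, adenine and guanine nucleotides,
the ubiquinone and cytochrome-c redox couples), both members drop out of
the denominator. For fluxes in which **every** species is paired (complex
I, III, IV, NDK) the law degenerates to reversible mass action with rate
constant $V_{maxf}/\prod K$; this is the only reading under which the
published maximal-rate table is dimensionally coherent — a literal
saturating cap of, e.g., 0.27 nmol·min⁻¹·mg⁻¹ for complex IV would
contradict the oxygen-consumption rates the same source reports.

Thermodynamic corrections enter through the apparent equilibrium
constant:

* pH: proton-releasing reactions use $K'_{eq} = K'^0_{eq}\,10^{pH-7}$,
  proton-consuming ones $K'^0_{eq}\,10^{7-pH}$, with the pH of the
  compartment where the reaction runs;
* membrane charge movement: a flux moving $n$ charges matrix→IMS picks up
  $e^{-nF\Delta\Psi_m/RT}$, and transported protons contribute
  $(H_e/H_m)^{n_{H,in}}$. Complexes I/III/IV pump 4/2/4 charges, ATP
  synthase consumes 3, ANT one, exactly the coefficients of the
  membrane-potential balance
  $d\Delta\Psi_m/dt = (4J_{CI}+2J_{CIII}+4J_{CIV}-3J_{CV}-J_{HLEAK}-J_{ANT})/C_{imm}$;
* temperature: every maximal rate is scaled by $Q_{10}^{(T-T_{ref})/10}$
  with $Q_{10} = 2.5$ and $T_{ref}$ = 30 °C, the temperature of the rate
  table.

The proton leak and the rhodamine-123 dye both cross the inner membrane
by Goldman–Hodgkin–Katz electrodiffusion. We use the uptake-positive form

$$ J = p\,w\,\frac{C_{out} e^{w} - C_{in}}{e^{w}-1}, \qquad
   w = \frac{zF\Delta\Psi_m}{RT}, $$

which has the Fick limit $p(C_{out}-C_{in})$ as $\Delta\Psi_m \to 0$
(evaluated by a second-order series below $|w| < 10^{-6}$ for numerical
robustness), vanishes at the Nernst ratio $C_{in}/C_{out}=e^{w}$, and
satisfies $J(\Delta\Psi, a, b) = -J(-\Delta\Psi, b, a)$.

## Units and bookkeeping

Concentrations are mM, time minutes, fluxes nmol·min⁻¹·mg⁻¹, potentials
mV. The matrix water volume of 1 µl per mg protein makes matrix contents
(nmol/mg) numerically equal to concentrations (mM); the IMS is 10% of the
matrix volume; buffer fluxes convert through the protocol's chamber volume
and protein mass. Oxygen is an explicit buffer state consumed at 0.5 O2
per two-electron complex-IV flux unit, with a small Michaelis dependence
(K ≈ 1 µM) so traces flatten on anoxia. Oxygen consumption rates are
reported as nmol **O2** min⁻¹ mg⁻¹; respirometry literature sometimes
reports nmol O (atoms), a factor of two — worth checking when comparing
absolute rates.

Seven conserved pools (pyridine and flavin nucleotides, adenine
nucleotides, CoA, cytochrome c, ubiquinone, aspartate+glutamate) are
closed by construction of the stoichiometric matrix; pools whose members
are carried across the inner membrane (adenine nucleotides, Asp/Glu) are
conserved as total amounts across compartments. `check_conservation_pools()`
audits them; trajectories hold them to better than $10^{-6}$ relative.

Matrix and buffer H⁺ are dynamic states. Net proton fluxes convert to
concentration change through buffering slopes (mM per pH unit). The
per-flux proton coefficients are chosen so the ledger closes identically
at flux steady state: each NADH-producing dehydrogenase releases one
proton, complex I consumes five (four pumped, one chemical), complex III
two, complex IV four, ATP synthase returns three, the phosphate carrier
imports one per Pi, the leak one. The matrix buffering slope defaults to
300 mM/pH — deliberately larger than the intrinsic chemical buffering
because it also stands in for K⁺/H⁺-exchange pH homeostasis, which the
model does not represent explicitly; without it, sustained Pi/H⁺ carrier
cycling during succinate protocols acidifies the matrix unphysically.

## Parameters

Extrinsic maximal rates (`Vmaxf_*`, `Tmaxf_*`) are the published
lung-specific estimates (e.g. PDH 307, ANT 523.9, proton leak 36
nmol·min⁻¹·mg⁻¹ at 30 °C) and are never altered by the package defaults.
Intrinsic constants — binding constants and pH-7 equilibrium constants —
are tissue-independent quantities whose source-of-record (isolated-enzyme
fits) is not reproduced here; the shipped defaults start from standard
literature/thermodynamic-table values and were calibrated **once**, as a
set, so that the integrated network reproduces the reported physiology of
isolated rat lung mitochondria:

* state-2 membrane potential near 140 mV at 23 °C with the tightly
  coupled preparation (leak scale 0.40);
* with 5 mM pyruvate + 5 mM malate at 30 °C: pyruvate uptake ≈ 10 and
  OCR ≈ 12 nmol·min⁻¹·mg⁻¹, citrate release carrying ≈ 80% of the carbon
  taken up, and ≈ 1.2 O2 consumed per pyruvate;
* succinate respiring faster than pyruvate+malate in every state, no
  respiratory reserve over ADP-stimulated state 3, non-additive
  convergent electron flow, and an inverse leak–RCI relationship.

Three kinetic choices deserve explanation. (1) CITDH (lumped aconitase +
NAD-isocitrate dehydrogenase) keeps NAD/NADH in its denominator with
$K_{NADH}$ = 4.7 µM: this strong product inhibition is the mechanism
behind the functionally incomplete TCA cycle — most carbon leaves as
citrate because reduced pyridine nucleotides switch CITDH off. (2) PDH
and MDH likewise use a saturable high-affinity NAD site instead of the
shared-site pair; this makes NADH supply inelastic at high NAD, so
uncoupling reveals no reserve capacity over state 3, matching the
experimental conclusion that the rate-limiting steps sit downstream of
complexes I/II. (3) ANT uses high-affinity external-ADP and matrix-ATP
sites and weak trans-side product binding, giving the sharp state-3 →
state-4 transition seen in oxygraph traces.

The citrate-release bookkeeping is carbon-based:
$6J_{CIT}/(3J_{PYR}+4J_{MAL})$. On a molar basis the release could never
reach 80% of the summed uptakes, since each citrate consumes one
malate-derived oxaloacetate and one pyruvate-derived acetyl-CoA; with
$J_{CIT}\approx J_{PYR}\approx J_{MAL}$ the carbon ratio is 6/7 ≈ 0.86,
and ≈ 0.8 once a fraction continues past citrate.

## Protocols and observables

`simulate_protocol()` integrates the stiff system with `deSolve::lsoda`
(relative tolerance $10^{-8}$, per-state absolute tolerances), restarting
at each timed addition; additions are instantaneous buffer concentration
steps with no volume change (Hamilton-syringe volumes are negligible).
FCCP is not a chemical species but a step of the leak scale to 7, the
uncoupling strength estimated for 2 µM FCCP. Mitochondria are "added" at
t = 0 with resting matrix contents (ADP-rich, moderately oxidized) and a
0.5-minute pre-equilibration precedes substrate addition in the canonical
protocols.

`respiration_summary()` measures state 2 on the pre-ADP interval; state 3
on the steep central ADP-consumption phase (90% → 40% of the dose
remaining — the linear segment an oxygraph trace would be fit on); state 4
after buffer ADP falls below 1% of the dose (configurable). Both RCI
conventions (state3/state4 and state3/state2) are reported because both
are used in the respirometry literature.

The rhodamine-123 probe adds two states driven by the GHK flux with
permeability 1.38 mol·(l mito)⁻¹·s⁻¹·M⁻¹ and apparent volumes (matrix
2.25 µl/mg; buffer volume as-is) that absorb matrix binding; the dye does
not feed back on $\Delta\Psi_m$, appropriate at 200 nM loading where
quenching is negligible and fluorescence is linear in concentration.

## Estimation and identifiability

The fitting objective is the dataset-size-weighted sum of squared
relative residuals
$f=\sum_j N_j^{-1}\sum_i ((x_{ij}-X_{ij})/X_{ij})^2$. Extrinsic rates are
estimated with a seeded real-coded genetic algorithm in log10 space
(tournament selection, BLX-α crossover, Gaussian mutation, elitism 2;
population 50 and 200 generations by default, all configurable) with an
optional Levenberg–Marquardt polish of the residual vector at tightened
solver tolerances (the genetic search supplies the basin; the quadratic
local step supplies the precision — finite-difference Jacobians taken at
the relaxed fitting tolerances are noise-dominated near the optimum).
Intrinsic binding constants are fitted to
isolated-enzyme initial-rate curves by Levenberg–Marquardt least squares
in log space (`fit_intrinsic_ls()`); the maximal rate estimated there is
a nuisance parameter, since isolated-enzyme activities do not transfer to
the integrated tissue model.

Normalized sensitivities $S_{\theta_i}=(\theta_i/E)\,\partial E/\partial
\theta_i$ use central differences with a 0.1% perturbation; the parameter
correlation matrix is $CC_{ij}=HH_{ij}/\sqrt{HH_{ii}HH_{jj}}$ with
$HH=(J^TJ)^{-1}$ from the finite-difference residual Jacobian
(pseudo-inverse with a warning if rank-deficient). The proton-leak rate
carries the largest sensitivity — it is the only energy sink in state 2 —
while carriers absent from a protocol (e.g. GLUH without glutamate) have
essentially none.

`recovery_harness_datasets()` builds the desk-scale parameter-recovery
exercise: noiseless synthetic O2 traces for the pyruvate+malate *and*
succinate protocols. A single trace is not enough — the genetic algorithm
then finds near-perfect fits with badly wrong parameters, the same
sloppiness the correlation matrix quantifies (e.g. the PDH/pyruvate-carrier
pair); the two-protocol design pins the five most sensitive parameters to
within a few percent.

## What the synthetic generator does and does not emulate

`generate_synthetic_respirometry()`, `generate_synthetic_tca_uptake()` and
`generate_synthetic_r123()` sample deterministic simulations at a stated
cadence and apply multiplicative Gaussian noise (matching the relative
residual objective), reproducibly under a seed. They emulate the *shapes*
of real experiments — state-2/3/4 oxygen kinetics, saturating substrate
dependence of uptake/release rates, ADP-evoked dye transients — under the
model's own dynamics. They do not emulate instrument drift, mixing
artifacts at additions, preparation-to-preparation variability of
mitochondrial quality, or any process missing from the model itself
(Ca²⁺/Mg²⁺ regulation, ROS production, fatty-acid oxidation, pyruvate
carboxylase — all absent by design, the first as a stated limitation, the
others because they are inactive in BSA-containing isolated lung
mitochondria preparations). Passing recovery tests on synthetic data
therefore demonstrates correctness of the estimation machinery and
internal identifiability, not fidelity of the model to any particular
laboratory's traces.

## Numerical choices and problem sizes

The right-hand side is evaluated by a compiled (C++) engine mirrored by a
pure-R reference implementation; a test pins their agreement at 1e-10.
Stiffness comes from near-equilibrium reactions (NDK at $V_{max}\sim
4\times10^6$, fumarase) and from ATP-synthase reversal at low potential;
`lsoda` with the default tolerances integrates a 10-minute protocol in a
fraction of a second, and halving the tolerances changes reported OCRs by
well under 0.1%. Fitting simulations run at relaxed tolerances
($10^{-6}/10^{-8}$), which is why closed-form objective oracles are
checked at the generator's tighter tolerances. The shipped GA exercises
use a population of 16 over 12 generations on 6-minute protocols,
followed by the Levenberg–Marquardt polish — sized for an interactive
desk check; production fits should scale these up via `ga_opts`.

Degenerate inputs are handled explicitly: zero concentrations are valid
(fluxes clamp at zero substrate), zero-valued observations are excluded
from relative residuals with a warning, negative fluorescence clips to
zero with a warning, unknown parameter names and non-identifiable designs
are errors, and integration failures report the offending flux and the
last good state.

## Known limitations

Constant metal-ion concentrations; no ROS or fatty-acid pathways; a
single effective matrix-pH homeostasis parameter; apparent (not
microscopic) kinetic constants throughout, so individual binding
constants should not be over-interpreted; equilibrium constants of the
respiratory complexes partition the redox span between the paired-species
poises and are calibrated jointly with them; and the model describes the
average mitochondrion of a whole-lung isolate, not any single cell type.
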