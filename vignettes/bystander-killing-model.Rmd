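---
title: "Modeling bystander killing by ADC payloads: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bystander killing by ADC payloads: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(bystandr)
```

## The problem

Antibody-drug conjugates (ADCs) deliver a cytotoxic payload selectively to
tumor cells that display the antibody's target antigen (Ag+ cells). For
membrane-permeable payloads such as MMAE, payload released inside an Ag+
cell can leak into the extracellular space and enter neighbouring
antigen-negative (Ag-) cells, killing tumor cells the antibody itself never
touched — the *bystander-killing effect*. Whether this effect materially
changes tumor growth inhibition (TGI) depends on three quantities this
package lets you explore: the intracellular dose `C0`, the efflux-to-influx
ratio `k = k_out / k_in` of the payload across cell membranes, and the Ag+
fraction `beta` of the tumor.

`bystandr` implements three coupled model layers, each exposed as
tibble-returning simulation functions:

1. a **closed three-compartment payload-exchange system** (Ag+ cells, Ag-
   cells, extracellular space);
2. a **two-population Emax-coupled TGI model**, one tumor compartment per
   antigen status, with bystander killing switchable on/off;
3. an **Erlang age-structured TGI model** (linear-chain ODE reduction plus
   a renewal-integral reference solver) that adds the inhibition delay the
   memoryless model cannot produce.

## Payload exchange

With `C_int_p`, `C_int_n`, `C_ext_p` the payload concentrations (nM) in
Ag+ cells, Ag- cells and the extracellular space,

$$
\begin{aligned}
\dot C_{int,p} &= \beta k_{in} C_{ext,p} - k_{out} C_{int,p},\\
\dot C_{int,n} &= (1-\beta) k_{in} C_{ext,p} - k_{out} C_{int,n},\\
\dot C_{ext,p} &= -k_{in} C_{ext,p} + k_{out}(C_{int,p} + C_{int,n}),
\end{aligned}
$$

from the initial state $(C_0, 0, 0)$: the whole dose starts inside Ag+
cells, as after direct intracellular release. The system is closed — the
three derivatives sum to zero, so total payload is conserved — and linear,
so `payload_closed_form()` evaluates the exact matrix-exponential solution
while `simulate_payload()` integrates numerically (`deSolve::lsoda`,
`rtol = 1e-8`, `atol = 1e-10`); the closed form is the ground truth the
numerical route is tested against.

Three structural facts drive everything downstream:

* **Conservation.** $C_{int,p}+C_{int,n}+C_{ext,p}=C_0$ for all $t$.
* **beta-independence of the total.** $S = C_{int,p}+C_{int,n}$ obeys
  $\dot S = k_{in} C_{ext} - k_{out} S$, which contains no $\beta$. A TGI
  model driven by the *total* intracellular payload therefore cannot
  distinguish tumor compositions — the reason the package drives each
  tumor population by its *own* concentration (the total-drive variant is
  retained as a diagnostic, `drive = "total"`).
* **Equilibrium.** For $k_{out}>0$ the system relaxes to
  $\left(\tfrac{\beta C_0}{1+k},\ \tfrac{(1-\beta)C_0}{1+k},\
  \tfrac{k C_0}{1+k}\right)$. At the reference setting ($k=2$,
  $\beta=0.7$, $C_0=200$ nM) this is 46.7 / 20 / 133.3 nM: about 50 nM in
  Ag+ cells, 20 nM in Ag- cells, a 70 nM intracellular total.

```{r payload}
params <- payload_params(k_in = 1, k_out = 2, beta = 0.7, C0 = 200)
payload_equilibrium(params)
```

One subtlety the tests pin down: although slower efflux always means more
payload in Ag+ cells, the Ag- compartment fills *through* the
extracellular pool, so for roughly the first day a larger `k_out` puts
*more* payload into Ag- cells, not less. The familiar "smaller k, higher
concentrations" ordering holds only after the pool has equilibrated
(time constant $1/(k_{in}+k_{out})$).

### Units and rate conventions

All simulations run on a day scale. Literature membrane-transport rates
for auristatin payloads are per-minute (`literature_rates`;
$8.46\times10^{-2}$/min converts to 121.824/day via
`convert_rate_minutes_to_days()`). Because influx on that scale is far too
fast to resolve the transient of interest, simulations use the
conventional normalization $k_{in} = 1$/day with the ratio $k$ as the
knob, and $k \in \{1,2,3\}$ as the sweep. The published day-scale efflux
value ($5.9357\times10^4$) is inconsistent by a factor of 1000 with the
per-minute rate it is derived from, and the published ratio 2.0442 is
inconsistent with the per-minute rates (which give $k<1$); the package
does not attempt to resolve this and simply treats $k$ as configurable
with default 2. `beta` is implemented literally as the Ag+ fraction.
`beta = 0` is rejected at construction: the initial dose lives in Ag+
cells, so a tumor without them leaves `C0` undefined.

## Dose response and the two-population TGI model

The inhibitory Emax (Hill) function maps intracellular payload to a growth
response,

$$E(c) = E_0\left(1 - \frac{E_{max}\, c^{\gamma}}{IC_{50}^{\gamma} +
c^{\gamma}}\right),$$

decreasing from $E_0$ at zero payload to $E_0(1-E_{max})$ at saturation,
with the half-maximal effect exactly at $c = IC_{50}$ for any $\gamma$.
Defaults: $E_0 = 120$ nM, $E_{max} = 0.6931$ (treated as a dimensionless
fraction), $IC_{50} = 300$ nM, $\gamma = 1$. Each tumor population then
follows

$$\dot T_i = c\,E(C_i)\,F(T_i)\,T_i - \lambda T_i,$$

with $F = 1$ (exponential) or $F = 1 - T_i/T_{max}$ (logistic, the
default), $c = 4.6\times10^{-3}$ per (nM day), $\lambda = 0.5$/day,
$T_0 = 1000$ mm³ split as $(\beta T_0, (1-\beta)T_0)$, and
$T_{max} = 2\times10^4$ mm³. The drug-free growth rate is
$c E_0 = 0.552$/day, a net $+0.052$/day against degradation — so an
untreated tumor grows, and `net_growth_rate()` classifies any payload
level into growing/decaying/critical regimes (tolerance $10^{-9}$/day,
configurable, since the boundary is otherwise a measure-zero event).
`critical_efflux_ratio()` finds the efflux ratio at which the
*equilibrium* payload sits exactly on that boundary (about $k = 3.24$
at the defaults) by bracketed root finding.

Coupling is strictly one-way: payload concentrations never see tumor
size (the exchange equations contain no $T$ terms, consistent with
concentrations rather than amounts), so the payload subsystem can be
solved independently — which the renewal solver exploits.

Bystander killing is switched off by forcing $k_{out}=0$: the payload is
trapped in Ag+ cells (which are then maximally suppressed) and never
reaches Ag- cells (which then grow at the exact drug-free rate — the
package tests this against the scalar closed form). The off-state
populations are conventionally labelled $T_3, T_4$; `bystander_gap()`
computes $100\,\big((T_3{+}T_4)-(T_1{+}T_2)\big)/T_0$, the extra
suppression attributable to bystander killing as a percentage of the
initial tumor. At the defaults this series is initially at or below zero
— leaking payload out of Ag+ cells costs direct killing before the Ag-
benefit has compounded — and crosses into a genuine benefit after roughly
a month.

### Capacity sharing under logistic growth

How two "independently growing" populations share one carrying capacity
is genuinely underdetermined. The default applies $F_i = 1 - T_i/T_{max}$
with the full $T_{max}$ to each population; `capacity = "proportional"`
instead allots $\beta T_{max}$ and $(1-\beta)T_{max}$. The default was
chosen because it treats the populations symmetrically and keeps the
$\beta \leftrightarrow 1-\beta$ comparison clean; the alternative is one
flag away.

### How symmetric is $\beta \leftrightarrow 1-\beta$?

Mirrored runs ($\beta = a$ and $\beta = 1-a$) have *identical* equilibrium
compositions — the same pair of (size, concentration) combinations — so
their total-tumor curves track each other closely. They are not identical:
during the payload transient the large population of one run is overdosed
(concentration falling from $C_0$) while the mirrored large population is
underdosed (rising from 0). That transient asymmetry leaves a persistent
multiplicative offset that grows with $|1-2\beta|$: about 1% for
$0.4/0.6$, about 5% for $0.1/0.9$ at the defaults, bounded near 10% by
the maximal response difference ($c\,(E(0)-E(C_0)) \approx 0.15$/day)
acting over the pool's relaxation time. The tests assert 2% agreement for
the near-balanced pair, the monotone growth of the offset towards extreme
splits, and the 10% bound.

## The age-structured layer: why and how

The memoryless TGI model reacts to payload instantaneously, so a 200 nM
dose suppresses growth from $t=0$ — but treated tumors are observed to
keep growing for a few days before inhibition takes hold, as the
payload-tumor interaction passes through intermediate stages. The package
models the stage transit time as an Erlang random variable (integer shape
$n$, rate parameter $\theta$ in days per stage; mean lag $n\theta$),
giving the distributed-delay growth equation

$$\dot T = \int_0^{t} c\,\phi(a)\,E(t-a)\,F(t-a)\,T(t-a)\,da + h(t)
  - \lambda T,$$

where $\phi$ is the Erlang density and $h(t)$ carries the pre-dose
history (below). The killing term stays instantaneous; only the
*growth* machinery is delayed, and the payload subsystem remains
memoryless — the lag models drug-tumor interaction stages, not payload
transport. `erlang_pdf()`, `erlang_survival()` and `hazard_rate()` expose
the kernel; the hazard $\gamma(a) = \phi(a)/\Phi(a)$ is evaluated as a
log-space ratio so the far tail neither under- nor overflows, and
satisfies $\Phi' = -\gamma\,\Phi$ (tested by central differences).

Because the kernel is Erlang, the integro-differential equation reduces
*exactly* to a chain of $n$ ODE stages (`chain_rhs()`,
`simulate_age_structured()`): the drive $c\,E\,F\,T$ enters stage 1 and
emerges from stage $n$ after the Erlang lag. `renewal_integral_reference()`
solves the integral form directly — uniform grid, trapezoidal history
convolution, Heun stepping — and serves as the independent oracle for the
chain reduction; the two agree to better than $10^{-3}$ sup-norm relative
error for $n \in \{1,2,5,10\}$ over 30 days at the default step
$\theta/40$ (the solver is second-order, and the step was set so that
even the steep $n=1$ kernel is well resolved; steps coarser than
$\theta/10$ are rejected).

### Initialization: the decision that makes or breaks the delay

What was the tumor doing *before* $t=0$? Three self-consistent answers
are implemented, as paired chain initializations and renewal history
terms:

| `chain_init` | chain state at $t=0$ | `history` | $h(t)$ |
|---|---|---|---|
| `"steady"` (default) | every stage at $\theta\,c\,E_0 F(T_0) T_0$ | `"steady"` | $c\,E_0 F(T_0) T_0\,\Phi(t)$ |
| `"paper"` | stage 1 at $c\,E_0 T_0$, rest empty | `"impulse"` | $c\,E_0 T_0\,\phi(t)$ |
| `"zero"` | empty chain | `"none"` | $0$ |

Each pairing is *exactly* equivalent (the homogeneous chain response to
the steady initialization is $c E_0 F_0 T_0 \Phi(t)$; to the stage-1-only
initialization, $c E_0 T_0 \phi(t)$), and all three pairings are tested.
The default is the steady pre-treatment history: it is the only
convention under which the model shows the delay phenomenon it exists
for. With an empty or stage-1-only chain and $n$ large, the growth flux
$F_\phi^n/\theta$ starts near zero and the tumor *decays* at rate
$\lambda$ from the first instant — the opposite of the observed initial
growth. Under the steady initialization the tumor keeps growing at its
pre-treatment net rate until the suppressed response works through the
chain, rises above $T_0$ for an initial interval despite the dose, peaks,
and only then turns over; the long-run regime matches the memoryless
classification. The stage-1-only convention is retained as `"paper"`
because it is a printed convention in the TGI delay literature; note its
initial value $c E_0 T_0$ is dimensionally inconsistent with the
$\theta^{\,n-1}$ unit normalization the chain variables carry, so both
are implemented literally as numerics.

The shape is not a measured quantity; the package defaults to $n = 20$ so
that the mean lag $n\theta = 2$ days matches the observed duration of the
initial growth phase at $\theta = 0.1$ d. This is an inference, not a
fact, and `n_shape` is a first-class configuration key. Whether the delay
layer runs on logistic or exponential $F$ is likewise configurable;
logistic is the default throughout. Two limits anchor the construction:
at $n=1$ with the first stage quasi-steady the chain collapses to the
memoryless model, and as $\theta \to 0^+$ (at $n=1$) the trajectories
converge to it (tested at $\theta \in \{0.1, 0.01, 0.001\}$).

```{r delay}
aged <- simulate_age_structured(payload_params(), dose_response_params(),
                                tumor_params(), age_params(),
                                times = seq(0, 15, by = 0.05))
glance(aged)[, c("T_total_min", "peak_time_days")]
```

## Scenarios, reproducibility, degenerate inputs

`scenario_config()` bundles a full run; YAML/JSON files round-trip
losslessly through `load_config()`/`save_config()`, unknown keys are
rejected by name, and field validation reuses the constructors so error
messages state the violated constraint. `run_scenario()` dispatches on
the presence of an age structure and can return a bystander on/off pair
with its gap. `run_figure()` provides the four built-in sweeps (payload
by $k \times \beta$; TGI by $\beta$; paired bystander runs by $\beta$;
the paired age-structured run). The pipeline contains no randomness;
identical configurations produce byte-identical CSV exports.
`add_measurement_noise()` (seeded lognormal, off by default) exists only
as a downstream-testing convenience.

Numerical choices worth knowing: solver tolerances default to
`rtol = 1e-8`, `atol = 1e-10`; concentrations in $[-\text{atol}, 0)$ are
clamped to zero on output while deeper undershoots raise an integration
error; tumor-state clamps use $\sqrt{\text{atol}}$ on the mm³ scale. The
default output grid is 0.1 d over a 60 d horizon (payload analyses use
30 d, by which the transient has decayed to $\sim e^{-90}$); the
chain↔renewal comparisons run on 15–30 d horizons at step $\theta/40$,
sizes at which the whole test suite completes in well under a minute.
Degenerate cases: `k_out = 0` makes the payload equilibrium question
ill-posed (`payload_equilibrium()` errors and callers branch on the
bystander flag); `beta = 1` zeroes the Ag- influx route exactly;
`Emax = 1` with saturating payload leaves pure degradation.

## What the built-in scenarios do and do not show

Everything here is an in-vitro-style idealization: the extracellular
space has no clearance or volume term (the payload system is closed,
which is precisely what makes the total conserved and the
$\beta\leftrightarrow 1-\beta$ comparison meaningful), dosing is a single
instantaneous intracellular release rather than ADC
internalization/cleavage kinetics, there is no ADC-target binding, no
drug-antibody-ratio bookkeeping, and no spatial structure — the two
populations are well-mixed compartments. Passing tests therefore validate
the model's internal mathematics (conservation, equilibria, oracle
equivalences, orderings), not its fidelity to any animal experiment.
Parameter estimation from data is out of scope; all parameters are
scenario inputs.
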