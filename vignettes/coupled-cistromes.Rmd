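---
title: "Branching-process dynamics of coupled cistromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching-process dynamics of coupled cistromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbp)
```

## The model

`tfbp` treats the expression of one transcription factor (TF) as a branching
process bounded by its cistrome.  A cistrome is summarised by two counts
derived from ChIP-seq data binned into fixed-width genome segments: `p`
segments carry at least one binding site for the TF, and `r` of those are
*producing* — when activated they transcribe further TF.  The remaining
`p - r` segments bind TF but produce none: they are pure absorbers.

One synchronous timestep does three things, for each cistrome:

1. every segment active at `t` emits `m` TF units and deactivates;
2. each unit lands independently and uniformly on one of the cistrome's `p`
   segments (landing on the emitting segment itself is allowed — nothing in
   the abstraction distinguishes it);
3. producing segments hit by at least one unit are active at `t + 1`
   (multiple hits collapse into a single activation, and a segment that
   emitted at `t` may be re-activated by units landing in the same step).

Extinction (`s_t = 0` everywhere) is absorbing.  In the noiseless infinite
limit a unit activates a producing segment with probability `r/p`, so the
single-cistrome process is critical at `m = p/r`.  Finite systems are noisy:
the one-step expectation given `s` active segments is the occupancy mean
`r * (1 - (1 - 1/p)^(s*m))`, and the observed integer critical value sits
above `p/r` because fluctuations around the small quasi-stationary activity
level find the absorbing state.

Cistromes interact only constructively here, through shared producing
segments (`sigma` per pair): a producing segment present in two cistromes is
a conduit that can hand a TF to the partner.  Inhibitory binding,
combinatorial activation, TF half-lives beyond one step, expression-strength
weights and spatial genome structure are all out of scope.

## Transfer modes

How a shared segment hands TF across is a genuine modelling freedom, and the
package implements the two natural readings:

* **`meanfield`** (default).  A unit landing on a shared segment transfers
  to one partner (uniform among the segment's partners) and activates the
  *counterpart* segment there; it does not activate the source segment.
  This makes the exact one-step expectation match the infinite-limit
  recursion
  `s'_X = s_X m_X (r_X - sigma)/p_X + s_Y m_Y sigma/p_Y`,
  whose own-activation term uses only the non-shared producing fraction.
  All closed-form criticality results refer to this recursion, so the
  default engine and the analytic layer agree by construction.

* **`two_site`**.  Every segment carries a primary site for own-cistrome TF
  and a single secondary site for one incoming foreign TF.  Own landings
  occupy primaries; each occupied primary on a shared segment then copies a
  TF to the secondary site of a counterpart whose secondary is still free
  (at most one foreign TF per segment per step, resolution order randomised)
  and a segment with either site occupied is active next step.  Here the
  source segment stays active, so shared segments contribute to both
  cistromes; this variant is the sensitivity check, and is slightly more
  supercritical than `meanfield` at equal parameters.

Whether a transfer is a move (the source gives the TF up) or a copy (the
source keeps it) cannot be settled by the abstraction itself; `meanfield`
realises the move, `two_site` the copy.  Every coupled result reported by
the test suite reproduces under the default mode, so the choice is not
load-bearing for the headline phenomena.

Accounting (`run_branching(record_accounting = TRUE)`) audits the flows:
in `meanfield` mode `emitted = own_hits + transferred + absorbed` holds as
an exact integer identity per cistrome and step; in `two_site` mode
transfers are copies, so the landing balance is
`emitted = own_hits + absorbed` with transfers reported separately.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `m` | TF units emitted per active segment per step | swept; integers |
| `s0` | initially active producing segments | `r` (fully saturated) |
| `timesteps` | horizon `T` | 1000 |
| `n_runs` | ensemble size per `m` | 200 |
| `sigma` | shared producing segments per pair | from data (see below) |
| `bin_size` | genome window for BED import | 50,000 bp |

The defaults are the study conditions under which the bundled mouse ESC
results were established: 200 runs of 1000 timesteps, target started at
`s0 = r`, partners held at their own observed critical values, integer `m`
sweeps, and the *any-survivor* rule (`m_crit` = smallest swept `m` with at
least one run active at `T`).  A survival-fraction threshold rule is exposed
for sensitivity analysis because no numeric cut-off beyond "any survivor"
is conventional.  `m` is an integer in all classic sweeps; fractional `m`
is honoured by emitting one extra unit with probability `frac(m)` per
active segment.  Initial activation is irrelevant to the estimates
(`s0 = r` and `s0 = r/2` give identical critical values; the suite checks
this), which is why saturation is a safe default.

The bundled `cistrome_preset("mouse_esc")` system fixes
Nanog (4316, 631), Sox2 (3330, 542), Oct4 (2540, 466), cMyc (2961, 864)
with pairwise shared counts 287/194/265/237/252/268 — segment counts from
ChIP-seq of mouse embryonic stem cells in serum + LIF, binned at 50 kb.
For BED import the window width is exposed because published descriptions
of such grids vary (50 kb and 100 kb are both in circulation); the dynamics
depend only on the resulting counts, never on coordinates.

## Segment layouts and the shared-pool structure

`generate_layout()` materialises counts into explicit segment indices with
a seeded, recorded assignment.  Pairwise shared sets are mutually disjoint
by default — only pairwise overlap counts are usually available from
ChIP-seq intersections, and publishing triple overlaps is rare — but an
explicit pool specification (`pools =`) accepts segments shared by three or
more cistromes, in which case transfer partners are drawn uniformly among
the pool members (`meanfield`) or among members with a free secondary site
(`two_site`).

Disjointness has one notable consequence for the bundled system: Nanog's
pairwise overlaps sum to 287 + 194 + 265 = 746 > r = 631, so no disjoint
layout of all four cistromes exists at once.  That is not a defect of the
counts — they are a valid set of pairwise intersections with triple
overlaps unpublished — so the system object is accepted and fully usable
for mean-field analysis, and the infeasibility error is raised only by
`generate_layout()`.  Every simulation experiment couples at most three
cistromes (the largest combination studied), which is always feasible.

The engine itself consumes only the partition *counts*; which indices are
shared cannot affect any distribution (the suite verifies trajectories are
bit-identical across relabelled layouts and that counts round-trip through
`layout_params()` exactly).  The explicit indices exist for introspection
and for the brute-force reference simulator.

## Random numbers and reproducibility

The compiled engine uses a self-contained xoshiro256++ generator seeded via
splitmix64, never touching R's RNG.  Each (run, cistrome-name) pair gets
its own substream derived from the master seed, and transfer-resolution
draws use a separate per-run substream.  Two consequences matter:

* results are bit-reproducible given the master seed, across platforms and
  regardless of the surrounding R session;
* with `sigma = 0` a cistrome's substream consumption is independent of the
  rest of the system, so an uncoupled multi-cistrome run is *bit-identical*
  to the corresponding single-cistrome runs — the decoupling test asserts
  equality, not similarity.

The brute-force reference (`brute_force_step()`) deliberately uses R's RNG
and a per-TF-unit event loop over explicit segment ids, sharing no code or
random stream with the engine; engine and reference are compared in
distribution (chi-squared on one-step activation counts, both modes,
10,000 replicates) on layouts small enough for the naive loop.

## Numerical choices

* Critical-value tables are computed at full precision and rounded half-up
  to one decimal only for presentation, the convention used for such
  tables (`round` half-to-even would turn 4.95 into 4.9 silently).
* `coupled_critical_m()` refuses a vanishing denominator (the closed form
  has a pole where the held partner exactly sustains the pair) rather than
  returning an infinity.
* The closed form is cross-checked against an independent root-finder on
  the dominant eigenvalue of the 2x2 update map; for three or more
  cistromes, where no closed form is available, criticality is *defined*
  by spectral radius 1 of the general linear map (`meanfield_matrix()`,
  `critical_m_spectral()`) — a natural extension, not a published result.
* Sweeps demand bracketing: an all-surviving or all-dissipating sweep is an
  error, never an extrapolated estimate.
* Ensembles early-exit on global extinction (trajectories are zero-padded);
  accounting mode disables the shortcut so every step is audited.

## What the experiments show — and known limitations

At the bundled parameters the package reproduces: single-cistrome critical
values 8 (Nanog), 7 (Sox2), 6 (Oct4), 4 (cMyc); ignition of a dissipated
Nanog by Oct4 at its critical value (and vice versa) within a few
timesteps; and coupled reductions Nanog 8→7 (with Oct4), Oct4 6→5 (with
Nanog), Nanog 8→6 (Oct4 + Sox2), Nanog 8→6 (cMyc), Oct4 6→4 (cMyc), and
cMyc unchanged at 4 (with Oct4) — all under the default transfer mode, at
200 runs × 1000 steps (about six minutes of compute for the full suite on
one CPU).

Three honest caveats, all traceable to one mechanism — extinction from a
quasi-stationary state just above criticality is slow and fat-tailed:

* **Dissipation speed at `m_crit - 1`.**  For cMyc at `m = 3` (mean-field
  growth factor 0.875) every run dissipates within ~70 steps.  For Nanog at
  `m = 7` the factor is 1.023 — *marginally supercritical* — with a
  quasi-stationary level of only ~28 active segments; all 200 runs still
  dissipate before `t = 1000`, but the extinction-time tail reaches past
  `t = 800`, so "all runs die within 200 steps" does not hold there.
* **Seed sensitivity of the Nanog estimate.**  Because `m = 7` is marginal,
  roughly one master seed in eight produces at least one 1000-step survivor
  among 200 runs, in which case the any-survivor estimate reads 7 rather
  than 8.  The other three cistromes (whose `m_crit - 1` values are
  strictly subcritical) are seed-stable.
* **Scaling.**  Multiplying `p` and `r` by 10 leaves `p/r` — and hence the
  infinite-limit value — unchanged, but *lowers* the observed `m_crit`
  toward `ceil(p/r)`: the quasi-stationary activity scales with system size
  while relative fluctuations shrink, so marginal-`m` extinction within
  `T = 1000` becomes rare (scaled Nanog survives at `m = 7` in ~99% of
  runs).  Observed critical values are therefore size-dependent near the
  margin; only the infinite-limit value is truly scale-free.

Separately, the direction of the overlap effect deserves care: with a
partner held *above* its infinite-limit critical value, a coupled critical
value exists only once `sigma` exceeds the boundary `r_Y - p_Y/m_Y` (below
it the partner sustains the pair on its own); on the feasible range the
predicted value rises from 0 with `sigma` yet always stays below the
uncoupled `p_X/r_X`.  More overlap is not monotonically "more help": it
also cannibalises the target's own producing sites and drains the partner.

Finally, the synthetic systems are abstractions: segments are exchangeable,
landing is uniform, activation strengths are equal, and interactions are
purely stimulatory.  Passing tests demonstrate the internal consistency of
this branching abstraction and its mean-field theory at ChIP-seq-derived
parameter sizes — not that real regulatory networks behave quantitatively
like the model.
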