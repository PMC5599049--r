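# tfbp — coupled transcription-factor branching processes on cistromes

`tfbp` simulates and analyses the dynamics of transcription-factor (TF)
expression cascades as branching processes over *cistromes* — the genome-wide
sets of DNA segments bound by a TF.  It is aimed at systems biologists
studying self-organisation of gene regulatory networks, in particular the
core pluripotency network of mouse embryonic stem cells (Nanog, Oct4, Sox2
and the broadly binding cMyc), whose ChIP-seq-derived segment counts ship
with the package.

## The model

A cistrome is reduced to two counts: `p`, the number of genome segments
carrying at least one binding site for the TF, and `r ≤ p`, the number of
those segments that can be transcribed into further TF ("producing"
segments).  At every timestep each active producing segment emits `m` TF
units (the *branching parameter*) and deactivates; each unit lands uniformly
on one of the cistrome's `p` segments, activating producing segments for the
next step and being absorbed everywhere else.  The active-segment count
`s_t` therefore follows a density-dependent branching process that either
*dissipates* (`s_t → 0`, absorbing) or sustains itself.  In the noiseless
infinite limit the process is critical at

    m_crit = p / r

and finite noisy systems tip at a somewhat larger integer value, found by
sweeping `m` over ensembles of simulations.

Cistromes couple through shared producing segments (`σ` per pair): a TF
landing on a shared segment can transfer to the partner cistrome and
activate the counterpart segment there.  For two cistromes X and Y the
infinite-limit recursion is

    s'_X = s_X m_X (r_X − σ)/p_X + s_Y m_Y σ/p_Y   (and symmetrically for Y)

which, with Y held at `m_Y`, is critical at

    m_X = p_X (p_Y − m_Y r_Y + m_Y σ) / [ (p_Y − m_Y r_Y)(r_X − σ) + m_Y r_X σ ]

With `σ = 0`, or with Y at its own critical value `p_Y / r_Y`, this recovers
`p_X / r_X`; with Y held *above* its critical value, the surplus TF flux
lowers the critical value of X.  The stochastic engine reproduces three
phenomena: the existence of integer critical branching values per cistrome;
*ignition* of a fully dissipated cistrome by an active partner; and the
reduction of critical values under coupling.

## Worked example

```r
library(tfbp)
sys <- cistrome_preset("mouse_esc")
sys
#> <cistrome_system> 4 cistrome(s)
#>    name    p   r  p/r
#> 1 Nanog 4316 631 6.84
#> 2  Sox2 3330 542 6.14
#> 3  Oct4 2540 466 5.45
#> 4  cMyc 2961 864 3.43
```

Infinite-limit predictions, with each partner held at its observed critical
value (rows: held partner; columns: target cistrome):

```r
critical_table(sys, held_m = c(Nanog = 8, Sox2 = 7, Oct4 = 6, cMyc = 4))
#>        target
#> held    Nanog Sox2 Oct4 cMyc
#>   Nanog    NA  4.9  4.0  2.9
#>   Sox2    6.0   NA  4.6  3.1
#>   Oct4    6.3  5.6   NA  3.2
#>   cMyc    5.0  4.2  3.6   NA
```

Every entry is below the target's own `p/r`: an overdriven partner always
helps.  The stochastic critical value of a single cistrome comes from an
`m` sweep (200 runs × 1000 timesteps, "any survivor" rule):

```r
sw <- sweep_m(subset_system(sys, "Oct4"), "Oct4", m_values = 1:8,
              n_runs = 200, timesteps = 1000, seed = 1,
              stop_at_first_survivor = TRUE)
sw
#> <sweep_result> target Oct4 (200 runs x 1000 steps, mode meanfield)
#>  m survival_fraction n_runs
#>  1             0.000    200
#>  2             0.000    200
#>  3             0.000    200
#>  4             0.000    200
#>  5             0.000    200
#>  6             0.995    200
estimate_mcrit(sw)
#> <criticality_estimate> m_crit = 6 (rule: any_survivor) for Oct4
```

All 200 runs dissipate for `m ≤ 5`; at `m = 6` almost all sustain — the
observed critical value (6) sits just above the infinite limit (5.45).  A
critically branching cistrome can ignite a fully dissipated partner through
their 194 shared segments, and coupling lowers the partner's critical value:

```r
ignition_experiment(sys, driver = list(cistrome = "Oct4", m = 6),
                    driven = list(cistrome = "Nanog", m = 8),
                    n_runs = 50, seed = 1)
#> <ignition_result> Oct4 (m = 6, s0 = r) driving Nanog (m = 8, s0 = 0), sigma = 194
#>   ignited 100% of 50 runs (median time to ignition 1); survived to T: 100%

coupling_reduction(sys, "Nanog", list(list(cistrome = "Oct4", m = 6)),
                   m_values = 1:10, uncoupled_mcrit = 8, seed = 1,
                   stop_at_first_survivor = TRUE)
#> <coupling_reduction> Nanog coupled to Oct4@6: m_crit 8 -> 7 (reduction 1)
```

Cistrome systems can also be built from BED3 interval lists
(`import_bed()`, default 50 kb bins) or read/written as JSON or TSV
(`write_system_json()` and friends).  A command-line front end with
`sweep`, `ignite`, `couple` and `tables` subcommands is installed under
`inst/cli/tfbp.R`.

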