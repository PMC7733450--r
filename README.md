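# pureregen

Simulation and analysis of **self-regenerating cell-free gene expression**
in microfluidic chemostats.

A reconstituted transcription–translation mix (the PURE system) running in a
chemostat is continuously diluted: every 15 minutes, 20% of the reactor
volume is replaced by fresh energy, protein/ribosome and DNA solutions. The
mix can only keep working if it *regenerates* essential proteins — T7 RNA
polymerase, aminoacyl-tRNA synthetases — from supplied DNA templates faster
than dilution removes them. `pureregen` is for researchers studying such
systems: it simulates the reactor, scores self-regeneration performance the
way these experiments are scored, and computes the DNA doses needed to
sustain a protein at steady state.

## The model

The core is a seven-species, three-parameter resource-limited ODE model of
coupled polymerase (T) and reporter (G) expression. With the resource
availability factor $h(R) = R/(R+K)$:

$$
\dot m_i = \alpha\, d_i\, p_T\, h(R), \qquad
\dot p_i = \beta\, m_i\, h(R), \qquad
\dot R = -\bigl[\alpha(d_T + d_G)p_T + \beta(m_T + m_G)\bigr]h(R),
$$

for $i \in \{T, G\}$; DNA is inert between dilutions. The model is solved
between discrete dilution events that replace 20% of the volume from three
sequentially loaded feed segments (fresh-volume contributions 8% / 8% / 4%
for energy, protein and DNA solutions). A three-phase protocol — kick-start
(complete PURE, 0–4 h), self-regeneration (ΔPURE lacking the essential
protein, 4–16 h), washout (essential protein's template withheld, 16 h–end)
— reproduces the experiment design, with positive (reporter-only) and
negative (no template) controls.

At the calibrated defaults ($\alpha = \beta = 0.1\,\mathrm{min}^{-1}$,
$K = 0.1$), a polymerase-template titration shows the three hallmark
regimes: washout at low $d_T$, reporter output *above* the positive control
at medium $d_T$ (resource reallocation from transcription to translation),
and suppressed output with a transient washout peak at high $d_T$. An
alternative shared-enzyme kernel (`resource_independent_rhs`) reproduces the
titration optimum but can never exceed the positive control — the
discriminating prediction between pure competition and resource limitation.

Analysis metrics: positive-control normalization, dilution-corrected
synthesis rates, SR/PC ratio at 15 h, regeneration duration, robustness
(duration / 24 h, capped at 1), yield (late self-regeneration mean),
theoretical maximal yield under proportional DNA allocation, washout-peak
detection, and Pareto fronts of yield vs. robustness.

## Worked example

```r
library(pureregen)

# dilution mathematics of the canonical schedule
dilution_schedule()
#> Dilution schedule: 20% replaced every 15 min
#>   dilution rate mu = 0.014876 / min, residence time = 67.2 min, dilution time t_d = 46.6 min

# full titration run: positive + negative controls and three
# self-regeneration experiments at the calibrated template levels
res <- run_from_config(default_run_config(seed = 1))
res$metrics[, 1:5]
#>   experiment     yield regeneration_duration_h robustness sr_pc_ratio
#> 1        low 0.4740499                    9.50  0.3958333   0.2443030
#> 2     medium 1.7737006                   15.75  0.6562500   1.7454649
#> 3       high 0.3622726                   15.75  0.6562500   0.3717182
```

Reading the table: at the `low` template level the reporter is washing out
during self-regeneration (SR/PC = 0.24 at 15 h, regeneration ceases after
9.5 h). At `medium`, output exceeds the positive control (SR/PC = 1.75) —
the resource-reallocation signature. At `high`, expression is suppressed
(SR/PC = 0.37) by resource loading. Durations of 15.75 h are the maximum
measurable in this 20 h run (the default protocol ends 4 h into washout;
robustness 0.66 is therefore a lower bound here, and the washout peak at
high template develops on longer runs — see the vignette). The eGFP channel
carries the default 2% simulated measurement noise; `yield` is the mean
normalized reporter level over the last 4 h of self-regeneration.

```r
# DNA dose needed to hold 100 nM of a synthetase against dilution,
# given a reporter reference: 10 nM/min synthesis from a 2 nM template
mu <- dilution_rate(0.2, 15)
min_dna_input(c_min = 100, mu = mu, rate_ref = 10, d_ref = 2)
#> [1] 0.2975247
```

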