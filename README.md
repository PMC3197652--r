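# reperfusim

Deterministic single-cell simulation of myocardial ischemia and
reperfusion in the guinea-pig ventricular myocyte, built for studying why
inhibiting the sodium–proton exchanger (NHE) fails to relieve the sodium
and calcium overloads of reperfusion.

## The science

During ischemia the myocyte acidifies, ATP and phosphocreatine collapse,
extracellular potassium accumulates in the isolated interstitium, the
resting membrane potential depolarizes and excitability fails.  On
reperfusion the acidic, hyperkalemic extracellular fluid is washed out,
restoring a transmembrane proton gradient: the NHE exchanges
intracellular H⁺ for Na⁺, the Na⁺/Ca²⁺ exchanger (NCX) converts the
sodium overload into a calcium overload, and the Na⁺/K⁺ pump (NaK) —
itself inhibited by the lingering intracellular acidosis — struggles to
clear the sodium.  Blocking the NHE blocks proton extrusion too, so
intracellular pH stays low for longer, the pump stays impaired, and the
intended benefit can invert.

`reperfusim` implements this cell as a *charge-difference* model: the
membrane potential is an affine function of the valence-weighted
intracellular ion content,

    V = (F / C_total) * ( Σ_s z_s n_s  −  n_offset )

with `n_s` the amounts of Na⁺, K⁺, total Ca²⁺ (free plus buffered, plus
the SR), Cl⁻, free and buffer-bound H⁺, OH⁻, HCO₃⁻ and the generic
conjugate anion of the imposed metabolic acid; the offset is calibrated
once so the initial state sits at −77.00 mV.  Around that core sit a
Luo–Rudy-dynamic-class current set, a thermodynamic-cycle SERCA (flux =
0.00820 × cycle rate), the four acid transporters with allosteric NHE
regulation (intracellular stimulation Hill 3, extracellular inhibition
Hill 1, shared binding constant), CO₂/bicarbonate kinetics in both
compartments, osmotic water flux with dynamic volumes, and imposed
ATP/PCr/osmolarity schedules.  The protocol is 5 min of 3-Hz pacing,
20 min of total ischemia, 10 min of reperfusion, integrated by forward
Euler at Δt = 0.005 ms; the NHE-inhibition grid scales NHE flux to 0.5
or 0 beginning at reperfusion, mid-ischemia, or ischemia onset
(R50/R0, M50/M0, I50/I0).

See the methods vignette (`vignettes/ischemia-reperfusion-model.Rmd`)
for the model's assumptions, every tunable constant, and the design
decisions taken where the component algebra was open.

## Worked example

A desk-scale run (time-compressed trajectories, see the vignette) of the
control and full-NHE-block scenarios:

```r
library(reperfusim)
params <- calibrated_parameters()
sched  <- protocol_schedule(pre_min = 5, isch_min = 5, rep_min = 2.5,
                            compress = 4)
grid   <- run_protocol_grid(c("control", "R0"), sched, params = params)
grid$summary[grid$summary$quantity == "Na_i", ]
```

```
#> # A tibble: 2 x 8
#>   scenario quantity  peak  mean end_ischemic end_reperfusion ratio normalized_ratio
#>   <chr>    <chr>    <dbl> <dbl>        <dbl>           <dbl> <dbl>            <dbl>
#> 1 control  Na_i      29.3  24.2         19.4            29.3  1.51             1
#> 2 R0       Na_i      26.7  22.9         19.4            26.7  1.38             0.911
```

Both scenarios start reperfusion from the same end-ischemic sodium load
(the ischemic segment is shared); the peak and mean columns summarize
the reperfusion window, and `ratio` is peak over end-ischemic sodium.
The full 10-minute reperfusion (the default schedule) lets the sodium
overload peak mid-reperfusion and then recede as pH recovery revives the
pump.
`sodium_ledger(grid$reperfusion$control)` breaks the reperfusion sodium
movement into the eight pathways (only the pump is negative), and
`autoplot(grid$reperfusion$control)` plots the time series.

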