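# smfret

Analysis of single-molecule FRET (smFRET) intensity trajectories, built
around the question of **which conformation of an E2~ubiquitin conjugate a
RING E3 ligase catalyses ubiquitin transfer from**. An E2~Ub conjugate
labelled with a Cy3B (donor) / AlexaFluor 647 (acceptor) pair reads out its
conformation as a FRET efficiency: ubiquitin folded back onto the E2 (the
"closed", catalytically primed arrangement) brings the dyes close and gives
high FRET, the open arrangement gives low FRET. Equilibrium imaging
quantifies how partner proteins (UEV, the RNF4 RING dimer) shift the
population between these states; real-time injection experiments watch
individual conjugates react and ask which state they react from.

The package is aimed at single-molecule biophysicists who have per-molecule
donor/acceptor trace tables (or dual-channel movies) and want a tested,
scriptable pipeline for:

* **FRET efficiency** per frame with spectral-leakage correction,
  `E = I_A / (I_D + α I_A)` with `α = 0.88` (12% donor bleed-through),
  plus the Förster relation `E = 1 / (1 + (r/R0)^6)` (`R0 = 60` Å);
* **population histograms** from first-ten-frame molecule averages,
  normalised to unit area;
* **Gaussian-mixture decomposition** of the population into low /
  intermediate / high FRET states (own EM, BIC model selection) and the
  fractional occupancy of each state;
* **per-frame state assignment** with hysteresis, and detection of rare
  interconversion events;
* **donor-acceptor cross-correlation**
  `G(τ) = Σ (I_D(t) − Ī_D)(I_A(t+τ) − Ī_A) / (N · mean(I_D·I_A))`;
* **event classification** for injection experiments — ubiquitin transfer
  (simultaneous dual-channel loss, no recovery) versus acceptor
  photobleaching (acceptor loss with donor recovery) versus donor
  photobleaching — with reacted fractions, dwell-time mono/biexponential
  fits, per-initial-state rates, time-windowed population contours and
  cumulative intensity curves;
* a **synthetic trajectory generator** (and dual-channel movie renderer +
  spot detection / registration / trace extraction) with full ground-truth
  labels, whose condition presets are calibrated to the published
  experiments so every stage is testable without any data download.

Everything is tidyverse-native: functions take a trace tibble
(`molecule_id`, `frame`, `time_s`, `I_D`, `I_A`) and return tibbles or
objects with `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Simulate the 12 °C equilibrium condition (41% closed-state occupancy) and
run the full population analysis:

```r
library(smfret)

sim <- simulate_traces(fret_presets("isopeptide_alone_12C"), 500, seed = 42)
res <- analyze_equilibrium(sim$traces)
res
#> <equilibrium_analysis> 475 molecules; 3 FRET states
#> # A tibble: 3 × 5
#>   state         mean     sd fraction percent
#>   <fct>        <dbl>  <dbl>    <dbl>   <dbl>
#> 1 low          0.359 0.0120    0.276    27.6
#> 2 intermediate 0.570 0.0137    0.267    26.7
#> 3 high         0.710 0.0128    0.457    45.7
#> dynamic molecules: 1.47%
```

The three fitted means recover the preset conformational states (0.36 /
0.57 / 0.71 apparent FRET); the high-state weight recovers the configured
41% closed-state preference within sampling error at n = 500; and about 1%
of trajectories show an interconversion event within the one-minute
observation window. `autoplot(res$fit)` draws the histogram with the
Gaussian components overlaid.

A real-time injection experiment, classified per molecule:

```r
rt  <- simulate_traces(fret_presets("thioester_reaction"), 270, seed = 7)
out <- analyze_realtime(rt$traces, injection_frame = 20, frame_interval = 1)
out
#> <realtime_analysis> 270 molecules
#> # A tibble: 6 × 4
#>   class                    n percent combined
#>   <chr>                <int>   <dbl> <lgl>
#> 1 acceptor_photobleach    64   23.7  FALSE
#> 2 donor_photobleach        3    1.11 FALSE
#> 3 transfer_FRET          156   57.8  FALSE
#> 4 transfer_donor_only     20    7.41 FALSE
#> 5 unreacted               27   10    FALSE
#> 6 transfer_combined      176   65.2  TRUE
#> transfer dwell rate(s): 0.043 /s

tidy(out$dwell_fit_transfer)
#> # A tibble: 1 × 4
#>   term    rate std.error amplitude
#>   <chr>  <dbl>     <dbl>     <dbl>
#> 1 k1    0.0430   0.00582      11.7
```

About 60% of conjugates undergo transfer (combined FRET-pair and
donor-only counts) with a fitted dwell rate of order 0.05 s⁻¹, against a
much slower photobleaching background; the UEV-only control preset yields
roughly 14%. `autoplot(out$contour)` shows the high-FRET column draining
over time while the other states persist — the signature that transfer
proceeds from the closed conformation.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "smfret.R", package = "smfret")` with `simulate`,
`equilibrium`, `realtime` and `presets` subcommands.

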