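# plor

Design and analysis of single-round "pause–restart" (PLOR) transcription
experiments in R.

PLOR — position-selective labeling of RNA — immobilises biotinylated DNA
templates on streptavidin beads and walks T7 RNA polymerase along them in
discrete steps, each supplied with only a subset of the four NTPs. Elongation
halts at the first template position requiring a missing nucleotide; rinsing
and a fresh NTP batch restart it. Run under single-round conditions on a
template carrying an intrinsic terminator (a GC-rich hairpin followed by a
U-tract), the ratio of terminated (T) to full-length (FL) product measures a
per-complex termination probability — which is how the method quantifies
riboswitch-controlled transcription termination.

The package handles the desk side of such experiments:

* **Transcript derivation** — locate the 17-nt T7 promoter consensus on
  either strand, emit the run-off transcript, annotate the terminator
  U-tract and the terminated product size.
* **Schedule design** — predict halt positions under included-NTP subsets,
  tile the transcript into per-step segments, and compute stoichiometric NTP
  batches: `[NTP] = (base count in segment) x [DNA] x fold`, with explicit
  overrides for the high-excess initiation step.
* **Inverse label placement** — find a minimal-step schedule confining a
  labeled NTP (e.g. Cy3-UTP) to exactly the requested transcript positions.
* **Quantification** — termination efficiency `T/(T+FL)` and read-through
  ratio `FL/T` from band-intensity tables, with replicate mean ± SD.
* **Yield model** — fit `E = Ei * Ee^n` (initiation efficiency, per-step
  elongation efficiency, `n = k − 1` post-initiation steps) by log-linear
  least squares.
* **Simulator** — seeded stochastic single-round transcription with
  ligand-dependent termination, emitting synthetic band tables.

## Worked example

The packaged fixture is an adenine riboswitch construct: a 155-nt template
with the T7 promoter on the reverse complement, and its published 8-step
schedule.

```r
library(plor)

tx <- derive_transcript(read_template(plor_example_template()))
tx$length
#> [1] 120
annotate_terminator(tx)
#> terminator U-tract at 101-108 (8 U); terminated product 100 nt

sched <- read_schedule(plor_example_schedule())
design_sheet(tx, sched)[, c("step", "included", "start", "end",
                            "A_uM", "C_uM", "G_uM", "U_uM")]
#> PLOR design sheet: 8 steps; products 100 nt (terminated) / 120 nt (full-length)
#> # A tibble: 8 × 8
#>    step included start   end  A_uM  C_uM  G_uM  U_uM
#>   <int> <chr>    <int> <int> <dbl> <dbl> <dbl> <dbl>
#> 1     1 A,G,U        1    14   400     0   600    64
#> 2     2 A,C,U       15    26    25    15     0    20
#> 3     3 A,G,U       27    39     5     0    35    25
#> 4     4 A,C,U       40    45    10    15     0     5
#> 5     5 A,C,G       46    52    10    10    15     0
#> 6     6 A,C,U       53    61    20    10     0    15
#> 7     7 A,G,U       62    66    10     0     5    10
#> 8     8 A,C,G,U     67   120    60    45    45   120
```

Step 1 carries its explicit initiation excess; steps 2–8 are the 1x
stoichiometric batches at 5 µM DNA — e.g. step 2 spans transcript positions
15–26 (5 A, 3 C, 4 U), hence 25 µM ATP, 15 µM CTP, 20 µM UTP. Step 4 is the
Cy3-UTP labeling step: its segment contains a single U, so 5 µM labeled UTP
suffices.

Simulate a single-round reaction at the no-ligand termination probability and
recover it from the emitted band table:

```r
sim <- simulate_single_round(tx, sched, sim_params(seed = 7))
sim$counts
#> # A tibble: 1 × 4
#>   initiated stalled terminated full_length
#>       <int>   <int>      <int>       <int>
#> 1     89755   46666      36509        6580
summarize_bands(emit_band_table(sim))
#> # A tibble: 1 × 6
#>   condition   n_replicates mean_efficiency sd_efficiency mean_ratio_FL_T
#>   <chr>              <int>           <dbl>         <dbl>           <dbl>
#> 1 adenine_0uM            3           0.847       0.00575           0.180
#> # ℹ 1 more variable: sd_ratio_FL_T <dbl>
```

A command-line front end over the same functions ships as
`system.file("scripts", "plor.R", package = "plor")` with subcommands
`derive`, `design`, `label-design`, `validate`, `quantify`, `simulate`,
`fit` and `efficiency`.

See `vignettes/plor-methods.Rmd` for the models, parameter choices and
limitations.

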