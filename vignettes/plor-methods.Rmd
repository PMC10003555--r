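---
title: "Models and design choices in plor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in plor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plor)
```

## The experiment this package models

PLOR (position-selective labeling of RNA) is a solid–liquid hybrid-phase
transcription in which biotinylated DNA templates are immobilised on
streptavidin beads and T7 RNA polymerase is walked along them in discrete
steps. Each step supplies only a subset of the four NTPs, so elongation halts
at the first template position requiring a missing nucleotide; rinsing removes
residual NTPs before the next batch restarts the polymerase. Because the
DNA:NTP ratio and temperature suppress re-initiation, each template yields at
most one transcript, and when the template encodes an intrinsic terminator —
a GC-rich hairpin followed by a run of consecutive U residues — the fraction
of terminated product is interpretable as a per-complex termination
probability. The packaged worked example is a transcription-regulatory
adenine riboswitch: a 120-nt run-off transcript whose terminator U-tract
starts at position 101, so termination releases a 100-nt product, and the
adenine ligand switches the RNA toward the anti-terminator (read-through)
fold.

## Sequence model

The promoter model is the 17-nt class-III T7 consensus `TAATACGACTCACTATA`
with transcription initiating at the next base (+1). Both the given strand
and its reverse complement are scanned; exactly one site across both strands
is required, and multiple sites are an explicit "ambiguous promoter" error
rather than a silent first-match choice, since a PLOR design hinges on a
unique start. Variant or mismatched promoters are out of scope. A transcript
that does not start with G raises a warning, not an error: T7 initiation
strongly prefers G, but PLOR on other templates may tolerate it.

Coordinates are 1-based and inclusive on the transcript, with position 1 the
+1 base. The run-off convention is that transcription reaches the template
end unless terminated, so "full length" equals template length minus the
promoter-plus-spacer offset.

The terminator annotation models only the U-tract, not the hairpin and not
its thermodynamics: the longest maximal run of at least `min_run` consecutive
U is selected, ties broken toward the most 3' (downstream) run. The packaged
riboswitch transcript contains both an internal 6-U run and the terminal 8-U
tract, which motivates the default `min_run = 6`: the 8-run is still selected
as the longest, while the parameter stays available for other templates. The
terminated product length is defined as `u_start - 1` — a single-number
convention; real 3' ends may distribute across the U-tract, which is not
modeled.

## Halting rule and stoichiometry

The pause semantics place the 3' end on the last incorporable base: the
missing nucleotide is *not* incorporated. A step that cannot incorporate even
its first required base is a "stall", and a schedule whose final segment
stops short of the transcript end is "incomplete"; `validate_schedule()`
reports both without raising so schedules can be audited, while
`build_segments()` treats them as errors unless `allow_partial = TRUE`.

Stoichiometric NTP batches follow the 1x convention: the amount of each
included NTP equals the segment's count of that base times the DNA
concentration times a fold-excess, so fold 1 supplies exactly the NTPs for
one RNA per template. Concentrations are real-valued (fold 0.5 of a 45 uM
batch is 22.5 uM) and linear in the fold by construction. The initiation step
of a real design typically uses a large non-stoichiometric excess, so each
step also accepts an explicit base-to-concentration map that bypasses the
stoichiometric policy; the packaged 8-step schedule carries 400/600/64 uM
(A/G/U) at step 1 for exactly this reason. A label substitution (e.g.
Cy3-UTP) replaces its regular NTP entirely within its step — partial doping
ratios are out of scope — and the design sheet reports the labeled species at
the same concentration.

## Inverse label placement

`design_label_schedule()` searches for the fewest-step schedule in which one
step's segment contains the label base at exactly the requested positions.
The feasible labeling windows are delimited by the neighbouring occurrences
of the label base; each candidate window must additionally end at a legal
pause (the next base must not be incorporable from the bases the segment
itself required — in particular, a requested position immediately followed by
the same base can never be isolated, because no NTP-omission pause can fall
between consecutive identical bases). The prefix covering of the transcript
up to the window is solved by a dynamic program over pause-feasible cut
positions that returns a provably minimal segment count, with ties broken
toward the longest first segment. The dynamic program is exact at O(L^2) for
any transcript length, so no separate exhaustive search mode is needed; this
replaces the heuristic-plus-fallback design that an earlier sketch of the
algorithm suggested. Two further constraints reflect the bench reality: the
labeling step is never the initiation step (step 1 runs with a large
non-stoichiometric NTP excess, incompatible with economical use of a costly
labeled analog, so a label at transcript position 1 is reported infeasible),
and the final step always supplies all four NTPs so the surviving complexes
run off.

## Yield and termination statistics

The overall yield of a k-step single-round reaction is modeled
multiplicatively, `E = Ei * Ee^n` with `n = k - 1` post-initiation steps:
initiation succeeds with probability `Ei` and each pause–restart cycle
retains a fraction `Ee` of complexes. The model is taken per step, not per
nucleotide — segment lengths do not enter — and `Ee` is shared across steps.
"Yield decreases with step count" here means monotone decay through `Ee^n`,
not literal 1/n proportionality. Fitting is unweighted least squares in log
space, where the model is exactly linear (`log E = log Ei + n log Ee`); no
error model is imposed because none is known. Back-transformed estimates
above 1 are clipped to 1 with an explicit flag rather than accepted:
efficiencies are probabilities. No published numeric values of `Ei`/`Ee`
exist for the worked example, so the fit is validated by recovery on exact
and simulated data only.

Termination efficiency is the fraction of terminated product in the total,
`T/(T+FL)`, and the read-through ratio is `FL/T`. Replicate aggregation
averages per-replicate efficiencies rather than pooling intensities, so
replicates with different exposures contribute equally, and reports the
sample (n-1) standard deviation — published error bars on triplicate gels
rarely state SD versus SEM, so SD is chosen and documented. Efficiency is
scale-free, which sidesteps the question of whether gel intensities are raw
or per-gel normalised.

Band tables default to no length correction, mirroring common practice with
stain-based UV quantification. The `per_length` mode divides intensities by
product length to convert mass-proportional stain signal into
molecule-proportional signal (single-fluorophore labeling is already
molecule-proportional); because the full-length band is longer than the
terminated band, this correction strictly raises the estimated T fraction,
and the user must choose it knowingly.

## Simulator

`simulate_single_round()` draws, per molecule, Bernoulli(Ei) initiation,
Bernoulli(Ee) survival at each of the `n = k - 1` post-initiation steps, and
for complexes reaching the terminator a single Bernoulli termination event at
probability `p_term` — one terminated product length, matching the single T
band; distributed 3' ends are not simulated. Ligand dependence uses a
single-site occupancy interpolation
`p = p0 - (p0 - p1) * ligand / (Kd + ligand)`; no mechanistic functional form
is published, so the hyperbola is the minimal saturating choice. All draws
come from one seeded generator (vectorised as binomial counts, which is
distributionally identical to per-molecule draws), so identical parameters
give identical counts. Band emission multiplies counts by independent
lognormal(0, sigma) factors — lognormal for positivity, and sigma = 0
reproduces counts exactly.

Defaults are the study conditions of the worked example: `p0 = 0.85` and
`p1 = 0.55` (termination ~80–90% without ligand, ~50–60% at saturating 1 mM
adenine), `Kd = 10` uM (observed half-effect between 1 and 10 uM, saturation
well below 1 mM), `Ei = Ee = 0.9` (plausible per-step losses for an
optimised bead-phase reaction; no published values exist), `1e5` molecules
and 5% multiplicative noise. Recovery tests run at 1e5 molecules — binomial
standard error ~0.001 on the termination fraction, comfortably inside the
±0.02 bands the tests assert — and the full suite plus the reproduction
script complete in a few minutes on one core.

What the simulator deliberately does not emulate: kinetic competition between
RNA folding and elongation (the routes by which Mg²⁺ and NTP concentration
shift termination in real gels), residual-NTP cross-contamination between
steps, re-initiation, and the empirical decline of total yield at high ligand
concentrations, whose mechanism is unknown. Passing recovery tests therefore
show that the analysis pipeline is self-consistent — they do not validate
these biochemical effects.

## Worked design

```{r design}
tx <- derive_transcript(read_template(plor_example_template()))
tx$length
annotate_terminator(tx)
sched <- read_schedule(plor_example_schedule())
design_sheet(tx, sched)
```

```{r label}
design_label_schedule(tx, 41, "U")
```

```{r simulate}
sim <- simulate_single_round(tx, sched, sim_params(seed = 7))
sim$counts
summarize_bands(emit_band_table(sim))
```

## Known limitations

* One promoter model (exact class-III consensus), one polymerase.
* The terminator is a U-run only; hairpin presence and stability are the
  user's responsibility.
* Single shared `Ee` across steps; per-step heterogeneity is not fitted.
* The simulator's ligand model is an occupancy interpolation, not folding
  kinetics; its `Kd` is a phenomenological half-effect concentration.
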