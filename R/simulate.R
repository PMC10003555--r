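#' Ligand-dependent termination probability
#'
#' Hyperbolic (single-site occupancy) interpolation between the termination
#' probability without ligand (`p0`) and at ligand saturation (`p1`):
#' `p = p0 - (p0 - p1) * adenine / (Kd + adenine)`. At `adenine = Kd` the
#' probability is the midpoint `(p0 + p1) / 2`.
#'
#' @param adenine Ligand concentration in uM (>= 0). Vectorized.
#' @param p0 Termination probability without ligand, in \[0, 1\].
#' @param p1 Termination probability at ligand saturation, in \[0, 1\].
#' @param Kd Dissociation constant in uM (> 0).
#' @return Termination probability between `min(p0, p1)` and `max(p0, p1)`.
#' @examples
#' p_term(0, 0.85, 0.55, 10)   # 0.85
#' p_term(10, 0.85, 0.55, 10)  # midpoint 0.70
#' @export
p_term <- function(adenine, p0, p1, Kd) {
  check_prob(p0, "p0"); check_prob(p1, "p1")
  if (!is.numeric(Kd) || Kd <= 0) abort("`Kd` must be > 0")
  if (any(adenine < 0)) abort("`adenine` must be >= 0")
  p0 - (p0 - p1) * adenine / (Kd + adenine)
}

#' Simulation parameters for single-round PLOR transcription
#'
#' Defaults reflect the adenine riboswitch study conditions: termination
#' probability ~0.85 without adenine falling to ~0.55 at saturating (1 mM)
#' adenine with half-effect near 10 uM, initiation and per-step elongation
#' efficiencies of 0.9, 1e5 template molecules and 5% multiplicative
#' band-intensity noise.
#'
#' @param n_molecules Number of DNA template molecules (>= 1).
#' @param Ei,Ee Initiation and per-step elongation efficiencies, in (0, 1].
#' @param p0,p1,Kd_uM Termination model parameters; see [p_term()].
#' @param adenine_uM Ligand concentration in uM.
#' @param noise_sigma Lognormal sdlog of multiplicative band-intensity noise
#'   (>= 0; 0 reproduces counts exactly).
#' @param seed Integer seed; identical parameters give identical results.
#' @return A list of class `plor_sim_params`.
#' @export
sim_params <- function(n_molecules = 100000L, Ei = 0.9, Ee = 0.9,
                       p0 = 0.85, p1 = 0.55, Kd_uM = 10,
                       adenine_uM = 0, noise_sigma = 0.05, seed = 1L) {
  check_prob(Ei, "Ei", open_zero = TRUE)
  check_prob(Ee, "Ee", open_zero = TRUE)
  check_prob(p0, "p0"); check_prob(p1, "p1")
  if (n_molecules < 1L) abort("`n_molecules` must be >= 1")
  if (Kd_uM <= 0) abort("`Kd_uM` must be > 0")
  if (adenine_uM < 0) abort("`adenine_uM` must be >= 0")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  structure(
    list(n_molecules = as.integer(n_molecules), Ei = Ei, Ee = Ee,
         p0 = p0, p1 = p1, Kd_uM = Kd_uM, adenine_uM = adenine_uM,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "plor_sim_params"
  )
}

#' Simulate one single-round PLOR reaction
#'
#' Per template molecule: initiation succeeds with probability `Ei`; the
#' complex survives each of the `n = k - 1` post-initiation steps with
#' probability `Ee` (a per-step, not per-nucleotide, stall model); complexes
#' reaching the terminator release a terminated product (length `u_start - 1`)
#' with probability [p_term()], otherwise run off full length. All draws come
#' from one seeded generator, so identical parameters give identical counts.
#'
#' @inheritParams build_segments
#' @param params A [sim_params()] object.
#' @param min_run Minimum U-run for terminator annotation.
#' @return A list of class `plor_sim`: `counts` (tibble: initiated,
#'   stalled, terminated, full_length), `stalled_per_step` (tibble),
#'   `p_term` (the realized termination probability), `terminated_length`,
#'   `full_length_nt`, and the `params` and schedule metadata.
#' @examples
#' tx <- derive_transcript(read_template(plor_example_template()))
#' sched <- read_schedule(plor_example_schedule())
#' simulate_single_round(tx, sched, sim_params(n_molecules = 1000, seed = 42))
#' @export
simulate_single_round <- function(tx, sched, params = sim_params(), min_run = 6L) {
  tx <- as_transcript(tx)
  chk <- validate_schedule(tx, sched)
  if (!chk$complete) {
    abort(sprintf("schedule is not complete for this transcript (%s)",
                  paste(chk$warnings, collapse = "; ")))
  }
  term <- annotate_terminator(tx, min_run = min_run)
  p <- p_term(params$adenine_uM, params$p0, params$p1, params$Kd_uM)
  n_post <- steps_to_n(nrow(sched))
  withr::local_seed(params$seed)
  initiated <- rbinom(1L, params$n_molecules, params$Ei)
  alive <- initiated
  stalled <- integer(n_post)
  for (j in seq_len(n_post)) {
    surv <- rbinom(1L, alive, params$Ee)
    stalled[j] <- alive - surv
    alive <- surv
  }
  terminated <- rbinom(1L, alive, p)
  full_length <- alive - terminated
  structure(
    list(
      counts = tibble(
        initiated = initiated, stalled = sum(stalled),
        terminated = terminated, full_length = full_length
      ),
      stalled_per_step = tibble(
        step = if (n_post > 0L) seq_len(n_post) + 1L else integer(0),
        stalled = stalled
      ),
      p_term = p,
      terminated_length = term$terminated_length,
      full_length_nt = tx$length,
      n_steps = nrow(sched),
      params = params
    ),
    class = "plor_sim"
  )
}

#' @export
print.plor_sim <- function(x, ...) {
  cat(sprintf(
    "single-round PLOR simulation: %d molecules, %d steps, p_term = %.3f\n",
    x$params$n_molecules, x$n_steps, x$p_term))
  print(x$counts)
  invisible(x)
}

#' Emit a synthetic band table from a simulation
#'
#' Converts simulated terminated / full-length molecule counts into a
#' [band_table()] with `replicates` technical replicates, each band intensity
#' the count times an independent lognormal(0, `noise_sigma`) factor.
#' `noise_sigma = 0` reproduces the counts exactly.
#'
#' @param sim A [simulate_single_round()] result.
#' @param noise_sigma Multiplicative noise sdlog; defaults to the simulation's.
#' @param replicates Number of replicates to emit (default 3).
#' @param seed Seed for the noise draws; defaults to the simulation seed + 1.
#' @param condition Condition label; defaults to `adenine_<x>uM`.
#' @return A `plor_band_table` with `2 * replicates` rows and `length_nt`.
#' @export
emit_band_table <- function(sim, noise_sigma = NULL, replicates = 3L,
                            seed = NULL, condition = NULL) {
  if (!inherits(sim, "plor_sim")) abort("`sim` must be a simulate_single_round() result")
  counts <- sim$counts
  if (counts$terminated + counts$full_length == 0L) abort("no signal to emit")
  noise_sigma <- noise_sigma %||% sim$params$noise_sigma
  seed <- seed %||% (sim$params$seed + 1L)
  condition <- condition %||% sprintf("adenine_%guM", sim$params$adenine_uM)
  withr::local_seed(seed)
  rows <- lapply(seq_len(replicates), function(r) {
    noise <- if (noise_sigma > 0) exp(rnorm(2L, 0, noise_sigma)) else c(1, 1)
    tibble(
      lane = sprintf("L%d", r),
      condition = condition,
      replicate = r,
      band = c("T", "FL"),
      intensity = c(counts$terminated, counts$full_length) * noise,
      length_nt = c(sim$terminated_length, sim$full_length_nt)
    )
  })
  validate_band_table(dplyr::bind_rows(rows))
}
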