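NTP_BASES <- c("A", "C", "G", "U")

check_bases <- function(x, what) {
  x <- toupper(chartr("T", "U", as.character(x)))
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  bad <- setdiff(x, NTP_BASES)
  if (length(bad)) abort(sprintf("%s contains invalid base(s): %s", what,
                                 paste(bad, collapse = ", ")))
  unique(x)
}

#' Specify one PLOR step
#'
#' A step supplies a subset of the four NTPs; the polymerase elongates until
#' the first template position requiring a missing NTP. NTP amounts are either
#' stoichiometric — segment base counts x DNA concentration x `fold`, so that
#' `fold = 1` is exactly one RNA per template — or an explicit map of
#' concentrations (used e.g. for the high-excess initiation step).
#'
#' @param included Bases supplied in this step, e.g. `c("A","C","U")` or
#'   `"ACU"`.
#' @param fold Fold-excess over the 1x stoichiometric batch (default 1).
#' @param explicit Optional named numeric map base -> concentration in uM;
#'   when given, it overrides the stoichiometric policy for this step.
#' @param label_base,label_name Optional label substitution: the labeled
#'   analog (e.g. Cy3-UTP) fully replaces `label_base` in this step.
#'   `label_base` must be included.
#' @param condition Optional metadata list (e.g. `Mg_mM`, `adenine_mM`,
#'   `temperature_C`, `duration_min`), carried through to the design sheet.
#' @return A one-row tibble usable with [plor_schedule()].
#' @export
plor_step <- function(included, fold = 1, explicit = NULL,
                      label_base = NULL, label_name = NULL,
                      condition = NULL) {
  included <- check_bases(included, "`included`")
  if (!length(included)) abort("`included` must be nonempty")
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 0) {
    abort("`fold` must be a positive number")
  }
  if (!is.null(explicit)) {
    if (is.null(names(explicit))) abort("`explicit` must be a named base -> uM map")
    names(explicit) <- check_bases(names(explicit), "`explicit` names")
    if (any(explicit < 0)) abort("`explicit` concentrations must be >= 0")
    extra <- setdiff(names(explicit), included)
    if (length(extra)) abort(sprintf(
      "`explicit` names bases not in `included`: %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(label_base)) {
    label_base <- check_bases(label_base, "`label_base`")
    if (length(label_base) != 1L) abort("`label_base` must be a single base")
    if (!label_base %in% included) abort("`label_base` must be an included base")
    label_name <- label_name %||% "label"
  }
  tibble(
    included = list(included),
    fold = as.numeric(fold),
    explicit = list(explicit),
    label_base = label_base %||% NA_character_,
    label_name = label_name %||% NA_character_,
    condition = list(condition)
  )
}

#' Assemble a PLOR schedule
#'
#' @param steps A list of [plor_step()] rows (or a character vector of base
#'   subsets like `c("AGU", "ACU", ...)`, each expanded with default policy).
#' @param dna_uM Template DNA concentration in uM (default 5).
#' @param rnap_uM T7 RNAP concentration in uM, metadata only (default 5).
#' @return A tibble of class `plor_schedule`, one row per step (column `step`
#'   numbered from 1), with `dna_uM` and `rnap_uM` attributes.
#' @examples
#' plor_schedule(c("AGU", "ACU", "ACGU"))
#' @export
plor_schedule <- function(steps, dna_uM = 5, rnap_uM = 5) {
  if (is.character(steps)) steps <- lapply(steps, plor_step)
  if (inherits(steps, "tbl_df")) steps <- list(steps)
  if (!length(steps)) abort("schedule must contain at least one step")
  sched <- dplyr::bind_rows(steps)
  sched <- dplyr::mutate(sched, step = dplyr::row_number(), .before = 1)
  if (!is.numeric(dna_uM) || dna_uM <= 0) abort("`dna_uM` must be positive")
  attr(sched, "dna_uM") <- as.numeric(dna_uM)
  attr(sched, "rnap_uM") <- as.numeric(rnap_uM)
  class(sched) <- c("plor_schedule", class(sched))
  sched
}

schedule_dna_uM <- function(sched) attr(sched, "dna_uM") %||% 5

#' Read a schedule from a YAML config file
#'
#' Expected layout: top-level `dna_uM`, `rnap_uM` and a `steps` list whose
#' entries carry `included` (list of bases), and optionally `fold`,
#' `explicit` (base -> uM map), `label` (`{base, name}`) and `condition`.
#' See the packaged `schedule_8step.yaml` for the full 8-step design.
#'
#' @param path Path to the YAML file.
#' @return A [plor_schedule()] tibble.
#' @examples
#' read_schedule(plor_example_schedule())
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$steps)) abort("schedule config must contain a `steps` list")
  steps <- lapply(cfg$steps, function(s) {
    plor_step(
      included = unlist(s$included),
      fold = s$fold %||% 1,
      explicit = if (!is.null(s$explicit)) unlist(s$explicit),
      label_base = s$label$base,
      label_name = s$label$name,
      condition = s$condition
    )
  })
  plor_schedule(steps, dna_uM = cfg$dna_uM %||% 5, rnap_uM = cfg$rnap_uM %||% 5)
}

#' Packaged example: the 8-step adenine riboswitch schedule
#'
#' @return Path to the packaged YAML schedule config.
#' @export
plor_example_schedule <- function() {
  system.file("extdata", "schedule_8step.yaml", package = "plor", mustWork = TRUE)
}

#' Halt position of the polymerase under an NTP subset
#'
#' With only `included` NTPs present, elongation proceeds from `start` until
#' the first position requiring a missing NTP; the 3' end rests on the last
#' incorporable base, which is `start - 1` when the very first required base
#' is missing (zero progress), and the transcript length when no excluded
#' base remains downstream.
#'
#' @inheritParams annotate_terminator
#' @param start 1-based transcript position at which this step resumes
#'   (`length + 1` is allowed and returns `length`).
#' @param included Bases supplied in the step.
#' @return The 1-based position of the last incorporated base.
#' @examples
#' halt_position("GGGAAC", 1, c("G", "A")) # 5: first C at 6
#' @export
halt_position <- function(tx, start, included) {
  tx <- as_transcript(tx)
  included <- check_bases(included, "`included`")
  if (start < 1L || start > tx$length + 1L) {
    abort(sprintf("`start` must be in [1, %d]", tx$length + 1L))
  }
  if (start > tx$length) return(tx$length)
  bases <- transcript_bases(tx)
  blocked <- which(!(bases[start:tx$length] %in% included))
  if (!length(blocked)) tx$length else start + blocked[[1L]] - 2L
}

#' Partition the transcript into per-step segments
#'
#' Applies the halting rule step by step: each step resumes at the previous 3'
#' end + 1 and halts at the first position requiring a missing NTP. For a
#' complete schedule the segments tile `[1, length]` contiguously.
#'
#' @inheritParams annotate_terminator
#' @param sched A [plor_schedule()].
#' @param allow_partial If `FALSE` (default), a schedule whose final segment
#'   stops short of the transcript end is an error.
#' @return A tibble with one row per step: `step`, `start`, `end`, `length`,
#'   base counts `n_A`, `n_C`, `n_G`, `n_U`.
#' @examples
#' tx <- derive_transcript("TAATACGACTCACTATAGGGA")
#' build_segments(tx, plor_schedule(c("G", "AG")))
#' @export
build_segments <- function(tx, sched, allow_partial = FALSE) {
  tx <- as_transcript(tx)
  bases <- transcript_bases(tx)
  pos <- 0L
  rows <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    start <- pos + 1L
    end <- halt_position(tx, start, sched$included[[k]])
    if (end < start) {
      abort(sprintf("stalled step %d: first required base %s at position %d is excluded",
                    k, bases[start], start))
    }
    seg <- bases[start:end]
    rows[[k]] <- tibble(
      step = sched$step[[k]], start = start, end = end,
      length = end - start + 1L,
      n_A = sum(seg == "A"), n_C = sum(seg == "C"),
      n_G = sum(seg == "G"), n_U = sum(seg == "U")
    )
    pos <- end
    if (pos == tx$length) break
  }
  segs <- dplyr::bind_rows(rows)
  if (pos < tx$length && !allow_partial) {
    abort(sprintf("incomplete schedule, stopped at %d of %d nt", pos, tx$length))
  }
  if (nrow(segs) < nrow(sched) && !allow_partial) {
    # schedule exhausted the transcript before its last step
    warn(sprintf("transcript completed at step %d of %d; trailing steps unused",
                 nrow(segs), nrow(sched)))
  }
  segs
}

batch_from_counts <- function(counts, included, dna_uM, fold, explicit = NULL) {
  conc <- setNames(numeric(4), NTP_BASES)
  if (is.null(explicit)) {
    conc[included] <- counts[included] * dna_uM * fold
  } else {
    conc[names(explicit)] <- explicit
  }
  conc
}

#' Stoichiometric NTP batch for one step's segment
#'
#' Under the stoichiometric policy the concentration of each included NTP is
#' the segment's count of that base x DNA concentration x fold-excess, so
#' `fold = 1` supplies exactly the NTPs needed for one RNA per template.
#' Explicit-policy steps pass their configured amounts through unchanged.
#' A label substitution reports the labeled species carrying the same
#' concentration.
#'
#' @param segments Output of [build_segments()].
#' @param sched The [plor_schedule()] the segments were built from.
#' @param step Which step to compute the batch for.
#' @return A one-row tibble: `step`, `policy`, `fold`, `A_uM`..`U_uM`,
#'   `labeled_species`.
#' @export
batch_for_segment <- function(segments, sched, step) {
  k <- match(step, segments$step)
  if (is.na(k)) abort(sprintf("no segment for step %d", step))
  srow <- sched[match(step, sched$step), ]
  counts <- setNames(
    as.numeric(segments[k, c("n_A", "n_C", "n_G", "n_U")]), NTP_BASES)
  off <- counts[setdiff(NTP_BASES, srow$included[[1]])]
  if (any(off > 0)) abort("internal consistency error: segment contains excluded base")
  conc <- batch_from_counts(counts, srow$included[[1]], schedule_dna_uM(sched),
                            srow$fold, srow$explicit[[1]])
  lab <- if (!is.na(srow$label_base)) {
    sprintf("%s-%sTP (%g uM)", srow$label_name, srow$label_base, conc[[srow$label_base]])
  } else NA_character_
  tibble(
    step = step,
    policy = if (is.null(srow$explicit[[1]])) "stoichiometric" else "explicit",
    fold = srow$fold,
    A_uM = conc[["A"]], C_uM = conc[["C"]], G_uM = conc[["G"]], U_uM = conc[["U"]],
    labeled_species = lab
  )
}

#' Full per-step design sheet
#'
#' Aggregates [build_segments()] and [batch_for_segment()] into one table per
#' step — included subset, segment bounds, base composition, NTP batch in uM,
#' label and condition metadata — and attaches the predicted product sizes
#' from [annotate_terminator()] as attributes `full_length` and
#' `terminated_length` (the latter `NA` if no U-tract qualifies).
#'
#' @inheritParams build_segments
#' @param min_run Minimum U-run for the terminator annotation (default 6).
#' @return A tibble of class `plor_design` with one row per step.
#' @examples
#' tx <- derive_transcript(read_template(plor_example_template()))
#' design_sheet(tx, read_schedule(plor_example_schedule()))
#' @export
design_sheet <- function(tx, sched, min_run = 6L) {
  tx <- as_transcript(tx)
  segments <- build_segments(tx, sched)
  batches <- dplyr::bind_rows(lapply(segments$step, function(k) {
    batch_for_segment(segments, sched, k)
  }))
  out <- segments |>
    dplyr::left_join(batches, by = "step") |>
    dplyr::mutate(
      included = vapply(sched$included[match(.data$step, sched$step)],
                        paste, character(1), collapse = ","),
      condition = sched$condition[match(.data$step, sched$step)],
      .after = "step"
    )
  term <- tryCatch(annotate_terminator(tx, min_run = min_run), error = function(e) NULL)
  attr(out, "full_length") <- tx$length
  attr(out, "terminated_length") <- if (is.null(term)) NA_integer_ else term$terminated_length
  class(out) <- c("plor_design", class(out))
  out
}

#' @export
print.plor_design <- function(x, ...) {
  cat(sprintf("PLOR design sheet: %d steps; products %s nt (terminated) / %d nt (full-length)\n",
              nrow(x), format(attr(x, "terminated_length")), attr(x, "full_length")))
  NextMethod()
}

#' Validate a schedule against a transcript without raising
#'
#' Dry-runs the halting rule and reports progress per step. Stalls and
#' incompleteness are encoded in the report rather than raised; a non-final
#' step that includes all four NTPs cannot pause and is flagged as a warning.
#'
#' @inheritParams build_segments
#' @return A list with `complete` (flag), `n_steps`, `progress` (tibble:
#'   step, start, end, stalled) and `warnings` (character vector).
#' @export
validate_schedule <- function(tx, sched) {
  tx <- as_transcript(tx)
  warnings <- character(0)
  rows <- vector("list", nrow(sched))
  pos <- 0L
  stopped <- FALSE
  for (k in seq_len(nrow(sched))) {
    inc <- sched$included[[k]]
    if (length(inc) == 4L && k < nrow(sched)) {
      warnings <- c(warnings, sprintf("step %d cannot pause (all four NTPs included)", k))
    }
    start <- pos + 1L
    if (stopped || start > tx$length) {
      rows[[k]] <- tibble(step = k, start = NA_integer_, end = NA_integer_, stalled = NA)
      next
    }
    end <- halt_position(tx, start, inc)
    stalled <- end < start
    rows[[k]] <- tibble(step = k, start = start,
                        end = if (stalled) NA_integer_ else end, stalled = stalled)
    if (stalled) {
      warnings <- c(warnings, sprintf("stalled step %d at position %d", k, start))
      stopped <- TRUE
    } else {
      pos <- end
    }
  }
  complete <- !stopped && pos == tx$length
  if (!stopped && pos < tx$length) {
    warnings <- c(warnings, sprintf("incomplete schedule, stopped at %d of %d nt",
                                    pos, tx$length))
  }
  list(complete = complete, n_steps = nrow(sched),
       progress = dplyr::bind_rows(rows), warnings = warnings)
}

# TRUE when a segment [start, end] is a legal pause: the next base is not
# incorporable from the bases the segment itself required. end == L always
# legal (run-off).
pause_ok <- function(bases, start, end) {
  end == length(bases) || !(bases[end + 1L] %in% unique(bases[start:end]))
}

# Minimal number of pause-feasible segments covering [from, to], by dynamic
# programming from the right; used by the inverse label-placement design.
# Returns NULL when infeasible, else the vector of segment end positions,
# preferring the longest first segment among minimal covers.
min_cover <- function(bases, from, to) {
  if (from > to) return(integer(0))
  INF <- .Machine$integer.max %/% 2L
  need <- rep(INF, to + 2L)            # need[i]: min segments covering [i, to]
  need[to + 1L] <- 0L
  for (i in to:from) {
    for (e in i:to) {
      # pause constraint at e: next base (e+1, may be beyond `to`) must not be
      # incorporable from bases[i..e]; transcript end is always legal
      if (pause_ok(bases, i, e) && need[e + 1L] < INF) {
        cand <- need[e + 1L] + 1L
        if (cand < need[i]) need[i] <- cand
      }
    }
  }
  if (need[from] >= INF) return(NULL)
  # reconstruct, longest segment first at each position
  ends <- integer(0)
  i <- from
  while (i <= to) {
    e_choices <- i:to
    ok <- vapply(e_choices, function(e) {
      pause_ok(bases, i, e) && need[e + 1L] == need[i] - 1L
    }, logical(1))
    e <- max(e_choices[ok])
    ends <- c(ends, e)
    i <- e + 1L
  }
  ends
}

#' Inverse design: a schedule placing a labeled NTP at chosen positions
#'
#' Searches for a schedule with the fewest steps in which one designated
#' step's segment contains `label_base` at exactly the requested transcript
#' positions — so that substituting the labeled NTP analog in that step labels
#' those positions and no others — while every earlier step pauses legally and
#' the final step supplies all four NTPs for run-off. The prefix segmentation
#' is solved exactly by dynamic programming over pause-feasible cut positions.
#'
#' @inheritParams annotate_terminator
#' @param label_positions 1-based transcript positions to label (must all
#'   carry `label_base`).
#' @param label_base The base carried by the labeled NTP analog.
#' @param label_name Label name recorded on the schedule (default `"Cy3"`).
#' @param dna_uM DNA concentration for the resulting schedule.
#' @return A [plor_schedule()] whose labeling step has `label_base`
#'   substitution set; it always validates `complete` on `tx`.
#' @examples
#' design_label_schedule("GGGAU", 5, "U")
#' @export
design_label_schedule <- function(tx, label_positions, label_base,
                                  label_name = "Cy3", dna_uM = 5) {
  tx <- as_transcript(tx)
  bases <- transcript_bases(tx)
  L <- tx$length
  label_base <- check_bases(label_base, "`label_base`")
  if (length(label_base) != 1L) abort("`label_base` must be a single base")
  R <- sort(unique(as.integer(label_positions)))
  if (!length(R)) abort("`label_positions` must be nonempty")
  if (any(R < 1L | R > L)) abort("label positions outside transcript")
  wrong <- R[bases[R] != label_base]
  if (length(wrong)) {
    abort(sprintf("position %d carries %s, not %s", wrong[[1]], bases[wrong[[1]]], label_base))
  }
  occ <- which(bases == label_base)
  inside <- occ[occ >= min(R) & occ <= max(R)]
  if (!setequal(inside, R)) {
    abort(sprintf("label not isolatable: %s also occurs at %s between the requested positions",
                  label_base, paste(setdiff(inside, R), collapse = ", ")))
  }
  prev_occ <- max(c(0L, occ[occ < min(R)]))
  next_occ <- min(c(L + 1L, occ[occ > max(R)]))

  # the labeling step is never the initiation step: step 1 runs with a large
  # non-stoichiometric NTP excess, incompatible with economical label use
  s_range <- max(prev_occ + 1L, 2L):min(R)
  if (min(R) < 2L) {
    abort("label not isolatable at 1: the initiation step cannot carry the label")
  }
  e_range <- max(R):min(next_occ - 1L, L)
  best <- NULL
  for (s in s_range) {
    prefix <- min_cover(bases, 1L, s - 1L)
    if (is.null(prefix)) next
    for (e in e_range) {
      if (!pause_ok(bases, s, e)) next
      n_steps <- length(prefix) + 1L + (if (e < L) 1L else 0L)
      if (is.null(best) || n_steps < best$n ||
          (n_steps == best$n && (length(prefix) && prefix[1] > best$first))) {
        best <- list(n = n_steps, prefix = prefix, s = s, e = e,
                     first = if (length(prefix)) prefix[1] else s - 1L)
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf("label not isolatable at %d (no pause separates it from the next %s)",
                  max(R), label_base))
  }
  ends <- c(best$prefix, best$e)
  starts <- c(1L, head(ends, -1L) + 1L)
  steps <- lapply(seq_along(ends), function(i) {
    seg_bases <- unique(bases[starts[i]:ends[i]])
    if (ends[i] == best$e) {
      inc <- if (best$e == L) NTP_BASES else seg_bases
      plor_step(inc, label_base = label_base, label_name = label_name)
    } else {
      plor_step(seg_bases)
    }
  })
  if (best$e < L) steps <- c(steps, list(plor_step(NTP_BASES)))
  plor_schedule(steps, dna_uM = dna_uM)
}

#' Automatic complete schedule with a chosen number of steps
#'
#' Builds a k-step schedule for a transcript by placing pause boundaries near
#' equal spacing, snapping each to the nearest pause-feasible position; each
#' step's included set is the set of bases its segment requires, and the final
#' step supplies all four NTPs for run-off. Useful for comparing pausing
#' strategies (e.g. 3-, 6-, 8- and 10-step designs) on one template.
#'
#' @inheritParams annotate_terminator
#' @param n_steps Number of steps (>= 1).
#' @param dna_uM DNA concentration for the schedule.
#' @return A [plor_schedule()] that validates `complete` on `tx`.
#' @export
auto_schedule <- function(tx, n_steps, dna_uM = 5) {
  tx <- as_transcript(tx)
  bases <- transcript_bases(tx)
  L <- tx$length
  if (n_steps < 1L) abort("`n_steps` must be >= 1")
  ends <- integer(0)
  start <- 1L
  for (j in seq_len(n_steps - 1L)) {
    target <- round(L * j / n_steps)
    cand <- which(vapply(start:(L - 1L), function(e) pause_ok(bases, start, e), logical(1)))
    if (!length(cand)) abort(sprintf("no pause-feasible boundary for step %d", j))
    cand <- cand + start - 1L
    e <- cand[which.min(abs(cand - target))]
    ends <- c(ends, e)
    start <- e + 1L
  }
  starts <- c(1L, ends + 1L)
  steps <- lapply(seq_len(n_steps), function(i) {
    if (i == n_steps) plor_step(NTP_BASES)
    else plor_step(unique(bases[starts[i]:ends[i]]))
  })
  plor_schedule(steps, dna_uM = dna_uM)
}
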