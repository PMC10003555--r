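# Independent oracles and fixture builders, deliberately implemented with
# different primitives than the package (chartr/rev, rle, per-base loops).

paper_tx <- function() derive_transcript(read_template(plor_example_template()))

paper_sched <- function() read_schedule(plor_example_schedule())

eight_step_subsets <- list(
  c("A", "G", "U"), c("A", "C", "U"), c("A", "G", "U"), c("A", "C", "U"),
  c("A", "C", "G"), c("A", "C", "U"), c("A", "G", "U"), c("A", "C", "G", "U")
)

# reverse complement by per-character complement then reversal
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_rna <- function(len, weights = c(1, 1, 1, 1)) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = weights),
        collapse = "")
}

# enumerate all maximal U-runs with rle; return the annotate_terminator answer
uruns_oracle <- function(rna, min_run) {
  r <- rle(strsplit(rna, "")[[1]] == "U")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(NULL)
  len <- r$lengths[keep]; st <- starts[keep]
  best <- which(len == max(len))
  best <- best[which.max(st[best])]
  list(u_start = st[best], u_end = st[best] + len[best] - 1L,
       terminated_length = st[best] - 1L)
}

# per-base halting simulation: advance one base at a time, stop when the next
# base is not in the step's included set
segments_oracle <- function(rna, subsets) {
  bases <- strsplit(rna, "")[[1]]
  pos <- 0L
  out <- list()
  for (k in seq_along(subsets)) {
    start <- pos + 1L
    p <- pos
    while (p < length(bases) && bases[p + 1L] %in% subsets[[k]]) p <- p + 1L
    if (p < start) return(list(error = sprintf("stalled step %d", k)))
    out[[k]] <- c(start = start, end = p)
    pos <- p
    if (pos == length(bases)) break
  }
  if (pos < length(bases)) return(list(error = "incomplete"))
  list(segments = do.call(rbind, out))
}

# a random schedule whose subsets are drawn anew each step; last step all four
random_subsets <- function(n_steps) {
  subs <- lapply(seq_len(max(n_steps - 1L, 0L)), function(i) {
    sample(c("A", "C", "G", "U"), sample(1:3, 1, prob = c(1, 2, 4)))
  })
  c(subs, list(c("A", "C", "G", "U")))
}

# bare string from a plor_seq (drops class/alphabet attributes)
seq_chr <- function(x) {
  x <- unclass(x)
  attributes(x) <- NULL
  x
}
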