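test_that("halt_position implements the last-incorporable-base rule", {
  tx <- paper_tx()
  expect_equal(halt_position(tx, 1, c("A", "G", "U")), 14L)   # first C at 15
  expect_equal(halt_position(tx, 15, c("A", "C", "U")), 26L)  # next G at 27
  expect_equal(halt_position(tx, 1, c("A", "C", "G", "U")), tx$length)
  expect_equal(halt_position("GGGA", 1, "A"), 0L)  # zero progress is legal
  expect_error(halt_position("GGGA", 7, "A"), "must be in")
})

test_that("build_segments reproduces the 8-step boundaries on the riboswitch transcript", {
  segs <- build_segments(paper_tx(), plor_schedule(vapply(
    eight_step_subsets, paste, character(1), collapse = "")))
  expect_equal(segs$start, c(1L, 15L, 27L, 40L, 46L, 53L, 62L, 67L))
  expect_equal(segs$end, c(14L, 26L, 39L, 45L, 52L, 61L, 66L, 120L))
  expect_equal(sum(segs$length), 120L)
})

test_that("build_segments errors on stalls and incompleteness", {
  expect_error(build_segments("GGGA", plor_schedule(c("A", "ACGU"))),
               "stalled step 1")
  segs <- build_segments("GGGA", plor_schedule(c("G", "AG")))
  expect_equal(segs$end, c(3L, 4L))
  expect_error(build_segments("GGGAC", plor_schedule(c("G", "AG"))),
               "incomplete schedule, stopped at 4")
  partial <- build_segments("GGGAC", plor_schedule(c("G", "AG")), allow_partial = TRUE)
  expect_equal(max(partial$end), 4L)
})

test_that("build_segments agrees with the per-base simulation oracle", {
  set.seed(47)
  n_complete <- 0L
  for (i in 1:1000) {
    rna <- random_rna(sample(5:200, 1))
    subsets <- random_subsets(sample(1:10, 1))
    want <- segments_oracle(rna, subsets)
    sched <- plor_schedule(lapply(subsets, plor_step))
    if (!is.null(want$error)) {
      expect_error(build_segments(rna, sched))
    } else {
      got <- suppressWarnings(build_segments(rna, sched))
      expect_equal(got$start, unname(want$segments[, "start"]))
      expect_equal(got$end, unname(want$segments[, "end"]))
      # tiling: contiguous, non-overlapping, sums to length
      expect_equal(got$start, c(1L, head(got$end, -1) + 1L))
      expect_equal(sum(got$length), nchar(rna))
      n_complete <- n_complete + 1L
    }
  }
  expect_gt(n_complete, 150L)
})

test_that("stoichiometric batches match segment composition x DNA x fold", {
  tx <- paper_tx()
  sched <- paper_sched()
  segs <- build_segments(tx, sched)
  b2 <- batch_for_segment(segs, sched, 2)
  expect_equal(c(b2$A_uM, b2$C_uM, b2$G_uM, b2$U_uM), c(25, 15, 0, 20))
  # explicit policy passes through
  b1 <- batch_for_segment(segs, sched, 1)
  expect_equal(b1$policy, "explicit")
  expect_equal(c(b1$A_uM, b1$G_uM, b1$U_uM), c(400, 600, 64))
  # linearity in fold, exactly
  sched05 <- sched
  sched05$fold[8] <- 0.5
  b8_half <- batch_for_segment(segs, sched05, 8)
  b8 <- batch_for_segment(segs, sched, 8)
  expect_identical(b8_half$C_uM, 0.5 * b8$C_uM)
  expect_identical(b8_half$U_uM, 0.5 * b8$U_uM)
})

test_that("design_sheet aggregates segments, batches and product sizes", {
  sheet <- design_sheet(paper_tx(), paper_sched())
  expect_s3_class(sheet, "plor_design")
  expect_equal(nrow(sheet), 8L)
  expect_equal(attr(sheet, "full_length"), 120L)
  expect_equal(attr(sheet, "terminated_length"), 100L)
  expect_equal(sheet$labeled_species[4], "Cy3-UTP (5 uM)")
  one <- design_sheet("GGGA", plor_schedule("ACGU"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$end, 4L)
  expect_true(is.na(attr(one, "terminated_length")))
})

test_that("validate_schedule encodes stalls and no-pause steps without raising", {
  tx <- paper_tx()
  rep8 <- validate_schedule(tx, paper_sched())
  expect_true(rep8$complete)
  expect_equal(rep8$n_steps, 8L)
  expect_length(rep8$warnings, 0L)

  rep_np <- validate_schedule("GGGA", plor_schedule(c("ACGU", "AG")))
  expect_match(rep_np$warnings, "step 1 cannot pause", all = FALSE)

  rep_stall <- validate_schedule("GGGA", plor_schedule(c("A", "ACGU")))
  expect_false(rep_stall$complete)
  expect_true(rep_stall$progress$stalled[1])
  expect_match(rep_stall$warnings, "stalled step 1 at position 1", all = FALSE)
})

test_that("read_schedule parses the YAML config faithfully", {
  sched <- paper_sched()
  expect_equal(nrow(sched), 8L)
  expect_equal(attr(sched, "dna_uM"), 5)
  expect_equal(sched$included[[5]], c("A", "C", "G"))
  expect_equal(sched$explicit[[1]], c(A = 400, G = 600, U = 64))
  expect_equal(sched$label_base[4], "U")
  expect_equal(sched$label_name[4], "Cy3")
  expect_equal(sched$condition[[8]]$Mg_mM, 6)
})

test_that("design_label_schedule isolates the label and detects infeasibility", {
  # paper case: single Cy3-U at transcript position 41
  tx <- paper_tx()
  sched <- design_label_schedule(tx, 41, "U")
  expect_true(validate_schedule(tx, sched)$complete)
  k <- which(!is.na(sched$label_base))
  expect_length(k, 1L)
  segs <- build_segments(tx, sched)
  expect_equal(segs$n_U[k], 1L)
  expect_true(segs$start[k] <= 41 && segs$end[k] >= 41)
  expect_equal(sched$included[[nrow(sched)]], c("A", "C", "G", "U"))

  # two-step toy design
  s2 <- design_label_schedule("GGGAU", 5, "U")
  expect_equal(nrow(s2), 2L)
  expect_equal(sort(s2$included[[1]]), c("A", "G"))
  expect_equal(s2$label_base[2], "U")
  expect_equal(s2$included[[2]], c("A", "C", "G", "U"))

  # consecutive identical bases cannot be separated by a pause
  expect_error(design_label_schedule("GGGUU", 4, "U"), "label not isolatable")
  # a non-requested occurrence between requested ones
  expect_error(design_label_schedule("GUUUG", c(2, 4), "U"), "not isolatable")
  expect_error(design_label_schedule("GGGAU", 4, "U"), "carries A, not U")
})

test_that("label schedules pass validation across random cases", {
  set.seed(59)
  n_ok <- 0L
  for (i in 1:200) {
    rna <- random_rna(sample(8:60, 1))
    bases <- strsplit(rna, "")[[1]]
    pos <- sample(seq_along(bases), 1)
    b <- bases[pos]
    sched <- tryCatch(design_label_schedule(rna, pos, b), error = function(e) NULL)
    if (is.null(sched)) next
    expect_true(validate_schedule(rna, sched)$complete)
    segs <- build_segments(rna, sched)
    k <- which(!is.na(sched$label_base))
    expect_equal(segs[segs$step == sched$step[k], ][[paste0("n_", b)]], 1L)
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 50L)
})

test_that("auto_schedule builds complete k-step designs on the riboswitch transcript", {
  tx <- paper_tx()
  for (k in c(3, 6, 8, 10)) {
    sched <- auto_schedule(tx, k)
    expect_equal(nrow(sched), k)
    expect_true(validate_schedule(tx, sched)$complete)
  }
})
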