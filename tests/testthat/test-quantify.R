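write_bands <- function(df, delim = ",") {
  path <- tempfile(fileext = if (delim == ",") ".csv" else ".tsv")
  readr::write_delim(df, path, delim = delim)
  path
}

toy_bands <- function() {
  tibble::tibble(
    lane = c("L1", "L1"), condition = "c1", replicate = 1L,
    band = c("T", "FL"), intensity = c(3, 1)
  )
}

test_that("read_band_table parses CSV and TSV with validation", {
  tbl <- read_band_table(write_bands(toy_bands()))
  expect_s3_class(tbl, "plor_band_table")
  expect_equal(nrow(tbl), 2L)
  tbl2 <- read_band_table(write_bands(toy_bands(), delim = "\t"))
  expect_equal(tbl2$intensity, c(3, 1))
  # extra columns are preserved
  extra <- dplyr::mutate(toy_bands(), Mg_mM = 6)
  tbl3 <- read_band_table(write_bands(extra))
  expect_true("Mg_mM" %in% names(tbl3))
})

test_that("band table validation names the offending problem", {
  dup <- dplyr::bind_rows(toy_bands(), toy_bands()[1, ])
  expect_error(band_table(dup), "duplicate")
  neg <- dplyr::mutate(toy_bands(), intensity = c(-1, 1))
  expect_error(band_table(neg), "negative")
  expect_error(read_band_table(write_bands(toy_bands()[, -4])), "missing column: band")
  badband <- dplyr::mutate(toy_bands(), band = c("T", "XX"))
  expect_error(band_table(badband), "T or FL")
})

test_that("molar_correct: none is identity, per_length divides by length", {
  tbl <- band_table(dplyr::mutate(toy_bands(), intensity = c(100, 120),
                                  length_nt = c(100L, 120L)))
  expect_identical(molar_correct(tbl, "none")$intensity, c(100, 120))
  corr <- molar_correct(tbl, "per_length")
  expect_equal(corr$intensity, c(1, 1))
  no_len <- band_table(toy_bands())
  expect_error(molar_correct(no_len, "per_length"), "length_nt")
  na_len <- band_table(dplyr::mutate(toy_bands(), length_nt = c(100L, NA)))
  expect_error(molar_correct(na_len, "per_length"), "row")
})

test_that("summarize_bands averages per-replicate efficiencies with sample sd", {
  tbl <- band_table(tibble::tibble(
    lane = rep(c("L1", "L2", "L3"), each = 2),
    condition = "c1",
    replicate = rep(1:3, each = 2),
    band = rep(c("T", "FL"), 3),
    intensity = c(3, 1, 3, 1, 3, 1)
  ))
  res <- summarize_bands(tbl)
  expect_equal(res$mean_efficiency, 0.75)
  expect_equal(res$sd_efficiency, 0)
  expect_equal(res$n_replicates, 3L)

  two <- band_table(tibble::tibble(
    lane = rep(c("L1", "L2"), each = 2), condition = "c1",
    replicate = rep(1:2, each = 2), band = rep(c("T", "FL"), 2),
    intensity = c(1, 1, 3, 1)
  ))
  res2 <- summarize_bands(two)
  expect_equal(res2$mean_efficiency, mean(c(0.5, 0.75)))
  expect_equal(res2$sd_efficiency, sd(c(0.5, 0.75)))
  expect_equal(res2$sd_efficiency, 0.1768, tolerance = 1e-3)
})

test_that("replicates missing one band are dropped with a warning count", {
  tbl <- band_table(tibble::tibble(
    lane = c("L1", "L1", "L2"), condition = "c1",
    replicate = c(1L, 1L, 2L), band = c("T", "FL", "T"),
    intensity = c(3, 1, 9)
  ))
  expect_warning(res <- summarize_bands(tbl), "1 replicate pair")
  expect_equal(attr(res, "n_dropped"), 1L)
  expect_equal(res$n_replicates, 1L)
  expect_true(is.na(res$sd_efficiency))
})

test_that("summaries are invariant under per-replicate intensity rescaling", {
  set.seed(83)
  base <- tibble::tibble(
    lane = rep(sprintf("L%d", 1:4), each = 2),
    condition = rep(c("a", "b"), each = 4),
    replicate = rep(c(1L, 2L), 2, each = 2),
    band = rep(c("T", "FL"), 4),
    intensity = runif(8, 1, 50)
  )
  scaled <- base |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::mutate(intensity = .data$intensity * runif(1, 0.1, 20)) |>
    dplyr::ungroup()
  r1 <- summarize_bands(band_table(base))
  r2 <- summarize_bands(band_table(scaled))
  expect_equal(r1$mean_efficiency, r2$mean_efficiency)
  expect_equal(r1$sd_efficiency, r2$sd_efficiency)
  expect_equal(r1$mean_ratio_FL_T, r2$mean_ratio_FL_T)
})

test_that("per_length correction raises the T fraction when FL is the longer band", {
  # stain signal scales with mass, so the longer FL band over-reports its
  # molecule count; dividing by length shrinks FL more than T and therefore
  # strictly increases the molecule-based efficiency whenever it is in (0,1)
  set.seed(89)
  for (i in 1:50) {
    T_int <- runif(1, 1, 100)
    FL_int <- runif(1, 1, 100)
    tbl <- band_table(tibble::tibble(
      lane = "L1", condition = "c", replicate = 1L,
      band = c("T", "FL"), intensity = c(T_int, FL_int),
      length_nt = c(100L, 120L)
    ))
    raw <- summarize_bands(tbl)$mean_efficiency
    corr <- summarize_bands(molar_correct(tbl, "per_length"))$mean_efficiency
    expect_gt(corr, raw)
    # closed form: T / (T + FL * len_T / len_FL)
    expect_equal(corr, T_int / (T_int + FL_int * 100 / 120))
  }
})
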