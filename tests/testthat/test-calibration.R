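test_that("derivatization factor estimation inverts the mixing equation", {
  stds <- default_standards()
  phe_cert <- -244 / 9  # so the mixed value is a round -28
  stds$certified_delta[stds$aa == "phenylalanine" & stds$element == "C13"] <- phe_cert

  # measured equals certified -> the factor equals the certified value
  pk_fix <- std_peaks("phenylalanine", "C13", injection = 1:3, delta = phe_cert)
  dc_fix <- estimate_dcorr(pk_fix, stds)
  expect_equal(dc_fix$dcorr, phe_cert, tolerance = 1e-12)

  # measured -28.0 with n_c = 9, n_d = 4 -> factor -30.0
  pk <- std_peaks("phenylalanine", "C13", injection = 1:3, delta = -28.0)
  dc <- estimate_dcorr(pk, stds)
  expect_equal(dc$dcorr, -30.0, tolerance = 1e-12)

  # start and end blocks are averaged
  m_for <- function(dcorr) (9 * phe_cert + 4 * dcorr) / 13
  pk2 <- dplyr::bind_rows(
    std_peaks("phenylalanine", "C13", injection = 1:3, delta = m_for(-29.8)),
    std_peaks("phenylalanine", "C13", injection = 20:22, delta = m_for(-30.2))
  )
  expect_equal(estimate_dcorr(pk2, stds)$dcorr, -30.0, tolerance = 1e-12)

  # n_d = 0 leaves the factor undefined
  chem0 <- aa_registry()
  chem0$n_d <- 0L
  expect_error(estimate_dcorr(pk, stds, chem0), "n_d = 0")
})

test_that("carbon correction removes the added derivatization carbon", {
  dc <- tibble::tibble(aa = "phenylalanine", dcorr = -30.0)
  expect_equal(correct_carbon(-28.0, "phenylalanine", dc),
               (13 * -28 - 4 * -30) / 9, tolerance = 1e-14)
  expect_equal(correct_carbon(-28.0, "phenylalanine", dc), -27.111111111111,
               tolerance = 1e-10)
  # fixed point: factor equal to the measured value leaves it unchanged
  dc_id <- tibble::tibble(aa = "phenylalanine", dcorr = -28.0)
  expect_equal(correct_carbon(-28.0, "phenylalanine", dc_id), -28.0)
  expect_error(correct_carbon(-28, "selenocysteine", dc), "Unknown")
})

test_that("mixing then correcting is the identity for any n_c, n_d", {
  set.seed(1)
  for (i in 1:50) {
    n_c <- sample(2:12, 1)
    n_d <- sample(1:6, 1)
    chem <- tibble::tibble(aa = "glutamic acid", code = "Glu",
                           n_c = n_c, n_d = n_d,
                           essential = FALSE, trophic_class = "trophic")
    d_c <- runif(1, -35, -10)
    d_d <- runif(1, -40, -20)
    d_cd <- (n_c * d_c + n_d * d_d) / (n_c + n_d)
    dc <- tibble::tibble(aa = "glutamic acid", dcorr = d_d)
    expect_equal(correct_carbon(d_cd, "glutamic acid", dc, chem), d_c,
                 tolerance = 1e-9)
  }
})

test_that("nitrogen regression calibration recovers affine responses", {
  # measured identical to certified: identity line, samples untouched
  id <- calibrate_nitrogen(c(3.5, 8.1), std_measured = c(-6.69, 10, 43.25),
                           std_certified = c(-6.69, 10, 43.25))
  expect_equal(id$fit$slope, 1, tolerance = 1e-12)
  expect_equal(id$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(id$corrected, c(3.5, 8.1), tolerance = 1e-12)

  # two-point line
  two <- calibrate_nitrogen(5, std_measured = c(0, 10), std_certified = c(1, 21))
  expect_equal(two$fit$slope, 2, tolerance = 1e-12)
  expect_equal(two$fit$intercept, 1, tolerance = 1e-12)
  expect_equal(two$corrected, 11, tolerance = 1e-12)

  expect_error(calibrate_nitrogen(1, std_measured = 3, std_certified = 4),
               "two standard")
  expect_error(calibrate_nitrogen(1, std_measured = c(3, 3), std_certified = c(4, 5)),
               "variance")
})

test_that("drift correction adjusts samples to the sequence-mean standard level", {
  stds <- tibble::tibble(aa = "glycine", element = "N15", certified_delta = 0)
  pk <- dplyr::bind_rows(
    std_peaks("glycine", "N15", injection = 1L, delta = 0.0),
    std_peaks("glycine", "N15", injection = 21L, delta = 1.0),
    peak_row(aa = "glycine", injection = 11L, delta = 4.2)
  )
  out <- drift_correct(pk, stds)
  expect_equal(out$delta[!out$is_standard], 4.2 - 0.5, tolerance = 1e-12)
  expect_equal(attr(out, "drift")$slope, 0.05, tolerance = 1e-12)

  # identical start and end standards: zero drift, identity
  pk0 <- dplyr::bind_rows(
    std_peaks("glycine", "N15", injection = 1L, delta = 0.0),
    std_peaks("glycine", "N15", injection = 21L, delta = 0.0),
    peak_row(aa = "glycine", injection = 11L, delta = 4.2)
  )
  out0 <- drift_correct(pk0, stds)
  expect_equal(out0$delta[!out0$is_standard], 4.2, tolerance = 1e-12)

  # single standard block: drift skipped with a warning
  pk1 <- dplyr::bind_rows(
    std_peaks("glycine", "N15", injection = 1:3, delta = 0.0),
    peak_row(aa = "glycine", injection = 11L, delta = 4.2)
  )
  expect_warning(out1 <- drift_correct(pk1, stds), "fewer than two")
  expect_equal(out1$delta, pk1$delta)
})

test_that("the calibration inverts the full instrument layer at zero noise", {
  cohort <- generate_cohort(seed = 31)
  inst <- noise_free_instrument(
    drift_slope = c(C13 = 0.05, N15 = 0.05),
    nitrogen_response = c(intercept = 1, slope = 2)
  )
  peaks <- forward_instrument(cohort, instrument = inst, seed = 32)
  cal <- calibrate_sequence(peaks)
  expect_lt(roundtrip_error(cohort, tidy(cal)), 1e-9)
  expect_equal(cal$nitrogen_fit$slope, 0.5, tolerance = 1e-9)
})

test_that("inversion is exact over random instrument parameters", {
  set.seed(99)
  par0 <- default_parameters()
  for (i in 1:100) {
    chem <- aa_registry()
    chem$n_c <- sample(2:12, nrow(chem), replace = TRUE)
    chem$n_d <- sample(1:6, nrow(chem), replace = TRUE)
    inst <- instrument_model(
      derivatization_delta = runif(1, -45, -15),
      drift_slope = c(C13 = runif(1, -0.1, 0.1), N15 = runif(1, -0.1, 0.1)),
      noise_sd = c(C13 = 0, N15 = 0),
      nitrogen_response = c(intercept = runif(1, -3, 3),
                            slope = runif(1, 0.5, 2))
    )
    cohort <- generate_cohort(params = par0, n_colonies = 2,
                              treatments = "mixotrophy", seed = 1000 + i)
    peaks <- forward_instrument(cohort, instrument = inst, chemistry = chem,
                                seed = 2000 + i)
    cal <- calibrate_sequence(peaks, chemistry = chem)
    expect_lt(roundtrip_error(cohort, tidy(cal)), 1e-9)
  }
})

test_that("re-calibrating already-consistent data is a no-op", {
  # identity instrument for nitrogen, zero drift: peaks equal tissue truth,
  # and running the full calibration chain anyway must not move them
  cohort <- generate_cohort(n_colonies = 2, treatments = "autotrophy", seed = 51)
  inst <- noise_free_instrument(drift_slope = c(C13 = 0, N15 = 0),
                                nitrogen_response = c(intercept = 0, slope = 1))
  peaks <- forward_instrument(cohort, instrument = inst, seed = 52)
  n_raw <- dplyr::filter(average_replicates(peaks), !is_standard, element == "N15")
  cal <- calibrate_sequence(peaks)
  n_cal <- dplyr::filter(tidy(cal), element == "N15")
  chk <- dplyr::inner_join(n_raw, n_cal, by = c("sample_id", "aa"),
                           suffix = c("_raw", "_cal"))
  expect_equal(chk$delta_cal, chk$delta_raw, tolerance = 1e-9)
  expect_lt(roundtrip_error(cohort, tidy(cal)), 1e-9)
})
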