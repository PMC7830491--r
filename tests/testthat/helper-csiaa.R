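# shared fixtures, built in code

noise_free_instrument <- function(...) {
  instrument_model(noise_sd = c(C13 = 0, N15 = 0), ...)
}

# minimal peak tibble builder (defaults describe one sample peak)
peak_row <- function(sample_id = "s1", colony = 1L, treatment = "autotrophy",
                     compartment = "host", aa = "glutamic acid",
                     element = "N15", replicate = 1L, injection = 1L,
                     delta = 0, is_standard = FALSE) {
  tibble::tibble(sample_id, colony, treatment, compartment, aa, element,
                 replicate, injection, delta, is_standard)
}

# standard peaks for one AA at given injections/readings
std_peaks <- function(aa, element, injection, delta) {
  tibble::tibble(sample_id = "standard", colony = NA_integer_,
                 treatment = NA_character_, compartment = NA_character_,
                 aa = aa, element = element,
                 replicate = 1L, injection = injection, delta = delta,
                 is_standard = TRUE)
}

# tissue-level truth vs calibrated output, joined
roundtrip_error <- function(cohort, calibrated) {
  chk <- dplyr::inner_join(cohort, calibrated,
                           by = c("sample_id", "aa", "element"),
                           suffix = c("_true", "_cal"))
  max(abs(chk$delta_cal - chk$delta_true))
}

# independent BH step-up, straight from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
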