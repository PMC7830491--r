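#' Trophic position from glutamic acid and phenylalanine delta-15N
#'
#' The trophic position statistic exploits the contrast between a trophic
#' amino acid (glutamic acid, strongly 15N-enriched at each trophic
#' transfer) and a source amino acid (phenylalanine, nearly unchanged):
#'
#' `TP = ((delta15N_Glu - delta15N_Phe - beta) / TDF) + 1`
#'
#' Primary producers have TP = 1 by construction (their Glu-Phe gap equals
#' `beta`); strict primary consumers have TP = 2; a mixotroph falls in
#' between in proportion to its heterotrophic input. TP is affine in the
#' Glu-Phe difference, so the expected TP of a group equals the TP of its
#' group-mean deltas.
#'
#' `tp_value()` is the vectorized numeric core; [compute_tp()] is the
#' data-frame interface.
#'
#' @param glu corrected delta-15N of glutamic acid (per mil, AIR scale).
#' @param phe corrected delta-15N of phenylalanine (per mil, AIR scale).
#' @param constants a [tp_constants()] object.
#' @return Numeric trophic position, same length as the inputs.
#' @examples
#' tp_value(5.00, 5.36)   # gap equal to beta: a primary producer, TP = 1
#' tp_value(14.17, 8.03)  # Artemia prey group means
#' @export
tp_value <- function(glu, phe, constants = tp_constants()) {
  stopifnot(inherits(constants, "tp_constants"))
  ((glu - phe - constants$beta) / constants$tdf) + 1
}

#' Compute per-sample trophic position
#'
#' Takes a tissue-level table of corrected delta values (long format:
#' `sample_id`, `colony`, `treatment`, `compartment`, `aa`, `element`,
#' `delta`), extracts the nitrogen values of glutamic acid and
#' phenylalanine per sample, and evaluates the trophic-position equation.
#' Samples missing either amino acid are dropped with a warning.
#'
#' @param data tissue-level tibble of corrected deltas.
#' @param constants a [tp_constants()] object.
#' @return A tibble: `sample_id`, `colony`, `treatment`, `compartment`,
#'   `glu_delta`, `phe_delta`, `tp`, `beta`, `tdf`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' tp <- compute_tp(cohort)
#' head(tp)
#' @export
compute_tp <- function(data, constants = tp_constants()) {
  stopifnot(is.data.frame(data))
  n15 <- filter(data, .data$element == "N15",
                .data$aa %in% c("glutamic acid", "phenylalanine"))
  if (nrow(n15) == 0L) {
    abort("No delta-15N glutamic acid / phenylalanine rows in `data`.")
  }
  wide <- n15 |>
    select("sample_id", "colony", "treatment", "compartment", "aa", "delta") |>
    pivot_wider(names_from = "aa", values_from = "delta")
  ok <- !is.na(wide[["glutamic acid"]]) & !is.na(wide[["phenylalanine"]])
  if (!all(ok)) {
    warn(paste0(sum(!ok), " sample(s) dropped: missing Glu or Phe delta-15N."))
    wide <- wide[ok, ]
  }
  tibble(
    sample_id = wide$sample_id,
    colony = wide$colony,
    treatment = wide$treatment,
    compartment = wide$compartment,
    glu_delta = wide[["glutamic acid"]],
    phe_delta = wide[["phenylalanine"]],
    tp = tp_value(wide[["glutamic acid"]], wide[["phenylalanine"]], constants),
    beta = constants$beta,
    tdf = constants$tdf
  )
}

#' Group summaries of trophic position and delta values
#'
#' Per (treatment, compartment) arithmetic mean, SD and n of the per-sample
#' trophic positions (and their Glu/Phe inputs), optionally together with
#' every (amino acid, element) delta of a cohort table. TP is averaged over
#' per-sample values, matching how group distributions are reported; by
#' linearity this estimates the TP of the group-mean deltas.
#'
#' @param tp_results output of [compute_tp()].
#' @param cohort optional tissue-level delta table to summarise alongside.
#' @return A tibble: `treatment`, `compartment`, `variable`, `mean`, `sd`,
#'   `n`. For cohort deltas `variable` is `"<aa> (<element>)"`. SD is `NA`
#'   for single-sample groups.
#' @export
summarize_groups <- function(tp_results, cohort = NULL) {
  tp_long <- tp_results |>
    select("treatment", "compartment", "glu_delta", "phe_delta", "tp") |>
    pivot_longer(c("glu_delta", "phe_delta", "tp"),
                 names_to = "variable", values_to = "value")
  if (!is.null(cohort)) {
    tp_long <- bind_rows(
      tp_long,
      cohort |>
        mutate(variable = paste0(.data$aa, " (", .data$element, ")")) |>
        select("treatment", "compartment", "variable", value = "delta")
    )
  }
  tp_long |>
    group_by(.data$treatment, .data$compartment, .data$variable) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n = dplyr::n(), .groups = "drop")
}

#' Trophic position by treatment and compartment
#'
#' Box-and-jitter plot of per-sample trophic positions, one panel per
#' compartment, treatments on the x axis.
#'
#' @param tp_results output of [compute_tp()].
#' @return A ggplot object.
#' @export
plot_tp <- function(tp_results) {
  ggplot(tp_results, aes(x = .data$treatment, y = .data$tp,
                         fill = .data$treatment)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, height = 0, size = 1.5) +
    facet_wrap(~compartment) +
    labs(x = NULL, y = "Trophic position",
         title = "Trophic position by nutritional treatment") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Delta values by treatment and compartment
#'
#' Box-and-jitter panels of tissue-level deltas for a chosen element,
#' one panel per amino acid x compartment.
#'
#' @param cohort tissue-level delta tibble.
#' @param element `"N15"` or `"C13"`.
#' @return A ggplot object.
#' @export
plot_deltas <- function(cohort, element = "N15") {
  el <- element
  dat <- filter(cohort, .data$element == el)
  ylab <- if (el == "N15") expression(delta^15 * N ~ "(‰ vs AIR)") else
    expression(delta^13 * C ~ "(‰ vs VPDB)")
  ggplot(dat, aes(x = .data$treatment, y = .data$delta,
                  fill = .data$treatment)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, height = 0, size = 1) +
    facet_wrap(aa ~ compartment, scales = "free_y") +
    labs(x = NULL, y = ylab) +
    theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
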