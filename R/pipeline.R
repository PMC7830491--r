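#' End-to-end pipeline: simulate, calibrate, trophic position, statistics
#'
#' Runs the full workflow on a synthetic cohort: generate tissue-level
#' truth, push it through the instrument forward model, invert the
#' instrument layer, compute per-sample trophic positions, and run the
#' statistical battery (Kruskal-Wallis + pairwise Wilcoxon/BH on the
#' delta-15N variables; per-AA additive two-way ANOVA with Tukey HSD,
#' PERMANOVA and nMDS on the essential-AA delta-13C fingerprint restricted
#' to the autotrophy/heterotrophy contrast). Every stage is deterministic
#' given `seed`: stage sub-seeds are derived from it.
#'
#' The individual stage functions ([generate_cohort()],
#' [forward_instrument()], [calibrate_sequence()], [compute_tp()],
#' [permanova()], ...) are exported and can be run standalone; this wrapper
#' wires them together and optionally writes every table to `out_dir`
#' (CSVs, calibration/stats JSON, and the resolved configuration as YAML,
#' which can be passed back as `config` to rerun identically).
#'
#' @param config optional path to a YAML file with any of the fields below;
#'   explicit arguments override it.
#' @param seed master integer seed (mandatory unless in `config`).
#' @param out_dir directory for outputs; `NULL` writes nothing.
#' @param n_colonies mother colonies per treatment x compartment cell.
#' @param colony_sd SD of the per-colony random intercept (per mil).
#' @param beta,tdf trophic position constants.
#' @param n_perm PERMANOVA permutations.
#' @param carbon_treatments treatment subset for the carbon fingerprint
#'   analyses.
#' @param params parameter table; `instrument` an [instrument_model()];
#'   these two are R objects and are not read from YAML.
#' @param instrument instrument model.
#' @return A list (invisible) with `cohort`, `peaks`, `calibration`, `tp`,
#'   `group_summary`, `stats` (list: `kruskal`, `pairwise`, `variance`,
#'   `anova`, `permanova`, `nmds`) and `config` (the resolved settings).
#' @examples
#' res <- run_pipeline(seed = 1, n_perm = 99)
#' res$group_summary
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL,
                         n_colonies = 6L, colony_sd = 0,
                         beta = -0.36, tdf = 4.54, n_perm = 999,
                         carbon_treatments = c("autotrophy", "heterotrophy"),
                         params = default_parameters(),
                         instrument = default_instrument()) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (is.null(seed)) seed <- cfg$seed
    if (!is.null(cfg$n_colonies)) n_colonies <- cfg$n_colonies
    if (!is.null(cfg$colony_sd)) colony_sd <- cfg$colony_sd
    if (!is.null(cfg$beta)) beta <- cfg$beta
    if (!is.null(cfg$tdf)) tdf <- cfg$tdf
    if (!is.null(cfg$n_perm)) n_perm <- cfg$n_perm
    if (!is.null(cfg$carbon_treatments)) carbon_treatments <- cfg$carbon_treatments
    if (is.null(out_dir) && !is.null(cfg$out_dir)) out_dir <- cfg$out_dir
  }
  if (is.null(seed)) abort("`seed` is mandatory (argument or config field).")
  seed <- as.integer(seed)
  sub <- function(k) (seed + k) %% 2147483647L
  constants <- tp_constants(beta = beta, tdf = tdf)

  # simulate
  cohort <- generate_cohort(params = params, n_colonies = n_colonies,
                            colony_sd = colony_sd, seed = sub(0L))
  peaks <- forward_instrument(cohort, instrument = instrument, seed = sub(1L))

  # calibrate
  cal <- calibrate_sequence(peaks)
  corrected <- tidy(cal)

  # trophic position
  tp <- compute_tp(corrected, constants)
  group_summary <- summarize_groups(tp, corrected)

  # statistics
  symb_glu <- filter(corrected, .data$compartment == "symbiont",
                     .data$aa == "glutamic acid", .data$element == "N15")
  kw <- kruskal_wallis(symb_glu, delta, treatment)
  pw <- pairwise_wilcoxon_bh(symb_glu, delta, treatment)
  vc <- variance_checks(symb_glu, delta, treatment)

  cmat <- essential_carbon_matrix(corrected, treatments = carbon_treatments)
  anova_tabs <- purrr::map(essential_aas(), function(a) {
    d <- cmat[, c("treatment", "compartment", a)]
    names(d)[3] <- "delta"
    tidy(two_way_anova_tukey(d, delta, treatment, compartment))
  })
  names(anova_tabs) <- essential_aas()
  pmv <- permanova(cmat, c("treatment", "compartment"),
                   n_perm = n_perm, seed = sub(2L))
  ord <- nmds(cmat, seed = sub(3L))

  resolved <- list(seed = seed, n_colonies = n_colonies, colony_sd = colony_sd,
                   beta = beta, tdf = tdf, n_perm = n_perm,
                   carbon_treatments = as.list(carbon_treatments))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peak_table(peaks, file.path(out_dir, "peaks.csv"))
    readr::write_csv(corrected, file.path(out_dir, "corrected_samples.csv"))
    readr::write_csv(tp, file.path(out_dir, "trophic_position.csv"))
    readr::write_csv(group_summary, file.path(out_dir, "group_summary.csv"))
    readr::write_csv(tidy(pmv), file.path(out_dir, "permanova.csv"))
    readr::write_csv(tidy(ord), file.path(out_dir, "nmds_coordinates.csv"))
    jsonlite::write_json(
      list(nitrogen_fit = cal$nitrogen_fit, dcorr = cal$dcorr,
           drift = cal$drift, kruskal = kw, pairwise = pw, variance = vc),
      file.path(out_dir, "calibration_stats.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  }

  invisible(list(
    cohort = cohort, peaks = peaks, calibration = cal, tp = tp,
    group_summary = group_summary,
    stats = list(kruskal = kw, pairwise = pw, variance = vc,
                 anova = anova_tabs, permanova = pmv, nmds = ord),
    config = resolved
  ))
}
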