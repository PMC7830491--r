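#' Instrument model for the forward simulator
#'
#' Describes the GC-C-IRMS measurement layer that sits between tissue-level
#' truth and the raw peak table:
#'
#' * **Derivatization carbon addition** — chloroformate derivatization adds
#'   `n_d` exogenous carbons per amino acid, so the measured delta-13C of a
#'   derivatized compound is the moles-weighted mixture of the amino acid
#'   carbon and the added carbon
#'   (`delta_cd = (n_c * delta_c + n_d * delta_d) / (n_c + n_d)`).
#'   `derivatization_delta` is the delta-13C of the added carbon (scalar or
#'   a named per-AA vector); its empirical counterpart recovered during
#'   calibration is the per-AA `dcorr` factor. No nitrogen is added, so
#'   delta-15N has no mixing step.
#' * **Nitrogen instrument response** — an affine response
#'   `measured = intercept + slope * true`, standing in for combustion and
#'   linearity effects; it is removed by the per-sequence certified-standard
#'   regression.
#' * **Linear drift** — `drift_slope` per mil per injection per element.
#' * **Analytical noise** — i.i.d. Gaussian, `noise_sd` per element.
#' * **Sequence layout** — `replicates` injections per sample per element
#'   (duplicates for carbon, triplicates for nitrogen by default), standard
#'   blocks of 3 injections at the sequence start and end and after at most
#'   `standards_interval` sample injections (18, the instrument protocol
#'   maximum).
#'
#' @param derivatization_delta delta-13C of derivatization carbon, per mil;
#'   scalar or named per-AA vector.
#' @param drift_slope named per-element drift, per mil per injection.
#' @param noise_sd named per-element analytical SD, per mil.
#' @param replicates named per-element injections per sample.
#' @param standards_interval maximum sample injections between standard
#'   blocks (must be <= 18).
#' @param nitrogen_response `c(intercept, slope)` of the affine delta-15N
#'   instrument response.
#' @return A list of class `instrument_model`.
#' @examples
#' instrument_model()                      # packaged defaults
#' instrument_model(noise_sd = c(C13 = 0, N15 = 0))  # noise-free
#' @export
instrument_model <- function(derivatization_delta = -30,
                             drift_slope = c(C13 = 0.02, N15 = 0.03),
                             noise_sd = c(C13 = 0.3, N15 = 0.5),
                             replicates = c(C13 = 2L, N15 = 3L),
                             standards_interval = 18L,
                             nitrogen_response = c(intercept = -0.6, slope = 0.985)) {
  if (standards_interval > 18L) {
    abort("`standards_interval` must be <= 18 (instrument protocol maximum).")
  }
  if (any(replicates < 1L)) abort("`replicates` must be >= 1 per element.")
  stopifnot(all(.elements %in% names(drift_slope)),
            all(.elements %in% names(noise_sd)),
            all(.elements %in% names(replicates)),
            length(nitrogen_response) == 2L)
  structure(
    list(
      derivatization_delta = derivatization_delta,
      drift_slope = drift_slope,
      noise_sd = noise_sd,
      replicates = setNames(as.integer(replicates), names(replicates)),
      standards_interval = as.integer(standards_interval),
      nitrogen_response = c(intercept = unname(nitrogen_response[[1]]),
                            slope = unname(nitrogen_response[[2]]))
    ),
    class = "instrument_model"
  )
}

#' Default instrument model
#' @return An [instrument_model()] with the packaged default settings.
#' @export
default_instrument <- function() instrument_model()

deriv_delta_for <- function(instrument, aa) {
  dd <- instrument$derivatization_delta
  if (length(dd) == 1L && is.null(names(dd))) return(rep(dd, length(aa)))
  if (is.null(names(dd))) abort("Per-AA derivatization_delta must be named.")
  out <- dd[aa]
  if (anyNA(out)) {
    abort(paste0("derivatization_delta missing for: ",
                 paste(unique(aa[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Generate a tissue-level synthetic cohort
#'
#' Draws per-sample amino acid delta values from the treatment parameter
#' table: each (sample, aa, element) value is independent
#' `Normal(mean, sd)`, optionally plus a shared per-colony random intercept
#' (`colony_sd`, default 0 — the study design crossed the same six mother
#' colonies with all treatments and published no variance component).
#' This is the "truth" upstream of the instrument; see
#' [forward_instrument()] for the measurement layer.
#'
#' @param params parameter table (see [default_parameters()]).
#' @param n_colonies number of mother colonies (>= 2); each appears in
#'   every treatment x compartment cell.
#' @param treatments character vector of treatments to generate.
#' @param compartments character vector of compartments.
#' @param include_prey also generate `n_prey` prey reference samples from
#'   the `prey` parameter cells.
#' @param n_prey number of prey samples when `include_prey = TRUE`.
#' @param colony_sd SD (per mil) of the optional per-colony random
#'   intercept, shared across amino acids within an element.
#' @param seed integer seed; mandatory, every draw is reproducible.
#' @return A tibble with columns `sample_id`, `colony`, `treatment`,
#'   `compartment`, `aa`, `element`, `delta`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' dplyr::count(cohort, treatment, compartment)
#' @export
generate_cohort <- function(params = default_parameters(),
                            n_colonies = 6L,
                            treatments = c("autotrophy", "mixotrophy", "heterotrophy"),
                            compartments = c("host", "symbiont"),
                            include_prey = FALSE,
                            n_prey = n_colonies,
                            colony_sd = 0,
                            seed) {
  if (missing(seed)) abort("`seed` is mandatory for generate_cohort().")
  if (n_colonies < 2L) abort("`n_colonies` must be >= 2.")

  design <- expand_grid(treatment = treatments, compartment = compartments)
  # every requested cell must at least parameterize the TP amino acids
  for (i in seq_len(nrow(design))) {
    cell <- filter(params, .data$treatment == design$treatment[i],
                   .data$compartment == design$compartment[i],
                   .data$element == "N15",
                   .data$aa %in% c("glutamic acid", "phenylalanine"))
    if (nrow(cell) < 2L) {
      abort(paste0("Parameter table has no Glu/Phe delta-15N entry for cell (",
                   design$treatment[i], ", ", design$compartment[i], ")."))
    }
  }

  grid <- expand_grid(colony = seq_len(n_colonies), design) |>
    inner_join(params, by = c("treatment", "compartment"),
               relationship = "many-to-many")

  if (include_prey) {
    prey_par <- filter(params, .data$treatment == "prey")
    if (nrow(prey_par) == 0L) abort("Parameter table has no prey entries.")
    prey <- expand_grid(colony = seq_len(n_prey),
                        tibble(treatment = "prey", compartment = "prey")) |>
      inner_join(prey_par, by = c("treatment", "compartment"),
                 relationship = "many-to-many")
    grid <- bind_rows(grid, prey)
  }

  withr_seed(seed, {
    colony_eff <- expand_grid(colony = unique(grid$colony), element = .elements)
    colony_eff$eff <- rnorm(nrow(colony_eff), 0, colony_sd)
    grid <- left_join(grid, colony_eff, by = c("colony", "element"))
    grid$delta <- rnorm(nrow(grid), grid$mean, grid$sd) + grid$eff
  })

  grid |>
    mutate(sample_id = paste(substr(.data$treatment, 1, 4),
                             .data$compartment, .data$colony, sep = "_")) |>
    select("sample_id", "colony", "treatment", "compartment",
           "aa", "element", "delta") |>
    arrange(.data$element, .data$treatment, .data$compartment, .data$colony, .data$aa)
}

# evaluate expr under a local RNG stream, restoring the global state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}

#' Forward instrument model: tissue truth to raw peak tables
#'
#' Emits one injection sequence per element. Carbon peaks are the
#' moles-weighted mixture of amino acid and derivatization carbon; nitrogen
#' peaks pass through the affine instrument response. Both then acquire
#' linear drift in injection index and Gaussian analytical noise. Standard
#' blocks (3 injections of the full certified mix) open and close every
#' sequence and recur after at most `standards_interval` sample injections;
#' samples are injected `replicates[element]` times consecutively.
#'
#' @param cohort tissue-level cohort from [generate_cohort()].
#' @param instrument an [instrument_model()].
#' @param chemistry chemistry table supplying `n_c`, `n_d` per amino acid.
#' @param standards certified standards table (see [default_standards()]).
#' @param seed integer seed for the analytical noise.
#' @return A peak tibble in the [read_peak_table()] schema; standard peaks
#'   have `is_standard = TRUE` and `sample_id = "standard"`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' peaks <- forward_instrument(cohort, seed = 2)
#' head(peaks)
#' @export
forward_instrument <- function(cohort,
                               instrument = default_instrument(),
                               chemistry = aa_registry(),
                               standards = default_standards(),
                               seed) {
  if (missing(seed)) abort("`seed` is mandatory for forward_instrument().")
  chem <- chemistry
  if (any(chem$n_d == 0) && any(deriv_delta_for(instrument, chem$aa[chem$n_d == 0]) != 0)) {
    warn("n_d = 0 with nonzero derivatization_delta: carbon mixing degenerates to identity for those amino acids.")
  }

  out <- withr_seed(seed, {
    purrr::map(.elements, function(el) {
      forward_one_element(cohort, el, instrument, chem, standards)
    })
  })
  bind_rows(out)
}

forward_one_element <- function(cohort, el, instrument, chem, standards) {
  tissue <- filter(cohort, .data$element == el)
  if (nrow(tissue) == 0L) return(NULL)
  std <- filter(standards, .data$element == el)
  if (nrow(std) == 0L) abort(paste0("No certified standards for element ", el, "."))

  n_rep <- instrument$replicates[[el]]
  samples <- distinct(tissue, .data$sample_id, .data$colony,
                      .data$treatment, .data$compartment)

  # schedule: standard blocks of 3 bracketing runs of <= standards_interval
  # sample injections
  schedule <- list()
  add_block <- function(schedule) {
    c(schedule, replicate(3L, list(type = "standard"), simplify = FALSE))
  }
  schedule <- add_block(schedule)
  gap <- 0L
  for (i in seq_len(nrow(samples))) {
    for (r in seq_len(n_rep)) {
      if (gap >= instrument$standards_interval) {
        schedule <- add_block(schedule)
        gap <- 0L
      }
      schedule <- c(schedule, list(list(type = "sample", idx = i, rep = r)))
      gap <- gap + 1L
    }
  }
  if (gap > 0L) schedule <- add_block(schedule)

  # one injection -> one peak per amino acid present in that material
  rows <- purrr::imap(schedule, function(inj, inj_index) {
    if (inj$type == "standard") {
      tibble(
        sample_id = "standard", colony = NA_integer_,
        treatment = NA_character_, compartment = NA_character_,
        aa = std$aa, element = el,
        replicate = ((inj_index - 1L) %% 3L) + 1L,
        injection = inj_index,
        true_delta = std$certified_delta,
        is_standard = TRUE
      )
    } else {
      s <- samples[inj$idx, ]
      tis <- filter(tissue, .data$sample_id == s$sample_id)
      tibble(
        sample_id = s$sample_id, colony = s$colony,
        treatment = s$treatment, compartment = s$compartment,
        aa = tis$aa, element = el,
        replicate = inj$rep,
        injection = inj_index,
        true_delta = tis$delta,
        is_standard = FALSE
      )
    }
  })
  peaks <- list_rbind(rows)

  # element-specific response
  if (el == "C13") {
    peaks <- left_join(peaks, select(chem, "aa", "n_c", "n_d"), by = "aa")
    if (anyNA(peaks$n_c)) {
      abort(paste0("Chemistry table missing: ",
                   paste(unique(peaks$aa[is.na(peaks$n_c)]), collapse = ", ")))
    }
    dd <- deriv_delta_for(instrument, peaks$aa)
    signal <- (peaks$n_c * peaks$true_delta + peaks$n_d * dd) /
      (peaks$n_c + peaks$n_d)
  } else {
    nr <- instrument$nitrogen_response
    signal <- nr[["intercept"]] + nr[["slope"]] * peaks$true_delta
  }

  peaks$delta <- signal +
    instrument$drift_slope[[el]] * peaks$injection +
    rnorm(nrow(peaks), 0, instrument$noise_sd[[el]])

  select(peaks, "sample_id", "colony", "treatment", "compartment", "aa",
         "element", "replicate", "injection", "delta", "is_standard")
}
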