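#' Read a GC-C-IRMS peak table
#'
#' Reads a peak-level CSV in the package's interchange schema: one row per
#' injected peak, columns `sample_id`, `colony`, `treatment`, `compartment`,
#' `aa`, `element`, `replicate`, `injection`, `delta`, `is_standard`. Delta
#' values are plain per-mil floats (VPDB scale for `C13`, AIR scale for
#' `N15`). Amino acid names are matched case-insensitively against the
#' chemistry table (full names or three-letter codes); unknown names and
#' non-numeric delta values are rejected with row numbers rather than
#' silently dropped.
#'
#' @param path path to a CSV file.
#' @param chemistry chemistry table, see [aa_registry()].
#' @return A tibble of peak measurements with canonical amino acid names.
#' @seealso [write_peak_table()], [average_replicates()]
#' @export
read_peak_table <- function(path, chemistry = aa_registry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample_id", "colony", "treatment", "compartment", "aa",
                "element", "replicate", "injection", "delta", "is_standard")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Peak table ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  delta <- suppressWarnings(as.numeric(raw$delta))
  bad <- which(is.na(delta) & !is.na(raw$delta) & raw$delta != "NA")
  if (length(bad) > 0) {
    abort(paste0(
      "Non-numeric delta value(s) at data row(s) ",
      paste(utils::head(bad, 5L), collapse = ", "),
      " (token(s): ", paste(sQuote(utils::head(raw$delta[bad], 5L)), collapse = ", "), ")."
    ))
  }
  if (!all(raw$element %in% .elements)) {
    bad_el <- unique(setdiff(raw$element, .elements))
    abort(paste0("Unknown element code(s): ", paste(sQuote(bad_el), collapse = ", "),
                 "; expected C13 or N15."))
  }
  tibble(
    sample_id   = raw$sample_id,
    colony      = suppressWarnings(as.integer(raw$colony)),
    treatment   = raw$treatment,
    compartment = raw$compartment,
    aa          = match_aa(raw$aa, chemistry),
    element     = raw$element,
    replicate   = as.integer(raw$replicate),
    injection   = as.integer(raw$injection),
    delta       = delta,
    is_standard = tolower(raw$is_standard) %in% c("true", "t", "1", "yes")
  )
}

#' Write a peak table CSV
#'
#' Inverse of [read_peak_table()]; comma-separated, UTF-8, `.` decimal,
#' one header row, per-mil values stored as plain floats.
#'
#' @param peaks a peak tibble as produced by [forward_instrument()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Read a certified standards table
#'
#' @param path CSV with columns `aa`, `element`, `certified_delta`.
#' @param chemistry chemistry table used to canonicalize amino acid names.
#' @return A tibble with canonical amino acid names.
#' @export
read_standards <- function(path, chemistry = aa_registry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    aa = readr::col_character(),
    element = readr::col_character(),
    certified_delta = readr::col_double()
  ))
  missing_cols <- setdiff(c("aa", "element", "certified_delta"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Standards table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw$aa <- match_aa(raw$aa, chemistry)
  as_tibble(raw)
}

#' Read an amino acid chemistry table
#'
#' @param path CSV with columns `aa`, `n_c`, `n_d`, `essential`,
#'   `trophic_class` (and optionally `code`).
#' @return A chemistry tibble usable wherever [aa_registry()] is.
#' @export
read_chemistry <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols())
  required <- c("aa", "n_c", "n_d", "essential", "trophic_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Chemistry table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("code" %in% names(raw))) raw$code <- raw$aa
  if (any(raw$n_c < 2)) abort("Chemistry table: n_c must be >= 2 for every amino acid.")
  if (any(raw$n_d < 0)) abort("Chemistry table: n_d must be >= 0.")
  raw$n_c <- as.integer(raw$n_c)
  raw$n_d <- as.integer(raw$n_d)
  as_tibble(raw)
}

#' Average replicate injections
#'
#' Each sample is injected multiple times per element (typically duplicates
#' for carbon, triplicates for nitrogen); downstream corrections operate on
#' one value per (sample, amino acid, element). Returns the arithmetic mean,
#' the replicate SD (`NA` when n = 1), the replicate count, and the mean
#' injection index (replicate injections are consecutive, and all
#' corrections downstream are linear in injection index, so averaging the
#' index commutes with drift correction).
#'
#' @param peaks a peak tibble (see [read_peak_table()]).
#' @return A tibble with one row per (sample_id, aa, element) and columns
#'   `delta` (mean), `delta_sd`, `n_rep`, `injection` (mean index), plus the
#'   carried design columns.
#' @export
average_replicates <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (!all(peaks$element %in% .elements)) {
    abort("average_replicates(): element must be C13 or N15 in every row.")
  }
  if (any(!is.finite(peaks$delta))) {
    abort("average_replicates(): non-finite delta value(s).")
  }
  peaks |>
    group_by(.data$sample_id, .data$colony, .data$treatment,
             .data$compartment, .data$aa, .data$element, .data$is_standard) |>
    summarise(
      delta_sd  = sd(.data$delta),
      n_rep     = dplyr::n(),
      injection = mean(.data$injection),
      delta     = mean(.data$delta),
      .groups = "drop"
    ) |>
    select("sample_id", "colony", "treatment", "compartment", "aa",
           "element", "injection", "delta", "delta_sd", "n_rep", "is_standard")
}

#' Validate a cohort of corrected sample records
#'
#' Report-only checks on a tissue-level table (`sample_id`, `colony`,
#' `treatment`, `compartment`, `aa`, `element`, `delta`): design balance
#' across colonies x treatments x compartments, missing (aa, element) cells
#' relative to the cohort-wide amino acid set, and out-of-range deltas
#' (|delta| > 100 per mil is flagged as physically implausible for natural
#' tissue). Nothing is enforced; real sequences lose peaks.
#'
#' @param records tissue-level tibble.
#' @return An object of class `csiaa_validation`: a list with `balance`
#'   (samples per treatment x compartment), `missing` (absent cells),
#'   `range_flags` (out-of-range rows) and `balanced` (logical).
#' @export
validate_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  samples <- distinct(records, .data$sample_id, .data$colony,
                      .data$treatment, .data$compartment)
  balance <- count(samples, .data$treatment, .data$compartment, name = "n_samples")
  balanced <- length(unique(balance$n_samples)) <= 1L

  expected <- expand_grid(
    distinct(samples, .data$sample_id),
    distinct(records, .data$aa, .data$element)
  )
  missing <- anti_join(expected, records, by = c("sample_id", "aa", "element"))
  range_flags <- filter(records, abs(.data$delta) > 100)

  structure(
    list(balance = balance, missing = missing, range_flags = range_flags,
         balanced = balanced && nrow(missing) == 0L),
    class = "csiaa_validation"
  )
}

#' @export
print.csiaa_validation <- function(x, ...) {
  cat("Cohort validation\n")
  cat("  design balance:", if (x$balanced) "balanced" else "NOT balanced", "\n")
  print(x$balance)
  cat("  missing (aa, element) cells:", nrow(x$missing), "\n")
  if (nrow(x$missing) > 0) print(x$missing)
  cat("  out-of-range deltas (|delta| > 100):", nrow(x$range_flags), "\n")
  if (nrow(x$range_flags) > 0) print(x$range_flags)
  invisible(x)
}
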