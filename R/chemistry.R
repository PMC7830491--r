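#' Amino acid registry
#'
#' Returns the amino acid chemistry table used throughout the package: one
#' row per amino acid with its canonical name, three-letter code, skeletal
#' carbon count `n_c`, derivatization carbon count `n_d`, essentiality, and
#' trophic class. Glutamic acid is the canonical "trophic" amino acid
#' (strong 15N enrichment per trophic transfer) and phenylalanine the
#' canonical "source" amino acid (minimal enrichment, preserving the
#' baseline), which together drive the trophic-position statistic.
#'
#' Chloroformate derivatization (the chemistry assumed by the instrument
#' model) adds exogenous carbon but no nitrogen, so only carbon needs a
#' per-AA correction. The number of added carbons depends on the reagent and
#' on each amino acid's side chain; the packaged default is `n_d = 4` for
#' every amino acid and can be overridden by supplying a modified table to
#' the functions that accept a `chemistry` argument.
#'
#' @return A tibble with columns `aa`, `code`, `n_c`, `n_d`, `essential`,
#'   `trophic_class`.
#' @examples
#' aa_registry()
#' @export
aa_registry <- function() {
  reg <- tribble(
    ~aa,             ~code,  ~n_c, ~essential, ~trophic_class,
    "alanine",       "Ala",  3L,   FALSE,      "trophic",
    "glycine",       "Gly",  2L,   FALSE,      "source",
    "valine",        "Val",  5L,   TRUE,       "trophic",
    "leucine",       "Leu",  6L,   TRUE,       "trophic",
    "isoleucine",    "Ile",  6L,   TRUE,       "trophic",
    "methionine",    "Met",  5L,   TRUE,       "other",
    "glutamic acid", "Glu",  5L,   FALSE,      "trophic",
    "phenylalanine", "Phe",  9L,   TRUE,       "source"
  )
  reg$n_d <- 4L
  as_tibble(reg[, c("aa", "code", "n_c", "n_d", "essential", "trophic_class")])
}

#' The five essential amino acids used for delta-13C fingerprinting
#' @return Character vector of canonical names.
#' @export
essential_aas <- function() {
  c("valine", "leucine", "isoleucine", "methionine", "phenylalanine")
}

#' Match amino acid names against the registry
#'
#' Case-insensitive; accepts canonical full names or three-letter codes.
#' Unknown names are an error (listing the offending tokens), never silently
#' dropped.
#'
#' @param x character vector of amino acid names or codes.
#' @param chemistry a chemistry table, see [aa_registry()].
#' @return Character vector of canonical names, same length as `x`.
#' @export
match_aa <- function(x, chemistry = aa_registry()) {
  lut <- setNames(
    rep(chemistry$aa, 2L),
    tolower(c(chemistry$aa, chemistry$code))
  )
  hit <- lut[tolower(trimws(x))]
  if (anyNA(hit)) {
    bad <- unique(x[is.na(hit)])
    abort(paste0(
      "Unknown amino acid name(s): ", paste(sQuote(bad), collapse = ", "),
      ". Known names: ", paste(chemistry$aa, collapse = ", "), "."
    ))
  }
  unname(hit)
}

#' Certified amino acid standard set
#'
#' The calibration standard is a mixture of amino acids with certified
#' delta values, injected in blocks of three at the start and end of every
#' sequence (and at least every 18 injections in between). The nitrogen set
#' spans -6.69 to +43.25 per mil — a wide range brackets the samples so the
#' per-sequence regression calibration interpolates rather than
#' extrapolates. Alanine (+43.25 per mil) and valine (+30.19 per mil) carry
#' their published certified delta-15N; the remaining certified values in
#' the packaged table are synthetic but span-preserving placeholders for a
#' typical seven-AA commercial mix, as are the certified delta-13C values.
#' Supply your own table (columns `aa`, `element`, `certified_delta`) for
#' real sequences.
#'
#' @return A tibble with columns `aa`, `element`, `certified_delta`.
#' @examples
#' default_standards()
#' @export
default_standards <- function() {
  n15 <- tribble(
    ~aa,             ~certified_delta,
    "alanine",       43.25,
    "valine",        30.19,
    "leucine",       12.77,
    "isoleucine",     7.41,
    "glutamic acid",  2.15,
    "methionine",    -1.33,
    "phenylalanine", -6.69
  )
  c13 <- tribble(
    ~aa,             ~certified_delta,
    "alanine",       -19.6,
    "valine",        -12.1,
    "leucine",       -28.3,
    "isoleucine",    -11.9,
    "glutamic acid", -16.5,
    "methionine",    -28.1,
    "phenylalanine", -27.1
  )
  bind_rows(
    mutate(n15, element = "N15"),
    mutate(c13, element = "C13")
  )[, c("aa", "element", "certified_delta")]
}
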