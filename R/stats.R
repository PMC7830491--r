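#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way comparison used for the delta-15N variables, which
#' fail the parametric assumptions (see [variance_checks()]). Midrank tie
#' correction, chi-square reference distribution (delegated to
#' [stats::kruskal.test()]). When every value is identical the test is
#' degenerate; the statistic is reported as 0 with p = 1 and a warning.
#'
#' @param data a data frame.
#' @param value bare column name of the response.
#' @param group bare column name of the grouping factor.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`,
#'   `n_total`.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                     g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(d, y, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  y <- pull(data, {{ value }})
  g <- factor(pull(data, {{ group }}))
  if (nlevels(g) < 2L) abort("kruskal_wallis(): need >= 2 groups.")
  if (length(unique(y)) < 2L) {
    warn("All values identical: Kruskal-Wallis test is degenerate (p = 1).")
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n_groups = nlevels(g), n_total = length(y)))
  }
  kt <- kruskal.test(y, g)
  tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n_groups = nlevels(g),
    n_total = length(y)
  )
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Post-hoc companion to [kruskal_wallis()]: every pair of groups is
#' compared with a two-sided rank-sum test and the p-values are adjusted
#' across the pairwise family with the BH step-up procedure. Exact p-values
#' are used when both groups have fewer than 50 observations and the data
#' are tie-free (the [stats::wilcox.test()] default); otherwise the normal
#' approximation with continuity correction. Pairs with fewer than 2
#' observations in a group are skipped with a warning.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with one row per pair: `group1`, `group2`, `statistic`
#'   (W), `p_value`, `p_adjusted`, `n1`, `n2`.
#' @export
pairwise_wilcoxon_bh <- function(data, value, group) {
  y <- pull(data, {{ value }})
  g <- factor(pull(data, {{ group }}))
  lev <- levels(g)
  if (length(lev) < 2L) abort("pairwise_wilcoxon_bh(): need >= 2 groups.")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    y1 <- y[g == p[1]]; y2 <- y[g == p[2]]
    if (length(y1) < 2L || length(y2) < 2L) {
      warn(paste0("Pair (", p[1], ", ", p[2], ") skipped: group with n < 2."))
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(y1, y2))
    tibble(group1 = p[1], group2 = p[2], statistic = unname(wt$statistic),
           p_value = wt$p.value, n1 = length(y1), n2 = length(y2))
  })
  out <- list_rbind(rows)
  if (nrow(out) > 0) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  select(out, "group1", "group2", "statistic", "p_value", "p_adjusted", "n1", "n2")
}

#' Variance-homogeneity checks
#'
#' Levene's test (Brown-Forsythe variant, centred at the group medians) and
#' Bartlett's test of homogeneity of variances, reported together to
#' justify the parametric/nonparametric branching of the downstream
#' analysis. Constant data make both tests degenerate and are flagged
#' rather than tested.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with one row per test: `test`, `statistic`, `df`,
#'   `p_value`, `note`.
#' @export
variance_checks <- function(data, value, group) {
  y <- pull(data, {{ value }})
  g <- factor(pull(data, {{ group }}))
  keep <- names(which(table(g) >= 2L))
  if (length(keep) < length(levels(g))) {
    warn("Groups with n < 2 excluded from variance checks.")
  }
  sel <- g %in% keep
  y <- y[sel]; g <- droplevels(g[sel])
  if (nlevels(g) < 2L) abort("variance_checks(): need >= 2 groups with n >= 2.")
  if (length(unique(y)) < 2L) {
    return(tibble(
      test = c("levene", "bartlett"), statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, note = "constant data: tests degenerate"
    ))
  }
  lev <- car::leveneTest(y, g, center = median)
  bar <- bartlett.test(y, g)
  tibble(
    test = c("levene", "bartlett"),
    statistic = c(lev[1, "F value"], unname(bar$statistic)),
    df = c(lev[1, "Df"], unname(bar$parameter)),
    p_value = c(lev[1, "Pr(>F)"], bar$p.value),
    note = NA_character_
  )
}

#' Additive two-way ANOVA with Tukey HSD
#'
#' Sequential (Type-I) sums of squares for the additive two-factor model
#' `response ~ factor_a + factor_b`, in that order — treatment entered
#' before compartment, matching how the carbon analysis partitions the
#' design — followed by Tukey honest significant differences on each
#' factor. The model is fitted with [stats::aov()]; an empty design cell is
#' an error naming the cell.
#'
#' @param data a data frame.
#' @param response bare column name of the numeric response.
#' @param factor_a bare column name of the first factor (enters first).
#' @param factor_b bare column name of the second factor.
#' @param conf_level confidence level for the Tukey intervals.
#' @return An object of class `csiaa_anova`: list with `anova_table`
#'   (term, df, sum_sq, mean_sq, statistic, p_value) and `tukey` (term,
#'   contrast, estimate, conf_low, conf_high, p_adjusted). `tidy()` returns
#'   the ANOVA table.
#' @export
two_way_anova_tukey <- function(data, response, factor_a, factor_b,
                                conf_level = 0.95) {
  df <- tibble(
    y = pull(data, {{ response }}),
    A = factor(pull(data, {{ factor_a }})),
    B = factor(pull(data, {{ factor_b }}))
  )
  cells <- complete(count(df, .data$A, .data$B), .data$A, .data$B,
                    fill = list(n = 0L))
  if (any(cells$n == 0L)) {
    empty <- cells[cells$n == 0L, ]
    abort(paste0("Empty design cell(s): ",
                 paste(paste0("(", empty$A, ", ", empty$B, ")"), collapse = ", ")))
  }
  fit <- aov(y ~ A + B, data = df)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  terms[terms == "A"] <- rlang::as_name(rlang::enquo(factor_a))
  terms[terms == "B"] <- rlang::as_name(rlang::enquo(factor_b))
  anova_table <- tibble(
    term = terms,
    df = sm$Df,
    sum_sq = sm$`Sum Sq`,
    mean_sq = sm$`Mean Sq`,
    statistic = sm$`F value`,
    p_value = sm$`Pr(>F)`
  )
  # constant response: pseudo 0/0 ratios are reported as 0 (no effect), p NA
  tot <- sum(anova_table$sum_sq)
  if (tot < 1e-10 * max(1, mean(df$y)^2)) {
    anova_table$sum_sq <- 0
    anova_table$mean_sq <- 0
    anova_table$statistic[seq_len(nrow(anova_table) - 1L)] <- 0
    anova_table$p_value[seq_len(nrow(anova_table) - 1L)] <- NA_real_
  }
  tk <- suppressWarnings(TukeyHSD(fit, conf.level = conf_level))
  tukey <- purrr::imap(tk, function(m, nm) {
    nm_out <- if (nm == "A") rlang::as_name(rlang::enquo(factor_a)) else
      rlang::as_name(rlang::enquo(factor_b))
    tibble(term = nm_out, contrast = rownames(m), estimate = m[, "diff"],
           conf_low = m[, "lwr"], conf_high = m[, "upr"],
           p_adjusted = m[, "p adj"])
  }) |> list_rbind()
  structure(list(anova_table = anova_table, tukey = tukey, fit = fit),
            class = "csiaa_anova")
}

#' @method tidy csiaa_anova
#' @export
tidy.csiaa_anova <- function(x, ...) x$anova_table

#' @method glance csiaa_anova
#' @export
glance.csiaa_anova <- function(x, ...) {
  res <- x$anova_table[x$anova_table$term == "Residuals", ]
  tibble(df_residual = res$df, sigma = sqrt(res$mean_sq),
         n = sum(x$anova_table$df) + 1L)
}

#' @export
print.csiaa_anova <- function(x, ...) {
  cat("Additive two-way ANOVA (sequential SS)\n")
  print(x$anova_table)
  cat("Tukey HSD:\n")
  print(x$tukey)
  invisible(x)
}

#' Wide matrix of essential amino acid delta-13C values
#'
#' Reshapes a tissue-level delta table into the samples-by-amino-acids
#' matrix used for the multivariate carbon fingerprint (PERMANOVA, nMDS):
#' one row per sample, one numeric column per essential amino acid.
#'
#' @param cohort tissue-level delta tibble.
#' @param aas amino acids to keep (default the five essential AAs).
#' @param treatments optional treatment subset (e.g.
#'   `c("autotrophy", "heterotrophy")`, the contrast for which the carbon
#'   fingerprint is informative).
#' @return A wide tibble: `sample_id`, `colony`, `treatment`,
#'   `compartment`, then one column per amino acid.
#' @export
essential_carbon_matrix <- function(cohort, aas = essential_aas(),
                                    treatments = NULL) {
  x <- filter(cohort, .data$element == "C13", .data$aa %in% aas)
  if (!is.null(treatments)) x <- filter(x, .data$treatment %in% .env$treatments)
  wide <- x |>
    select("sample_id", "colony", "treatment", "compartment", "aa", "delta") |>
    pivot_wider(names_from = "aa", values_from = "delta")
  if (anyNA(wide)) abort("Incomplete essential-AA matrix: missing delta-13C value(s).")
  wide
}

# -0.5 * D^2, double-centred (Gower); trace equals the total sum of squares
gower_center <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  Q <- qr.Q(qr(X))
  tcrossprod(Q)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Distance-based MANOVA with sequential (Type-I) partitioning of the
#' Gower-centred squared-distance matrix over an additive model, in the
#' order the terms are given (treatment before compartment for the carbon
#' fingerprint). Pseudo-F per term is mean-square ratio against the
#' residual; p-values come from free permutation of the sample rows (no
#' strata), with the observed configuration counted in both the numerator
#' and the denominator: `p = (1 + #(F* >= F)) / (1 + n_perm)`.
#'
#' This is the in-package implementation of the standard distance-based
#' partitioning; tests cross-check it against an independent reference and
#' against exhaustive label enumeration on small designs.
#'
#' @param data wide tibble, e.g. from [essential_carbon_matrix()]: factor
#'   columns named in `terms`, response columns in `vars`.
#' @param terms character vector of factor column names, in entry order.
#' @param vars response column names; default every numeric column not in
#'   `terms` (identifier columns `sample_id`/`colony` are ignored).
#' @param n_perm number of permutations (default 999; < 99 gives a coarse
#'   p resolution and a warning).
#' @param seed integer seed for the permutation stream (mandatory).
#' @param distance currently `"euclidean"`.
#' @return An object of class `csiaa_permanova` whose `table` element has
#'   one row per term plus `Residual` and `Total`: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic` (pseudo-F), `r_squared`, `p_value`. `tidy()`
#'   returns the table.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' mat <- essential_carbon_matrix(cohort,
#'                                treatments = c("autotrophy", "heterotrophy"))
#' permanova(mat, c("treatment", "compartment"), n_perm = 199, seed = 1)
#' @export
permanova <- function(data, terms, vars = NULL, n_perm = 999, seed,
                      distance = "euclidean") {
  if (missing(seed)) abort("`seed` is mandatory for permanova().")
  if (n_perm < 99) warn("n_perm < 99: permutation p-values will be coarse.")
  distance <- match.arg(distance)
  stopifnot(all(terms %in% names(data)))
  if (is.null(vars)) {
    cand <- setdiff(names(data), c(terms, "sample_id", "colony"))
    vars <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(vars) == 0L) abort("No numeric response columns found.")
  Y <- as.matrix(data[, vars])
  n <- nrow(Y)
  G <- gower_center(dist(Y))

  # sequential hat matrices: intercept, then each term added in order
  f <- data[terms]
  f[] <- lapply(f, factor)
  X <- matrix(1, n, 1)
  hats <- list(hat_matrix(X))
  dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~x, data.frame(x = f[[k]]))[, -1, drop = FALSE])
    hats[[k + 1L]] <- hat_matrix(X)
    dfs[k] <- qr(X)$rank - sum(dfs) - 1L
  }
  H_full <- hats[[length(hats)]]
  df_res <- n - qr(X)$rank
  if (df_res <= 0L) abort("No residual degrees of freedom.")

  ss_tol <- 1e-10 * max(1, abs(sum(diag(G))))
  ss_terms <- function(G) {
    ss <- vapply(seq_along(terms), function(k) {
      sum((hats[[k + 1L]] - hats[[k]]) * G)
    }, numeric(1))
    ss_res <- sum((diag(n) - H_full) * G)
    # clamp numerical dust so that degenerate partitions give exact 0 / Inf
    ss[abs(ss) < ss_tol] <- 0
    if (abs(ss_res) < ss_tol) ss_res <- 0
    list(ss = ss, ss_res = ss_res)
  }

  obs <- ss_terms(G)
  ss_tot <- sum(diag(G))
  f_obs <- (obs$ss / dfs) / (obs$ss_res / df_res)

  exceed <- rep(1L, length(terms))  # observed counted in the numerator
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      perm <- ss_terms(G[p, p])
      f_perm <- (perm$ss / dfs) / (perm$ss_res / df_res)
      exceed <- exceed + (f_perm >= f_obs - 1e-12)
    }
  })
  p_values <- exceed / (n_perm + 1)

  table <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_tot),
    mean_sq = c(obs$ss / dfs, obs$ss_res / df_res, NA_real_),
    statistic = c(f_obs, NA_real_, NA_real_),
    r_squared = c(obs$ss / ss_tot, obs$ss_res / ss_tot, 1),
    p_value = c(p_values, NA_real_, NA_real_)
  )
  structure(list(table = table, n = n, n_perm = n_perm, seed = seed,
                 vars = vars, terms = terms),
            class = "csiaa_permanova")
}

#' @method tidy csiaa_permanova
#' @export
tidy.csiaa_permanova <- function(x, ...) x$table

#' @method glance csiaa_permanova
#' @export
glance.csiaa_permanova <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm, n_vars = length(x$vars))
}

#' @export
print.csiaa_permanova <- function(x, ...) {
  cat("PERMANOVA (Euclidean distances, sequential SS,",
      x$n_perm, "free permutations)\n")
  print(x$table)
  invisible(x)
}

#' Nonmetric multidimensional scaling of a carbon fingerprint
#'
#' 2-D nMDS embedding minimizing Kruskal stress-1, delegated to
#' [vegan::metaMDS()] (isotonic-regression majorization with 20 random
#' starts plus a metric start; the best solution is kept). Interpretation
#' is rank-based: only relative point configuration is meaningful, not
#' axes, rotation or scale.
#'
#' @param data wide tibble (see [essential_carbon_matrix()]) or a
#'   [stats::dist] object.
#' @param dims embedding dimension (default 2).
#' @param seed integer seed (mandatory; starts are random).
#' @param trymax maximum random starts.
#' @return Object of class `csiaa_nmds`: `points` (tibble of coordinates
#'   `NMDS1`, `NMDS2`, plus carried factor columns), `stress`, `converged`.
#'   `tidy()` returns the coordinates, `glance()` the stress;
#'   `autoplot()` draws the ordination.
#' @export
nmds <- function(data, dims = 2, seed, trymax = 20) {
  if (missing(seed)) abort("`seed` is mandatory for nmds().")
  meta <- NULL
  if (inherits(data, "dist")) {
    d <- data
  } else {
    keep <- setdiff(names(data), c("sample_id", "colony", "treatment", "compartment"))
    num <- keep[vapply(data[keep], is.numeric, logical(1))]
    d <- dist(as.matrix(data[, num]))
    meta <- data[, intersect(c("sample_id", "colony", "treatment", "compartment"),
                             names(data))]
  }
  fit <- withr_seed(seed, {
    suppressWarnings(suppressMessages(
      vegan::metaMDS(d, k = dims, trymax = trymax, trace = 0)
    ))
  })
  pts <- as_tibble(as.data.frame(fit$points))
  names(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  if (!is.null(meta)) pts <- dplyr::bind_cols(meta, pts)
  structure(
    list(points = pts, stress = fit$stress,
         converged = isTRUE(fit$converged) || identical(fit$converged, TRUE) ||
           (is.numeric(fit$converged) && fit$converged > 0),
         dims = dims, seed = seed),
    class = "csiaa_nmds"
  )
}

#' @method tidy csiaa_nmds
#' @export
tidy.csiaa_nmds <- function(x, ...) x$points

#' @method glance csiaa_nmds
#' @export
glance.csiaa_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged, dims = x$dims)
}

#' @method autoplot csiaa_nmds
#' @export
autoplot.csiaa_nmds <- function(object, ...) {
  pts <- object$points
  p <- ggplot(pts, aes(x = .data$NMDS1, y = .data$NMDS2))
  if (all(c("treatment", "compartment") %in% names(pts))) {
    p <- p + geom_point(aes(colour = .data$treatment,
                            shape = .data$compartment), size = 2.5)
  } else {
    p <- p + geom_point(size = 2.5)
  }
  p + coord_equal() +
    labs(title = "nMDS of essential amino acid δ13C",
         subtitle = sprintf("stress = %.3f", object$stress)) +
    theme_minimal()
}

#' @export
print.csiaa_nmds <- function(x, ...) {
  cat("nMDS ordination:", nrow(x$points), "points in", x$dims,
      "dimensions; stress =", signif(x$stress, 4),
      if (x$converged) "(converged)\n" else "(best of non-converged runs)\n")
  invisible(x)
}
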