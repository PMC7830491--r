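test_that("Kruskal-Wallis matches the hand rank computation and handles degeneracy", {
  d <- tibble::tibble(y = as.numeric(1:9), g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(d, y, g)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)  # no ties: 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  expect_equal(kw$df, 2)

  same <- tibble::tibble(y = rep(2.5, 6), g = rep(c("a", "b"), each = 3))
  expect_warning(kw0 <- kruskal_wallis(same, y, g), "degenerate")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
})

test_that("Kruskal-Wallis null p-values are uniform", {
  set.seed(17)
  p <- replicate(1000, {
    d <- tibble::tibble(y = rnorm(90), g = rep(c("a", "b", "c"), each = 30))
    kruskal_wallis(d, y, g)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("pairwise Wilcoxon applies BH across the pairwise family", {
  set.seed(5)
  d <- tibble::tibble(
    y = c(rnorm(8), rnorm(8, 1), rnorm(8, 3)),
    g = rep(c("a", "b", "c"), each = 8)
  )
  pw <- pairwise_wilcoxon_bh(d, y, g)
  expect_equal(nrow(pw), 3L)
  # adjusted values match an independent BH step-up on the raw p's
  expect_equal(pw$p_adjusted, bh_stepup(pw$p_value), tolerance = 1e-12)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))
  expect_true(all(pw$p_adjusted <= 1))

  # single pair: adjusted equals raw
  d2 <- dplyr::filter(d, g != "c")
  pw2 <- pairwise_wilcoxon_bh(d2, y, g)
  expect_equal(pw2$p_adjusted, pw2$p_value)

  # identical raw p's are a BH fixed point
  expect_equal(bh_stepup(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bh_stepup(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))

  # a tiny group is skipped with a warning
  d3 <- dplyr::bind_rows(d2, tibble::tibble(y = 0, g = "z"))
  msgs <- testthat::capture_warnings(pw3 <- pairwise_wilcoxon_bh(d3, y, g))
  expect_true(all(grepl("skipped", msgs)))
  expect_equal(nrow(pw3), 1L)
})

test_that("variance checks detect heteroscedasticity and flag constants", {
  set.seed(11)
  eq <- tibble::tibble(y = rnorm(60), g = rep(c("a", "b"), each = 30))
  v_eq <- variance_checks(eq, y, g)
  expect_equal(v_eq$test, c("levene", "bartlett"))
  expect_true(all(v_eq$p_value > 0.05))

  het <- tibble::tibble(y = c(rnorm(30, sd = 1), rnorm(30, sd = 10)),
                        g = rep(c("a", "b"), each = 30))
  v_het <- variance_checks(het, y, g)
  expect_true(all(v_het$p_value < 0.01))

  const <- tibble::tibble(y = rep(1, 6), g = rep(c("a", "b"), each = 3))
  v_c <- variance_checks(const, y, g)
  expect_true(all(grepl("degenerate", v_c$note)))
})

test_that("two-way ANOVA uses sequential SS in the stated factor order", {
  # balanced 2x2, additive means, zero noise
  d <- tidyr::expand_grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- ifelse(d$A == "a2", 4, 0) + ifelse(d$B == "b2", 2, 0)
  res <- two_way_anova_tukey(d, y, A, B)
  tab <- tidy(res)
  # hand arithmetic: SS_A = n * sum (mean_a - grand)^2 = 12 * 2^2 ... = 48
  expect_equal(tab$sum_sq[tab$term == "A"], 12 * 2^2, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "B"], 12 * 1^2, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "Residuals"], 0, tolerance = 1e-10)

  # constant response: all F reported as 0
  d0 <- d
  d0$y <- 3
  tab0 <- tidy(two_way_anova_tukey(d0, y, A, B))
  expect_equal(tab0$statistic[tab0$term %in% c("A", "B")], c(0, 0))

  # sequential SS agree with explicit projection arithmetic on unbalanced data
  set.seed(23)
  du <- d[-c(1, 5), ]
  du$y <- rnorm(nrow(du))
  tabu <- tidy(two_way_anova_tukey(du, y, A, B))
  ss <- function(r) sum((r - mean(r))^2)
  r0 <- du$y
  r1 <- stats::residuals(stats::lm(y ~ A, du))
  r2 <- stats::residuals(stats::lm(y ~ A + B, du))
  expect_equal(tabu$sum_sq[tabu$term == "A"], ss(r0) - sum(r1^2), tolerance = 1e-8)
  expect_equal(tabu$sum_sq[tabu$term == "B"], sum(r1^2) - sum(r2^2), tolerance = 1e-8)

  # empty cell is an error naming the cell
  de <- dplyr::filter(d, !(A == "a1" & B == "b2"))
  expect_error(two_way_anova_tukey(de, y, A, B), "a1, b2")
})

test_that("PERMANOVA pseudo-F and p match exhaustive label enumeration", {
  dat <- tibble::tibble(
    treatment = rep(c("g1", "g2"), each = 3),
    x = c(0, 0, 0, 10, 10, 10)
  )
  res <- permanova(dat, "treatment", n_perm = 1999, seed = 7)
  tab <- tidy(res)

  # brute force in 1-D: Euclidean PERMANOVA reduces to univariate ANOVA
  f_for <- function(lab) {
    sst <- sum((dat$x - mean(dat$x))^2)
    ssw <- sum(tapply(dat$x, lab, function(v) sum((v - mean(v))^2)))
    ((sst - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_for(dat$treatment)
  expect_equal(tab$statistic[1], f_obs)  # both infinite for a perfect split

  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(i) {
    lab <- rep("g2", 6); lab[i] <- "g1"; f_for(lab)
  })
  p_exact <- mean(f_all >= f_obs)  # 2/20 under label exchange
  expect_equal(p_exact, 0.1)
  expect_lt(abs(tab$p_value[1] - p_exact), 0.03)

  # same enumeration on a noisy toy with finite F
  set.seed(8)
  dat2 <- tibble::tibble(treatment = rep(c("g1", "g2"), each = 3),
                         x = c(0.1, -0.2, 0.3, 9.8, 10.1, 10.4))
  res2 <- permanova(dat2, "treatment", n_perm = 1999, seed = 9)
  f_for2 <- function(lab) {
    sst <- sum((dat2$x - mean(dat2$x))^2)
    ssw <- sum(tapply(dat2$x, lab, function(v) sum((v - mean(v))^2)))
    ((sst - ssw) / 1) / (ssw / 4)
  }
  expect_equal(tidy(res2)$statistic[1], f_for2(dat2$treatment), tolerance = 1e-10)
})

test_that("PERMANOVA agrees with an independent reference implementation", {
  set.seed(31)
  dat <- tibble::tibble(
    treatment = rep(c("autotrophy", "heterotrophy"), each = 12),
    compartment = rep(rep(c("host", "symbiont"), each = 6), 2)
  )
  mat <- matrix(rnorm(24 * 5), 24, 5,
                dimnames = list(NULL, paste0("aa", 1:5)))
  mat[dat$treatment == "heterotrophy", 4] <- mat[dat$treatment == "heterotrophy", 4] - 3
  dat <- dplyr::bind_cols(dat, tibble::as_tibble(mat))

  mine <- tidy(permanova(dat, c("treatment", "compartment"),
                         n_perm = 999, seed = 3))
  ref <- vegan::adonis2(mat ~ treatment + compartment, data = dat,
                        permutations = 999, method = "euclidean", by = "terms")
  expect_equal(mine$sum_sq, ref$SumOfSqs, tolerance = 1e-8)
  expect_equal(mine$statistic[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$df, ref$Df, tolerance = 0)

  # partition identity holds on every run
  expect_equal(sum(mine$sum_sq[1:3]), mine$sum_sq[4], tolerance = 1e-9)
})

test_that("PERMANOVA null p-values are uniform", {
  set.seed(41)
  p <- replicate(1000, {
    dat <- tibble::tibble(treatment = rep(c("a", "b"), each = 6),
                          x = rnorm(12), y = rnorm(12))
    tidy(permanova(dat, "treatment", n_perm = 199,
                   seed = sample.int(1e6, 1)))$p_value[1]
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("nMDS recovers planar geometry", {
  # three equidistant points embed as an equilateral triangle, stress ~ 0
  d3 <- stats::dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  ord3 <- nmds(d3, seed = 1)
  emb <- as.matrix(ord3$points[, c("NMDS1", "NMDS2")])
  dd <- as.numeric(stats::dist(emb))
  expect_lt(max(dd) - min(dd), 1e-4)
  expect_lt(ord3$stress, 1e-6)

  # points already planar: near-perfect 2-D recovery
  set.seed(2)
  pts <- matrix(rnorm(2 * 15), 15, 2)
  ord <- nmds(stats::dist(pts), seed = 3)
  expect_lt(ord$stress, 0.01)

  # deterministic under a fixed seed
  ord_b <- nmds(stats::dist(pts), seed = 3)
  expect_equal(ord$points, ord_b$points)
  expect_error(nmds(stats::dist(pts)), "seed")
})
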