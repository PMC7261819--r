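test_that("e_g centring matches the digamma formula and its symmetries", {
  # d_g = 4, s_p^2 = 1: e_g = -digamma(2) + log 2
  expect_equal(compute_eg(1, 4), -digamma(2) + log(2), tolerance = 1e-12)
  expect_equal(compute_eg(1, 4), 0.2703629, tolerance = 1e-6)
  # inversion: a variance of exp(digamma - log) has e_g exactly 0
  for (df in c(1, 4, 10))
    expect_equal(compute_eg(exp(digamma(df / 2) - log(df / 2)), df), 0,
                 tolerance = 1e-12)
  # multiplying all variances by c shifts e_g by log(c)
  set.seed(31)
  v <- rexp(20)
  expect_equal(compute_eg(3 * v, 4), compute_eg(v, 4) + log(3),
               tolerance = 1e-12)
  expect_error(compute_eg(c(1, 0), 4), "positive")
  expect_error(compute_eg(1, 0.5), "df")
})

test_that("the variance trend reproduces flat and linear signals", {
  set.seed(32)
  x <- runif(100, 0, 5)
  expect_equal(fit_trend(x, rep(2.5, 100)), rep(2.5, 100), tolerance = 1e-8)
  y <- 1.2 - 0.7 * x
  expect_equal(fit_trend(x, y), y, tolerance = 1e-8)
  # predictions outside the covariate range clamp to the boundary fit
  f <- fit_trend(x, y, newx = c(-10, 10))
  expect_equal(f, 1.2 - 0.7 * c(min(x), max(x)), tolerance = 1e-6)
  # too few distinct covariate values -> flat fallback with a warning
  expect_warning(ff <- fit_trend(rep(c(0, 1), 50), y), "flat prior")
  expect_equal(ff, rep(mean(y), 100))
  expect_error(fit_trend(x[1:5], y[1:5]), "at least 10")
})

test_that("the fitted trend is decreasing on count-dependent-variance data", {
  sim <- simulate_null(sim_spec(n_proteins = 3000, seed = 33))
  des <- design_spec(colnames(sim$matrix$values),
                     rep(c("A", "B", "C"), each = 3))
  lf <- fit_group_means(sim$matrix, des)
  x <- log2(as.numeric(sim$matrix$count))
  f <- fit_trend(x, log(lf$pooled_var))
  med <- tapply(f, x, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) < 0.05))
})

test_that("d0 grid estimation lands on the grid and recovers the truth", {
  # simulate variances from a scaled-inverse-chi-square prior with known d0
  gen <- function(d0_true, n, dg, seed) {
    set.seed(seed)
    sigma2 <- d0_true / rchisq(n, d0_true)       # s0^2 = 1
    sigma2 * rchisq(n, dg) / dg
  }
  sp2 <- gen(4, 5000, 4, seed = 34)
  eg <- compute_eg(sp2, 4)
  d0 <- estimate_d0(eg, rep(mean(eg), length(eg)), 4)
  expect_true(d0 >= 3 && d0 <= 5)
  expect_equal(d0 %% 0.1, 0, tolerance = 1e-9)

  # no excess scatter beyond sampling noise -> infinitely informative prior
  # (deterministic limit: a perfect predictor leaves zero residual scatter)
  set.seed(35)
  sp2c <- rchisq(2000, 4) / 4
  egc <- compute_eg(sp2c, 4)
  expect_true(is.infinite(estimate_d0(egc, egc, 4)))
  expect_error(estimate_d0(numeric(0), numeric(0), 4), "empty")
})

test_that("d0 recovery is within 30% of truth in median over seeds", {
  dg <- 4
  for (d0_true in c(2, 4, 10)) {
    est <- vapply(1:20, function(s) {
      set.seed(1000 * d0_true + s)
      sp2 <- (d0_true / rchisq(5000, d0_true)) * rchisq(5000, dg) / dg
      eg <- compute_eg(sp2, dg)
      estimate_d0(eg, rep(mean(eg), 5000), dg)
    }, 0)
    expect_lt(abs(median(est) - d0_true), 0.3 * d0_true)
  }
})

test_that("trigamma inverse round-trips and matches limma and pi^2/6", {
  expect_equal(trigamma_inverse(trigamma(5)), 5, tolerance = 1e-6)
  expect_equal(trigamma_inverse(pi^2 / 6), 1, tolerance = 1e-6)
  ys <- c(1e-6, 1e-3, 0.5, 2, 100, 1e6)
  xs <- trigamma_inverse(ys)
  expect_true(all(diff(xs) < 0))            # monotone decreasing in y
  expect_true(all(abs(trigamma(xs) - ys) < 1e-8))
  expect_equal(xs, limma::trigammaInverse(ys), tolerance = 1e-6)
  expect_error(trigamma_inverse(-1), "y > 0")
})

test_that("prior variance follows the moment chain", {
  # d_g = 4, d0 = 2, flat fitted log-variance 0
  expect_equal(prior_variance(0, 2, 4),
               exp(-digamma(2) + log(2) + digamma(1)), tolerance = 1e-12)
  expect_equal(prior_variance(0, 2, 4), 0.7357589, tolerance = 1e-6)
  # constant fitted -> constant prior; doubling variances doubles the prior
  f <- rep(1.3, 8)
  expect_equal(length(unique(prior_variance(f, 4, 4))), 1)
  expect_equal(prior_variance(f + log(2), 4, 4), 2 * prior_variance(f, 4, 4),
               tolerance = 1e-12)
  # d0 = Inf limit: the digamma correction vanishes
  expect_equal(prior_variance(0, Inf, 4), exp(-digamma(2) + log(2)),
               tolerance = 1e-12)
  expect_error(prior_variance(0, 0, 4), "positive")
})

test_that("posterior variance is the df-weighted average with correct limits", {
  expect_equal(posterior_variance(1, 4, 4, 2), 2)     # (4*1 + 2*4)/6
  v <- c(0.5, 2); s0 <- c(1, 1)
  expect_equal(posterior_variance(v, s0, 4, 0), v)    # d0 = 0
  expect_equal(posterior_variance(v, s0, 4, Inf), s0) # d0 = Inf
  # always a convex combination
  set.seed(36)
  vv <- rexp(50); ss <- rexp(50)
  for (d0 in c(0.3, 2, 17)) {
    pv <- posterior_variance(vv, ss, 4, d0)
    expect_true(all(pv >= pmin(vv, ss) - 1e-12 & pv <= pmax(vv, ss) + 1e-12))
  }
})

test_that("moderated t follows the posterior-variance formula", {
  y <- matrix(c(1, 1, 1, 2, 2, 2), 1)
  rownames(y) <- "P1"; colnames(y) <- paste0("s", 1:6)
  des <- design_spec(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  lf <- fit_group_means(protein_matrix(y, 1), des)
  mt <- moderated_t(lf, post_var = 0.75, d0 = 2, contrast = c("A", "B"))
  expect_equal(mt$t, -1 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(mt$df, 6)
  # equal means -> t = 0, p = 1 even with zero posterior variance
  lfz <- fit_group_means(protein_matrix(matrix(1, 1, 6,
    dimnames = list("P1", paste0("s", 1:6))), 1), des)
  mtz <- moderated_t(lfz, post_var = 0, d0 = 1, contrast = c("A", "B"))
  expect_equal(c(mtz$t, mtz$p), c(0, 1))

  # d0 = 0 on a balanced design reduces to the pooled ordinary t
  set.seed(37)
  yy <- matrix(rnorm(40 * 6), 40)
  rownames(yy) <- paste0("P", 1:40); colnames(yy) <- paste0("s", 1:6)
  lf2 <- fit_group_means(protein_matrix(yy, rep(1, 40)), des)
  mt2 <- moderated_t(lf2, lf2$pooled_var, 0, c("A", "B"))
  tp <- sapply(1:40, function(i)
    unname(t.test(yy[i, 1:3], yy[i, 4:6], var.equal = TRUE)$statistic))
  expect_equal(mt2$t, tp, tolerance = 1e-10)
})

test_that("moderated F reduces to ANOVA at d0 = 0 and to t^2 for two groups", {
  set.seed(38)
  y <- matrix(rnorm(30 * 9), 30)
  rownames(y) <- paste0("P", 1:30); colnames(y) <- paste0("s", 1:9)
  des <- design_spec(paste0("s", 1:9), rep(c("A", "B", "C"), each = 3))
  pm <- protein_matrix(y, rep(2, 30))
  lf <- fit_group_means(pm, des)
  f0 <- moderated_f(lf, lf$pooled_var, 0)
  fa <- anova_f(lf)
  expect_equal(f0$F, fa$F, tolerance = 1e-12)
  expect_equal(f0$p, fa$p, tolerance = 1e-12)

  des2 <- design_spec(paste0("s", 1:9), rep(c("A", "B"), c(4, 5)))
  lf2 <- fit_group_means(pm, des2)
  pv <- (lf2$pooled_var + 0.2) / 2
  f2 <- moderated_f(lf2, pv, 3)
  t2 <- moderated_t(lf2, pv, 3, c("A", "B"))
  expect_equal(f2$F, t2$t^2, tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 6)), rep(0.4, 6))
  set.seed(39)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  p <- runif(10)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("the full count-covariate pipeline shrinks toward the count trend", {
  sim <- simulate_null(sim_spec(n_proteins = 2000, seed = 40))
  cols <- colnames(sim$matrix$values)[1:6]
  sub <- protein_matrix(sim$matrix$values[, cols], sim$matrix$count)
  des <- design_spec(cols, rep(c("A", "B"), each = 3))
  lf <- fit_group_means(sub, des)
  eb <- spectra_count_ebayes(lf, sub, contrasts = list(c("A", "B")))
  # prior variance is non-increasing in count (known monotone truth)
  med <- tapply(eb$s0_sq, sub$count, median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) < 0.005))
  # posterior variance is a convex combination of pooled and prior
  ok <- lf$pooled_var > 0
  expect_true(all(eb$post_var[ok] >= pmin(lf$pooled_var, eb$s0_sq)[ok] - 1e-12))
  expect_true(all(eb$post_var[ok] <= pmax(lf$pooled_var, eb$s0_sq)[ok] + 1e-12))
  # moderated |t| beats the pooled ordinary |t| exactly when variance shrinks
  tp <- moderated_t(lf, lf$pooled_var, 0, c("A", "B"))$t
  shrunk <- eb$post_var < lf$pooled_var
  expect_true(all((abs(eb$mod_t[, 1]) >= abs(tp) - 1e-12)[shrunk & ok]))
  expect_true(all((abs(eb$mod_t[, 1]) <= abs(tp) + 1e-12)[!shrunk & ok]))
})

test_that("the constant-covariate pipeline equals an independent flat-prior fit", {
  set.seed(41)
  y <- matrix(rnorm(600 * 6, sd = rep(sqrt(rexp(600, 2)), 6)), 600)
  rownames(y) <- paste0("P", 1:600); colnames(y) <- paste0("s", 1:6)
  pm <- protein_matrix(y, sample(1:20, 600, replace = TRUE))
  des <- design_spec(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  lf <- fit_group_means(pm, des)
  cfg <- run_config(covariate_mode = "constant")
  eb <- spectra_count_ebayes(lf, pm, contrasts = list(c("A", "B")),
                             config = cfg)
  oracle <- flat_ebayes_brute(y, rep(c("A", "B"), each = 3), c("A", "B"))
  expect_equal(eb$d0, oracle$d0, tolerance = 1e-9)
  expect_equal(unname(eb$s0_sq), rep(oracle$s0_sq, 600), tolerance = 1e-6)
  expect_equal(unname(eb$post_var), unname(oracle$post_var), tolerance = 1e-6)
  expect_equal(unname(eb$mod_t[, 1]), unname(oracle$t), tolerance = 1e-6)
})

test_that("constant and count covariates coincide when every count is equal", {
  set.seed(42)
  y <- matrix(rnorm(500 * 6), 500)
  rownames(y) <- paste0("P", 1:500); colnames(y) <- paste0("s", 1:6)
  pm <- protein_matrix(y, rep(4L, 500))
  des <- design_spec(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  lf <- fit_group_means(pm, des)
  ebc <- spectra_count_ebayes(lf, pm, contrasts = list(c("A", "B")),
                              config = run_config(covariate_mode = "constant"))
  ebn <- suppressWarnings(
    spectra_count_ebayes(lf, pm, contrasts = list(c("A", "B"))))
  expect_equal(ebn$mod_t[, 1], ebc$mod_t[, 1], tolerance = 1e-9)
  expect_equal(ebn$d0, ebc$d0)
})

test_that("zero-variance proteins are retained with the prior variance", {
  set.seed(43)
  y <- matrix(rnorm(100 * 6), 100)
  y[5, ] <- rep(c(1, 2), each = 3)    # identical replicates, zero pooled var
  rownames(y) <- paste0("P", 1:100); colnames(y) <- paste0("s", 1:6)
  pm <- protein_matrix(y, sample(1:10, 100, replace = TRUE))
  des <- design_spec(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  lf <- fit_group_means(pm, des)
  eb <- spectra_count_ebayes(lf, pm, contrasts = list(c("A", "B")))
  expect_equal(unname(eb$post_var[5]), unname(eb$s0_sq[5]))
  expect_true(is.finite(eb$mod_t[5, 1]))
  expect_true(all(is.finite(eb$p[, 1])))
})
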