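# Empirical-Bayes variance moderation with a covariate-dependent prior.
#
# The log of a sample variance on d_g degrees of freedom is, up to a
# constant, Fisher's Z distributed.  Writing
#   e_g = log(s_p^2) - psi(d_g/2) + log(d_g/2),
# its expectation is log(s0^2) - psi(d0/2) + log(d0/2) and its variance is
# psi'(d_g/2) + psi'(d0/2), where psi and psi' are the digamma and
# trigamma functions.  A local regression of log(s_p^2) on the log2
# PSM/peptide count supplies a per-protein estimate of E(e_g), from which
# the prior variance s0^2 (per protein) and the prior degrees of freedom
# d0 (shared) are solved by the moment equations; the moderated t and F
# statistics then use the posterior variance
#   (d_g s_p^2 + d0 s0^2) / (d_g + d0)
# on d_g + d0 degrees of freedom.

#' Fisher's-Z centred log variance
#'
#' Computes \eqn{e_g = \log s_p^2 - \psi(d_g/2) + \log(d_g/2)} per protein
#' (natural logs throughout).  Zero variances must be excluded by the
#' caller; `d_g` must be at least 1.
#'
#' @param pooled_var vector of positive pooled variances.
#' @param df residual degrees of freedom (scalar).
#' @return Numeric vector `e_g`.
#' @export
compute_eg <- function(pooled_var, df) {
  if (df < 1) stop("residual df must be >= 1")
  if (any(pooled_var <= 0))
    stop("pooled variances must be positive (exclude zero-variance proteins)")
  log(pooled_var) - digamma(df / 2) + log(df / 2)
}

#' Local-regression fit of log variance against a covariate
#'
#' Fits `loess(logVAR ~ x)` with tricube weights and returns the fitted
#' curve evaluated at `newx` (default: the training covariates).
#' Predictions for covariate values outside the fitted range are clamped
#' to the boundary fit.  With fewer distinct covariate values than
#' `degree + 1` the fit falls back to a flat prior (the mean of `logVAR`)
#' with a warning.
#'
#' @param x covariate per protein (log2 count, log2 mean intensity, ...).
#' @param logVAR natural-log pooled variances, parallel to `x`.
#' @param span,degree loess span and local polynomial degree.
#' @param newx covariate values at which to evaluate the fit.
#' @return Numeric vector of fitted log variances at `newx`.
#' @export
fit_trend <- function(x, logVAR, span = 0.75, degree = 2, newx = x) {
  if (length(x) != length(logVAR))
    stop("x and logVAR must be parallel")
  if (length(x) < 10)
    stop("need at least 10 proteins to fit a variance trend")
  if (any(!is.finite(x)) || any(!is.finite(logVAR)))
    stop("covariate and logVAR must be finite")
  if (length(unique(x)) < degree + 1) {
    warning("fewer distinct covariate values than degree + 1; ",
            "falling back to a flat prior")
    return(rep(mean(logVAR), length(newx)))
  }
  lo <- tryCatch(
    suppressWarnings(stats::loess(logVAR ~ x, span = span, degree = degree,
                                  family = "gaussian")),
    error = function(e) NULL)
  if (is.null(lo)) {
    warning("loess fit failed; falling back to a flat prior")
    return(rep(mean(logVAR), length(newx)))
  }
  clamped <- pmin(pmax(newx, min(x)), max(x))
  fitted_vals <- suppressWarnings(as.numeric(stats::predict(lo, clamped)))
  if (any(!is.finite(fitted_vals))) {
    # interpolation can leave NAs at extreme replicated points
    exact <- suppressWarnings(as.numeric(
      stats::predict(lo, data.frame(x = clamped))))
    fitted_vals[!is.finite(fitted_vals)] <- exact[!is.finite(fitted_vals)]
  }
  if (any(!is.finite(fitted_vals)))
    stop("loess prediction produced non-finite values")
  fitted_vals
}

#' Grid estimate of the prior degrees of freedom
#'
#' Solves the moment equation
#' \eqn{\psi'(d_0/2) = \mathrm{mean}[(e_g - \mathrm{pred}(e_g))^2] - \psi'(d_g/2)}
#' by scanning \eqn{d_0 = k \cdot \mathrm{step}} for k = 1, 2, ... and
#' stopping at the first increase of
#' \eqn{|\mathrm{mean}[(e_g - \mathrm{pred}(e_g))^2] - \psi'(d_g/2) - \psi'(d_0/2)|};
#' the returned value is the grid point with the smallest discrepancy.
#' If the excess variance is non-positive (the observed scatter of
#' \eqn{e_g} around the trend is no larger than the sampling noise
#' \eqn{\psi'(d_g/2)}), the prior is effectively infinitely informative
#' and `Inf` is returned; likewise if the cap is reached while the
#' discrepancy is still decreasing.
#'
#' @param e_g,pred_e_g observed and trend-predicted `e_g`, parallel vectors.
#' @param df residual degrees of freedom (scalar).
#' @param grid_step,grid_max grid step (default 0.1) and cap (default 500).
#' @return The estimated `d0`, a multiple of `grid_step`, or `Inf`.
#' @export
estimate_d0 <- function(e_g, pred_e_g, df, grid_step = 0.1, grid_max = 500) {
  if (!length(e_g)) stop("empty e_g")
  if (length(e_g) != length(pred_e_g))
    stop("e_g and pred_e_g must be parallel")
  excess <- mean((e_g - pred_e_g)^2) - trigamma(df / 2)
  if (excess <= 0) return(Inf)
  prev <- Inf
  k <- 0L
  repeat {
    k <- k + 1L
    d0 <- k * grid_step
    if (d0 > grid_max) {
      warning("d0 grid cap reached while still improving; returning Inf")
      return(Inf)
    }
    dk <- abs(excess - trigamma(d0 / 2))
    if (dk > prev)
      return((k - 1L) * grid_step)
    prev <- dk
  }
}

#' Inverse of the trigamma function
#'
#' Solves \eqn{\psi'(x) = y} for x > 0 by a Newton iteration on the
#' nearly-linear transform \eqn{1/\psi'(x)}, converging to
#' \eqn{|\psi'(x) - y| < 10^{-8}}.  Used by the non-grid variant of the
#' prior-df estimate and as a numerical primitive in its own right.
#'
#' @param y positive real (vectorized).
#' @return x with `trigamma(x)` equal to `y`.
#' @export
trigamma_inverse <- function(y) {
  if (any(y <= 0)) stop("trigamma_inverse requires y > 0")
  x <- 0.5 + 1 / y
  for (iter in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(trigamma(x) - y)) < 1e-8) break
  }
  x
}

#' Per-protein prior variance from the fitted trend
#'
#' \eqn{s_0^2 = \exp[\mathrm{pred}(e_g) + \psi(d_0/2) - \log(d_0/2)]} with
#' \eqn{\mathrm{pred}(e_g) = \mathrm{fitted}(\log VAR) - \psi(d_g/2) + \log(d_g/2)}.
#' For `d0 = Inf` the digamma correction vanishes and
#' \eqn{s_0^2 = \exp[\mathrm{pred}(e_g)]}.
#'
#' @param fitted_logVAR fitted log variances per protein.
#' @param d0 prior degrees of freedom (positive, possibly `Inf`).
#' @param df residual degrees of freedom (scalar).
#' @return Vector of strictly positive prior variances.
#' @export
prior_variance <- function(fitted_logVAR, d0, df) {
  if (d0 <= 0) stop("d0 must be positive")
  pred_eg <- fitted_logVAR - digamma(df / 2) + log(df / 2)
  adj <- if (is.infinite(d0)) 0 else digamma(d0 / 2) - log(d0 / 2)
  exp(pred_eg + adj)
}

#' Posterior variance
#'
#' The df-weighted average of the pooled and prior variances,
#' \eqn{(d_g s_p^2 + d_0 s_0^2) / (d_g + d_0)}: equal to the pooled
#' variance at `d0 = 0` and to the prior variance at `d0 = Inf`.
#'
#' @param pooled_var,s0_sq pooled and prior variances, parallel vectors.
#' @param df residual degrees of freedom.
#' @param d0 prior degrees of freedom (>= 0, possibly `Inf`).
#' @return Vector of posterior variances.
#' @export
posterior_variance <- function(pooled_var, s0_sq, df, d0) {
  if (df < 1) stop("residual df must be >= 1")
  if (d0 < 0) stop("d0 must be >= 0")
  if (is.infinite(d0)) return(s0_sq)
  (df * pooled_var + d0 * s0_sq) / (df + d0)
}

.t_to_p <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df)   # df = Inf gives the normal limit
  p[is.infinite(t)] <- 0
  p
}

#' Moderated t-statistic per protein
#'
#' \eqn{t = (\bar Y_{G1} - \bar Y_{G2}) /
#'   (s_{p[\mathrm{mod}]} \sqrt{1/n_1 + 1/n_2})}
#' with a two-sided p-value on \eqn{d_g + d_0} degrees of freedom
#' (`d0 = Inf` gives the normal reference distribution).
#'
#' @param fit a [fit_group_means()] result.
#' @param post_var posterior variance per protein.
#' @param d0 prior degrees of freedom.
#' @param contrast length-2 character vector `c(G1, G2)`.
#' @return A data.frame with columns `protein`, `logFC`, `t`, `df`, `p`.
#' @export
moderated_t <- function(fit, post_var, d0, contrast) {
  stopifnot(inherits(fit, "linear_fit"))
  i <- .contrast_index(fit, contrast)
  n1 <- fit$group_ns[i[1]]; n2 <- fit$group_ns[i[2]]
  dm <- fit$group_means[, i[1]] - fit$group_means[, i[2]]
  se <- sqrt(post_var) * sqrt(1 / n1 + 1 / n2)
  t <- dm / se
  t[se == 0 & dm == 0] <- 0
  t[se == 0 & dm != 0] <- sign(dm[se == 0 & dm != 0]) * Inf
  df_total <- fit$df_resid + d0
  p <- .t_to_p(t, df_total)
  p[se == 0 & dm == 0] <- 1
  data.frame(protein = fit$protein_ids, logFC = unname(dm), t = unname(t),
             df = df_total, p = unname(p), stringsAsFactors = FALSE)
}

#' Moderated ANOVA F per protein
#'
#' The between-group mean square over the posterior variance, referred to
#' F(k - 1, d_g + d0).  With `d0 = 0` this is the ordinary ANOVA F.
#'
#' @inheritParams moderated_t
#' @return A data.frame with columns `protein`, `F`, `df1`, `df2`, `p`.
#' @export
moderated_f <- function(fit, post_var, d0) {
  stopifnot(inherits(fit, "linear_fit"))
  k <- length(fit$group_levels)
  if (k < 2) stop("need at least two groups")
  msb <- .between_ms(fit)
  Fstat <- msb / post_var
  Fstat[post_var == 0 & msb == 0] <- 0
  Fstat[post_var == 0 & msb > 0] <- Inf
  df2 <- fit$df_resid + d0
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  data.frame(protein = fit$protein_ids, F = unname(Fstat),
             df1 = k - 1, df2 = df2, p = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest p down, cap at 1, restore input order),
#' delegated to [stats::p.adjust()] after validating the input range.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count-dependent empirical-Bayes moderated tests
#'
#' The full moderation pipeline: centre the log pooled variances
#' ([compute_eg()]), fit the variance trend against the chosen covariate
#' ([fit_trend()]), estimate the prior degrees of freedom
#' ([estimate_d0()]), form per-protein prior and posterior variances
#' ([prior_variance()], [posterior_variance()]) and compute moderated t
#' (per contrast) and moderated F statistics with Benjamini-Hochberg
#' adjusted p-values.
#'
#' The covariate is selected by `config$covariate_mode`:
#' \describe{
#'   \item{`"count"`}{log2 of the per-protein PSM/peptide count (the
#'     method this package exists for).}
#'   \item{`"intensity"`}{the per-protein mean of the matrix values,
#'     treating them as log2 intensities (the limma-trend style fit for
#'     label-free data).}
#'   \item{`"constant"`}{a flat prior: every protein shares the mean log
#'     variance (the classic limma fit).}
#' }
#'
#' Proteins whose pooled variance is exactly zero (all replicates
#' identical) cannot enter the log-variance trend or the d0 estimate;
#' they are retained in the output with their posterior variance set to
#' the prior variance at their covariate.
#'
#' @param fit a [fit_group_means()] result.
#' @param matrix the [protein_matrix()] the fit came from (supplies counts
#'   and, for `covariate_mode = "intensity"`, the values).
#' @param contrasts list of length-2 character vectors; default: all
#'   pairwise contrasts between the fit's groups.
#' @param config a [run_config()].
#' @return An object of class `ebayes_fit`: a list with the prior df `d0`,
#'   per-protein `s0_sq` and `post_var`, matrices `logFC`, `ord_t`,
#'   `mod_t`, `p`, `p_adj` (one column per contrast), vectors `mod_F`,
#'   `p_F`, `p_F_adj`, the `trend` diagnostics (class `variance_trend`)
#'   and the underlying `base` linear fit.
#' @export
spectra_count_ebayes <- function(fit, matrix, contrasts = NULL,
                                 config = run_config()) {
  stopifnot(inherits(fit, "linear_fit"), inherits(matrix, "protein_matrix"),
            inherits(config, "run_config"))
  if (!identical(fit$protein_ids, rownames(matrix$values)))
    stop("fit and matrix disagree on proteins")
  sp2 <- fit$pooled_var
  df <- fit$df_resid
  ok <- sp2 > 0
  if (sum(ok) < 10)
    stop("need at least 10 proteins with positive pooled variance")
  x <- switch(config$covariate_mode,
    count = log2(as.numeric(matrix$count)),
    intensity = rowMeans(matrix$values),
    constant = rep(0, nrow(matrix$values)))
  logVAR <- rep(NA_real_, length(sp2))
  logVAR[ok] <- log(sp2[ok])
  if (config$covariate_mode == "constant") {
    fitted_all <- rep(mean(logVAR[ok]), length(sp2))
  } else {
    fitted_all <- fit_trend(x[ok], logVAR[ok], span = config$loess_span,
                            degree = config$loess_degree, newx = x)
  }
  e_g <- rep(NA_real_, length(sp2))
  e_g[ok] <- compute_eg(sp2[ok], df)
  pred_e_g <- fitted_all - digamma(df / 2) + log(df / 2)
  d0 <- estimate_d0(e_g[ok], pred_e_g[ok], df,
                    grid_step = config$d0_grid_step,
                    grid_max = config$d0_grid_max)
  s0_sq <- prior_variance(fitted_all, d0, df)
  post_var <- posterior_variance(sp2, s0_sq, df, d0)
  post_var[!ok] <- s0_sq[!ok]
  if (is.null(contrasts))
    contrasts <- pairwise_contrasts(fit$group_levels)
  nc <- length(contrasts)
  tags <- vapply(contrasts, function(ct) paste(ct, collapse = ".vs."), "")
  p_n <- length(sp2)
  logFC <- ord_t <- mod_t <- pmat <- padj <- matrix(
    NA_real_, p_n, nc, dimnames = list(fit$protein_ids, tags))
  for (j in seq_len(nc)) {
    mt <- moderated_t(fit, post_var, d0, contrasts[[j]])
    logFC[, j] <- mt$logFC
    mod_t[, j] <- mt$t
    pmat[, j] <- mt$p
    padj[, j] <- bh_adjust(mt$p)
    i <- .contrast_index(fit, contrasts[[j]])
    if (all(fit$group_ns[i] >= 2))
      ord_t[, j] <- ordinary_t(fit, contrasts[[j]])$t
  }
  mf <- moderated_f(fit, post_var, d0)
  trend <- structure(list(x = x, logVAR = logVAR, fitted_logVAR = fitted_all,
                          e_g = e_g, pred_e_g = pred_e_g, ok = ok,
                          count = matrix$count,
                          loess_span = config$loess_span,
                          loess_degree = config$loess_degree,
                          covariate_mode = config$covariate_mode),
                     class = "variance_trend")
  structure(list(protein_ids = fit$protein_ids, count = matrix$count,
                 d0 = d0, s0_sq = s0_sq, post_var = post_var,
                 total_df = df + d0, contrasts = contrasts,
                 logFC = logFC, ord_t = ord_t, mod_t = mod_t,
                 p = pmat, p_adj = padj,
                 mod_F = mf$F, p_F = mf$p, p_F_adj = bh_adjust(mf$p),
                 trend = trend, base = fit),
            class = "ebayes_fit")
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat("ebayes_fit:", length(x$protein_ids), "proteins,",
      length(x$contrasts), "contrast(s); covariate =",
      x$trend$covariate_mode, "; d0 =", format(x$d0), "\n")
  invisible(x)
}
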