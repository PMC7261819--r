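# Per-protein one-factor linear models: group means, pooled variance,
# ordinary t and ANOVA F.  All operations are vectorized over proteins;
# the residual degrees of freedom d_g = N - k are shared by every protein
# because the matrix is complete-case.

#' Fit per-protein group means and pooled variance
#'
#' For each protein computes the group means, per-group sample standard
#' deviations, the pooled within-group variance
#' \eqn{s_p^2 = \sum_i (n_i - 1) s_i^2 / \sum_i (n_i - 1)} and the shared
#' residual degrees of freedom \eqn{d_g = N - k} (N samples, k groups).
#' Groups of size 1 are allowed (they contribute a mean but no degrees of
#' freedom); if every group has size 1 there is no residual variance and
#' the fit errors.
#'
#' @param matrix a [protein_matrix()].
#' @param design a [design_spec()]; its sample order must equal the matrix
#'   column order exactly (a silent reorder would hide sample mix-ups).
#' @return An object of class `linear_fit` with elements `protein_ids`,
#'   `group_levels`, `group_means` (proteins x groups), `group_ns`,
#'   `group_sds`, `pooled_var`, `df_resid`, `overall_mean`.
#' @export
fit_group_means <- function(matrix, design) {
  stopifnot(inherits(matrix, "protein_matrix"), inherits(design, "design_spec"))
  y <- matrix$values
  if (!identical(colnames(y), design$samples))
    stop("matrix columns and design samples disagree (order matters; ",
         "reorder the design, not the data)")
  g <- factor(design$groups, levels = unique(design$groups))
  lev <- levels(g)
  k <- length(lev)
  N <- ncol(y)
  ns <- as.integer(table(g)[lev])
  if (N - k < 1)
    stop("no residual degrees of freedom (every group has a single sample)")
  p <- nrow(y)
  means <- matrix(NA_real_, p, k, dimnames = list(rownames(y), lev))
  vars <- matrix(NA_real_, p, k, dimnames = list(rownames(y), lev))
  ss_tot <- numeric(p)
  for (i in seq_len(k)) {
    yi <- y[, g == lev[i], drop = FALSE]
    m <- rowMeans(yi)
    means[, i] <- m
    ss <- rowSums((yi - m)^2)
    ss_tot <- ss_tot + ss
    vars[, i] <- if (ns[i] > 1) ss / (ns[i] - 1) else NA_real_
  }
  structure(list(protein_ids = rownames(y), group_levels = lev,
                 group_means = means, group_ns = ns,
                 group_sds = sqrt(vars),
                 pooled_var = ss_tot / (N - k),
                 df_resid = N - k,
                 overall_mean = rowMeans(y)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("linear_fit:", length(x$protein_ids), "proteins,",
      length(x$group_levels), "groups, residual df", x$df_resid, "\n")
  invisible(x)
}

.contrast_index <- function(fit, contrast) {
  i <- match(contrast, fit$group_levels)
  if (anyNA(i))
    stop("unknown group(s) in contrast: ",
         paste(contrast[is.na(i)], collapse = ", "))
  i
}

#' Ordinary (Welch) two-sample t-test per protein
#'
#' The unpooled-denominator t statistic
#' \eqn{t = (\bar Y_{G1} - \bar Y_{G2}) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with a two-sided p-value from a t distribution on Welch-Satterthwaite
#' degrees of freedom.  Sign convention: first group minus second.
#' Proteins with zero denominator get t = 0, p = 1 when the group means
#' agree and t = +/-Inf, p = 0 otherwise.
#'
#' @param fit a [fit_group_means()] result.
#' @param contrast length-2 character vector `c(G1, G2)`; both groups must
#'   have at least 2 replicates.
#' @return A data.frame with columns `protein`, `logFC`, `t`, `df`, `p`.
#' @export
ordinary_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "linear_fit"))
  i <- .contrast_index(fit, contrast)
  n1 <- fit$group_ns[i[1]]; n2 <- fit$group_ns[i[2]]
  if (n1 < 2 || n2 < 2)
    stop("ordinary_t needs at least 2 replicates per group")
  v1 <- fit$group_sds[, i[1]]^2
  v2 <- fit$group_sds[, i[2]]^2
  dm <- fit$group_means[, i[1]] - fit$group_means[, i[2]]
  se2 <- v1 / n1 + v2 / n2
  t <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero <- se2 == 0
  t[zero & dm == 0] <- 0
  t[zero & dm != 0] <- sign(dm[zero & dm != 0]) * Inf
  df[zero] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & dm == 0] <- 1
  data.frame(protein = fit$protein_ids, logFC = unname(dm), t = unname(t),
             df = unname(df), p = unname(p), stringsAsFactors = FALSE)
}

.between_ms <- function(fit) {
  k <- length(fit$group_levels)
  dev <- fit$group_means - fit$overall_mean
  rowSums(sweep(dev^2, 2, fit$group_ns, `*`)) / (k - 1)
}

#' One-way ANOVA F-test per protein
#'
#' F is the between-group mean square (the group-size-weighted sum of
#' squared deviations of group means from the overall mean, divided by
#' k - 1) over the pooled within-group variance, referred to
#' F(k - 1, d_g).  For two groups F equals the square of the
#' pooled-variance two-sample t.
#'
#' @param fit a [fit_group_means()] result with k >= 2 groups.
#' @return A data.frame with columns `protein`, `F`, `df1`, `df2`, `p`.
#' @export
anova_f <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  k <- length(fit$group_levels)
  if (k < 2) stop("need at least two groups")
  msb <- .between_ms(fit)
  Fstat <- msb / fit$pooled_var
  zero <- fit$pooled_var == 0
  Fstat[zero & msb == 0] <- 0
  Fstat[zero & msb > 0] <- Inf
  p <- stats::pf(Fstat, k - 1, fit$df_resid, lower.tail = FALSE)
  data.frame(protein = fit$protein_ids, F = unname(Fstat),
             df1 = k - 1, df2 = fit$df_resid, p = unname(p),
             stringsAsFactors = FALSE)
}
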