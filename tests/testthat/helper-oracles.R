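# Independent reference implementations used as oracles.  Deliberately
# naive: plain loops over the definitions, no shared code with the package.

# Benjamini-Hochberg step-up, straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1)
      adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Median sweeping, one loop per step of the procedure.
median_sweep_brute <- function(intens, protein) {
  m <- log2(intens)
  for (r in seq_len(nrow(m)))
    m[r, ] <- m[r, ] - median(m[r, ])
  prots <- unique(protein)
  vals <- matrix(NA_real_, length(prots), ncol(m),
                 dimnames = list(prots, colnames(intens)))
  for (pp in prots)
    for (j in seq_len(ncol(m)))
      vals[pp, j] <- median(m[protein == pp, j])
  for (j in seq_len(ncol(vals)))
    vals[, j] <- vals[, j] - median(vals[, j])
  vals
}

# Partial AUC by explicit enumeration of every distinct threshold.
pauc_brute <- function(scores, labels, spec_floor = 0.95) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0))
  fmax <- 1 - spec_floor
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    f0 <- fpr[i]; f1 <- fpr[i + 1]; t0 <- tpr[i]; t1 <- tpr[i + 1]
    if (f0 >= fmax) break
    if (f1 > fmax) {
      t1 <- t0 + (t1 - t0) * (fmax - f0) / (f1 - f0)
      f1 <- fmax
    }
    area <- area + (f1 - f0) * (t0 + t1) / 2
  }
  100 * area / fmax
}

# Small random protein matrix + two-group design for model tests.
random_two_group <- function(n_prot = 50, n_per_group = 3, seed = 1) {
  set.seed(seed)
  y <- matrix(rnorm(n_prot * 2 * n_per_group), n_prot)
  rownames(y) <- paste0("P", seq_len(n_prot))
  colnames(y) <- paste0("s", seq_len(2 * n_per_group))
  pm <- protein_matrix(y, sample(1:10, n_prot, replace = TRUE))
  des <- design_spec(colnames(y), rep(c("A", "B"), each = n_per_group))
  list(pm = pm, design = des)
}

# Flat-prior moderation written out longhand (no calls into the package):
# shared fitted log-variance, grid d0, prior/posterior variance, t.
flat_ebayes_brute <- function(y, groups, contrast, grid_step = 0.1,
                              grid_max = 500) {
  lev <- unique(groups)
  k <- length(lev)
  N <- ncol(y)
  ss <- 0
  means <- sapply(lev, function(g) rowMeans(y[, groups == g, drop = FALSE]))
  for (g in lev)
    ss <- ss + rowSums((y[, groups == g, drop = FALSE] -
                          rowMeans(y[, groups == g, drop = FALSE]))^2)
  dg <- N - k
  sp2 <- ss / dg
  logv <- log(sp2)
  fitted_flat <- mean(logv)
  eg <- logv - digamma(dg / 2) + log(dg / 2)
  pred <- fitted_flat - digamma(dg / 2) + log(dg / 2)
  excess <- mean((eg - pred)^2) - trigamma(dg / 2)
  if (excess <= 0) {
    d0 <- Inf
  } else {
    ks <- seq(grid_step, grid_max, by = grid_step)
    diffs <- abs(excess - trigamma(ks / 2))
    first_up <- which(diff(diffs) > 0)
    d0 <- if (length(first_up)) ks[which.min(diffs[seq_len(first_up[1] + 1)])]
          else Inf
  }
  adj <- if (is.infinite(d0)) 0 else digamma(d0 / 2) - log(d0 / 2)
  s0 <- exp(pred + adj)
  post <- if (is.infinite(d0)) rep(s0, length(sp2))
          else (dg * sp2 + d0 * s0) / (dg + d0)
  n1 <- sum(groups == contrast[1]); n2 <- sum(groups == contrast[2])
  t <- (means[, contrast[1]] - means[, contrast[2]]) /
    sqrt(post * (1 / n1 + 1 / n2))
  list(d0 = d0, s0_sq = s0, post_var = post, t = unname(t), df = dg)
}
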