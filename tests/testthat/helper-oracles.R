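# Independent oracles used to cross-check the package implementations.
# These deliberately use the slowest, most literal formulation available.

# Volume-based BPE by an explicit per-voxel triple loop.
brute_bpe <- function(pre, post, fgt, breast, k, floor = 1e-6) {
  dims <- dim(pre)
  n_enh <- 0L; n_breast <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (l in seq_len(dims[3])) {
    if (breast[i, j, l] > 0) n_breast <- n_breast + 1L
    if (fgt[i, j, l] > 0 && pre[i, j, l] > floor) {
      e <- 100 * (post[i, j, l] - pre[i, j, l]) / pre[i, j, l]
      if (e >= k) n_enh <- n_enh + 1L
    }
  }
  n_enh / n_breast
}

# AUC by exhaustive concordance counting over all (positive, negative) pairs.
brute_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Spearman correlation from first principles: average ranks, then the
# Pearson product-moment formula on the ranks.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) vapply(v, function(t) mean(which(sort(v) == t)), numeric(1))
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Negative Efron partial log-likelihood, written out from the definition.
efron_nll <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- as.vector(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    swR <- sum(w[R]); swD <- sum(w[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(swR - (l / d) * swD)
  }
  -ll
}

# Negative Bernoulli log-likelihood of a logistic model with intercept.
logistic_nll <- function(theta, y, x) {
  x <- cbind(1, as.matrix(x))
  eta <- as.vector(x %*% theta)
  -sum(y * eta - log(1 + exp(eta)))
}

# A random study + nested masks on a small grid, for oracle comparisons.
random_small_case <- function(dims = NULL) {
  if (is.null(dims)) dims <- sample(3:8, 3, replace = TRUE)
  n <- prod(dims)
  pre <- array(runif(n, 0, 2), dim = dims)
  pre[runif(n) < 0.05] <- 0                      # some undefined voxels
  post <- array(runif(n, 0, 3), dim = dims)
  breast <- array(as.integer(runif(n) < 0.7), dim = dims)
  if (sum(breast) == 0L) breast[1, 1, 1] <- 1L
  fgt <- array(as.integer(breast == 1L & runif(n) < 0.6), dim = dims)
  list(pre = pre, post = post, breast = breast, fgt = fgt, dims = dims)
}

make_study <- function(pre, post, spacing = c(1, 1, 1)) {
  dce_study(list(pre, post), spacing)
}

# cohort reconstructed from printed per-grade counts of a baseline table;
# each row of `counts` is level x grade.
cohort_from_counts <- function(var_name, counts, grade_n) {
  rows <- list()
  for (g in seq_along(grade_n)) {
    lv <- rep(rownames(counts), counts[, g])
    other <- grade_n[g] - length(lv)
    stopifnot(other >= 0)
    lv <- c(lv, rep("other", other))
    rows[[g]] <- data.frame(patient_id = sprintf("g%d_%04d", g, seq_along(lv)),
                            radiologist_grade = g, v = lv,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "v"] <- var_name
  out
}
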