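# Independent oracles and small fixture builders used across the suite.
# The oracles are deliberately written with different mechanics than the
# package implementations (stats::ecdf, explicit step-up loops, MASS::ginv,
# grid searches) so a shared bug cannot hide.

# One-sided two-sample KS statistic via stats::ecdf.
oracle_ks_stat <- function(plus, minus) {
  grid <- sort(unique(c(plus, minus)))
  Fp <- stats::ecdf(plus)
  Fm <- stats::ecdf(minus)
  max(0, max(Fm(grid) - Fp(grid)))
}

# All one-sided KS statistics over every split of the pooled sample into
# groups of sizes (m, n); exact permutation p for each split follows as the
# fraction of splits at least as extreme.
oracle_ks_all_splits <- function(pooled, m) {
  sel <- utils::combn(length(pooled), m)
  d <- apply(sel, 2L, function(ix) {
    oracle_ks_stat(pooled[ix], pooled[-ix])
  })
  p <- vapply(d, function(di) mean(d >= di - 1e-12), numeric(1L))
  list(splits = sel, D = d, p = p)
}

# Benjamini-Hochberg step-up formula q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Cox partial log-likelihood (no ties) for a single covariate; grid-search
# maximizer as the oracle estimate.
oracle_cox_grid <- function(time, event, x, grid = seq(-3, 3, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    eta <- x * b
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      eta[i] - log(sum(exp(eta[risk])))
    }, numeric(1L)))
  }, numeric(1L))
  grid[which.max(ll)]
}

# Align fitted signature columns to the planted B_true: greedy matching on
# |cor|, returning per-true-feature the matched fitted column and the signed
# correlation.
match_features <- function(B_hat, B_true) {
  cm <- stats::cor(B_hat, B_true)   # fitted x true
  out <- data.frame(true = colnames(B_true) %||% seq_len(ncol(B_true)),
                    fitted = NA_integer_, r = NA_real_)
  used <- integer(0L)
  for (j in order(-apply(abs(cm), 2L, max))) {
    i <- setdiff(order(-abs(cm[, j])), used)[1L]
    out$fitted[j] <- i
    out$r[j] <- cm[i, j]
    used <- c(used, i)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small compendium with prescribed cosines between drug profiles and given
# signature vectors, used to exercise the match-score arithmetic: returns a
# unit vector g with g . b_i = targets[i] for the rows of B (dim must allow
# a positive residual).
vector_with_cosines <- function(B_unit, targets) {
  gram <- crossprod(B_unit)
  alpha <- solve(gram, targets)
  base <- as.numeric(B_unit %*% alpha)
  resid2 <- 1 - sum(base^2)
  stopifnot(resid2 > 0)
  # orthogonal completion
  n <- nrow(B_unit)
  cand <- diag(n)[, seq_len(ncol(B_unit) + 1L)]
  q <- qr.Q(qr(cbind(B_unit, cand)))
  ortho <- q[, ncol(B_unit) + 1L]
  base + sqrt(resid2) * ortho
}

# Tiny deterministic cohort fixture for io tests.
toy_cohort_files <- function(dir) {
  expr <- rbind(g1 = c(5, 7, 9), g2 = c(1, 1, 4), g3 = c(2, 0, 1))
  colnames(expr) <- c("s1", "s2", "s3")
  expr_path <- file.path(dir, "expr.tsv")
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fac <- rbind(mycn = c(0, 1, 1), stage = c(1.2, 3.4, 2.2))
  colnames(fac) <- colnames(expr)
  fac_path <- file.path(dir, "factors.tsv")
  utils::write.table(
    data.frame(factor = rownames(fac), fac, check.names = FALSE),
    fac_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expression = expr_path, factors = fac_path, expr = expr, fac = fac)
}

# A calibration object with known reference scales, bypassing estimation.
fixed_calib <- function(rho, lines = names(rho)) {
  structure(list(rho_same = rho, n_pairs = rep(99L, length(rho)),
                 fallback = rep(FALSE, length(rho)), score_threshold = 900),
            class = "similarity_calibration")
}

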