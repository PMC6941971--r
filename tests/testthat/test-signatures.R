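test_that("extract_features matches the truncated eigendecomposition oracle", {
  set.seed(7)
  # continuous Y so standardization is plain centre+scale
  Y <- matrix(rnorm(60, sd = 2) + 1, 6, 10)
  rownames(Y) <- paste0("f", 1:6)
  fd <- extract_features(Y, k = 2)

  Ys <- t(scale(t(Y)))  # oracle standardization (centre + unit sd rows)
  attr(Ys, "scaled:center") <- attr(Ys, "scaled:scale") <- NULL
  ev <- eigen(crossprod(Ys), symmetric = TRUE)
  recon_oracle <- Ys %*% ev$vectors[, 1:2] %*% t(ev$vectors[, 1:2])
  expect_equal(fd$H %*% fd$F, recon_oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # convention: unit-norm feature rows, positively oriented loadings
  expect_equal(rowSums(fd$F^2), c(f1 = 1, f2 = 1), tolerance = 1e-12)
  for (j in 1:2) expect_gt(fd$H[which.max(abs(fd$H[, j])), j], 0)
  expect_true(all(fd$explained_fraction > 0) &&
                sum(fd$explained_fraction) <= 1 + 1e-12)
  expect_true(!is.unsorted(rev(fd$explained_fraction)))
})

test_that("extract_features is exact on low-rank input and errors past the rank", {
  set.seed(8)
  a <- rnorm(5) + 2
  b <- rnorm(12)
  Y1 <- a %o% b  # exact rank 1
  fd1 <- extract_features(Y1, k = 1)
  Ys <- t(scale(t(Y1)))
  expect_lt(max(abs(fd1$H %*% fd1$F - Ys)), 1e-10)

  Yf <- matrix(rnorm(4 * 9), 4, 9)
  fdf <- extract_features(Yf, k = 4)  # full rank: zero reconstruction error
  expect_lt(max(abs(fdf$H %*% fdf$F - t(scale(t(Yf))))), 1e-10)

  expect_error(extract_features(Yf, k = 5), "k must lie")
  expect_error(extract_features(Y1, k = 2), "numerical rank")
})

test_that("supervised features solve the normal equations and score markers", {
  set.seed(9)
  # identity loadings: features proportional to the rows of Y
  Y <- matrix(rnorm(4 * 20), 4, 20)
  fd <- supervised_features(Y = Y, H = diag(4))
  expect_lt(max(abs(fd$H %*% fd$F - Y)), 1e-10)
  for (i in 1:4) expect_equal(abs(cor(fd$F[i, ], Y[i, ])), 1,
                              tolerance = 1e-12)

  # random well-conditioned H, Y = H F_true: recovery via normal equations
  H <- matrix(rnorm(25), 5) + diag(5) * 3
  F_true <- matrix(rnorm(5 * 30), 5, 30)
  fd2 <- supervised_features(Y = H %*% F_true, H = H)
  expect_lt(max(abs(fd2$H %*% fd2$F - H %*% F_true)), 1e-8)
  scales <- sqrt(rowSums(F_true^2))
  expect_equal(fd2$F, F_true / scales, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(supervised_features(Y = Y, H = matrix(1, 4, 2)),
               "rank-deficient")

  # single up-marker: feature equals the z-scored gene row, normalized
  Z <- matrix(rnorm(6 * 15), 6, 15,
              dimnames = list(paste0("g", 1:6), NULL))
  Z <- Z - rowMeans(Z)
  fd3 <- supervised_features(markers = list(mk = list(up = "g2")), Z = Z)
  zrow <- scale(Z["g2", ])[, 1]
  expect_equal(fd3$F[1, ], zrow / sqrt(sum(zrow^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(
    supervised_features(markers = list(mk = list(up = "g9")), Z = Z),
    "absent")
})

test_that("Cox risk feature matches a partial-likelihood grid search", {
  # 4-patient toy, binary covariate, distinct times, no censoring,
  # event order mixes the groups so the partial-likelihood MLE is finite
  time <- c(2, 1, 5, 8)
  event <- rep(1, 4)
  x <- c(1, 0, 1, 0)
  surv <- survival_table(paste0("p", 1:4), time, event)
  res <- cox_risk_feature(surv, matrix(x, ncol = 1), ridge = 1e-6)
  # the model was fitted on the scaled covariate; map back to x's scale
  beta_scaled <- coef(res$fit)[1] / sd(x)
  beta_oracle <- oracle_cox_grid(time, event, x)
  expect_equal(unname(beta_scaled), beta_oracle, tolerance = 1e-3)
  expect_equal(sum(res$feature^2), 1, tolerance = 1e-12)

  expect_error(cox_risk_feature(surv, matrix(1, 4, 1)), "constant")
  expect_error(
    cox_risk_feature(survival_table(paste0("p", 1:4), time, c(1, 0, 0, 0)),
                     matrix(x, ncol = 1)),
    "2 observed events")
})

test_that("null survival data give near-zero Cox coefficients", {
  hits <- 0L
  for (s in 1:20) {
    surv <- simulate_survival(n = 200, beta = 0, censoring_rate = 0.2,
                              seed = s)
    res <- cox_risk_feature(surv, as.matrix(surv[, "x1", drop = FALSE]))
    if (abs(coef(res$fit)[1]) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("fit_signatures equals the pseudo-inverse oracle and leaves orthogonal residuals", {
  skip_if_not_installed("MASS")
  set.seed(11)
  for (rep in 1:10) {
    p <- sample(3:8, 1); k <- sample(1:3, 1); n <- sample(10:25, 1)
    F_mat <- matrix(rnorm(k * n), k, n)
    Z <- matrix(rnorm(p * n), p, n)
    Z <- Z - rowMeans(Z)
    B <- fit_signatures(Z, F_mat)$B
    B_oracle <- Z %*% MASS::ginv(F_mat)
    expect_equal(unname(B), B_oracle, tolerance = 1e-10)
    resid <- Z - B %*% F_mat
    expect_lt(max(abs(resid %*% t(F_mat))), 1e-8)
  }
})

test_that("fit_signatures simplifications and scale covariance hold", {
  set.seed(12)
  # orthonormal feature rows: B = Z F'
  F_mat <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  F_mat <- t(F_mat)
  Z <- matrix(rnorm(5 * 20), 5, 20); Z <- Z - rowMeans(Z)
  expect_equal(unname(fit_signatures(Z, F_mat)$B), Z %*% t(F_mat),
               tolerance = 1e-10)
  # noise-free consistency
  B_true <- matrix(rnorm(10), 5, 2)
  Z2 <- B_true %*% F_mat
  expect_equal(unname(fit_signatures(Z2, F_mat)$B), B_true,
               tolerance = 1e-10)
  # scale covariance: c * Z -> c * B
  expect_equal(fit_signatures(3.7 * Z, F_mat)$B,
               3.7 * fit_signatures(Z, F_mat)$B, tolerance = 1e-12)
  # singular F F': duplicated feature row
  expect_error(fit_signatures(Z, rbind(F_mat[1, ], F_mat[1, ])), "singular")
})

test_that("signature consistency reports correlations, flips and the threshold", {
  set.seed(13)
  B <- matrix(rnorm(978 * 2), 978, 2, dimnames = list(NULL, c("f1", "f2")))
  sets <- lapply(1:3, function(i) signature_set(paste0("c", i), B))
  rep1 <- signature_consistency(sets)
  expect_true(all(rep1$summary$mean_r == 1))
  expect_true(all(rep1$summary$pass))

  # a sign-flipped cohort is aligned and recorded
  B2 <- B; B2[, 1] <- -B2[, 1]
  sets2 <- list(signature_set("c1", B), signature_set("c2", B2))
  rep2 <- signature_consistency(sets2)
  expect_true(rep2$flips["c2", "f1"])
  expect_false(rep2$flips["c2", "f2"])
  expect_equal(rep2$summary$mean_r, c(1, 1), tolerance = 1e-12)

  # independent signatures: mean r near zero, fails the 0.4 default
  null_ok <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    sets3 <- lapply(1:3, function(i) {
      signature_set(paste0("c", i), matrix(rnorm(978 * 2), 978, 2,
                                           dimnames = list(NULL, c("f1", "f2"))))
    })
    rep3 <- signature_consistency(sets3)
    if (all(abs(rep3$summary$mean_r) < 0.1)) null_ok <- null_ok + 1L
    expect_false(any(rep3$summary$pass))
  }
  expect_gte(null_ok, 4L)

  expect_error(signature_consistency(sets[1]), "at least 2")
})

test_that("signature projection recovers planted orthogonal axes", {
  set.seed(14)
  b1 <- rnorm(200); b2 <- rnorm(200)
  b2 <- b2 - sum(b1 * b2) / sum(b1^2) * b1  # orthogonalize
  B <- cbind(f1 = b1 * 3, f2 = b2 * 2)
  sets <- lapply(1:3, function(i) {
    signature_set(paste0("c", i), B + matrix(rnorm(400, sd = 0.05), 200, 2))
  })
  pj <- project_signatures(sets)
  # each planted axis aligns with one PC of the gene cloud
  g <- pj$gene_coords
  align <- abs(cor(cbind(b1, b2), g))
  expect_gt(max(align[1, ]), 0.99)
  expect_gt(max(align[2, ]), 0.99)
  # duplicated feature -> collinear feature coordinates
  sets_dup <- list(signature_set("c1", cbind(f1 = b1, f2 = b1)))
  expect_error(project_signatures(list(signature_set("c1",
                                                     cbind(f1 = b1)))),
               "at least 2")
  pj2 <- project_signatures(sets_dup)
  cc <- pj2$feature_coords
  expect_equal(abs(sum(cc[1, ] * cc[2, ])), 1, tolerance = 1e-8)
})
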