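test_that("similarity is a calibrated clipped cosine with the stated symmetries", {
  set.seed(30)
  calib <- fixed_calib(c(CL1 = 0.5))
  h <- rnorm(50)
  # proportional profiles reach the calibration ceiling
  expect_equal(similarity(2 * h, h, calib), 1)
  # orthogonal profiles score zero
  g <- rnorm(50); g <- g - sum(g * h) / sum(h^2) * h
  expect_equal(similarity(g, h, calib), 0)
  # negation antisymmetry, exact
  g2 <- rnorm(50)
  expect_identical(similarity(g2, -h, calib), similarity(-g2, h, calib))
  # scale equivariance: cosine-based, so positive scaling is a no-op
  expect_equal(similarity(3.3 * g2, h, calib), similarity(g2, h, calib),
               tolerance = 1e-12)
  expect_error(similarity(0 * h, h, calib), "zero-norm")
})

test_that("calibration is estimated from same-target pairs with pooled fallback", {
  set.seed(31)
  p <- 60
  base <- rnorm(p)
  mk <- function(n, center, sd = 0.2) {
    vapply(seq_len(n), function(i) center + rnorm(p, sd = sd), numeric(p))
  }
  # 10 drugs share target P1 (correlated profiles); 20 inert drugs
  m <- cbind(mk(10, base), matrix(rnorm(p * 20), p, 20))
  colnames(m) <- paste0("d", 1:30)
  comp <- perturbation_compendium(list(CL1 = m), zscored = TRUE)
  links <- target_link_table(paste0("d", 1:10), "P1", 950)
  calib <- fit_calibration(comp, links, min_pairs = 30)
  same_cos <- sigdecon:::cosine_matrix(m[, 1:10])
  oracle_rho <- (sum(same_cos) - 10) / (10 * 9)
  expect_equal(unname(calib$rho_same["CL1"]), oracle_rho, tolerance = 1e-10)
  expect_false(calib$fallback[["CL1"]])

  # too few pairs in a second line -> pooled fallback, flagged
  comp2 <- perturbation_compendium(list(CL1 = m, CL2 = m[, 11:30]),
                                   zscored = TRUE)
  expect_message(calib2 <- fit_calibration(comp2, links, min_pairs = 30),
                 "fall back")
  expect_true(calib2$fallback[["CL2"]])
  expect_equal(unname(calib2$rho_same["CL2"]),
               unname(calib2$rho_same["CL1"]), tolerance = 1e-10)

  # no usable same-target pairs at all
  links_none <- target_link_table("dX", "P1", 950)
  expect_error(fit_calibration(comp, links_none), "no same-target")
})

test_that("drug consistency weights reward cross-line reproducibility", {
  set.seed(32)
  p <- 80
  prof <- matrix(rnorm(p * 6), p, 6, dimnames = list(NULL, paste0("d", 1:6)))
  # identical profiles in all lines -> sigma_bar = 1
  comp_same <- perturbation_compendium(
    list(CL1 = prof, CL2 = prof, CL3 = prof), zscored = TRUE)
  dc <- drug_consistency(comp_same)
  expect_equal(unname(dc$sigma_bar), rep(1, 6), tolerance = 1e-12)

  # single-line drug gets the declared neutral default and a flag
  comp_single <- perturbation_compendium(
    list(CL1 = prof, CL2 = prof[, 1:5]), zscored = TRUE)
  dc2 <- drug_consistency(comp_single)
  expect_equal(unname(dc2$sigma_bar["d6"]), 0.5)
  expect_true(dc2$single_line[["d6"]])

  # independent random profiles, judged against a meaningful reference
  # scale: median sigma_bar near zero
  meds <- numeric(5)
  for (s in 1:5) {
    set.seed(200 + s)
    # landmark-scale dimension: null cosines concentrate near zero
    pl <- 978
    rnd <- function() matrix(rnorm(pl * 40), pl, 40,
                             dimnames = list(NULL, paste0("r", 1:40)))
    comp_null <- perturbation_compendium(
      list(CL1 = rnd(), CL2 = rnd(), CL3 = rnd()), zscored = TRUE)
    dcn <- drug_consistency(comp_null, rho_cons = 0.8)
    meds[s] <- median(dcn$sigma_bar)
  }
  expect_lt(max(meds), 0.05)
})

test_that("match score reproduces the hand-evaluated combination rule", {
  set.seed(33)
  p <- 10
  rho <- 0.5
  # two cohort signatures (unit vectors, not collinear)
  b1 <- rnorm(p); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- rnorm(p); b2 <- b2 - sum(b2 * b1) * b1; b2 <- b2 / sqrt(sum(b2^2))
  Bu <- cbind(b1, b2)
  # per-line cohort sigmas: line1 (0.8, 0.6), line2 (0.5, 0.5)
  g1 <- vector_with_cosines(-Bu, rho * c(0.8, 0.6))
  g2 <- vector_with_cosines(-Bu, rho * c(0.5, 0.5))
  comp <- perturbation_compendium(
    list(L1 = matrix(g1, ncol = 1, dimnames = list(NULL, "drugA")),
         L2 = matrix(g2, ncol = 1, dimnames = list(NULL, "drugA"))),
    gene_ids = paste0("g", 1:p), zscored = TRUE)
  sets <- list(signature_set("c1", matrix(b1, ncol = 1,
                                          dimnames = list(paste0("g", 1:p), "f1"))),
               signature_set("c2", matrix(b2, ncol = 1,
                                          dimnames = list(paste0("g", 1:p), "f1"))))
  calib <- fixed_calib(c(L1 = rho, L2 = rho))
  consistency <- list(sigma_bar = c(drugA = 0.9), rho_cons = 1,
                      single_line = c(drugA = FALSE))
  s <- match_score("drugA", comp, sets, calib, consistency,
                   feature = "f1", direction = "-")
  expect_equal(s, 0.9 * ((0.8 * 0.6) + (0.5 * 0.5)) / 2, tolerance = 1e-10)
  expect_equal(s, 0.3285, tolerance = 1e-10)
  # direction antisymmetry: the same suppressor scored as enhancer is 0
  s_plus <- match_score("drugA", comp, sets, calib, consistency,
                        feature = "f1", direction = "+")
  expect_equal(s_plus, 0)
})

test_that("score_all emits bounded scores with the expected cardinality", {
  set.seed(34)
  sim <- simulate_cohorts(n_cohorts = 2, n_patients = 60, p_disease = 8,
                          p_genes = 120, k = 2, seed = 34)
  cp <- simulate_compendium(sim$truth$B_true, n_drugs = 60,
                            n_cell_lines = 2, n_targets = 5,
                            drugs_per_target = 6, seed = 35)
  comp <- z_transform(cp$compendium)
  sets <- list(signature_set("truth", sim$truth$B_true))
  calib <- fit_calibration(comp, cp$links)
  sc <- score_all(comp, sets, calib)
  # 2 directions x 2 features x 60 drugs (dense coverage)
  expect_equal(nrow(sc), 2L * 2L * 60L)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(sc$sigma_bar >= 0 & sc$sigma_bar <= 1))
  sig_cols <- sc[, grep("^sigma\\.", names(sc))]
  expect_true(all(is.na(sig_cols) | (sig_cols >= 0 & sig_cols <= 1)))

  # planted suppressors occupy the top decile of "-" scores
  top_rate <- vapply(1:10, function(s) {
    cps <- simulate_compendium(sim$truth$B_true, n_drugs = 60,
                               n_cell_lines = 2, n_targets = 5,
                               drugs_per_target = 6, seed = 300 + s)
    comps <- z_transform(cps$compendium)
    cal <- fit_calibration(comps, cps$links)
    scs <- score_all(comps, sets, cal, directions = "-", features = "f1")
    cut <- quantile(scs$score, 0.9)
    mean(scs$score[scs$drug %in% cps$truth$causal_drugs] >= cut)
  }, numeric(1L))
  expect_gte(mean(top_rate == 1), 0.95)
})

test_that("failing consistency features are refused unless forced", {
  set.seed(36)
  sim <- simulate_cohorts(n_cohorts = 2, n_patients = 40, p_disease = 6,
                          p_genes = 80, k = 2, seed = 36)
  cp <- simulate_compendium(sim$truth$B_true, n_drugs = 30,
                            n_cell_lines = 2, n_targets = 3,
                            drugs_per_target = 5, seed = 37)
  comp <- z_transform(cp$compendium)
  calib <- fit_calibration(comp, cp$links)
  # a consistency report where f2 fails
  fake_rep <- structure(
    list(summary = data.frame(feature = c("f1", "f2"),
                              mean_r = c(0.9, 0.1),
                              pass = c(TRUE, FALSE)),
         flips = matrix(FALSE, 1, 2,
                        dimnames = list("truth", c("f1", "f2"))),
         threshold = 0.4),
    class = "consistency_report")
  sets <- list(signature_set("truth", sim$truth$B_true))
  expect_error(score_all(comp, sets, calib, features = c("f1", "f2"),
                         consistency_report = fake_rep),
               "consistency filter")
  sc <- score_all(comp, sets, calib, features = c("f1", "f2"),
                  consistency_report = fake_rep, force = TRUE)
  expect_setequal(unique(sc$feature), c("f1", "f2"))
})

test_that("permutation null is seed-reproducible and applies the add-one rule", {
  set.seed(38)
  sim <- simulate_cohorts(n_cohorts = 1, n_patients = 40, p_disease = 6,
                          p_genes = 100, k = 1, seed = 38)
  cp <- simulate_compendium(sim$truth$B_true, n_drugs = 40,
                            n_cell_lines = 2, n_targets = 4,
                            drugs_per_target = 6, effect_size = 8,
                            seed = 39)
  comp <- z_transform(cp$compendium)
  sets <- list(signature_set("truth", sim$truth$B_true))
  calib <- fit_calibration(comp, cp$links)
  pn1 <- permutation_null(comp, sets, calib, feature = "f1",
                          direction = "-", n_perm = 50, seed = 7)
  pn2 <- permutation_null(comp, sets, calib, feature = "f1",
                          direction = "-", n_perm = 50, seed = 7)
  expect_identical(pn1$null, pn2$null)
  expect_identical(pn1$p, pn2$p)
  # a strongly planted suppressor beats every null score: p = 1/(1+n_perm)
  causal <- cp$truth$causal_drugs[1]
  expect_equal(unname(pn1$p[causal]), 1 / 51)
  expect_error(permutation_null(comp, sets, calib, feature = "f1",
                                n_perm = 0), "n_perm")
})
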