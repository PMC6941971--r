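test_that("one-sided KS handles degenerate and separated samples", {
  same <- c(0.2, 0.5, 0.9)
  res <- ks_one_sided(same, same)
  expect_equal(res$D, 0)
  expect_equal(res$p, 1)
  # complete separation: R+ entirely above R-
  res2 <- ks_one_sided(c(0.7, 0.8, 0.9), c(0.1, 0.2, 0.3))
  expect_equal(res2$D, 1)
  # shift in the wrong direction gives D = 0 (one-sided)
  res3 <- ks_one_sided(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(res3$D, 0)
  expect_error(ks_one_sided(numeric(0), same), "non-empty")
})

test_that("exact KS p equals exhaustive enumeration for every 3+4 split", {
  vals <- seq(0.1, 0.7, by = 0.1)
  oracle <- oracle_ks_all_splits(vals, 3L)
  for (j in seq_len(ncol(oracle$splits))) {
    plus <- vals[oracle$splits[, j]]
    minus <- vals[-oracle$splits[, j]]
    res <- ks_one_sided(plus, minus)
    expect_identical(res$method, "exact")
    expect_identical(res$D, oracle$D[j])
    expect_equal(res$p, oracle$p[j], tolerance = 1e-12)
  }
})

test_that("asymptotic KS branch matches the one-sided bound and base R's statistic", {
  set.seed(40)
  plus <- runif(30, 0.3, 1)
  minus <- runif(200)
  res <- ks_one_sided(plus, minus)
  expect_identical(res$method, "asymptotic")
  # independent statistic: base R's one-sided two-sample KS
  d_ref <- unname(suppressWarnings(
    stats::ks.test(minus, plus, alternative = "greater")$statistic))
  expect_equal(res$D, d_ref, tolerance = 1e-12)
  m <- length(plus); n <- length(minus)
  expect_equal(res$p, exp(-2 * res$D^2 * m * n / (m + n)), tolerance = 1e-12)
})

test_that("BH q-values match the step-up formula; Storey scales by pi0", {
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p4, "BH"), rep(0.04, 4))
  set.seed(41)
  for (rep in 1:25) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    q <- qvalue_storey(p)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(q <= stats::p.adjust(p, "BH") + 1e-12))
  }
  expect_equal(qvalue_storey(0.03), 0.03)  # single test: q = p
})

test_that("enrich_all splits at the strict threshold, skips small targets and sorts by q", {
  # scores: target P1's four drugs clearly enriched in "-"
  drugs <- paste0("d", 1:12)
  sc <- sigdecon:::match_score_table(data.frame(
    drug = rep(drugs, 2), feature = "f1",
    direction = rep(c("-", "+"), each = 12),
    score = c(c(0.9, 0.85, 0.8, 0.95, runif(8, 0, 0.3)),
              runif(12, 0, 0.3)),
    sigma_bar = 0.5, n_cell_lines = 2))
  links <- target_link_table(
    chemical = c("d1", "d2", "d3", "d4",   # P1, strong links
                 "d5",                     # P1 at exactly 900: stays in R-
                 "d6", "d7", "d8"),        # P2: only 3 linked drugs
    protein = c(rep("P1", 5), rep("P2", 3)),
    combined_score = c(950, 950, 901, 950, 900, 950, 950, 950))
  expect_message(enr <- enrich_all(sc, links, alpha_q = 0.01),
                 "skipping 1 target")
  expect_setequal(unique(enr$target), "P1")
  p1_minus <- enr[enr$direction == "-", ]
  expect_equal(p1_minus$n_plus, 4L)
  expect_equal(p1_minus$n_minus, 8L)  # d5 at score 900 stays in R-
  expect_equal(p1_minus$D, 1)
  expect_true(p1_minus$significant)
  expect_false(enr$significant[enr$direction == "+"])
  expect_true(!is.unsorted(enr$q))
})

test_that("null links keep the false positive rate at the nominal level", {
  set.seed(42)
  fracs <- vapply(1:20, function(s) {
    drugs <- paste0("d", 1:80)
    sc <- sigdecon:::match_score_table(data.frame(
      drug = drugs, feature = "f1", direction = "-",
      score = runif(80), sigma_bar = 0.5, n_cell_lines = 1))
    links <- target_link_table(
      chemical = sample(drugs, 40, replace = TRUE),
      protein = paste0("P", rep(1:8, each = 5)),
      combined_score = 950)
    enr <- suppressMessages(enrich_all(sc, links, alpha_q = 0.05,
                                       min_group_size = 4))
    if (nrow(enr) == 0) return(0)
    mean(enr$q < 0.05)
  }, numeric(1L))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 2 * se + 1e-9)
})

test_that("MST keeps the shortest non-redundant backbone deterministically", {
  # triangle with distances 1, 2, 3 (scores 999, 998, 997)
  pl <- data.frame(protein_a = c("A", "A", "B"),
                   protein_b = c("B", "C", "C"),
                   combined_score = c(999, 998, 997))
  mst <- mst_of_targets(c("A", "B", "C"), pl)
  expect_equal(nrow(mst$edges), 2L)
  expect_setequal(mst$edges$combined_score, c(999, 998))
  expect_equal(mst$n_components, 1L)

  # complete graph: n - 1 edges, total weight equal to igraph's MST
  skip_if_not_installed("igraph")
  set.seed(43)
  nodes <- paste0("T", 1:8)
  cmb <- combn(nodes, 2)
  pl2 <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                    combined_score = sample(500:999, ncol(cmb)))
  mst2 <- mst_of_targets(nodes, pl2)
  expect_equal(nrow(mst2$edges), 7L)
  g <- igraph::graph_from_data_frame(
    data.frame(pl2$protein_a, pl2$protein_b), directed = FALSE)
  ig <- igraph::mst(g, weights = 1000 - pl2$combined_score)
  expect_equal(sum(mst2$edges$distance),
               sum(igraph::E(ig)$weight %||% (1000 - pl2$combined_score)[
                 match(apply(igraph::as_edgelist(ig), 1, function(e)
                   paste(sort(e), collapse = "-")),
                   paste(pmin(pl2$protein_a, pl2$protein_b),
                         pmax(pl2$protein_a, pl2$protein_b), sep = "-"))]))

  # two disconnected pairs: 2 edges, 2 components
  pl3 <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"),
                    combined_score = c(950, 960))
  mst3 <- mst_of_targets(c("A", "B", "C", "D"), pl3)
  expect_equal(nrow(mst3$edges), 2L)
  expect_equal(mst3$n_components, 2L)

  # equal weights: lexicographic tie-break is reproducible
  pl4 <- data.frame(protein_a = c("A", "A", "B"),
                    protein_b = c("B", "C", "C"),
                    combined_score = 900)
  mst4 <- mst_of_targets(c("A", "B", "C"), pl4)
  expect_identical(paste(mst4$edges$protein_a, mst4$edges$protein_b),
                   c("A B", "A C"))

  expect_warning(mst_of_targets(c("X", "Y"), pl3), "no protein links")
  expect_error(mst_of_targets("A", pl3), "at least 2")
})

test_that("ROC evaluation sweeps thresholds and matches the rank-sum AUC", {
  set.seed(44)
  # perfectly separating scores
  obs <- data.frame(drug = paste0("d", 1:10), feature = "f1",
                    observed_change = c(rep(-1, 5), rep(1, 5)))
  pred <- data.frame(
    drug = rep(paste0("d", 1:10), 2), feature = "f1",
    direction = rep(c("-", "+"), each = 10),
    score = c(c(0.9, 0.8, 0.95, 0.85, 0.7, 0.1, 0.2, 0.1, 0.3, 0.2),
              c(0.1, 0.2, 0.1, 0.3, 0.2, 0.9, 0.8, 0.95, 0.85, 0.7)))
  roc <- roc_predictions(pred, obs)
  expect_equal(roc$suppress$auc, 1)
  expect_equal(roc$enhance$auc, 1)
  expect_equal(roc$mean_auc, 1)

  # AUC equals the Mann-Whitney statistic; negation flips it
  score <- runif(100)
  label <- runif(100) < 0.4
  rc <- sigdecon:::roc_curve(score, label)
  u <- wilcox.test(score[label], score[!label], exact = FALSE)$statistic
  expect_equal(rc$auc, unname(u) / (sum(label) * sum(!label)),
               tolerance = 1e-12)
  rc_neg <- sigdecon:::roc_curve(-score, label)
  expect_equal(rc_neg$auc, 1 - rc$auc, tolerance = 1e-12)

  # null scores: AUC near 1/2
  inside <- vapply(1:10, function(s) {
    set.seed(400 + s)
    rcn <- sigdecon:::roc_curve(runif(500), runif(500) < 0.5)
    rcn$auc > 0.4 && rcn$auc < 0.6
  }, logical(1L))
  expect_gte(mean(inside), 0.95)

  # single observed class is an error
  obs_one <- transform(obs, observed_change = -1)
  expect_error(roc_predictions(pred, obs_one), "single class")
})
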