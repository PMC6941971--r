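# Synthetic data with planted ground truth. The generators emulate the
# linear-Gaussian structure assumed by the signature model (Y = H F + noise,
# Z = B F + noise), the compendium contract of the match score (causal drugs
# displace expression along a planted signature), exponential survival with a
# linear predictor, and exponentially distributed protrusion lengths.

#' Simulate patient cohorts with a shared planted signature
#'
#' Generates `n_cohorts` cohorts sharing the same true gene signature matrix
#' `B_true` and factor loadings `H_true`, with independent latent features
#' and noise per cohort: `Y = H_true F + e_Y`, `Z = signal_scale * B_true F
#' + e_Z`. Each disease factor loads on exactly one latent feature (risk
#' factors cluster into axes, e.g. amplification-related versus
#' differentiation-related), with block sizes and strengths decreasing over
#' features so the latent axes stay identifiable by SVD even after
#' per-factor standardization; a fraction of factor rows is dichotomized at
#' the median to mimic binary clinical aberrations.
#'
#' @param n_cohorts number of cohorts (default 3).
#' @param n_patients patients per cohort (default 200).
#' @param p_disease number of disease factors (default 16).
#' @param p_genes number of landmark genes (default 978).
#' @param k number of latent features (default 2).
#' @param signal_scale multiplier on the expression signal (default 1).
#' @param noise_sd sd of the gene-level expression noise (default 1).
#' @param y_noise_sd sd of the disease-factor noise (default 0.5).
#' @param binary_fraction fraction of factor rows dichotomized (default
#'   0.25).
#' @param heavy_tails if `TRUE`, draw noise from a t distribution with 3
#'   degrees of freedom (scaled to `noise_sd`) instead of Gaussian.
#' @param seed RNG seed.
#' @return list with `cohorts` (list of [cohort_data]) and `truth` (list
#'   with `B_true`, `H_true`, `F_list`, generation parameters).
#' @export
simulate_cohorts <- function(n_cohorts = 3L, n_patients = 200L,
                             p_disease = 16L, p_genes = 978L, k = 2L,
                             signal_scale = 1, noise_sd = 1,
                             y_noise_sd = 0.5, binary_fraction = 0.25,
                             heavy_tails = FALSE, seed = 1L) {
  if (k > min(p_disease, n_patients)) stop("k exceeds min(p_disease, n)")
  with_seed(seed, {
    rnoise <- function(n, sd) {
      if (heavy_tails) sd * stats::rt(n, df = 3) / sqrt(3)
      else stats::rnorm(n, sd = sd)
    }
    B_true <- matrix(stats::rnorm(p_genes * k), p_genes, k,
                     dimnames = list(paste0("g", seq_len(p_genes)),
                                     paste0("f", seq_len(k))))
    # one block of factors per latent feature; unequal block sizes and
    # decreasing strengths keep the singular values separated after
    # per-factor standardization
    block_w <- rev(seq_len(k))
    sizes <- diff(round(cumsum(c(0, block_w)) / sum(block_w) * p_disease))
    if (any(sizes < 1L)) stop("p_disease too small for k blocks")
    strengths <- 4 - (seq_len(k) - 1) * (1.5 / max(k - 1, 1))
    H_true <- matrix(0, p_disease, k)
    binary_rows <- integer(0L)
    row0 <- 0L
    for (j in seq_len(k)) {
      rows <- row0 + seq_len(sizes[j])
      H_true[rows, j] <- strengths[j] * stats::runif(sizes[j], 0.6, 1) *
        sample(c(-1, 1), sizes[j], replace = TRUE)
      # dichotomized factors spread over blocks so every latent axis keeps
      # its share of continuous factors
      binary_rows <- c(binary_rows,
                       rows[seq_len(round(binary_fraction * sizes[j]))])
      row0 <- row0 + sizes[j]
    }
    rownames(H_true) <- paste0("factor", seq_len(p_disease))
    cohorts <- vector("list", n_cohorts)
    F_list <- vector("list", n_cohorts)
    for (i in seq_len(n_cohorts)) {
      F_raw <- matrix(stats::rnorm(k * n_patients), k, n_patients)
      Y <- H_true %*% F_raw +
        matrix(rnoise(p_disease * n_patients, y_noise_sd),
               p_disease, n_patients)
      for (r in binary_rows) {
        Y[r, ] <- as.numeric(Y[r, ] > stats::median(Y[r, ]))
      }
      Z <- signal_scale * (B_true %*% F_raw) +
        matrix(rnoise(p_genes * n_patients, noise_sd), p_genes, n_patients)
      rownames(Y) <- rownames(H_true)
      rownames(Z) <- rownames(B_true)
      colnames(Y) <- colnames(Z) <-
        sprintf("C%d_P%03d", i, seq_len(n_patients))
      cohorts[[i]] <- cohort_data(sprintf("cohort%d", i), Y, Z)
      F_list[[i]] <- F_raw
    }
    list(
      cohorts = cohorts,
      truth = list(B_true = B_true, H_true = H_true, F_list = F_list,
                   k = k, signal_scale = signal_scale, noise_sd = noise_sd,
                   y_noise_sd = y_noise_sd, seed = seed)
    )
  })
}

#' Simulate a perturbation compendium with a planted causal target
#'
#' Drugs linked to the causal target displace expression along the planted
#' signature: their fold-change profile in every cell line is
#' `direction_sign * effect_size * b + noise`, where `b` is the signature
#' column scaled to unit population sd (so `effect_size` is in noise-sd
#' units per gene); all other drugs are pure noise. The link table assigns
#' the causal drugs to the causal target at score 950; decoy targets receive
#' the same number of random inert drugs at score 950 (testable but null),
#' and additional random sub-threshold links (scores 100-900) exercise the
#' strict-threshold split.
#'
#' @param B_true planted gene x feature signature matrix (from
#'   [simulate_cohorts()]).
#' @param n_drugs total drugs (default 300).
#' @param n_cell_lines cell lines (default 3).
#' @param n_targets total protein targets incl. the causal one (default 20).
#' @param drugs_per_target linked drugs per target (default 10; must be at
#'   least the enrichment `min_group_size`).
#' @param effect_size causal displacement in per-gene noise-sd units
#'   (default 5); must be nonnegative, direction carries the sign.
#' @param noise_sd profile noise sd (default 1).
#' @param causal_feature feature (column of `B_true`) the causal target acts
#'   on (default first).
#' @param causal_direction `"-"` (suppressor, default) or `"+"` (enhancer).
#' @param coverage probability a (drug, cell line) profile is present
#'   (default 1 = dense; 0.7 mimics sparse compendium coverage).
#' @param seed RNG seed.
#' @return list with `compendium` (raw fold changes, run [z_transform()]
#'   before scoring), `links` (a [target_link_table]) and `truth`.
#' @export
simulate_compendium <- function(B_true, n_drugs = 300L, n_cell_lines = 3L,
                                n_targets = 20L, drugs_per_target = 10L,
                                effect_size = 5, noise_sd = 1,
                                causal_feature = colnames(B_true)[1L],
                                causal_direction = "-", coverage = 1,
                                seed = 1L) {
  if (effect_size < 0) stop("effect_size must be nonnegative; the direction carries the sign")
  if (!causal_direction %in% c("-", "+")) stop('causal_direction must be "-" or "+"')
  stopifnot(is.matrix(B_true))
  p <- nrow(B_true)
  with_seed(seed, {
    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    lines <- sprintf("CL%d", seq_len(n_cell_lines))
    targets <- sprintf("T%02d", seq_len(n_targets))
    causal_target <- targets[1L]
    b <- B_true[, causal_feature]
    b_std <- b / sqrt(mean((b - mean(b))^2))
    sgn <- if (causal_direction == "-") -1 else 1
    causal_drugs <- drugs[seq_len(drugs_per_target)]
    inert_drugs <- setdiff(drugs, causal_drugs)

    present <- matrix(stats::runif(n_drugs * n_cell_lines) < coverage,
                      n_drugs, n_cell_lines,
                      dimnames = list(drugs, lines))
    none <- rowSums(present) == 0L
    present[none, 1L] <- TRUE  # every drug present somewhere

    profiles <- list()
    for (s in seq_along(lines)) {
      here <- drugs[present[, s]]
      m <- matrix(stats::rnorm(p * length(here), sd = noise_sd), p,
                  length(here),
                  dimnames = list(rownames(B_true), here))
      hit <- intersect(here, causal_drugs)
      if (length(hit) > 0L) {
        m[, hit] <- m[, hit, drop = FALSE] + sgn * effect_size * b_std
      }
      profiles[[lines[s]]] <- m
    }

    # link table: causal + decoy assignments at 950, background sub-threshold
    assign_list <- list(data.frame(chemical = causal_drugs,
                                   protein = causal_target,
                                   combined_score = 950,
                                   stringsAsFactors = FALSE))
    for (tg in targets[-1L]) {
      picked <- sample(inert_drugs, drugs_per_target)
      assign_list[[length(assign_list) + 1L]] <-
        data.frame(chemical = picked, protein = tg, combined_score = 950,
                   stringsAsFactors = FALSE)
    }
    bg <- data.frame(
      chemical = sample(drugs, n_drugs, replace = TRUE),
      protein = sample(targets, n_drugs, replace = TRUE),
      combined_score = round(stats::runif(n_drugs, 100, 900)),
      stringsAsFactors = FALSE)
    link_df <- rbind(do.call(rbind, assign_list), bg)
    links <- suppressWarnings(
      target_link_table(link_df$chemical, link_df$protein,
                        link_df$combined_score))

    comp <- perturbation_compendium(profiles, gene_ids = rownames(B_true),
                                    zscored = FALSE)

    # protein-protein links among the targets (for the MST summary):
    # a random connected-ish scored graph
    pp <- utils::combn(targets, 2L)
    take <- stats::runif(ncol(pp)) < 0.3
    take[seq_len(n_targets - 1L)] <- TRUE  # spanning-path edges kept
    protein_links <- data.frame(
      protein_a = pp[1L, take], protein_b = pp[2L, take],
      combined_score = round(stats::runif(sum(take), 400, 999)),
      stringsAsFactors = FALSE)

    list(
      compendium = comp,
      links = links,
      protein_links = protein_links,
      truth = list(
        causal_targets = data.frame(feature = causal_feature,
                                    target = causal_target,
                                    direction = causal_direction,
                                    effect_size = effect_size,
                                    stringsAsFactors = FALSE),
        causal_drugs = causal_drugs,
        drug_assignment = do.call(rbind, assign_list),
        seed = seed)
    )
  })
}

#' Simulate survival data with exponential hazards
#'
#' Event times are exponential with rate `exp(X beta)`; censoring is an
#' independent exponential calibrated so roughly `censoring_rate` of
#' baseline-hazard patients are censored.
#'
#' @param n patients.
#' @param beta coefficient vector (its length sets the covariate count).
#' @param censoring_rate expected censoring fraction in \[0, 1).
#' @param seed RNG seed.
#' @return a [survival_table] with covariate columns `x1..xq`; the true
#'   coefficients are attached as `attr(x, "beta_true")`.
#' @export
simulate_survival <- function(n = 200L, beta = 1, censoring_rate = 0.2,
                              seed = 1L) {
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  beta <- as.numeric(beta)
  with_seed(seed, {
    q <- length(beta)
    X <- matrix(stats::rnorm(n * q), n, q,
                dimnames = list(NULL, paste0("x", seq_len(q))))
    rate <- exp(as.numeric(X %*% beta))
    t_event <- stats::rexp(n, rate = rate)
    if (censoring_rate == 0) {
      time <- t_event; event <- rep(1, n)
    } else {
      c_rate <- censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.numeric(t_event <= t_cens)
    }
    out <- survival_table(sprintf("P%04d", seq_len(n)), time, event,
                          covariates = as.data.frame(X))
    attr(out, "beta_true") <- beta
    out
  })
}

#' Simulate cell-protrusion length measurements
#'
#' Per image, the protrusion count is Poisson with mean `A_true` and lengths
#' are i.i.d. exponential with decay `k_true`, matching the exponential
#' survival-count model fitted by [fit_protrusion_decay()].
#'
#' @param A_true expected protrusion count per image.
#' @param k_true exponential decay per length unit (> 0).
#' @param n_images number of images.
#' @param interface_length cell-background interface length `N_bp` attached
#'   to every image.
#' @param seed RNG seed.
#' @return list with `lengths` (data.frame image_id, protrusion_length),
#'   `images` (data.frame image_id, N_bp) and `truth`.
#' @export
simulate_protrusions <- function(A_true = 50, k_true = 0.002,
                                 n_images = 10L, interface_length = 1000,
                                 seed = 1L) {
  if (k_true <= 0) stop("k_true must be positive")
  with_seed(seed, {
    ids <- sprintf("img%03d", seq_len(n_images))
    counts <- stats::rpois(n_images, A_true)
    lengths <- data.frame(
      image_id = rep(ids, counts),
      protrusion_length = stats::rexp(sum(counts), rate = k_true),
      stringsAsFactors = FALSE)
    list(lengths = lengths,
         images = data.frame(image_id = ids, N_bp = interface_length,
                             stringsAsFactors = FALSE),
         truth = list(A_true = A_true, k_true = k_true, seed = seed))
  })
}
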