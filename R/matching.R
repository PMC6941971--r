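# Signature-to-perturbation matching: calibrated similarity sigma, the
# cross-cell-line consistency weight sigma_bar, the bounded match score S(r),
# and its permutation null.

#' Fit the similarity calibration from same-target drug pairs
#'
#' The similarity sigma between a drug profile and a signature is a clipped,
#' calibrated cosine: the raw cosine divided by a per-cell-line reference
#' scale `rho_same`, the mean cosine between pairs of drugs sharing a
#' high-confidence protein target. A cosine at the same-target level thus
#' maps to 1, orthogonality to 0. Cell lines with fewer than `min_pairs`
#' same-target pairs fall back to the pooled estimate across all lines
#' (flagged in the result).
#'
#' @param comp a z-scored [perturbation_compendium].
#' @param links a [target_link_table].
#' @param score_threshold minimum link score defining "same target"
#'   (strictly greater; default 900).
#' @param min_pairs minimum same-target pairs for a per-line estimate
#'   (default 30).
#' @return object of class `similarity_calibration`: `rho_same` (named per
#'   cell line), `n_pairs`, `fallback` (logical), `score_threshold`.
#' @export
fit_calibration <- function(comp, links, score_threshold = 900,
                            min_pairs = 30L) {
  stopifnot(inherits(comp, "perturbation_compendium"),
            inherits(links, "target_link_table"))
  strong <- links[links$combined_score > score_threshold, , drop = FALSE]
  by_protein <- split(strong$chemical, strong$protein)
  rho <- n_pairs <- stats::setNames(numeric(length(comp$cell_lines)),
                                    comp$cell_lines)
  sums <- stats::setNames(numeric(length(comp$cell_lines)), comp$cell_lines)
  for (cl in comp$cell_lines) {
    m <- comp$profiles[[cl]]
    u <- sweep(m, 2L, col_norms(m), "/")
    s_sum <- 0; s_n <- 0L
    for (drugs in by_protein) {
      present <- unique(intersect(drugs, colnames(u)))
      if (length(present) < 2L) next
      cm <- crossprod(u[, present, drop = FALSE])
      s_sum <- s_sum + (sum(cm) - length(present)) / 2
      s_n <- s_n + length(present) * (length(present) - 1L) / 2L
    }
    sums[cl] <- s_sum
    n_pairs[cl] <- s_n
    rho[cl] <- if (s_n > 0L) s_sum / s_n else NA_real_
  }
  fallback <- n_pairs < min_pairs
  if (any(fallback)) {
    if (sum(n_pairs) == 0L) {
      stop("no same-target drug pairs available for calibration")
    }
    pooled <- sum(sums) / sum(n_pairs)
    message("fit_calibration: ", sum(fallback), " cell line(s) fall back ",
            "to the pooled same-target estimate (", signif(pooled, 4L), ")")
    rho[fallback] <- pooled
  }
  if (any(rho <= 0)) {
    stop("nonpositive same-target reference cosine; the link table carries ",
         "no usable same-target signal for calibration")
  }
  structure(list(rho_same = rho, n_pairs = n_pairs, fallback = fallback,
                 score_threshold = score_threshold),
            class = "similarity_calibration")
}

#' Calibrated similarity between a profile and a signature
#'
#' `sigma = clip(cos(g, h) / rho_same, 0, 1)`: 0 means no match (orthogonal
#' or opposed), 1 a match at the level expected for two drugs sharing a
#' target. Monotone non-decreasing in the scalar product `g'h`, and
#' symmetric under joint negation: `sigma(g, -h) = sigma(-g, h)`.
#'
#' @param g profile vector (z-scored).
#' @param h signature vector.
#' @param calib a `similarity_calibration`.
#' @param cell_line which line's reference scale to use (default: first).
#' @return sigma in \[0, 1\].
#' @export
similarity <- function(g, h, calib, cell_line = names(calib$rho_same)[1L]) {
  rho <- calib$rho_same[[cell_line]]
  ng <- sqrt(sum(g^2)); nh <- sqrt(sum(h^2))
  if (ng == 0 || nh == 0) stop("zero-norm input to similarity()")
  clip01(sum(g * h) / (ng * nh) / rho)
}

#' Cross-cell-line consistency weight per drug
#'
#' `sigma_bar(r)` measures a drug's propensity to produce the same
#' transcriptional response in different cell lines: the mean, over
#' unordered line pairs where the drug is present, of the clipped cosine
#' between its two profiles divided by `rho_cons`, the compendium-wide mean
#' same-drug cross-line cosine. Drugs present in a single line receive the
#' neutral value 0.5 and are flagged.
#'
#' @param comp a z-scored [perturbation_compendium].
#' @param neutral value assigned to single-line drugs (default 0.5).
#' @param rho_cons optional fixed reference scale; when `NULL` (default) it
#'   is estimated from the compendium itself.
#' @return list with `sigma_bar` (named per drug), `rho_cons`,
#'   `single_line` (logical per drug).
#' @export
drug_consistency <- function(comp, neutral = 0.5, rho_cons = NULL) {
  stopifnot(inherits(comp, "perturbation_compendium"))
  units <- lapply(comp$profiles, function(m) {
    sweep(m, 2L, col_norms(m), "/")
  })
  lines <- comp$cell_lines
  cos_sum <- stats::setNames(numeric(length(comp$drugs)), comp$drugs)
  cos_n <- stats::setNames(integer(length(comp$drugs)), comp$drugs)
  if (length(lines) >= 2L) {
    for (a in seq_along(lines)[-length(lines)]) {
      for (b in (a + 1L):length(lines)) {
        shared <- intersect(colnames(units[[a]]), colnames(units[[b]]))
        if (length(shared) == 0L) next
        cc <- colSums(units[[a]][, shared, drop = FALSE] *
                        units[[b]][, shared, drop = FALSE])
        cos_sum[shared] <- cos_sum[shared] + cc
        cos_n[shared] <- cos_n[shared] + 1L
      }
    }
  }
  multi <- cos_n > 0L
  sigma_bar <- stats::setNames(rep(neutral, length(comp$drugs)), comp$drugs)
  if (any(multi)) {
    if (is.null(rho_cons)) {
      rho_cons <- sum(cos_sum[multi]) / sum(cos_n[multi])
    }
    if (rho_cons <= 0) {
      warning("nonpositive compendium-wide cross-line cosine; ",
              "sigma_bar set to the neutral value for all drugs")
    } else {
      # per-pair clipping, then mean over pairs: recompute pairwise
      clip_sum <- stats::setNames(numeric(length(comp$drugs)), comp$drugs)
      for (a in seq_along(lines)[-length(lines)]) {
        for (b in (a + 1L):length(lines)) {
          shared <- intersect(colnames(units[[a]]), colnames(units[[b]]))
          if (length(shared) == 0L) next
          cc <- colSums(units[[a]][, shared, drop = FALSE] *
                          units[[b]][, shared, drop = FALSE])
          clip_sum[shared] <- clip_sum[shared] + clip01(cc / rho_cons)
        }
      }
      sigma_bar[multi] <- clip_sum[multi] / cos_n[multi]
    }
  }
  list(sigma_bar = sigma_bar, rho_cons = rho_cons %||% NA_real_,
       single_line = !multi)
}

# Core scorer: for one feature and one direction, returns the per-drug match
# score and the per-(drug, line) cohort-product sigma term.
compute_scores <- function(comp, sets, calib, sigma_bar, feature, direction,
                           weights = NULL, gene_perm = NULL) {
  sgn <- if (direction == "-") -1 else 1
  lines <- comp$cell_lines
  w <- weights %||% stats::setNames(rep(1, length(lines)), lines)
  w <- w[lines]
  if (any(is.na(w)) || any(w < 0)) stop("weights must be nonnegative, one per cell line")
  # unit signature vectors per cohort (signs applied; permutation optional)
  Bu <- vapply(sets, function(s) {
    b <- s$B[, feature]
    if (!is.null(gene_perm)) b <- b[gene_perm]
    sgn * b / sqrt(sum(b^2))
  }, numeric(length(comp$gene_ids)))
  prod_mat <- matrix(NA_real_, length(comp$drugs), length(lines),
                     dimnames = list(comp$drugs, lines))
  for (cl in lines) {
    m <- comp$profiles[[cl]]
    u <- sweep(m, 2L, col_norms(m), "/")
    cosines <- crossprod(u, Bu)                 # drugs x cohorts
    sig <- clip01(cosines / calib$rho_same[[cl]])
    pr <- sig[, 1L]
    for (j in seq_len(ncol(sig))[-1L]) pr <- pr * sig[, j]
    prod_mat[colnames(m), cl] <- pr
  }
  present <- !is.na(prod_mat)
  w_mat <- matrix(w, nrow(prod_mat), length(lines), byrow = TRUE)
  w_mat[!present] <- 0
  denom <- rowSums(w_mat)
  pm0 <- prod_mat; pm0[!present] <- 0
  score <- sigma_bar[comp$drugs] * rowSums(pm0 * w_mat) / denom
  score[denom == 0] <- NA_real_
  list(score = score, sigma = prod_mat,
       n_cell_lines = rowSums(present))
}

#' Match score of one drug against the cohort signatures
#'
#' The bounded match score
#' `S(r) = sigma_bar(r) * (1/N_r) * sum_s w_s prod_i sigma(g_rs, +/- B_i)`:
#' the per-cell-line product of calibrated similarities across cohorts,
#' averaged over the cell lines where the drug is present (weights `w`
#' normalized over those lines), and weighted by the drug's cross-line
#' consistency. Direction `"-"` scores against the negated signatures
#' (suppressors), `"+"` against the signatures themselves (enhancers).
#'
#' @param drug drug identifier.
#' @param comp z-scored [perturbation_compendium].
#' @param sets list of [signature_set] (one per cohort), genes matching the
#'   compendium.
#' @param calib a `similarity_calibration`.
#' @param consistency result of [drug_consistency()] (computed if `NULL`).
#' @param feature feature name to score against.
#' @param direction `"-"` or `"+"`.
#' @param weights optional named nonnegative per-cell-line weights.
#' @return S(r) in \[0, 1\].
#' @export
match_score <- function(drug, comp, sets, calib, consistency = NULL,
                        feature, direction = "-", weights = NULL) {
  consistency <- consistency %||% drug_consistency(comp)
  res <- compute_scores(comp, sets, calib, consistency$sigma_bar,
                        feature, direction, weights)
  s <- res$score[[drug]]
  if (is.na(s)) stop("drug absent from every cell line: ", drug)
  s
}

#' Score every drug against every signature feature and direction
#'
#' @inheritParams match_score
#' @param directions directions to score (default both `"-"` and `"+"`).
#' @param features features to score (default: all shared feature names).
#' @param consistency_report optional [signature_consistency()] result; when
#'   supplied, its cross-cohort sign alignment is applied to the signatures
#'   (see [align_signatures()]) and features failing the consistency filter
#'   are refused unless `force = TRUE`.
#' @param force score failing features anyway.
#' @return a `match_score_table` data.frame with one row per (drug, feature,
#'   direction), per-cell-line cohort-product sigma columns (`sigma.<line>`),
#'   `sigma_bar` and `n_cell_lines`.
#' @export
score_all <- function(comp, sets, calib, consistency = NULL,
                      directions = c("-", "+"), features = NULL,
                      weights = NULL, consistency_report = NULL,
                      force = FALSE) {
  stopifnot(inherits(comp, "perturbation_compendium"))
  if (inherits(sets, "signature_set")) sets <- list(sets)
  for (s in sets) {
    if (!identical(s$gene_ids, comp$gene_ids)) {
      stop("signature gene set does not match the compendium")
    }
  }
  features <- features %||% sets[[1L]]$feature_names
  if (!is.null(consistency_report)) {
    failing <- consistency_report$summary$feature[!consistency_report$summary$pass]
    bad <- intersect(features, failing)
    if (length(bad) > 0L && !force) {
      stop("feature(s) failed the cross-cohort consistency filter: ",
           paste(bad, collapse = ", "), " (use force = TRUE to override)")
    }
    sets <- align_signatures(sets, consistency_report)
  }
  consistency <- consistency %||% drug_consistency(comp)
  rows <- list()
  for (f in features) {
    for (d in directions) {
      res <- compute_scores(comp, sets, calib, consistency$sigma_bar, f, d,
                            weights)
      sig_df <- as.data.frame(res$sigma)
      names(sig_df) <- paste0("sigma.", comp$cell_lines)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = comp$drugs, feature = f, direction = d,
        score = as.numeric(res$score),
        sigma_bar = as.numeric(consistency$sigma_bar[comp$drugs]),
        n_cell_lines = as.integer(res$n_cell_lines),
        sig_df, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  match_score_table(out)
}

#' Permutation null for match scores
#'
#' Generates a null score distribution by permuting the gene labels of the
#' signatures -- the same fresh permutation applied to every cohort's vector
#' at each iteration, preserving the drug-drug correlation structure of the
#' compendium -- and rescoring all drugs. Per-drug empirical p-values use the
#' add-one rule `p = (1 + #{null >= S}) / (1 + n_perm)` against the drug's
#' own null scores. An alternative null that permutes drug labels instead is
#' available via `unit = "drugs"`.
#'
#' @inheritParams score_all
#' @param feature single feature name.
#' @param direction `"-"` or `"+"`.
#' @param n_perm number of permutations (>= 100 recommended for p-values).
#' @param seed RNG seed; same seed reproduces the null exactly.
#' @param unit permutation unit: `"genes"` (default) or `"drugs"`.
#' @return list with `observed` (named scores), `null` (n_perm x drugs
#'   matrix), `p` (named per-drug empirical p-values), `null_ecdf`.
#' @export
permutation_null <- function(comp, sets, calib, consistency = NULL,
                             feature, direction = "-", n_perm = 100L,
                             seed = 1L, weights = NULL,
                             unit = c("genes", "drugs")) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  unit <- match.arg(unit)
  if (inherits(sets, "signature_set")) sets <- list(sets)
  consistency <- consistency %||% drug_consistency(comp)
  obs <- compute_scores(comp, sets, calib, consistency$sigma_bar,
                        feature, direction, weights)$score
  keep <- !is.na(obs)
  obs <- obs[keep]
  p_genes <- length(comp$gene_ids)
  null <- matrix(NA_real_, n_perm, length(obs),
                 dimnames = list(NULL, names(obs)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  for (b in seq_len(n_perm)) {
    if (unit == "genes") {
      perm <- sample.int(p_genes)
      sc <- compute_scores(comp, sets, calib, consistency$sigma_bar,
                           feature, direction, weights,
                           gene_perm = perm)$score
    } else {
      sc <- stats::setNames(sample(obs), names(obs))
    }
    null[b, ] <- sc[names(obs)]
  }
  p <- vapply(seq_along(obs), function(i) {
    nl <- null[, i]; nl <- nl[!is.na(nl)]
    (1 + sum(nl >= obs[i])) / (1 + length(nl))
  }, numeric(1L))
  names(p) <- names(obs)
  list(observed = obs, null = null, p = p,
       null_ecdf = stats::ecdf(null[!is.na(null)]))
}
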