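# Signature estimation: low-rank disease features and their regression onto
# landmark-gene expression.

# Standardize a disease-factor matrix row-wise: continuous rows are centred
# and scaled to unit sd, binary (0/1) rows are centred only. Missing entries
# are masked during the statistics and set to 0 (the row mean) afterwards so
# the downstream SVD sees a complete matrix.
standardize_disease <- function(Y) {
  Ys <- Y
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    obs <- y[!is.na(y)]
    if (length(obs) < 2L || stats::sd(obs) == 0) {
      stop("constant factor row: ", rownames(Y)[i] %||% i)
    }
    is_binary <- all(obs %in% c(0, 1))
    y <- y - mean(obs)
    if (!is_binary) y <- y / stats::sd(obs)
    y[is.na(y)] <- 0
    Ys[i, ] <- y
  }
  Ys
}

#' Extract low-rank latent features from a disease-factor matrix
#'
#' Models the disease data as `Y = H F + noise` and extracts the rank-`k`
#' features by truncated SVD of the standardized matrix, so `H F` is the best
#' rank-`k` Frobenius approximation. Rows of `F` (one latent feature per row)
#' are unit L2 norm; each feature is oriented so that its largest-magnitude
#' loading in `H` is positive, making signs reproducible.
#'
#' @param Y disease matrix, factors x patients. Continuous rows are
#'   standardized, binary rows centred only; `NA`s are masked.
#' @param k number of latent features, `1 <= k <= min(dim(Y))`.
#' @return a [feature_decomposition] with `H` (factors x k), `F` (k x
#'   patients) and per-feature `explained_fraction` of the squared norm.
#' @export
extract_features <- function(Y, k) {
  stopifnot(is.matrix(Y))
  if (k < 1L || k > min(dim(Y))) {
    stop("k must lie in [1, min(p_disease, n)]")
  }
  Ys <- standardize_disease(Y)
  sv <- svd(Ys)
  pos <- sum(sv$d > max(dim(Ys)) * .Machine$double.eps * sv$d[1L])
  if (k > pos) stop("k exceeds the numerical rank (", pos, ") of Y")
  H <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  F_mat <- t(sv$v[, seq_len(k), drop = FALSE])  # rows already unit norm
  # orient: largest-|loading| entry of each H column positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(H[, j]))
    if (H[i_max, j] < 0) {
      H[, j] <- -H[, j]
      F_mat[j, ] <- -F_mat[j, ]
    }
  }
  rownames(H) <- rownames(Y)
  colnames(H) <- rownames(F_mat) <- paste0("f", seq_len(k))
  colnames(F_mat) <- colnames(Y)
  feature_decomposition(H, F_mat,
                        explained_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Compute latent features in supervised mode
#'
#' Two entry points: (i) given factor-space loadings `H`, solve
#' `F = argmin ||Y - H F||` by least squares per patient; (ii) given signed
#' marker gene sets and expression `Z`, score each patient as the mean
#' z-scored expression of the up-markers minus the down-markers. In both
#' cases rows of `F` are renormalized to unit L2 norm with the compensating
#' scale moved into the returned `H`.
#'
#' @param Y disease matrix (required for the `H` route).
#' @param H factor loadings, factors x k, full column rank.
#' @param markers list of marker sets, each a list with character vectors
#'   `up` and optionally `down`.
#' @param Z row-centred expression matrix, genes x patients (marker route).
#' @param allow_missing if `TRUE`, marker genes absent from `Z` are dropped
#'   with a message.
#' @return a [feature_decomposition].
#' @export
supervised_features <- function(Y = NULL, H = NULL, markers = NULL, Z = NULL,
                                allow_missing = FALSE) {
  if (!is.null(H)) {
    stopifnot(is.matrix(Y), is.matrix(H), nrow(H) == nrow(Y))
    if (qr(H)$rank < ncol(H)) stop("H is rank-deficient")
    # H is supplied in the units of Y, so Y is used unstandardized here
    F_mat <- qr.solve(H, Y)
    if (is.null(rownames(F_mat))) {
      rownames(F_mat) <- colnames(H) %||% paste0("f", seq_len(ncol(H)))
    }
  } else if (!is.null(markers)) {
    stopifnot(is.matrix(Z), is.list(markers))
    Zz <- t(scale(t(Z)))  # gene-wise z-score across patients
    F_mat <- t(vapply(markers, function(mk) {
      up <- mk$up %||% character(0L)
      down <- mk$down %||% character(0L)
      miss <- setdiff(c(up, down), rownames(Z))
      if (length(miss) > 0L) {
        if (!allow_missing) {
          stop("marker genes absent from expression: ",
               paste(utils::head(miss, 10L), collapse = ", "))
        }
        message("supervised_features: dropping ", length(miss),
                " absent marker gene(s)")
        up <- intersect(up, rownames(Z)); down <- intersect(down, rownames(Z))
      }
      score <- if (length(up)) colMeans(Zz[up, , drop = FALSE]) else 0
      if (length(down)) score <- score - colMeans(Zz[down, , drop = FALSE])
      score
    }, numeric(ncol(Z))))
    rownames(F_mat) <- names(markers) %||% paste0("f", seq_len(nrow(F_mat)))
    H <- diag(nrow(F_mat))
  } else {
    stop("provide either H (with Y) or markers (with Z)")
  }
  scales <- sqrt(rowSums(F_mat^2))
  if (any(scales == 0)) stop("a supervised feature is identically zero")
  F_unit <- F_mat / scales
  H_scaled <- if (is.matrix(H)) H %*% diag(scales, nrow = length(scales))
              else diag(scales, nrow = length(scales))
  rownames(H_scaled) <- rownames(H) %||% rownames(F_mat)
  colnames(H_scaled) <- rownames(F_unit)
  feature_decomposition(H_scaled, F_unit)
}

#' Cox proportional-hazards risk feature
#'
#' Fits a Cox regression of survival on standardized covariates and returns
#' each patient's linear predictor (log-proportional hazard) as one extra
#' latent feature row, unit L2 normed. A small ridge penalty stabilizes the
#' fit; ties are handled by the Efron approximation.
#'
#' @param surv a [survival_table] (or data.frame with `time`, `event`).
#' @param X covariate matrix, patients x covariates (e.g. selected expression
#'   rows transposed), standardized internally.
#' @param ridge ridge penalty (default 1e-4).
#' @return list with `feature` (named unit-norm numeric vector over
#'   patients), `lp` (raw linear predictor) and `fit` (the `coxph` object).
#' @export
cox_risk_feature <- function(surv, X, ridge = 1e-4) {
  stopifnot(is.data.frame(surv), all(c("time", "event") %in% names(surv)))
  X <- as.matrix(X)
  if (nrow(X) != nrow(surv)) stop("X rows must match survival rows")
  if (sum(surv$event) < 2L) stop("need at least 2 observed events")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s): ",
         paste(colnames(X)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  Xs <- scale(X)
  df <- data.frame(time = surv$time, event = surv$event)
  # the ridge() penalty term must appear unqualified for coxph's
  # special-term handling, so bind it in the formula environment
  fml <- stats::as.formula(
    "Surv(time, event) ~ ridge(Xs, theta = .theta, scale = FALSE)")
  env <- new.env(parent = getNamespace("survival"))
  env$.theta <- ridge
  env$Xs <- Xs
  environment(fml) <- env
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    error = function(e) {
      stop("Cox fit failed to converge (ridge penalty ", ridge, "): ",
           conditionMessage(e))
    })
  lp <- as.numeric(Xs %*% stats::coef(fit))
  names(lp) <- surv$patient %||% rownames(X)
  centred <- lp - mean(lp)
  nrm <- sqrt(sum(centred^2))
  if (nrm == 0) stop("degenerate Cox linear predictor")
  list(feature = centred / nrm, lp = lp, fit = fit)
}

#' Fit landmark-gene signatures by regression onto latent features
#'
#' Solves `B = Z F' (F F')^-1`, the least-squares projection of row-centred
#' expression onto the latent features; residual rows are orthogonal to every
#' feature row by the normal equations.
#'
#' @param Z row-centred expression matrix, genes x patients.
#' @param features a [feature_decomposition] or a bare k x patients matrix
#'   with full row rank.
#' @param cohort_id label for the returned signature set.
#' @return a [signature_set] with `B` of dimension genes x k.
#' @export
fit_signatures <- function(Z, features, cohort_id = "cohort") {
  F_mat <- if (inherits(features, "feature_decomposition")) features$F
           else features
  stopifnot(is.matrix(Z), is.matrix(F_mat), ncol(Z) == ncol(F_mat))
  G <- tcrossprod(F_mat)
  if (rcond(G) < 1e-12) {
    stop("F F' is numerically singular; reduce the number of features k")
  }
  B <- Z %*% t(F_mat) %*% solve(G)
  rownames(B) <- rownames(Z)
  colnames(B) <- rownames(F_mat) %||% paste0("f", seq_len(ncol(B)))
  signature_set(cohort_id, B)
}

#' Cross-cohort consistency of signatures
#'
#' For each feature, computes all pairwise Pearson correlations between the
#' cohorts' signature vectors, after aligning signs against the first cohort
#' (a cohort's vector is flipped, and the flip recorded, if its correlation
#' with cohort 1 is negative). A feature passes when its mean pairwise
#' correlation exceeds the threshold.
#'
#' @param sets list of [signature_set] objects with matched `feature_names`
#'   and `gene_ids`.
#' @param threshold pass threshold on the mean pairwise correlation
#'   (default 0.4).
#' @param align_signs apply the sign alignment before correlating (default
#'   `TRUE`). Set to `FALSE` for null calibrations such as label-shuffle
#'   controls, where aligning signs would bias the mean correlation upward
#'   by construction.
#' @return list of class `consistency_report`: `summary` data.frame (feature,
#'   mean_r, pass), `pairwise` data.frame of per-pair correlations, `flips`
#'   logical matrix (cohort x feature), `threshold`.
#' @export
signature_consistency <- function(sets, threshold = 0.4,
                                  align_signs = TRUE) {
  if (length(sets) < 2L) stop("need at least 2 cohorts")
  genes <- sets[[1L]]$gene_ids
  feats <- sets[[1L]]$feature_names
  for (s in sets) {
    if (!identical(s$gene_ids, genes)) stop("mismatched gene sets")
    if (!identical(s$feature_names, feats)) stop("mismatched feature names")
  }
  n_coh <- length(sets)
  coh_ids <- vapply(sets, `[[`, character(1L), "cohort_id")
  flips <- matrix(FALSE, n_coh, length(feats),
                  dimnames = list(coh_ids, feats))
  pairwise <- list()
  mean_r <- numeric(length(feats))
  for (j in seq_along(feats)) {
    vecs <- lapply(sets, function(s) s$B[, j])
    if (align_signs) {
      for (i in seq_len(n_coh)[-1L]) {
        if (stats::cor(vecs[[i]], vecs[[1L]]) < 0) {
          vecs[[i]] <- -vecs[[i]]
          flips[i, j] <- TRUE
        }
      }
    }
    pr <- utils::combn(n_coh, 2L, function(ij) {
      stats::cor(vecs[[ij[1L]]], vecs[[ij[2L]]])
    })
    cmb <- utils::combn(n_coh, 2L)
    pairwise[[j]] <- data.frame(
      feature = feats[j], cohort_a = coh_ids[cmb[1L, ]],
      cohort_b = coh_ids[cmb[2L, ]], r = pr, stringsAsFactors = FALSE)
    mean_r[j] <- mean(pr)
  }
  structure(
    list(
      summary = data.frame(feature = feats, mean_r = mean_r,
                           pass = mean_r > threshold,
                           stringsAsFactors = FALSE),
      pairwise = do.call(rbind, pairwise),
      flips = flips,
      threshold = threshold
    ),
    class = "consistency_report"
  )
}

#' Apply cross-cohort sign alignment to signature sets
#'
#' Flips the signature vectors recorded as sign-inverted by
#' [signature_consistency()], so that a given (feature, direction) means the
#' same transcriptional sense in every cohort. Without this step the
#' suppress/enhance directions of the match score are ill-defined across
#' cohorts: latent features carry an arbitrary sign per cohort, and a drug
#' opposing the signature in one cohort would appear to enhance it in
#' another, cancelling the cross-cohort product.
#'
#' @param sets list of [signature_set] objects.
#' @param report a `consistency_report` for the same sets.
#' @return the list of signature sets with flips applied.
#' @export
align_signatures <- function(sets, report) {
  stopifnot(inherits(report, "consistency_report"))
  for (i in seq_along(sets)) {
    for (f in sets[[i]]$feature_names) {
      if (report$flips[i, f]) {
        sets[[i]]$B[, f] <- -sets[[i]]$B[, f]
      }
    }
  }
  sets
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency_report: %d/%d features pass (mean r > %g)\n",
              sum(x$summary$pass), nrow(x$summary), x$threshold))
  print(x$summary)
  invisible(x)
}

#' Principal-component projection of signatures
#'
#' Stacks the cohorts' signature matrices column-wise (one column per
#' (cohort, feature)), after the same sign alignment used by
#' [signature_consistency()], and computes principal components of the genes
#' x signatures matrix. Features are rendered at unit length on the leading
#' component plane, genes as points.
#'
#' @param sets list of [signature_set] objects (>= 2 features overall).
#' @return list with `feature_coords` (unit-length 2-D directions per
#'   (cohort, feature)), `gene_coords` (gene scores on PC1/PC2) and
#'   `explained` (variance fractions).
#' @export
project_signatures <- function(sets) {
  if (inherits(sets, "signature_set")) sets <- list(sets)
  mats <- lapply(sets, function(s) {
    m <- s$B
    colnames(m) <- paste(s$cohort_id, s$feature_names, sep = ":")
    m
  })
  stacked <- do.call(cbind, mats)
  if (ncol(stacked) < 2L) stop("need at least 2 signatures to project")
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  gene_coords <- pc$x[, 1:2, drop = FALSE]
  # feature directions: biplot variable coordinates (loadings scaled by the
  # component sd, so zero-variance directions drop out), then unit length
  fc <- pc$rotation[, 1:2, drop = FALSE] %*% diag(pc$sdev[1:2], nrow = 2)
  colnames(fc) <- c("PC1", "PC2")
  lens <- sqrt(rowSums(fc^2))
  lens[lens == 0] <- 1
  list(feature_coords = fc / lens, gene_coords = gene_coords,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}
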