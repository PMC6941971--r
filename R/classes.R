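#' Cohort container: disease factors and landmark expression
#'
#' Bundles one patient cohort's disease-factor matrix `Y` (risk factors,
#' genetic aberrations or signature scores by patients) with its matched
#' landmark-gene expression matrix `Z` over the same patients. `Z` is stored
#' row-centred (each gene has mean zero across patients), the scale expected
#' by [fit_signatures()].
#'
#' @param cohort_id single string naming the cohort.
#' @param Y numeric matrix, disease factors x patients. Binary aberrations
#'   coded 0/1; continuous scores on their input scale. `NA` allowed (masked
#'   during feature extraction).
#' @param Z numeric matrix, landmark genes x patients, log-scale expression.
#'   Rows are centred by the constructor if not already.
#' @param center_Z if `TRUE` (default) row-centre `Z`.
#' @return object of class `cohort_data` with elements `cohort_id`,
#'   `patients`, `factors`, `Y`, `Z`, `gene_ids`.
#' @export
cohort_data <- function(cohort_id, Y, Z, center_Z = TRUE) {
  if (!is.matrix(Y) || !is.matrix(Z)) stop("Y and Z must be matrices")
  if (ncol(Y) != ncol(Z)) stop("Y and Z must share the same patients")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("P", seq_len(ncol(Y)))
  if (is.null(colnames(Z))) colnames(Z) <- colnames(Y)
  if (!identical(colnames(Y), colnames(Z))) {
    stop("Y and Z must have identical patient ordering")
  }
  if (is.null(rownames(Y))) rownames(Y) <- paste0("factor", seq_len(nrow(Y)))
  if (is.null(rownames(Z))) rownames(Z) <- paste0("g", seq_len(nrow(Z)))
  if (anyNA(Z)) stop("missing values in expression are not supported")
  if (center_Z) Z <- Z - rowMeans(Z)
  obj <- structure(
    list(
      cohort_id = as.character(cohort_id),
      patients = colnames(Y),
      factors = rownames(Y),
      Y = Y,
      Z = Z,
      gene_ids = rownames(Z)
    ),
    class = "cohort_data"
  )
  validate_cohort_data(obj)
  obj
}

#' Validate a `cohort_data` object's invariants
#'
#' Checks shared patient ordering, row-centred expression (tolerance 1e-8)
#' and that no factor row is constant.
#' @param x a `cohort_data` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_cohort_data <- function(x) {
  stopifnot(inherits(x, "cohort_data"))
  if (!identical(colnames(x$Y), colnames(x$Z))) {
    stop("Y and Z patient ordering differs")
  }
  if (max(abs(rowMeans(x$Z))) > 1e-8) {
    stop("expression rows are not centred (tolerance 1e-8)")
  }
  sds <- apply(x$Y, 1L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- x$factors[!is.finite(sds) | sds == 0]
    stop("constant factor row(s): ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Low-rank decomposition of a disease-factor matrix
#'
#' @param H loadings matrix, factors x k.
#' @param F_mat latent features, k x patients, rows unit L2 norm.
#' @param explained_fraction fraction of squared norm captured per feature.
#' @return object of class `feature_decomposition`.
#' @export
feature_decomposition <- function(H, F_mat, explained_fraction = NULL) {
  stopifnot(is.matrix(H), is.matrix(F_mat), ncol(H) == nrow(F_mat))
  structure(
    list(H = H, F = F_mat, k = nrow(F_mat),
         explained_fraction = explained_fraction),
    class = "feature_decomposition"
  )
}

#' Per-cohort landmark-gene signature matrix
#'
#' @param cohort_id cohort label.
#' @param B numeric matrix genes x features of signature weights.
#' @param feature_names feature labels (defaults to colnames of `B`).
#' @param gene_ids gene identifiers (defaults to rownames of `B`).
#' @return object of class `signature_set`.
#' @export
signature_set <- function(cohort_id, B, feature_names = colnames(B),
                          gene_ids = rownames(B)) {
  stopifnot(is.matrix(B))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(B)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(B)))
  if (!all(is.finite(B))) stop("signature weights must be finite")
  dimnames(B) <- list(gene_ids, feature_names)
  structure(
    list(cohort_id = as.character(cohort_id), B = B,
         feature_names = feature_names, gene_ids = gene_ids),
    class = "signature_set"
  )
}

#' Drug-perturbation expression compendium
#'
#' Holds one expression profile per (drug, cell line) pair; coverage may be
#' sparse (a drug need not be present in every line). Profiles are columns of
#' per-cell-line matrices over a common landmark gene set.
#'
#' @param profiles named list, one element per cell line, each a numeric
#'   matrix genes x drugs (colnames = drug ids; a drug absent from a line is
#'   simply not a column).
#' @param gene_ids common gene identifiers (rows of every matrix).
#' @param zscored logical flag: have profiles been gene-wise standardized
#'   within each cell line (see [z_transform()])?
#' @return object of class `perturbation_compendium` with elements `drugs`
#'   (union over lines), `cell_lines`, `gene_ids`, `profiles`, `zscored`.
#' @export
perturbation_compendium <- function(profiles, gene_ids = NULL,
                                    zscored = FALSE) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            !is.null(names(profiles)))
  gene_ids <- gene_ids %||% rownames(profiles[[1L]])
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(nrow(profiles[[1L]])))
  }
  for (s in names(profiles)) {
    m <- profiles[[s]]
    if (!is.matrix(m) || nrow(m) != length(gene_ids)) {
      stop("cell line ", s, ": profile matrix does not match gene set")
    }
    if (is.null(colnames(m))) stop("cell line ", s, ": drugs must be named")
    rownames(profiles[[s]]) <- gene_ids
  }
  drugs <- sort(unique(unlist(lapply(profiles, colnames), use.names = FALSE)))
  structure(
    list(drugs = drugs, cell_lines = names(profiles), gene_ids = gene_ids,
         profiles = profiles, zscored = isTRUE(zscored)),
    class = "perturbation_compendium"
  )
}

# Number of distinct drugs per cell line.
compendium_drug_counts <- function(comp) {
  vapply(comp$profiles, function(m) length(unique(colnames(m))), integer(1L))
}

#' Chemical-protein link table
#'
#' Records (chemical, protein, combined_score) links with integer confidence
#' scores on the 0-1000 scale used by STITCH-style resources. Duplicated
#' (chemical, protein) pairs are collapsed to their maximum score with a
#' warning.
#'
#' @param chemical,protein character vectors of identifiers.
#' @param combined_score integer scores in \[0, 1000\].
#' @return a `target_link_table` (also a `data.frame`) with an attached
#'   protein -> chemicals index (`attr(x, "protein_index")`).
#' @export
target_link_table <- function(chemical, protein, combined_score) {
  combined_score <- as.numeric(combined_score)
  if (any(!is.finite(combined_score)) ||
      any(combined_score < 0 | combined_score > 1000)) {
    bad <- which(!is.finite(combined_score) |
                   combined_score < 0 | combined_score > 1000)
    stop("combined_score outside [0, 1000] at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df <- data.frame(
    chemical = as.character(chemical),
    protein = as.character(protein),
    combined_score = combined_score,
    stringsAsFactors = FALSE
  )
  key <- paste(df$chemical, df$protein, sep = "\r")
  if (anyDuplicated(key)) {
    scores <- tapply(df$combined_score, key, max)
    if (any(tapply(df$combined_score, key, function(s) length(unique(s))) > 1)) {
      warning("duplicate (chemical, protein) pairs with conflicting scores; ",
              "keeping the maximum")
    }
    df <- df[!duplicated(key), , drop = FALSE]
    df$combined_score <- as.numeric(scores[paste(df$chemical, df$protein,
                                                 sep = "\r")])
  }
  rownames(df) <- NULL
  structure(df, class = c("target_link_table", "data.frame"),
            protein_index = split(df$chemical, df$protein))
}

#' Survival outcome table
#'
#' @param patient patient identifiers.
#' @param time nonnegative follow-up durations.
#' @param event 0/1 event indicators (1 = event observed).
#' @param covariates optional data.frame of covariates, one row per patient.
#' @return a `survival_table` (also a `data.frame`).
#' @export
survival_table <- function(patient, time, event, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (any(time < 0)) stop("time must be nonnegative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  df <- data.frame(patient = as.character(patient), time = time,
                   event = event, stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  structure(df, class = c("survival_table", "data.frame"))
}

# Constructors for the two result tables: plain data.frames with a class tag
# so write_tables() knows the column schema.
match_score_table <- function(df) {
  needed <- c("drug", "feature", "direction", "score", "sigma_bar",
              "n_cell_lines")
  stopifnot(all(needed %in% names(df)))
  if (!all(df$direction %in% c("-", "+"))) {
    stop('direction labels must be exactly "-" or "+"')
  }
  if (any(df$score < -1e-12 | df$score > 1 + 1e-12)) {
    stop("match scores must lie in [0, 1]")
  }
  structure(as.data.frame(df), class = c("match_score_table", "data.frame"))
}

enrichment_table <- function(df) {
  needed <- c("target", "feature", "direction", "D", "p", "q",
              "n_plus", "n_minus")
  stopifnot(all(needed %in% names(df)))
  structure(as.data.frame(df), class = c("enrichment_table", "data.frame"))
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf(
    "cohort_data '%s': %d patients, %d disease factors, %d landmark genes\n",
    x$cohort_id, length(x$patients), length(x$factors), length(x$gene_ids)))
  invisible(x)
}

#' @export
print.perturbation_compendium <- function(x, ...) {
  cat(sprintf(
    "perturbation_compendium: %d drugs, %d cell lines, %d genes (%s)\n",
    length(x$drugs), length(x$cell_lines), length(x$gene_ids),
    if (x$zscored) "z-scored" else "raw fold changes"))
  invisible(x)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d genes x %d features\n",
              x$cohort_id, nrow(x$B), ncol(x$B)))
  invisible(x)
}
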