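# Building the drug-profile compendium: replicate pooling, gene-wise
# z-transformation within cell lines, and cell-line coverage filters.

#' Pool replicate perturbation profiles into per-drug fold changes
#'
#' Converts replicate-level (level-3-style) expression into one log2
#' fold-change profile per (drug, cell line). Each plate's mean vehicle
#' (e.g. DMSO) profile is subtracted from that plate's treated profiles;
#' replicates of a drug across doses and time points are then combined by a
#' precision-weighted mean, where replicate `j`'s weight is the inverse of
#' its mean squared deviation from the replicate mean across genes. With
#' fewer than 3 replicates the unweighted mean is used.
#'
#' @param expr numeric matrix genes x profiles (log2 scale); colnames are
#'   profile ids.
#' @param meta data.frame with columns `profile_id`, `drug`, `cell_line`,
#'   `plate`, `is_vehicle` (0/1 or logical); `dose` and `time` are carried
#'   but not required.
#' @return a [perturbation_compendium] (`zscored = FALSE`) with an attached
#'   `replicate_counts` data.frame.
#' @export
pool_replicates <- function(expr, meta) {
  stopifnot(is.matrix(expr), is.data.frame(meta))
  needed <- c("profile_id", "drug", "cell_line", "plate", "is_vehicle")
  if (!all(needed %in% names(meta))) {
    stop("metadata must have columns: ", paste(needed, collapse = ", "))
  }
  meta$is_vehicle <- as.logical(meta$is_vehicle)
  if (!all(meta$profile_id %in% colnames(expr))) {
    stop("metadata profile_id(s) absent from expression matrix")
  }
  # plate-wise vehicle centring
  fc <- expr[, meta$profile_id, drop = FALSE]
  for (pl in unique(meta$plate)) {
    on_plate <- meta$plate == pl
    veh <- on_plate & meta$is_vehicle
    if (!any(veh)) stop("plate without vehicle control: ", pl)
    veh_mean <- rowMeans(fc[, meta$profile_id[veh], drop = FALSE])
    fc[, meta$profile_id[on_plate]] <-
      fc[, meta$profile_id[on_plate], drop = FALSE] - veh_mean
  }
  treated <- meta[!meta$is_vehicle, , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated profiles to pool")
  counts <- list()
  profiles <- list()
  for (cl in unique(treated$cell_line)) {
    sub <- treated[treated$cell_line == cl, , drop = FALSE]
    drugs <- unique(sub$drug)
    pooled <- matrix(NA_real_, nrow(fc), length(drugs),
                     dimnames = list(rownames(expr), drugs))
    for (d in drugs) {
      reps <- fc[, sub$profile_id[sub$drug == d], drop = FALSE]
      pooled[, d] <- pool_profile(reps)
      counts[[length(counts) + 1L]] <-
        data.frame(drug = d, cell_line = cl, n_replicates = ncol(reps),
                   stringsAsFactors = FALSE)
    }
    profiles[[cl]] <- pooled
  }
  comp <- perturbation_compendium(profiles, gene_ids = rownames(expr),
                                  zscored = FALSE)
  attr(comp, "replicate_counts") <- do.call(rbind, counts)
  comp
}

# Precision-weighted mean of replicate columns; unweighted below 3 columns.
pool_profile <- function(reps) {
  m <- ncol(reps)
  if (m == 1L) return(reps[, 1L])
  ctr <- rowMeans(reps)
  if (m < 3L) return(ctr)
  v <- colMeans((reps - ctr)^2)
  if (any(v == 0)) return(ctr)  # an exact-duplicate replicate: plain mean
  w <- 1 / v
  as.numeric(reps %*% w) / sum(w)
}

#' Gene-wise z-transformation of a compendium
#'
#' Standardizes each gene to mean 0 and (population, ddof = 0) standard
#' deviation 1 across the drugs of each cell line, so a profile entry is the
#' drug's displacement of that gene relative to all drugs in the line. Genes
#' constant within a line are set to 0 with a warning.
#'
#' @param comp a [perturbation_compendium] of pooled fold changes.
#' @return the compendium with `zscored = TRUE`.
#' @export
z_transform <- function(comp) {
  stopifnot(inherits(comp, "perturbation_compendium"))
  profiles <- comp$profiles
  for (cl in names(profiles)) {
    m <- profiles[[cl]]
    if (ncol(m) < 3L) {
      stop("cell line ", cl, " has fewer than 3 drugs; cannot standardize")
    }
    mu <- rowMeans(m)
    sd_pop <- sqrt(rowMeans((m - mu)^2))
    flat <- sd_pop == 0
    if (any(flat)) {
      warning(sum(flat), " constant gene(s) in cell line ", cl,
              " set to 0 after z-transform")
      sd_pop[flat] <- 1
    }
    m <- (m - mu) / sd_pop
    m[flat, ] <- 0
    profiles[[cl]] <- m
  }
  out <- perturbation_compendium(profiles, gene_ids = comp$gene_ids,
                                 zscored = TRUE)
  attr(out, "replicate_counts") <- attr(comp, "replicate_counts")
  out
}

#' Drop cell lines with insufficient drug coverage
#'
#' Retains only cell lines carrying at least `min_drugs` unique drugs, the
#' coverage filter used to select deeply profiled lines from a large
#' perturbation compendium.
#'
#' @param comp a [perturbation_compendium].
#' @param min_drugs minimum unique drugs per retained line (default 1000).
#' @return the filtered compendium; removals are reported via `message()`.
#' @export
filter_cell_lines <- function(comp, min_drugs = 1000L) {
  stopifnot(inherits(comp, "perturbation_compendium"))
  counts <- compendium_drug_counts(comp)
  keep <- counts >= min_drugs
  if (!any(keep)) {
    stop("all cell lines fall below min_drugs = ", min_drugs)
  }
  if (any(!keep)) {
    message("filter_cell_lines: removing ", sum(!keep), " cell line(s): ",
            paste(sprintf("%s (%d drugs)", names(counts)[!keep],
                          counts[!keep]), collapse = ", "))
  }
  out <- perturbation_compendium(comp$profiles[keep],
                                 gene_ids = comp$gene_ids,
                                 zscored = comp$zscored)
  attr(out, "replicate_counts") <- attr(comp, "replicate_counts")
  out
}
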