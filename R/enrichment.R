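# Target deconvolution: R+/R- splits from chemical-protein links, one-tailed
# two-sample Kolmogorov-Smirnov tests on match scores, FDR control, and a
# minimum-spanning-tree summary of the significant targets.

#' Split compendium drugs by linkage to a protein target
#'
#' `R+` contains the drugs linked to the target with a confidence score
#' strictly above `score_threshold`; `R-` contains every other compendium
#' drug (including drugs with sub-threshold links to the target).
#'
#' @param target protein identifier.
#' @param links a [target_link_table].
#' @param drugs character vector of compendium drug identifiers.
#' @param score_threshold link score cut (strict `>`; default 900).
#' @return list with character vectors `plus` and `minus`.
#' @export
split_by_target <- function(target, links, drugs, score_threshold = 900) {
  idx <- attr(links, "protein_index")
  if (!target %in% names(idx)) {
    stop("target absent from link table: ", target)
  }
  sub <- links[links$protein == target &
                 links$combined_score > score_threshold, , drop = FALSE]
  plus <- intersect(drugs, sub$chemical)
  list(plus = plus, minus = setdiff(drugs, plus))
}

#' One-tailed two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the `plus` sample is stochastically shifted toward HIGHER
#' values than the `minus` sample. The statistic is the one-sided supremum
#' `D = sup_x [ecdf_minus(x) - ecdf_plus(x)]`. The p-value is computed by
#' exhaustive permutation enumeration when the combined sample size is at
#' most `exact_limit` (exact, and valid under ties), and otherwise by the
#' one-sided asymptotic bound `exp(-2 D^2 m n / (m + n))`.
#'
#' @param plus,minus numeric score samples (non-empty).
#' @param exact_limit maximum combined size for exact enumeration
#'   (default 16).
#' @return list with `D`, `p`, `n_plus`, `n_minus`, `method`.
#' @export
ks_one_sided <- function(plus, minus, exact_limit = 16L) {
  if (length(plus) == 0L || length(minus) == 0L) {
    stop("both samples must be non-empty")
  }
  m <- length(plus); n <- length(minus)
  D <- ks_one_sided_stat(plus, minus)
  if (m + n <= exact_limit) {
    pooled <- c(plus, minus)
    sel <- utils::combn(m + n, m)
    tol <- 1e-12
    count <- 0L
    for (j in seq_len(ncol(sel))) {
      idx <- sel[, j]
      d_star <- ks_one_sided_stat(pooled[idx], pooled[-idx])
      if (d_star >= D - tol) count <- count + 1L
    }
    p <- count / ncol(sel)
    method <- "exact"
  } else {
    p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
    method <- "asymptotic"
  }
  list(D = D, p = p, n_plus = m, n_minus = n, method = method)
}

# One-sided KS statistic sup_x [F_minus(x) - F_plus(x)] evaluated on the
# pooled support (ties handled by counting at each unique value).
ks_one_sided_stat <- function(plus, minus) {
  xs <- sort(unique(c(plus, minus)))
  f_plus <- vapply(xs, function(x) mean(plus <= x), numeric(1L))
  f_minus <- vapply(xs, function(x) mean(minus <= x), numeric(1L))
  max(0, f_minus - f_plus)
}

#' Storey-style q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution on a
#' lambda grid with spline smoothing (the behaviour of `mafdr`-style FDR
#' estimation), then scales Benjamini-Hochberg adjusted values by pi0.
#'
#' @param p numeric p-values.
#' @param lambda grid of tuning values in (0, 1).
#' @return q-values in \[0, 1\].
#' @export
qvalue_storey <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m < 2L) return(pmin(p, 1))
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
  pi0 <- if (length(lambda) >= 4L) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    min(pi0_l)
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
}

#' Deconvolve enriched targets from match scores
#'
#' For every protein target with at least `min_group_size` linked compendium
#' drugs, tests whether the target's drugs have higher match scores than the
#' rest with a one-tailed two-sample KS test, separately within each
#' (feature, direction) family, and controls the FDR within each family
#' (Benjamini-Hochberg by default; Storey's pi0-scaled variant via
#' `fdr = "storey"`; `pool_families = TRUE` corrects across all families
#' jointly).
#'
#' @param scores a `match_score_table` from [score_all()].
#' @param links a [target_link_table].
#' @param alpha_q significance threshold on q (default 1e-4).
#' @param score_threshold link-score cut for the R+ split (default 900).
#' @param min_group_size minimum `|R+|` for a testable target (default 4).
#' @param fdr `"bh"` or `"storey"`.
#' @param pool_families correct across families jointly instead of within
#'   each (feature, direction) family.
#' @param exact_limit passed to [ks_one_sided()].
#' @return an `enrichment_table` data.frame sorted by `q` then `D`
#'   (descending), with a `significant` flag at `alpha_q`. Skipped targets
#'   are reported via `message()`.
#' @export
enrich_all <- function(scores, links, alpha_q = 1e-4, score_threshold = 900,
                       min_group_size = 4L, fdr = c("bh", "storey"),
                       pool_families = FALSE, exact_limit = 16L) {
  fdr <- match.arg(fdr)
  stopifnot(inherits(links, "target_link_table"))
  drugs <- unique(scores$drug)
  targets <- names(attr(links, "protein_index"))
  splits <- lapply(targets, function(tg) {
    split_by_target(tg, links, drugs, score_threshold)
  })
  names(splits) <- targets
  eligible <- vapply(splits, function(sp) {
    length(sp$plus) >= min_group_size && length(sp$minus) >= 1L
  }, logical(1L))
  if (any(!eligible)) {
    message("enrich_all: skipping ", sum(!eligible), " target(s) with ",
            "fewer than ", min_group_size, " linked compendium drugs")
  }
  splits <- splits[eligible]
  if (length(splits) == 0L) {
    warning("no eligible targets")
    return(enrichment_table(data.frame(
      target = character(0), feature = character(0), direction = character(0),
      D = numeric(0), p = numeric(0), q = numeric(0),
      n_plus = integer(0), n_minus = integer(0), significant = logical(0),
      stringsAsFactors = FALSE)))
  }
  fams <- unique(scores[, c("feature", "direction")])
  rows <- list()
  for (i in seq_len(nrow(fams))) {
    fam <- scores[scores$feature == fams$feature[i] &
                    scores$direction == fams$direction[i], , drop = FALSE]
    s_vec <- stats::setNames(fam$score, fam$drug)
    res <- lapply(names(splits), function(tg) {
      sp <- splits[[tg]]
      plus <- s_vec[intersect(sp$plus, names(s_vec))]
      minus <- s_vec[intersect(sp$minus, names(s_vec))]
      if (length(plus) < min_group_size || length(minus) == 0L) return(NULL)
      ks <- ks_one_sided(plus, minus, exact_limit = exact_limit)
      data.frame(target = tg, feature = fams$feature[i],
                 direction = fams$direction[i], D = ks$D, p = ks$p,
                 n_plus = ks$n_plus, n_minus = ks$n_minus,
                 stringsAsFactors = FALSE)
    })
    fam_df <- do.call(rbind, res)
    if (is.null(fam_df)) next
    if (!pool_families) {
      fam_df$q <- if (fdr == "bh") stats::p.adjust(fam_df$p, method = "BH")
                  else qvalue_storey(fam_df$p)
    }
    rows[[length(rows) + 1L]] <- fam_df
  }
  out <- do.call(rbind, rows)
  if (pool_families) {
    out$q <- if (fdr == "bh") stats::p.adjust(out$p, method = "BH")
             else qvalue_storey(out$p)
  }
  out$significant <- out$q < alpha_q
  out <- out[order(out$q, -out$D), c("target", "feature", "direction",
                                     "D", "p", "q", "n_plus", "n_minus",
                                     "significant")]
  rownames(out) <- NULL
  enrichment_table(out)
}

#' Minimum spanning forest of significant targets over protein links
#'
#' Induces the protein-protein link graph on the given targets, weights each
#' link by `1000 - combined_score` (stronger links are shorter), and returns
#' a minimum spanning forest (one tree per connected component) by Kruskal's
#' algorithm with deterministic lexicographic tie-breaking on edge names.
#' The forest keeps the strongest non-redundant backbone for visualization.
#'
#' @param targets character vector of significant target ids (>= 2).
#' @param protein_links data.frame with `protein_a`, `protein_b`,
#'   `combined_score` (see [read_protein_links()]).
#' @return list with `edges` (data.frame protein_a, protein_b,
#'   combined_score, distance), `nodes`, `n_components`.
#' @export
mst_of_targets <- function(targets, protein_links) {
  targets <- unique(targets)
  if (length(targets) < 2L) stop("need at least 2 significant targets")
  pl <- protein_links
  keep <- pl$protein_a %in% targets & pl$protein_b %in% targets &
    pl$protein_a != pl$protein_b
  pl <- pl[keep, , drop = FALSE]
  if (nrow(pl) > 0L) {
    a <- pmin(pl$protein_a, pl$protein_b)
    b <- pmax(pl$protein_a, pl$protein_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(pl$combined_score, key, max)[key]
    pl <- data.frame(protein_a = a, protein_b = b,
                     combined_score = as.numeric(score),
                     stringsAsFactors = FALSE)
    pl <- pl[!duplicated(key), , drop = FALSE]
    pl$distance <- 1000 - pl$combined_score
    pl <- pl[order(pl$distance, pl$protein_a, pl$protein_b), , drop = FALSE]
  }
  # Kruskal with union-find; edge order above fixes all tie-breaks
  chosen <- logical(if (nrow(pl) > 0L) nrow(pl) else 0L)
  if (nrow(pl) > 0L) {
    idx_of <- stats::setNames(seq_along(targets), targets)
    parent <- seq_along(targets)
    root <- function(i) {
      while (parent[[i]] != i) i <- parent[[i]]
      i
    }
    for (e in seq_len(nrow(pl))) {
      ra <- root(idx_of[[pl$protein_a[e]]])
      rb <- root(idx_of[[pl$protein_b[e]]])
      if (ra != rb) {
        parent[[max(ra, rb)]] <- min(ra, rb)
        chosen[e] <- TRUE
      }
    }
  }
  edges <- if (nrow(pl) > 0L) pl[chosen, , drop = FALSE] else
    data.frame(protein_a = character(0), protein_b = character(0),
               combined_score = numeric(0), distance = numeric(0))
  rownames(edges) <- NULL
  n_components <- length(targets) - nrow(edges)
  if (nrow(edges) == 0L) {
    warning("no protein links among the given targets; edgeless forest")
  }
  list(edges = edges, nodes = targets, n_components = n_components)
}

# ROC curve by threshold sweep; AUC by trapezoid rule.
roc_curve <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  if (length(unique(label)) < 2L) {
    stop("observed labels contain a single class")
  }
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]; sc <- score[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)  # group tied scores
  tpr <- c(0, tp[last] / sum(lab))
  fpr <- c(0, fp[last] / sum(!lab))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' ROC evaluation of predicted signature modulation
#'
#' Assesses whether the match scores predict the observed direction of
#' signature change after drug treatment. For the suppression call, the
#' positive class is an observed decrease of the signature and the score is
#' the drug's `"-"` match score; for the enhancement call, an observed
#' increase against the `"+"` score. Curves are built by sweeping the score
#' threshold; AUC uses the trapezoid rule.
#'
#' @param predicted a `match_score_table` (both directions present) or a
#'   data.frame with columns `drug`, `feature`, `direction`, `score`.
#' @param observed data.frame with columns `drug`, `feature`,
#'   `observed_change`: the measured signature change (e.g. correlation of
#'   the post-treatment fold-change profile with the signature); negative =
#'   signature decreased.
#' @return list with `suppress` and `enhance` ROC curves (`fpr`, `tpr`,
#'   `auc`) and `mean_auc`.
#' @export
roc_predictions <- function(predicted, observed) {
  needed <- c("drug", "feature", "observed_change")
  stopifnot(all(needed %in% names(observed)))
  out <- list()
  for (d in c("-", "+")) {
    pr <- predicted[predicted$direction == d, c("drug", "feature", "score")]
    mg <- merge(pr, observed, by = c("drug", "feature"))
    if (nrow(mg) == 0L) stop("no matched keys between predicted and observed")
    lab <- if (d == "-") mg$observed_change < 0 else mg$observed_change > 0
    out[[if (d == "-") "suppress" else "enhance"]] <-
      roc_curve(mg$score, lab)
  }
  out$mean_auc <- mean(c(out$suppress$auc, out$enhance$auc))
  out
}
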