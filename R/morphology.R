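# Protrusion-based morphological differentiation scoring: the count of
# protrusions longer than d decays approximately exponentially in d, so an
# exponential fit A * exp(-k * d) summarizes each image. Two derived scores:
# Y_np = A / N_bp (protrusion density per interface length) and
# Y_md = -1000 * k (higher = relatively more long protrusions).

#' Fit the exponential protrusion-length decay of one image
#'
#' Builds the survival-count curve `n(d) = #{lengths > d}` on a fixed grid
#' of 50 equal-width thresholds from 0 to the 99th percentile length (or
#' uses a supplied counts-vs-threshold table), and fits
#' `log n(d) = log A - k d` by least squares over thresholds with
#' `n(d) >= 3`. The fit is linear in the log counts, hence deterministic and
#' initialization-free; `refine = TRUE` adds a nonlinear least-squares
#' refinement on the raw counts started from the log-linear solution.
#'
#' @param lengths numeric protrusion lengths (>= 10 required), or `NULL`
#'   when `counts` is given.
#' @param counts optional data.frame with columns `d` (threshold) and `n`
#'   (count of protrusions longer than `d`).
#' @param N_bp total cell-background interface length (> 0).
#' @param n_grid number of thresholds when building the curve from lengths
#'   (default 50).
#' @param refine nonlinear refinement flag (default `FALSE`).
#' @param unit pass-through length unit label recorded in the result.
#' @return object of class `protrusion_fit`: `A`, `k`, `N_bp`,
#'   `Y_np = A / N_bp`, `Y_md = -1000 * k`, `residual` (root mean squared
#'   log-count residual), `n_points`, `unit`.
#' @export
fit_protrusion_decay <- function(lengths = NULL, counts = NULL, N_bp,
                                 n_grid = 50L, refine = FALSE,
                                 unit = "pixel") {
  if (N_bp <= 0) stop("N_bp must be positive")
  if (is.null(counts)) {
    if (length(lengths) < 10L) stop("need at least 10 protrusions")
    grid <- seq(0, stats::quantile(lengths, 0.99, names = FALSE),
                length.out = n_grid)
    n_d <- vapply(grid, function(d) sum(lengths > d), numeric(1L))
    counts <- data.frame(d = grid, n = n_d)
  } else {
    stopifnot(all(c("d", "n") %in% names(counts)))
  }
  use <- counts$n >= 3
  if (sum(use) < 2L) stop("too few thresholds with count >= 3 to fit")
  d <- counts$d[use]; n <- counts$n[use]
  fit <- stats::lm(log(n) ~ d)
  k <- -unname(stats::coef(fit)[2L])
  A <- exp(unname(stats::coef(fit)[1L]))
  if (!is.finite(k) || k <= 0) {
    stop("protrusion counts do not decay; cannot fit an exponential")
  }
  if (refine) {
    nls_fit <- try(stats::nls(n ~ A0 * exp(-k0 * d),
                              start = list(A0 = A, k0 = k)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      A <- unname(stats::coef(nls_fit)[["A0"]])
      k <- unname(stats::coef(nls_fit)[["k0"]])
    }
  }
  structure(
    list(A = A, k = k, N_bp = N_bp, Y_np = A / N_bp, Y_md = -1000 * k,
         residual = sqrt(mean(stats::residuals(fit)^2)),
         n_points = sum(use), unit = unit),
    class = "protrusion_fit"
  )
}

#' @export
print.protrusion_fit <- function(x, ...) {
  cat(sprintf(
    "protrusion_fit: A = %.4g, k = %.4g per %s, Y_np = %.4g, Y_md = %.4g\n",
    x$A, x$k, x$unit, x$Y_np, x$Y_md))
  invisible(x)
}

#' Fit protrusion decay for every image of a measurement table
#'
#' @param lengths data.frame with `image_id`, `protrusion_length`.
#' @param images data.frame with `image_id`, `N_bp`.
#' @param ... passed to [fit_protrusion_decay()].
#' @return data.frame with one row per image: `image_id`, `A`, `k`, `Y_np`,
#'   `Y_md`, `n_protrusions`.
#' @export
fit_protrusions_by_image <- function(lengths, images, ...) {
  stopifnot(all(c("image_id", "protrusion_length") %in% names(lengths)),
            all(c("image_id", "N_bp") %in% names(images)))
  nbp <- stats::setNames(images$N_bp, images$image_id)
  rows <- lapply(unique(lengths$image_id), function(id) {
    lv <- lengths$protrusion_length[lengths$image_id == id]
    f <- fit_protrusion_decay(lv, N_bp = nbp[[id]], ...)
    data.frame(image_id = id, A = f$A, k = f$k, Y_np = f$Y_np,
               Y_md = f$Y_md, n_protrusions = length(lv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence intervals for morphology scores
#'
#' Percentile bootstrap over images: within each group, images are resampled
#' with replacement and the group mean of `Y_md` (and `Y_np`) recomputed,
#' giving per-group confidence intervals and intervals for all pairwise
#' group differences.
#'
#' @param fits per-image fit table (as from [fit_protrusions_by_image()])
#'   with numeric columns `Y_md` and `Y_np`.
#' @param groups group label per row of `fits` (>= 3 images per group).
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with data.frames `groups` (group, mean, lower, upper per
#'   score) and `contrasts` (group_a, group_b, difference of means with CI).
#' @export
bootstrap_morphology <- function(fits, groups, n_boot = 1000L, seed = 1L,
                                 level = 0.95) {
  stopifnot(is.data.frame(fits), nrow(fits) == length(groups))
  if (n_boot < 100L) warning("n_boot < 100 gives unstable intervals")
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 3L)) {
    stop("need at least 3 images per group; offending group(s): ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  }
  gl <- sort(unique(groups))
  alpha <- (1 - level) / 2
  with_seed(seed, {
    boots <- lapply(gl, function(g) {
      idx <- which(groups == g)
      md <- np <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        take <- sample(idx, length(idx), replace = TRUE)
        md[b] <- mean(fits$Y_md[take])
        np[b] <- mean(fits$Y_np[take])
      }
      list(md = md, np = np)
    })
    names(boots) <- gl
    grp <- do.call(rbind, lapply(gl, function(g) {
      data.frame(
        group = g,
        mean_Y_md = mean(fits$Y_md[groups == g]),
        Y_md_lower = stats::quantile(boots[[g]]$md, alpha, names = FALSE),
        Y_md_upper = stats::quantile(boots[[g]]$md, 1 - alpha, names = FALSE),
        mean_Y_np = mean(fits$Y_np[groups == g]),
        Y_np_lower = stats::quantile(boots[[g]]$np, alpha, names = FALSE),
        Y_np_upper = stats::quantile(boots[[g]]$np, 1 - alpha, names = FALSE),
        stringsAsFactors = FALSE)
    }))
    ctr <- NULL
    if (length(gl) >= 2L) {
      cmb <- utils::combn(gl, 2L)
      ctr <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
        a <- cmb[1L, j]; b <- cmb[2L, j]
        diff_md <- boots[[a]]$md - boots[[b]]$md
        data.frame(
          group_a = a, group_b = b,
          diff_Y_md = mean(fits$Y_md[groups == a]) -
            mean(fits$Y_md[groups == b]),
          lower = stats::quantile(diff_md, alpha, names = FALSE),
          upper = stats::quantile(diff_md, 1 - alpha, names = FALSE),
          stringsAsFactors = FALSE)
      }))
    }
    list(groups = grp, contrasts = ctr)
  })
}
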