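#' Read an expression matrix from TSV or GCT
#'
#' TSV input is a dense genes x samples matrix with a header row of sample
#' identifiers and gene identifiers in the first column. GCT 1.2 and dense
#' GCT 1.3 are detected from the `#1.2` / `#1.3` version line.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2") || startsWith(first, "#1.3")) {
    read_gct(path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- trimws(as.character(df[[1L]]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    colnames(m) <- trimws(colnames(m))
    m
  }
}

#' Read a GCT 1.2 / 1.3 file (dense)
#'
#' @param path file path.
#' @return numeric matrix (genes x samples); row/column metadata beyond the
#'   identifier columns is dropped.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file: ", path)
  version <- trimws(lines[[1L]])
  dims <- as.integer(strsplit(trimws(lines[[2L]]), "\t")[[1L]])
  if (version == "#1.2") {
    n_rmeta <- 1L; n_cmeta <- 0L
  } else if (version == "#1.3") {
    if (length(dims) < 4L) stop("GCT 1.3 requires 4 dimension fields")
    n_rmeta <- dims[[3L]] + 1L
    n_cmeta <- dims[[4L]]
  } else {
    stop("unsupported GCT version line: ", version)
  }
  nr <- dims[[1L]]; nc <- dims[[2L]]
  header <- strsplit(lines[[3L]], "\t")[[1L]]
  sample_ids <- trimws(utils::tail(header, nc))
  body <- lines[(3L + n_cmeta + 1L):(3L + n_cmeta + nr)]
  fields <- strsplit(body, "\t")
  ids <- trimws(vapply(fields, `[[`, character(1L), 1L))
  vals <- t(vapply(fields, function(f) {
    as.numeric(utils::tail(f, nc))
  }, numeric(nc)))
  if (nc == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, sample_ids)
  vals
}

#' Write a matrix as GCT 1.2
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param description optional per-row description column (defaults to the
#'   row names).
#' @return `path`, invisibly.
#' @export
write_gct <- function(mat, path, description = rownames(mat)) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("#1.2")
  wl(paste(nrow(mat), ncol(mat), sep = "\t"))
  wl(paste(c("Name", "Description", colnames(mat)), collapse = "\t"))
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], description[i],
            format(mat[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  wl(rows)
  invisible(path)
}

#' Read one cohort's disease factors and landmark expression
#'
#' Loads a disease-factor table and an expression matrix, restricts both to
#' their shared samples and the expression matrix to a landmark gene set, and
#' returns a row-centred [cohort_data] object. The factor table may be
#' oriented either way (factors x samples or samples x factors); the
#' orientation is resolved by matching identifiers against the expression
#' sample ids.
#'
#' @param factor_table_path TSV of disease factors.
#' @param expression_path TSV or GCT expression matrix (genes x samples),
#'   log-scale.
#' @param landmark_list character vector of landmark gene identifiers.
#' @param cohort_id cohort label (defaults to the expression file name).
#' @param allow_missing_genes if `TRUE`, landmark genes absent from the
#'   expression matrix are dropped with a message instead of an error.
#' @return a [cohort_data] object.
#' @export
read_cohort <- function(factor_table_path, expression_path, landmark_list,
                        cohort_id = NULL,
                        allow_missing_genes = FALSE) {
  cohort_id <- cohort_id %||%
    sub("\\.[^.]+$", "", basename(expression_path))
  Z <- read_expression_matrix(expression_path)
  landmark_list <- trimws(as.character(landmark_list))
  missing_genes <- setdiff(landmark_list, rownames(Z))
  if (length(missing_genes) > 0L) {
    if (!allow_missing_genes) {
      stop("landmark genes absent from expression: ",
           paste(utils::head(missing_genes, 10L), collapse = ", "),
           if (length(missing_genes) > 10L) ", ...")
    }
    message("read_cohort: dropping ", length(missing_genes),
            " landmark gene(s) absent from expression")
    landmark_list <- setdiff(landmark_list, missing_genes)
  }
  Z <- Z[landmark_list, , drop = FALSE]

  fdf <- utils::read.delim(factor_table_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rn <- trimws(as.character(fdf[[1L]]))
  fm <- as.matrix(fdf[, -1L, drop = FALSE])
  storage.mode(fm) <- "double"
  rownames(fm) <- rn
  colnames(fm) <- trimws(colnames(fm))
  samples <- colnames(Z)
  if (length(intersect(colnames(fm), samples)) == 0L &&
      length(intersect(rownames(fm), samples)) > 0L) {
    fm <- t(fm)  # table was samples x factors
  }
  shared <- intersect(colnames(fm), samples)
  if (length(shared) == 0L) {
    stop("no overlap between factor-table and expression sample ids")
  }
  dropped <- length(samples) - length(shared)
  if (dropped > 0L) {
    message("read_cohort: dropping ", dropped,
            " expression sample(s) without factor data")
  }
  cohort_data(cohort_id, Y = fm[, shared, drop = FALSE],
              Z = Z[, shared, drop = FALSE])
}

#' Read a chemical-protein link table
#'
#' Expects a TSV in the `protein_chemical.links` dialect: columns `chemical`,
#' `protein`, `combined_score` (extra columns ignored, header required).
#' All records are kept -- thresholding into linked/unlinked groups happens
#' at [split_by_target()] time -- but scores are validated to \[0, 1000\]
#' and duplicated pairs are collapsed to their maximum score.
#'
#' @param path TSV path.
#' @return a [target_link_table].
#' @export
read_target_links <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("chemical", "protein", "combined_score")
  if (!all(needed %in% names(df))) {
    stop("link table must have columns: ", paste(needed, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(!is.finite(score) | score < 0 | score > 1000)
  if (length(bad) > 0L) {
    stop("combined_score outside [0, 1000] at line(s): ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  target_link_table(trimws(df$chemical), trimws(df$protein), score)
}

#' Read a protein-protein link table
#'
#' STRING-style TSV with columns `protein_a`, `protein_b`, `combined_score`
#' (0-1000), used for the minimum-spanning-tree summary of significant
#' targets.
#'
#' @param path TSV path.
#' @return data.frame with validated scores.
#' @export
read_protein_links <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("protein_a", "protein_b", "combined_score")
  if (!all(needed %in% names(df))) {
    stop("protein link table must have columns: ",
         paste(needed, collapse = ", "))
  }
  score <- as.numeric(df$combined_score)
  if (any(!is.finite(score) | score < 0 | score > 1000)) {
    stop("combined_score outside [0, 1000]")
  }
  data.frame(protein_a = trimws(df$protein_a),
             protein_b = trimws(df$protein_b),
             combined_score = score, stringsAsFactors = FALSE)
}

#' Read a survival table
#'
#' TSV with columns `patient`, `time`, `event`; any further columns are kept
#' as covariates.
#'
#' @param path TSV path.
#' @return a [survival_table].
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("patient", "time", "event")
  if (!all(needed %in% names(df))) {
    stop("survival table must have columns: ", paste(needed, collapse = ", "))
  }
  extra <- setdiff(names(df), needed)
  survival_table(df$patient, df$time, df$event,
                 covariates = if (length(extra)) df[extra] else NULL)
}

# Fixed column schemas for the typed result tables.
table_schema <- function(x) {
  if (inherits(x, "enrichment_table")) {
    c("target", "feature", "direction", "D", "p", "q", "n_plus", "n_minus",
      intersect("significant", names(x)))
  } else if (inherits(x, "match_score_table")) {
    c("drug", "feature", "direction", "score", "sigma_bar", "n_cell_lines",
      setdiff(names(x), c("drug", "feature", "direction", "score",
                          "sigma_bar", "n_cell_lines")))
  } else if (inherits(x, "target_link_table")) {
    c("chemical", "protein", "combined_score")
  } else if (inherits(x, "survival_table")) {
    names(x)
  } else if (is.data.frame(x)) {
    names(x)
  } else {
    stop("unsupported object of class ", paste(class(x), collapse = "/"))
  }
}

#' Write typed result tables as TSV
#'
#' Writes each object in a named list to `<out_dir>/<name>.tsv` with a fixed,
#' class-specific column order, floating-point values at 6 significant
#' digits, UTF-8 encoding and LF line endings. Matrices with dimnames are
#' written with an `id` first column; empty tables yield a header-only file.
#'
#' @param objects named list of data frames / typed tables / matrices.
#' @param out_dir output directory, created if needed.
#' @return character vector of file paths written, invisibly.
#' @export
write_tables <- function(objects, out_dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  paths <- character(0L)
  for (nm in names(objects)) {
    x <- objects[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x) %||% seq_len(nrow(x)),
                      as.data.frame(x), check.names = FALSE)
    }
    cols <- table_schema(x)
    df <- as.data.frame(x)[, cols, drop = FALSE]
    df[] <- lapply(df, format_num6)
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, open = "wb", encoding = "UTF-8")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
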