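# End-to-end orchestration: signatures -> consistency -> compendium ->
# calibration -> match scores -> target enrichment -> MST, with a manifest
# making every run reproducible bit-for-bit.

default_config <- function() {
  list(
    seed = 1L,
    mode = "synthetic",
    synthetic = list(
      n_cohorts = 3L, n_patients = 200L, p_disease = 16L, p_genes = 978L,
      k = 2L, signal_scale = 1, noise_sd = 1,
      n_drugs = 300L, n_cell_lines = 3L, n_targets = 20L,
      drugs_per_target = 10L, effect_size = 5, coverage = 1
    ),
    inputs = NULL,
    signatures = list(k = NULL, consistency_threshold = 0.4),
    compendium = list(min_drugs = 0L),
    scoring = list(directions = c("-", "+"), n_perm = 100L,
                   cell_line_weights = NULL),
    enrichment = list(q_threshold = 1e-4, stitch_threshold = 900,
                      min_drugs_per_target = 4L, fdr = "bh")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML key/value configuration file (or accepts a list) and fills
#' unset fields with package defaults.
#'
#' @param config path to a YAML file, or a named list.
#' @return complete configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  merge_config(default_config(), config)
}

#' Validate pipeline inputs before computing
#'
#' Checks type invariants, gene-set overlaps and cardinalities; in report
#' mode issues are collected, not thrown.
#'
#' @param cohorts list of [cohort_data].
#' @param compendium a [perturbation_compendium] (optional).
#' @param links a [target_link_table] (optional).
#' @param report if `TRUE` (default) return the issue list instead of
#'   erroring.
#' @return list with character vectors `errors` and `warnings`; empty
#'   vectors mean a valid bundle.
#' @export
validate_inputs <- function(cohorts, compendium = NULL, links = NULL,
                            report = TRUE) {
  errors <- character(0L)
  warns <- character(0L)
  note <- function(kind, msg) {
    if (kind == "error") errors <<- c(errors, msg) else warns <<- c(warns, msg)
  }
  genes <- NULL
  for (co in cohorts) {
    ok <- tryCatch({ validate_cohort_data(co); TRUE },
                   error = function(e) { note("error", paste0(
                     "cohort ", co$cohort_id, ": ", conditionMessage(e)));
                     FALSE })
    if (ok) {
      if (is.null(genes)) genes <- co$gene_ids
      else if (!identical(genes, co$gene_ids)) {
        note("error", paste0("cohort ", co$cohort_id,
                             ": gene set differs from first cohort"))
      }
    }
  }
  if (!is.null(compendium)) {
    counts <- compendium_drug_counts(compendium)
    if (any(counts < 3L)) {
      note("error", paste0("cell line(s) with < 3 drugs: ",
                           paste(names(counts)[counts < 3L], collapse = ", ")))
    }
    if (!is.null(genes)) {
      ov <- length(intersect(genes, compendium$gene_ids)) /
        length(union(genes, compendium$gene_ids))
      if (ov < 0.5) {
        note("warning", sprintf(
          "cohort/compendium gene overlap below 50%% (%d shared of %d)",
          length(intersect(genes, compendium$gene_ids)),
          length(union(genes, compendium$gene_ids))))
      }
    }
  }
  if (!is.null(links)) {
    if (any(links$combined_score < 0 | links$combined_score > 1000)) {
      note("error", "link scores outside [0, 1000]")
    }
    if (!is.null(compendium) &&
        length(intersect(links$chemical, compendium$drugs)) == 0L) {
      note("error", "no link-table chemical matches any compendium drug")
    }
  }
  res <- list(errors = errors, warnings = warns)
  if (!report && length(errors) > 0L) {
    stop("input validation failed:\n  ", paste(errors, collapse = "\n  "))
  }
  res
}

# Run one pipeline stage, prefixing any failure with the stage name and
# recording emitted messages in the shared log.
run_stage <- function(name, log_env, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    }),
    message = function(m) {
      log_env$lines <- c(log_env$lines,
                         paste0("[", name, "] ", trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    },
    warning = function(w) {
      log_env$lines <- c(log_env$lines,
                         paste0("[", name, "] WARNING: ",
                                trimws(conditionMessage(w))))
      invokeRestart("muffleWarning")
    }
  )
}

#' Run the full pipeline
#'
#' Orchestrates signature estimation, cross-cohort consistency filtering,
#' compendium preparation, similarity calibration, match scoring (both
#' directions), permutation control, target enrichment and the MST summary,
#' writing all artifacts plus a manifest to `out_dir`. Re-running with the
#' same configuration (see [rerun_manifest()]) reproduces every output file
#' byte-identically.
#'
#' In `mode: synthetic` all inputs are generated by the package's planted
#' ground-truth simulators from per-stage seeds derived from the global
#' seed; in `mode: files` the configuration's `inputs` section names the
#' cohort, compendium and link-table files.
#'
#' @param config configuration list or YAML path (see [load_config()]).
#' @param out_dir output directory.
#' @return invisible list with all intermediate objects (`cohorts`,
#'   `signatures`, `consistency`, `compendium`, `calibration`, `scores`,
#'   `enrichment`, `mst`, `truth` when synthetic, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- load_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_env <- new.env()
  log_env$lines <- character(0L)
  seed <- as.integer(cfg$seed)
  truth <- NULL

  # --- inputs ---------------------------------------------------------
  if (identical(cfg$mode, "synthetic")) {
    sy <- cfg$synthetic
    sim <- run_stage("simulate", log_env, {
      co <- simulate_cohorts(
        n_cohorts = sy$n_cohorts, n_patients = sy$n_patients,
        p_disease = sy$p_disease, p_genes = sy$p_genes, k = sy$k,
        signal_scale = sy$signal_scale, noise_sd = sy$noise_sd,
        seed = stage_seed(seed, "cohorts"))
      cp <- simulate_compendium(
        co$truth$B_true, n_drugs = sy$n_drugs,
        n_cell_lines = sy$n_cell_lines, n_targets = sy$n_targets,
        drugs_per_target = sy$drugs_per_target,
        effect_size = sy$effect_size, noise_sd = sy$noise_sd,
        coverage = sy$coverage, seed = stage_seed(seed, "compendium"))
      list(cohorts = co$cohorts, comp_raw = cp$compendium,
           links = cp$links, protein_links = cp$protein_links,
           truth = c(co$truth, cp$truth))
    })
    cohorts <- sim$cohorts
    comp_raw <- sim$comp_raw
    links <- sim$links
    protein_links <- sim$protein_links
    truth <- sim$truth
  } else if (identical(cfg$mode, "files")) {
    ins <- cfg$inputs
    if (is.null(ins)) stop("config field 'inputs' is missing")
    for (fld in c("cohorts", "compendium", "links")) {
      if (is.null(ins[[fld]])) stop("config field 'inputs$", fld,
                                    "' is missing")
    }
    landmark <- readLines(ins$landmark_genes)
    cohorts <- run_stage("read_cohorts", log_env, {
      lapply(ins$cohorts, function(ci) {
        read_cohort(ci$factors, ci$expression, landmark,
                    cohort_id = ci$id %||% NULL)
      })
    })
    comp_raw <- run_stage("read_compendium", log_env, {
      if (!is.null(ins$compendium$metadata)) {
        expr <- read_expression_matrix(ins$compendium$expression)
        meta <- utils::read.delim(ins$compendium$metadata,
                                  stringsAsFactors = FALSE)
        pool_replicates(expr, meta)
      } else {
        # pre-pooled per-cell-line fold-change matrices
        profiles <- lapply(ins$compendium$pooled, function(pi) {
          read_expression_matrix(pi$path)
        })
        names(profiles) <- vapply(ins$compendium$pooled, `[[`,
                                  character(1L), "cell_line")
        perturbation_compendium(profiles, zscored = FALSE)
      }
    })
    links <- run_stage("read_links", log_env,
                       read_target_links(ins$links))
    protein_links <- if (!is.null(ins$protein_links)) {
      run_stage("read_protein_links", log_env,
                read_protein_links(ins$protein_links))
    } else NULL
  } else {
    stop("config mode must be 'synthetic' or 'files'")
  }

  run_stage("validate", log_env, {
    validate_inputs(cohorts, comp_raw, links, report = FALSE)
    invisible(NULL)
  })

  # --- signatures -----------------------------------------------------
  k <- cfg$signatures$k %||% (if (!is.null(truth)) truth$k else 2L)
  sigs <- run_stage("signatures", log_env, {
    lapply(cohorts, function(co) {
      fit_signatures(co$Z, extract_features(co$Y, k), co$cohort_id)
    })
  })
  consistency_rep <- run_stage("consistency", log_env, {
    if (length(sigs) >= 2L) {
      signature_consistency(sigs, cfg$signatures$consistency_threshold)
    } else NULL
  })
  # align signs across cohorts and keep the features that replicate; if
  # none replicate, score everything but say so in the log
  score_features <- sigs[[1L]]$feature_names
  force_features <- FALSE
  if (!is.null(consistency_rep)) {
    sigs <- align_signatures(sigs, consistency_rep)
    passing <- consistency_rep$summary$feature[consistency_rep$summary$pass]
    if (length(passing) > 0L) {
      score_features <- passing
    } else {
      force_features <- TRUE
      run_stage("consistency", log_env, message(
        "no feature passed the cross-cohort consistency filter; ",
        "scoring all features"))
    }
  }

  # --- compendium -----------------------------------------------------
  comp <- run_stage("compendium", log_env, {
    cc <- comp_raw
    if ((cfg$compendium$min_drugs %||% 0L) > 0L) {
      cc <- filter_cell_lines(cc, cfg$compendium$min_drugs)
    }
    if (!cc$zscored) cc <- z_transform(cc)
    cc
  })

  # --- matching -------------------------------------------------------
  calib <- run_stage("calibration", log_env, {
    fit_calibration(comp, links,
                    score_threshold = cfg$enrichment$stitch_threshold)
  })
  consistency_w <- run_stage("drug_consistency", log_env,
                             drug_consistency(comp))
  weights <- cfg$scoring$cell_line_weights
  if (!is.null(weights)) weights <- unlist(weights)
  scores <- run_stage("scoring", log_env, {
    score_all(comp, sigs, calib, consistency_w,
              directions = cfg$scoring$directions,
              features = score_features, weights = weights)
  })

  perm <- NULL
  n_perm <- cfg$scoring$n_perm %||% 0L
  if (n_perm > 0L) {
    perm <- run_stage("permutation", log_env, {
      f1 <- score_features[1L]
      permutation_null(comp, sigs, calib, consistency_w, feature = f1,
                       direction = cfg$scoring$directions[1L],
                       n_perm = n_perm,
                       seed = stage_seed(seed, "permutation"),
                       weights = weights)
    })
  }

  # --- enrichment -----------------------------------------------------
  enr <- run_stage("enrichment", log_env, {
    enrich_all(scores, links,
               alpha_q = cfg$enrichment$q_threshold,
               score_threshold = cfg$enrichment$stitch_threshold,
               min_group_size = cfg$enrichment$min_drugs_per_target,
               fdr = cfg$enrichment$fdr)
  })
  mst <- run_stage("mst", log_env, {
    sig_targets <- unique(enr$target[enr$significant])
    if (length(sig_targets) >= 2L && !is.null(protein_links)) {
      mst_of_targets(sig_targets, protein_links)
    } else {
      message("fewer than 2 significant targets (or no protein links); ",
              "MST skipped")
      NULL
    }
  })

  # --- outputs --------------------------------------------------------
  sig_mat <- do.call(cbind, lapply(sigs, function(s) {
    m <- s$B
    colnames(m) <- paste(s$cohort_id, s$feature_names, sep = ".")
    m
  }))
  out_objects <- list(
    signatures = data.frame(gene_id = rownames(sig_mat),
                            as.data.frame(sig_mat), check.names = FALSE),
    match_scores = scores,
    enrichment = enr
  )
  if (!is.null(consistency_rep)) {
    out_objects$consistency <- consistency_rep$summary
  }
  if (!is.null(mst)) out_objects$mst_edges <- mst$edges
  if (!is.null(perm)) {
    out_objects$permutation <- data.frame(
      drug = names(perm$p), observed = as.numeric(perm$observed),
      empirical_p = as.numeric(perm$p), stringsAsFactors = FALSE)
  }
  files <- write_tables(out_objects, out_dir)
  writeLines(log_env$lines, file.path(out_dir, "log.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("sigdecon")),
    seed = seed,
    config = cfg,
    outputs = as.list(tools::md5sum(sort(c(files,
                                           file.path(out_dir, "log.txt")))))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  if (identical(cfg$mode, "files")) {
    input_files <- unlist(cfg$inputs, use.names = FALSE)
    input_files <- input_files[file.exists(input_files)]
    manifest$inputs <- as.list(tools::md5sum(input_files))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohorts = cohorts, signatures = sigs,
                 consistency = consistency_rep, compendium = comp,
                 calibration = calib, drug_consistency = consistency_w,
                 scores = scores, permutation = perm, enrichment = enr,
                 mst = mst, truth = truth, manifest = manifest,
                 files = files))
}

#' Re-run a pipeline from its manifest
#'
#' Reads the manifest written by [run_pipeline()] and repeats the run with
#' the recorded configuration, reproducing all outputs byte-identically.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory (defaults to the manifest's directory).
#' @return see [run_pipeline()].
#' @export
rerun_manifest <- function(manifest_path, out_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- drop_empty(man$config)
  # JSON round-trip turns scalar vectors into lists in some fields
  cfg$scoring$directions <- unlist(cfg$scoring$directions)
  run_pipeline(cfg, out_dir)
}

# JSON serializes NULL fields as empty objects; strip them back to NULL.
drop_empty <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_empty)
  x[vapply(x, function(e) is.list(e) && length(e) == 0L, logical(1L))] <- NULL
  x
}
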