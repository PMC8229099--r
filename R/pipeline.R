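#' Configuration for the end-to-end pipeline
#'
#' Flat key-value configuration with the study defaults: detection alpha
#' 0.05, max missing fraction 10%, 15 components x 20 loadings, variance
#' 0.1, correlation 0.7, 5 feature-selection folds, outer 5 / inner 3
#' cross-validation, 1000 permutations, top-50 survival CpGs. Every value
#' can be overridden; all randomness derives from the single `seed`.
#'
#' @param ... Overrides for any default listed above (see
#'   [pipeline_defaults()]).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$max_missing_frac >= 0, cfg$max_missing_frac <= 1,
            cfg$outer_k >= 2, cfg$inner_k >= 2, cfg$k_folds >= 2,
            cfg$n_permutations >= 1, cfg$top_k >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Default pipeline parameter values
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(alpha = 0.05, max_missing_frac = 0.10, mad_factor = 5,
       n_components = 15, top_per_component = 20,
       var_threshold = 0.1, corr_threshold = 0.7, k_folds = 5,
       outer_k = 5, inner_k = 3, n_permutations = 1000,
       top_k = 50, min_group = 3, seed = 1L,
       run_simulate = TRUE, run_preprocess = TRUE, run_features = TRUE,
       run_classification = TRUE, run_permutation = TRUE,
       run_differential = TRUE, run_heterogeneity = TRUE,
       run_survival = TRUE,
       heterogeneity_subtype = "NK",
       survival_subtypes = c("t(8;21)", "MLL", "NK"))
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (comments with `#`); values are parsed
#' as logical/numeric where possible, comma-separated values become
#' vectors.
#'
#' @param path Configuration file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    suppressWarnings({
      num <- as.numeric(parts)
      if (!any(is.na(num))) return(num)
    })
    if (all(parts %in% c("TRUE", "FALSE", "true", "false"))) {
      return(toupper(parts) == "TRUE")
    }
    parts
  }
  vals <- stats::setNames(lapply(kv, function(x) parse_val(x[2])),
                          vapply(kv, `[[`, "", 1))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline into an output directory
#'
#' Stages: simulate (or load supplied inputs) -> mask/filter/outlier QC ->
#' dual feature selection -> nested cross-validated model selection,
#' final fit, permutation validation -> prediction of undefined samples ->
#' one-vs-rest differential methylation -> intra-subtype heterogeneity ->
#' within-subtype survival. Every stage writes its artifacts under
#' `out_dir`; a manifest records parameters, the seed, and input
#' checksums. A stage failure halts the run with the stage name while
#' earlier artifacts are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param beta,detection_p,sheet Optional pre-loaded inputs; when any is
#'   NULL and `run_simulate` is TRUE, a synthetic cohort is generated.
#' @param sim_config Optional [simulation_config()] for the simulate
#'   stage (its seed is overridden by the pipeline seed).
#' @param blacklist,autosomal_ids Optional probe filters.
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         beta = NULL, detection_p = NULL, sheet = NULL,
                         sim_config = NULL, blacklist = character(),
                         autosomal_ids = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  results <- list()
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline halted in stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(beta) && isTRUE(config$run_simulate)) {
    results$simulate <- stage("simulate", {
      sc <- if (is.null(sim_config)) simulation_config(seed = config$seed)
            else { sim_config$seed <- as.integer(config$seed); sim_config }
      sim <- simulate_cohort(sc)
      write_beta_matrix(sim$beta, file.path(out_dir, "beta.tsv"))
      write_beta_matrix(sim$detection_p, file.path(out_dir, "detection_p.tsv"))
      write_sample_sheet(sim$sheet, file.path(out_dir, "sample_sheet.tsv"))
      write_truth_map(sim$truth, file.path(out_dir, "truth.tsv"))
      sim
    })
    beta <- results$simulate$beta
    detection_p <- results$simulate$detection_p
    sheet <- results$simulate$sheet
  }
  if (!isTRUE(config$run_preprocess)) {
    say("pipeline stopped after simulate (run_preprocess = FALSE)")
    return(invisible(results))
  }
  if (is.null(beta) || is.null(sheet)) {
    stop("pipeline needs a beta matrix and sample sheet ",
         "(supply them or enable run_simulate)")
  }

  results$preprocess <- stage("preprocess", {
    pp <- preprocess_beta(beta, detection_p, alpha = config$alpha,
                          blacklist = blacklist,
                          autosomal_ids = autosomal_ids,
                          max_missing_frac = config$max_missing_frac,
                          mad_factor = config$mad_factor)
    write_filter_report(pp$report, file.path(out_dir, "filter_report.tsv"))
    pp
  })
  clean <- results$preprocess$beta
  if (!isTRUE(config$run_features)) {
    say("pipeline stopped after preprocess (run_features = FALSE)")
    return(invisible(results))
  }

  results$features <- stage("select_features", {
    fs <- select_features(clean, k_folds = config$k_folds,
                          seed = config$seed + 10,
                          n_components = config$n_components,
                          top_per_component = config$top_per_component,
                          var_threshold = config$var_threshold,
                          corr_threshold = config$corr_threshold)
    write_feature_set(fs, file.path(out_dir, "feature_set.tsv"))
    fs
  })
  fs_ids <- results$features$cpg_ids
  m <- bm_values(clean)
  beta_fs_all <- beta_matrix(m[fs_ids, , drop = FALSE])

  labelled <- sheet$timepoint == "diagnosis" &
    sheet$reported_subtype != "undefined"
  lab_ids <- sheet$sample_id[labelled]
  labels <- sheet$reported_subtype[labelled]
  beta_fs <- beta_matrix(m[fs_ids, lab_ids, drop = FALSE])

  if (!isTRUE(config$run_classification)) {
    say("classification stages skipped (run_classification = FALSE)")
  } else {
  results$model_report <- stage("nested_cv_select", {
    rep <- suppressWarnings(nested_cv_select(
      beta_fs, labels, outer_k = config$outer_k, inner_k = config$inner_k,
      seed = config$seed + 20))
    acc <- data.frame(family = names(rep$mean_accuracies),
                      mean_accuracy = as.numeric(rep$mean_accuracies))
    utils::write.table(acc, file.path(out_dir, "model_accuracies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })
  best <- results$model_report$best_family

  results$classifier <- stage("fit_final", {
    suppressWarnings(fit_final(beta_fs, labels, model_spec(best),
                               seed = config$seed + 30))
  })

  if (isTRUE(config$run_permutation)) {
    results$permutation <- stage("permutation_test", {
      chosen <- results$classifier$params
      pt <- suppressWarnings(permutation_test(
        beta_fs, labels, model_spec(best, grid = list(chosen)),
        n_permutations = config$n_permutations,
        outer_k = config$outer_k, inner_k = config$inner_k,
        seed = config$seed + 40))
      writeLines(sprintf("permutation_p\t%.6g", pt$p.value),
                 file.path(out_dir, "permutation.tsv"))
      pt
    })
  }

  results$predictions <- stage("predict", {
    new_ids <- sheet$sample_id[!labelled]
    if (length(new_ids)) {
      pred <- predict_subtypes(results$classifier,
                               beta_matrix(m[fs_ids, new_ids, drop = FALSE]))
      utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pred
    } else NULL
  })
  }  # run_classification

  if (isTRUE(config$run_differential)) {
    results$differential <- stage("diffmeth", {
      dm <- suppressWarnings(one_vs_rest_dm(beta_fs, labels,
                                            alpha = config$alpha,
                                            min_group = config$min_group))
      write_dm_result(dm, file.path(out_dir, "differential.tsv"))
      dm
    })
  }

  if (isTRUE(config$run_heterogeneity)) {
    results$heterogeneity <- stage("cluster", {
      st <- config$heterogeneity_subtype
      pred_ids <- if (!is.null(results$predictions)) {
        p <- results$predictions
        p$sample_id[p$predicted_subtype == st & p$subtype_suspected]
      } else character()
      ids <- union(sheet$sample_id[labelled & sheet$reported_subtype == st],
                   intersect(pred_ids,
                             sheet$sample_id[sheet$timepoint == "diagnosis"]))
      if (length(ids) < 4) return(NULL)
      cl <- hier_cluster(beta_matrix(m[fs_ids, ids, drop = FALSE]), k = 2)
      assoc <- suppressWarnings(associate_clusters(cl, sheet))
      utils::write.table(assoc, file.path(out_dir, "cluster_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(clusters = cl, association = assoc)
    })
  }

  if (isTRUE(config$run_survival)) {
    results$survival <- stage("survival", {
      out <- list()
      for (st in config$survival_subtypes) {
        pred_ids <- if (!is.null(results$predictions)) {
          p <- results$predictions
          p$sample_id[p$predicted_subtype == st]
        } else character()
        sg <- tryCatch(
          run_survival_stage(beta_fs_all, sheet, st,
                             include_predicted = TRUE,
                             predicted = pred_ids,
                             alpha = config$alpha, top_k = config$top_k),
          error = function(e) { say("survival skipped for ", st, ": ",
                                    conditionMessage(e)); NULL })
        if (!is.null(sg)) {
          utils::write.table(
            data.frame(sample_id = names(sg$groups), group = sg$groups),
            file.path(out_dir, paste0("survival_groups_",
                                      gsub("[^A-Za-z0-9]", "_", st), ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
        out[[st]] <- sg
      }
      out
    })
  }

  manifest <- c(
    sprintf("seed\t%d", as.integer(config$seed)),
    if (!is.null(results$model_report))
      sprintf("best_family\t%s", results$model_report$best_family),
    vapply(setdiff(names(unclass(config)),
                   c("survival_subtypes", "heterogeneity_subtype")),
           function(k) sprintf("%s\t%s", k,
                               paste(config[[k]], collapse = ",")), ""),
    vapply(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE),
           function(f) sprintf("md5:%s\t%s", basename(f),
                               unname(tools::md5sum(f))), ""))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  say("pipeline complete")
  invisible(results)
}
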