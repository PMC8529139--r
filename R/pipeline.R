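#' Run the full pooled-accuracy pipeline and write a report bundle
#'
#' Orchestrates per-study metrics, the bivariate fit, the SROC curve and
#' AUC, heterogeneity and threshold-effect statistics, Deeks' asymmetry
#' test, leave-one-out, outlier detection and subgroup analyses, writing
#' `report.json`, `per_study.csv`, `sroc_curve.csv`, `subgroups.csv`,
#' `funnel.csv`, `loo.csv`, a human-readable `summary.txt` and a
#' `MANIFEST.txt` of completed stages into `output_dir`. The pipeline is
#' deterministic: identical inputs give byte-identical `report.json`.
#'
#' @param input a [study_set], a path to a study CSV, or a fixture name.
#' @param output_dir directory for outputs (created if needed); `NULL`
#'   skips file output.
#' @param cc,cc_policy continuity correction for the descriptive layers.
#' @param exclude study ids to drop before everything else.
#' @param subgroup_columns grouping columns for stratified refits.
#' @param sroc_mode `"hsroc"` or `"regression"`.
#' @param auc_range FPR integration range.
#' @param quad_nodes Gauss-Hermite nodes per dimension.
#' @return the report bundle (named list), invisibly when writing files.
#' @export
run_pipeline <- function(input, output_dir = NULL, cc = 0.5,
                         cc_policy = "zero_cells_only",
                         exclude = character(),
                         subgroup_columns = c("ethnicity_group", "cancer_group",
                                              "sample_group", "pancreatic"),
                         sroc_mode = "hsroc", auc_range = c(0, 1),
                         quad_nodes = 25) {
  studies <- if (inherits(input, "study_set")) {
    input
  } else if (is.character(input) && file.exists(input)) {
    read_studies(input)
  } else if (is.character(input)) {
    load_fixture(input)
  } else {
    study_set(input)
  }
  if (length(exclude) > 0L) {
    unknown <- setdiff(exclude, studies$study_id)
    if (length(unknown) > 0L) {
      stop("unknown study id(s) in exclude: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    studies <- studies[!studies$study_id %in% exclude, , drop = FALSE]
  }

  done <- character()
  emit <- function(stage) done <<- c(done, stage)
  flush_manifest <- function() {
    if (!is.null(output_dir)) {
      writeLines(done, file.path(output_dir, "MANIFEST.txt"))
    }
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  on.exit(flush_manifest(), add = TRUE)

  per_study <- metrics_table(studies, cc, cc_policy)
  emit("per_study")
  fit <- fit_bivariate(studies, quad_nodes = quad_nodes)
  summary <- pooled_summary(fit)
  emit("bivariate_fit")
  sroc_res <- sroc(fit, fpr_range = auc_range, mode = sroc_mode)
  emit("sroc")
  het <- heterogeneity(studies, cc, cc_policy)
  spear <- threshold_spearman(studies, cc, cc_policy)
  deeks <- deeks_test(studies, cc, cc_policy)
  emit("heterogeneity_bias")
  loo <- leave_one_out(studies, quad_nodes = quad_nodes)
  outliers <- detect_outliers(studies, fit)
  emit("robustness")
  subgroups <- lapply(
    setNames(nm = intersect(subgroup_columns, names(studies))),
    function(colnm) subgroup_analysis(studies, colnm, quad_nodes = quad_nodes))
  emit("subgroups")

  bundle <- list(
    n_trials = nrow(studies),
    provenance = attr(studies, "provenance"),
    excluded = exclude,
    pooled = summary,
    fit = list(mu = as.list(fit$mu), sigma = as.vector(fit$sigma),
               cov_mu = as.vector(fit$cov_mu), loglik = fit$loglik,
               converged = fit$converged, method = fit$method,
               quad_nodes = fit$quad_nodes, n_trials = fit$n_trials),
    sroc = list(lambda = sroc_res$lambda, beta = sroc_res$beta,
                auc = sroc_res$auc, fpr_range = sroc_res$fpr_range,
                summary_point = as.list(sroc_res$summary_point)),
    heterogeneity = het,
    spearman = spear[c("rho", "p", "n", "threshold_effect")],
    deeks = deeks[c("slope", "slope_se", "intercept", "t_stat", "p", "n",
                    "significant")],
    loo = list(stable = attr(loo, "stable"),
               sens_range = range(loo$sens, na.rm = TRUE),
               spec_range = range(loo$spec, na.rm = TRUE)),
    outliers = list(flagged_ids = outliers$flagged_ids,
                    threshold = outliers$threshold,
                    statistic = as.list(outliers$statistic)),
    subgroups = subgroups
  )

  if (!is.null(output_dir)) {
    write_results(bundle, file.path(output_dir, "report.json"), "json")
    write_results(per_study, file.path(output_dir, "per_study.csv"), "csv")
    write_results(sroc_res$curve, file.path(output_dir, "sroc_curve.csv"), "csv")
    write_results(deeks$data, file.path(output_dir, "funnel.csv"), "csv")
    write_results(as.data.frame(loo), file.path(output_dir, "loo.csv"), "csv")
    if (length(subgroups) > 0L) {
      allsub <- do.call(rbind, Map(function(nm, df) {
        cbind(data.frame(grouping = nm, stringsAsFactors = FALSE), df)
      }, names(subgroups), subgroups))
      write_results(allsub, file.path(output_dir, "subgroups.csv"), "csv")
    }
    writeLines(.text_summary(bundle), file.path(output_dir, "summary.txt"))
    emit("outputs")
    flush_manifest()
    return(invisible(bundle))
  }
  bundle
}

.fmt_ci <- function(df, m, digits = 2) {
  i <- match(m, df$measure)
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          df$estimate[i], df$lo[i], df$hi[i])
}

.text_summary <- function(b) {
  p <- b$pooled
  c(sprintf("Pooled diagnostic accuracy over %d trials", b$n_trials),
    sprintf("  sensitivity %s, specificity %s",
            .fmt_ci(p, "sens"), .fmt_ci(p, "spec")),
    sprintf("  PLR %s, NLR %s", .fmt_ci(p, "plr"), .fmt_ci(p, "nlr")),
    sprintf("  DOR %s", .fmt_ci(p, "dor")),
    sprintf("  SROC AUC %.4f (FPR range %g-%g)",
            b$sroc$auc, b$sroc$fpr_range[1], b$sroc$fpr_range[2]),
    sprintf("Heterogeneity: I2(sens) %.1f%%, I2(spec) %.1f%%",
            b$heterogeneity$i2_sens, b$heterogeneity$i2_spec),
    sprintf("Threshold effect: Spearman rho %.3f, p %.3f (%s)",
            b$spearman$rho, b$spearman$p,
            if (isTRUE(b$spearman$threshold_effect)) "present" else "absent"),
    sprintf("Deeks asymmetry: slope %.2f, p %.4f", b$deeks$slope, b$deeks$p),
    sprintf("Leave-one-out: pooled sensitivity %.3f-%.3f, %s",
            b$loo$sens_range[1], b$loo$sens_range[2],
            if (isTRUE(b$loo$stable)) "stable" else "not stable"),
    sprintf("Outliers flagged: %s",
            if (length(b$outliers$flagged_ids)) {
              paste(b$outliers$flagged_ids, collapse = ", ")
            } else "none"))
}

#' Simulate a study set and write it as a study CSV
#'
#' @param config a [sim_config()] or a path to a YAML/JSON config file.
#' @param out output CSV path.
#' @return the output path, invisibly.
#' @export
simulate_to_csv <- function(config, out) {
  if (is.character(config)) config <- read_sim_config(config)
  studies <- simulate_studies(config)
  write_results(as.data.frame(studies), out, "csv")
  message("wrote ", nrow(studies), " simulated trials (seed ",
          config$seed, ") to ", out)
  invisible(out)
}
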