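read_cohort_inputs <- function(input) {
  need <- c("patients", "complications", "followup")
  miss <- setdiff(need, names(input))
  if (length(miss) > 0) {
    abort(paste0("Input block is missing path(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (nm in need) {
    if (!file.exists(input[[nm]])) {
      abort(paste0("Input file not found: ", input[[nm]], " (", nm, ")"))
    }
  }
  list(
    patients = readr::read_csv(input$patients, show_col_types = FALSE),
    complications = readr::read_csv(input$complications,
                                    show_col_types = FALSE),
    followup = readr::read_csv(input$followup, show_col_types = FALSE)
  )
}

roc_block <- function(ra) {
  list(
    score = ra$score_name,
    auc = ra$auc,
    n_pos = ra$n_pos,
    n_neg = ra$n_neg,
    cutpoint = ra$cutpoint$cutpoint,
    sensitivity = ra$metrics$sensitivity,
    specificity = ra$metrics$specificity,
    ppv = ra$metrics$ppv,
    npv = ra$metrics$npv,
    confusion = list(tp = ra$metrics$tp, fp = ra$metrics$fp,
                     tn = ra$metrics$tn, fn = ra$metrics$fn),
    bootstrap = if (is.null(ra$boot)) NULL else
      lapply(split(ra$boot, ra$boot$metric), function(r) {
        list(estimate = r$estimate, lower = r$lower, upper = r$upper,
             level = r$level, B = r$B)
      })
  )
}

#' Run the full VISUAL validation pipeline
#'
#' End-to-end orchestration: score the cohort's VISUAL totals; compute both
#' clinical severity scores and their Cluster A/B assignments (fixed
#' cut-offs, with the exact 1-D 2-means boundary and silhouette widths
#' reported alongside for comparison); ROC/optimal-cutpoint diagnostics of
#' VISUAL and of smB alone against each severity score's clusters, with
#' paired McNemar and bootstrap AUC comparisons; per-point logistic and
#' threshold Fisher association statistics; and the Kaplan-Meier /
#' log-rank progression analysis by VISUAL risk group. Identical inputs,
#' configuration and seed produce a byte-identical report.
#'
#' The smB-alone comparator predicts severe evolution when the smB
#' percentage is below `smb_cutpoint_pct` (default 2, the EUROclass
#' threshold); its ROC uses the negated smB percentage so that higher
#' values indicate more severe disease.
#'
#' @param simulate A [cohort_config()]; the cohort is generated in memory.
#'   Exactly one of `simulate` and `input` must be given.
#' @param input A list with CSV paths `patients`, `complications`,
#'   `followup` (schemas as written by [write_cohort_csv()]).
#' @param ref A [visual_reference()].
#' @param visual_cutoff High-risk VISUAL threshold. Default 10.
#' @param smb_cutpoint_pct smB percentage below which the comparator
#'   classifier predicts severe evolution. Default 2.
#' @param boot_b Bootstrap replicates for CIs and AUC comparison; 0
#'   disables the bootstrap blocks. Default 2000.
#' @param seed Seed for all stochastic stages; defaults to the simulate
#'   block's seed, and is required with file input when `boot_b > 0`.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   per-comparison ROC coordinate TSVs, a Kaplan-Meier table TSV and the
#'   scored patient CSV there.
#' @return Invisibly, the report as a nested list (class `visual_report`),
#'   with the fitted objects in the `objects` attribute.
#' @examples
#' rep <- run_pipeline(simulate = cohort_config(n = 30, seed = 7),
#'                     boot_b = 0)
#' rep$diagnostics$ameratunga$visual$auc
#' @export
run_pipeline <- function(simulate = NULL, input = NULL,
                         ref = visual_reference(), visual_cutoff = 10,
                         smb_cutpoint_pct = 2, boot_b = 2000, seed = NULL,
                         out_dir = NULL) {
  if (is.null(simulate) == is.null(input)) {
    abort("Give exactly one of `simulate` (a cohort_config) or `input` (paths).")
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "cohort_config"))
    if (is.null(seed)) seed <- simulate$seed
    cohort <- generate_cohort(simulate)
    data <- cohort[c("patients", "complications", "followup")]
  } else {
    data <- read_cohort_inputs(input)
  }
  if (boot_b > 0 && is.null(seed)) {
    abort("A `seed` is required when `boot_b` > 0.")
  }

  scored <- score_cohort(data$patients, ref, visual_cutoff)
  scored$smb_inverted <- -scored$smb_pct
  scored$pred_visual <- as.integer(scored$visual_total >= visual_cutoff)
  scored$pred_smb <- as.integer(scored$smb_pct < smb_cutpoint_pct)
  rejects <- scoring_rejects(scored)

  catalogs <- list(ameratunga = severity_catalog("ameratunga"),
                   grimbacher = severity_catalog("grimbacher"))
  objects <- list(scored = scored, severity = list(), roc = list(),
                  km = NULL)
  severity_rep <- list()
  diagnostics_rep <- list()
  association_rep <- list()

  for (nm in names(catalogs)) {
    cat_obj <- catalogs[[nm]]
    sev <- score_severity(data$complications, cat_obj,
                          patients = scored$patient_id)
    km2 <- tryCatch(two_means_1d(sev$total), error = function(e) NULL)
    sil <- if (!is.null(km2)) silhouette_1d(sev$total, km2$labels) else NULL
    joined <- dplyr::inner_join(scored, sev, by = "patient_id")
    objects$severity[[nm]] <- joined

    severity_rep[[nm]] <- list(
      cutoff = cat_obj$cluster_cutoff,
      n = nrow(sev),
      n_cluster_b = sum(sev$cluster == "B"),
      prop_cluster_b = mean(sev$cluster == "B"),
      median_total = stats::median(sev$total),
      range_total = range(sev$total),
      kmeans_boundary = if (is.null(km2)) NULL else km2$boundary,
      kmeans_agreement = if (is.null(km2)) NULL else
        mean((km2$labels == 2) == (sev$cluster == "B")),
      mean_silhouette = if (is.null(sil)) NULL else sil$mean
    )

    ra_visual <- roc_analysis(joined, visual_total, cluster,
                              boot_b = boot_b, seed = seed)
    ra_smb <- roc_analysis(joined, smb_inverted, cluster,
                           boot_b = boot_b, seed = seed)
    objects$roc[[paste0(nm, "_visual")]] <- ra_visual
    objects$roc[[paste0(nm, "_smb")]] <- ra_smb

    mc_sens <- mcnemar_paired(joined$pred_visual, joined$pred_smb,
                              joined$cluster, "positives")
    mc_spec <- mcnemar_paired(joined$pred_visual, joined$pred_smb,
                              joined$cluster, "negatives")
    auc_cmp <- if (boot_b > 0) {
      bootstrap_compare_auc(joined, visual_total, smb_inverted,
                            cluster, B = boot_b, seed = seed)
    } else {
      NULL
    }
    diagnostics_rep[[nm]] <- list(
      cluster_definition = paste0(nm, " total >= ", cat_obj$cluster_cutoff),
      visual = roc_block(ra_visual),
      smb = roc_block(ra_smb),
      mcnemar_sensitivity = as.list(mc_sens),
      mcnemar_specificity = as.list(mc_spec),
      auc_comparison = if (is.null(auc_cmp)) NULL else as.list(auc_cmp)
    )

    fit <- fit_logistic(joined, visual_total, cluster)
    thr <- odds_at_threshold(joined, visual_total, cluster,
                             cutoff = visual_cutoff)
    association_rep[[nm]] <- list(
      per_point = list(odds_ratio = fit$odds_ratio, lower = fit$ci[1],
                       upper = fit$ci[2], p_value = fit$p_wald, n = fit$n),
      threshold = as.list(thr)
    )
  }

  fu <- dplyr::inner_join(
    data$followup,
    dplyr::select(scored, "patient_id", "risk_class"),
    by = "patient_id"
  )
  km <- tryCatch(
    km_progression(fu, age_progression_or_censor, event,
                   risk_class),
    error = function(e) NULL
  )
  objects$km <- km
  survival_rep <- if (is.null(km)) {
    list(note = "Kaplan-Meier stage skipped: a risk group is empty.")
  } else {
    list(
      n = km$n, n_events = km$n_events,
      medians = as.list(setNames(km$medians$median_time,
                                 km$medians$group)),
      logrank = as.list(km$logrank)
    )
  }

  report <- list(
    run = list(
      package = "visualcvid",
      version = as.character(packageVersion("visualcvid")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      visual_cutoff = visual_cutoff,
      smb_cutpoint_pct = smb_cutpoint_pct,
      bootstrap_b = boot_b,
      config_hash = rlang::hash(list(simulate = simulate, input = input,
                                     visual_cutoff = visual_cutoff,
                                     smb_cutpoint_pct = smb_cutpoint_pct,
                                     boot_b = boot_b, seed = seed))
    ),
    cohort = list(
      n_input = nrow(data$patients),
      n_scored = nrow(scored),
      n_rejected = nrow(rejects),
      reject_reasons = as.list(rejects$reason)
    ),
    visual = list(
      mean_total = mean(scored$visual_total),
      median_total = stats::median(scored$visual_total),
      n_high_risk = sum(scored$risk_class == "high")
    ),
    severity = severity_rep,
    diagnostics = diagnostics_rep,
    association = association_rep,
    survival = survival_rep
  )
  class(report) <- c("visual_report", "list")
  attr(report, "objects") <- objects

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    readr::write_csv(scored, file.path(out_dir, "scored_patients.csv"))
    for (nm in names(objects$roc)) {
      readr::write_tsv(objects$roc[[nm]]$curve,
                       file.path(out_dir, paste0("roc_", nm, ".tsv")))
    }
    if (!is.null(km)) {
      readr::write_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
    }
  }
  invisible(report)
}

#' @export
print.visual_report <- function(x, ...) {
  cat("VISUAL validation report (n scored = ", x$cohort$n_scored, ")\n",
      sep = "")
  for (nm in names(x$diagnostics)) {
    d <- x$diagnostics[[nm]]
    cat(sprintf("  vs %s clusters: AUC visual %.3f, smB alone %.3f\n",
                nm, d$visual$auc, d$smb$auc))
  }
  if (!is.null(x$survival$logrank)) {
    cat(sprintf("  log-rank p = %.4g\n", x$survival$logrank$p_value))
  }
  invisible(x)
}
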