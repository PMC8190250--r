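default_intervals <- function() {
  list(
    smb = list(`1` = c(6, 29), `2` = c(2, 6), `3` = c(1, 2), `4` = c(0, 1)),
    iga = list(`1` = c(0.7, 4.0), `2` = c(0.07, 0.7), `4` = c(0, 0.07)),
    igm = list(normal = c(0.4, 2.3), elevated = c(2.31, 6)),
    cd4 = list(`1` = c(700, 1500), `2` = c(500, 700), `3` = c(200, 500),
               `4` = c(20, 200))
  )
}

#' Configuration of the synthetic CVID cohort generator
#'
#' Defaults encode the published cohort structure: n = 50 patients; smB
#' category frequencies 24/36/14/26% (points 1/2/3/4); IgA 26/24/50%
#' (low-normal / below 2SD / undetectable); elevated IgM in 6%; antibody
#' responses 58% both altered, 28% polysaccharide-only, 14% protein-only;
#' CD4 strata 44/12/32/12%; diagnosis ages bounded on (4, 70) with median
#' about 32; a per-VISUAL-point severity log-odds of ln(1.3) with the
#' intercept calibrated so severe-cluster prevalence is about 56% at the
#' mean score; and progression mostly within two years of diagnosis.
#'
#' @param n Cohort size (at least 2). Default 50.
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @param smb_probs,iga_probs,cd4_probs Category probabilities over the
#'   reachable point values (named by point). Must sum to 1.
#' @param igm_elevated_p Probability of elevated serum IgM (4 points).
#' @param ab_probs Probabilities over antibody-response patterns
#'   `both_altered`, `poly_only`, `protein_only`, `normal`.
#' @param beta Per-VISUAL-point log-odds of severe-cluster membership.
#'   Default `log(1.3)`.
#' @param target_cluster_b Severe-cluster probability at the expected
#'   VISUAL total, used to calibrate the intercept. Default 0.56.
#' @param visual_cutoff High-risk VISUAL threshold. Default 10.
#' @param age_range,age_shape Diagnosis-age model: `age_range[1] +
#'   diff(age_range) * Beta(age_shape)`. Defaults (4, 70) and (2, 2.6).
#' @param p_immediate Probability a progressor progresses at diagnosis
#'   (delay 0). Default 0.5.
#' @param delay_mean_late Mean (years) of the exponential delay of the
#'   non-immediate progressors, before hazard scaling. Default 4.
#' @param hazard_ratio_high Factor by which the late-progression hazard is
#'   raised in high-VISUAL patients. Default 2.
#' @param followup_range Uniform range (years since diagnosis) of the
#'   censoring time of non-progressors. Default (1, 31).
#' @param amer_range_a,amer_range_b,grim_range_a,grim_range_b Integer
#'   ranges (inclusive) from which Ameratunga / Grimbacher totals are drawn
#'   uniformly for Cluster A and Cluster B patients. Defaults (8, 13) /
#'   (14, 21) and (2, 4) / (5, 10), bracketing the published medians,
#'   ranges and cut-offs.
#' @param intervals Category-to-interval map for the continuous lab draws;
#'   see `visualcvid:::default_intervals()`. Intended as a testing hook.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 50, seed,
                          smb_probs = c(`1` = 0.24, `2` = 0.36,
                                        `3` = 0.14, `4` = 0.26),
                          iga_probs = c(`1` = 0.26, `2` = 0.24, `4` = 0.50),
                          igm_elevated_p = 0.06,
                          ab_probs = c(both_altered = 0.58,
                                       poly_only = 0.28,
                                       protein_only = 0.14,
                                       normal = 0.00),
                          cd4_probs = c(`1` = 0.44, `2` = 0.12,
                                        `3` = 0.32, `4` = 0.12),
                          beta = log(1.3),
                          target_cluster_b = 0.56,
                          visual_cutoff = 10,
                          age_range = c(4, 70),
                          age_shape = c(2, 2.6),
                          p_immediate = 0.5,
                          delay_mean_late = 4,
                          hazard_ratio_high = 2,
                          followup_range = c(1, 31),
                          amer_range_a = c(8, 13),
                          amer_range_b = c(14, 21),
                          grim_range_a = c(2, 4),
                          grim_range_b = c(5, 10),
                          intervals = NULL) {
  if (missing(seed)) abort("A `seed` is mandatory for cohort generation.")
  if (n < 2) abort("`n` must be at least 2.")
  for (p in list(smb_probs, iga_probs, ab_probs, cd4_probs)) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort("Category probabilities must be non-negative and sum to 1.")
    }
  }
  if (!is.finite(beta)) abort("`beta` must be finite.")
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    smb_probs = smb_probs, iga_probs = iga_probs,
    igm_elevated_p = igm_elevated_p, ab_probs = ab_probs,
    cd4_probs = cd4_probs,
    beta = beta, target_cluster_b = target_cluster_b,
    visual_cutoff = visual_cutoff,
    age_range = age_range, age_shape = age_shape,
    p_immediate = p_immediate, delay_mean_late = delay_mean_late,
    hazard_ratio_high = hazard_ratio_high,
    followup_range = followup_range,
    amer_range_a = as.integer(amer_range_a),
    amer_range_b = as.integer(amer_range_b),
    grim_range_a = as.integer(grim_range_a),
    grim_range_b = as.integer(grim_range_b),
    intervals = if (is.null(intervals)) default_intervals() else intervals
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Expected VISUAL total under the configured category probabilities.
expected_visual_total <- function(cfg) {
  e_smb <- sum(as.numeric(names(cfg$smb_probs)) * cfg$smb_probs)
  e_iga <- sum(as.numeric(names(cfg$iga_probs)) * cfg$iga_probs)
  e_igm <- 1 * (1 - cfg$igm_elevated_p) + 4 * cfg$igm_elevated_p
  ab_pts <- c(both_altered = 4, poly_only = 2, protein_only = 2, normal = 1)
  e_ab <- sum(ab_pts[names(cfg$ab_probs)] * cfg$ab_probs)
  e_cd4 <- sum(as.numeric(names(cfg$cd4_probs)) * cfg$cd4_probs)
  e_smb + e_iga + e_igm + e_ab + e_cd4
}

draw_in_interval <- function(cat, intervals) {
  lo <- vapply(intervals, `[`, numeric(1), 1)[as.character(cat)]
  hi <- vapply(intervals, `[`, numeric(1), 2)[as.character(cat)]
  runif(length(cat), lo, hi)
}

# Decompose an Ameratunga total into item grades (weights 1/5/10) over
# randomly chosen distinct catalog items.
decompose_ameratunga <- function(total, items) {
  n10 <- total %/% 10
  rest <- total - 10 * n10
  n5 <- rest %/% 5
  n1 <- rest - 5 * n5
  grades <- c(rep("severe", n10), rep("moderate", n5), rep("mild", n1))
  if (length(grades) > length(items)) {
    abort("Severity total too large for the catalog's item count.")
  }
  tibble::tibble(item_id = sample(items, length(grades)), grade = grades)
}

# Decompose a Grimbacher total into grades 0-3 (grade = weight).
decompose_grimbacher <- function(total, items) {
  n3 <- total %/% 3
  rest <- total - 3 * n3
  grades <- c(rep("3", n3), if (rest > 0) as.character(rest))
  if (length(grades) > length(items)) {
    abort("Severity total too large for the catalog's item count.")
  }
  tibble::tibble(item_id = sample(items, length(grades)), grade = grades)
}

#' Generate a synthetic CVID cohort
#'
#' Draws each analyte's point category independently from the configured
#' multinomials, then a continuous laboratory value uniformly within that
#' category's interval (so re-categorizing the labs reproduces the drawn
#' categories exactly — see [roundtrip_check()]); computes the VISUAL
#' total; draws severe-cluster (Cluster B) membership from the logistic
#' link on the total, with the intercept solved so that the severe
#' probability equals the configured target at the expected total; draws
#' Ameratunga and Grimbacher severity totals on the cluster-consistent side
#' of each cut-off and decomposes them into complication records; and
#' simulates progression/censoring ages on the age axis.
#'
#' @param config A [cohort_config()].
#' @param complications Draw complication records? Setting `FALSE` skips
#'   the record decomposition (the severity totals remain in `truth`);
#'   complication draws come last in the random stream, so all other
#'   tables are identical either way. Useful for large simulation studies.
#' @return A list of class `visual_cohort` with tibbles `patients`
#'   (the laboratory panel CSV schema), `complications` (`patient_id`,
#'   `catalog`, `item_id`, `grade`), `followup` (`patient_id`,
#'   `age_progression_or_censor`, `event`), `truth` (the drawn categories,
#'   totals and cluster per patient), and `config` with the resolved
#'   `intercept` attached.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 20, seed = 42))
#' nrow(cohort$patients)
#' @export
generate_cohort <- function(config, complications = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n
  intercept <- qlogis(cfg$target_cluster_b) -
    cfg$beta * expected_visual_total(cfg)
  if (!is.finite(intercept)) {
    abort("Calibration failed: the intercept solve produced a non-finite value.")
  }
  cfg$intercept <- intercept
  amer <- severity_catalog("ameratunga")
  grim <- severity_catalog("grimbacher")
  ab_pts <- c(both_altered = 4, poly_only = 2, protein_only = 2, normal = 1)

  withr::with_seed(cfg$seed, {
    smb_cat <- sample(as.integer(names(cfg$smb_probs)), n, TRUE,
                      cfg$smb_probs)
    iga_cat <- sample(as.integer(names(cfg$iga_probs)), n, TRUE,
                      cfg$iga_probs)
    igm_cat <- ifelse(runif(n) < cfg$igm_elevated_p, 4L, 1L)
    ab_cat <- sample(names(cfg$ab_probs), n, TRUE, cfg$ab_probs)
    cd4_cat <- sample(as.integer(names(cfg$cd4_probs)), n, TRUE,
                      cfg$cd4_probs)

    smb_pct <- draw_in_interval(smb_cat, cfg$intervals$smb)
    iga_g_l <- draw_in_interval(iga_cat, cfg$intervals$iga)
    igm_g_l <- draw_in_interval(ifelse(igm_cat == 4L, "elevated", "normal"),
                                cfg$intervals$igm)
    cd4_per_ul <- draw_in_interval(cd4_cat, cfg$intervals$cd4)
    diag_age <- cfg$age_range[1] + diff(cfg$age_range) *
      rbeta(n, cfg$age_shape[1], cfg$age_shape[2])

    total <- smb_cat + iga_cat + igm_cat + ab_pts[ab_cat] + cd4_cat
    high <- total >= cfg$visual_cutoff
    cluster_b <- rbinom(n, 1, plogis(intercept + cfg$beta * total)) == 1

    amer_total <- ifelse(
      cluster_b,
      sample(seq(cfg$amer_range_b[1], cfg$amer_range_b[2]), n, TRUE),
      sample(seq(cfg$amer_range_a[1], cfg$amer_range_a[2]), n, TRUE)
    )
    grim_total <- ifelse(
      cluster_b,
      sample(seq(cfg$grim_range_b[1], cfg$grim_range_b[2]), n, TRUE),
      sample(seq(cfg$grim_range_a[1], cfg$grim_range_a[2]), n, TRUE)
    )

    ids <- sprintf("P%03d", seq_len(n))
    patients <- tibble::tibble(
      patient_id = ids,
      smb_pct = smb_pct,
      iga_g_l = iga_g_l,
      igm_g_l = igm_g_l,
      poly_response = ifelse(ab_cat %in% c("both_altered", "poly_only"),
                             "inadequate", "adequate"),
      protein_response = ifelse(ab_cat %in% c("both_altered", "protein_only"),
                                "inadequate", "adequate"),
      cd4_per_ul = cd4_per_ul,
      age_at_diagnosis_years = diag_age
    )

    delay <- ifelse(
      runif(n) < cfg$p_immediate, 0,
      rexp(n, rate = ifelse(high, cfg$hazard_ratio_high, 1) /
             cfg$delay_mean_late)
    )
    censor_after <- runif(n, cfg$followup_range[1], cfg$followup_range[2])
    followup <- tibble::tibble(
      patient_id = ids,
      age_progression_or_censor = diag_age +
        ifelse(cluster_b, delay, censor_after),
      event = as.integer(cluster_b)
    )

    truth <- tibble::tibble(
      patient_id = ids,
      points_smb = smb_cat, points_iga = iga_cat, points_igm = igm_cat,
      points_ab = unname(ab_pts[ab_cat]), points_cd4 = cd4_cat,
      visual_total = as.integer(total),
      risk_class = factor(ifelse(high, "high", "low"),
                          levels = c("low", "high")),
      cluster = factor(ifelse(cluster_b, "B", "A"), levels = c("A", "B")),
      ameratunga_total = as.integer(amer_total),
      grimbacher_total = as.integer(grim_total)
    )

    # complication records are drawn last so that skipping them leaves
    # every other table's random stream untouched
    comp <- if (complications) {
      dplyr::bind_rows(lapply(seq_len(n), function(i) {
        dplyr::bind_rows(
          dplyr::mutate(decompose_ameratunga(amer_total[i], amer$items),
                        patient_id = ids[i], catalog = "ameratunga",
                        .before = 1),
          dplyr::mutate(decompose_grimbacher(grim_total[i], grim$items),
                        patient_id = ids[i], catalog = "grimbacher",
                        .before = 1)
        )
      }))
    } else {
      NULL
    }

    structure(list(patients = patients, complications = comp,
                   followup = followup, truth = truth, config = cfg),
              class = "visual_cohort")
  })
}

#' Verify that generated labs re-categorize to their drawn categories
#'
#' Runs [categorize_analytes()] on a synthetic cohort's laboratory table
#' and compares the resulting point values with the categories drawn by the
#' generator. By construction (values drawn inside category intervals)
#' every row must match; mismatches indicate a corrupted interval
#' configuration and are reported by row.
#'
#' @param cohort A `visual_cohort` from [generate_cohort()].
#' @param ref Reference configuration used for re-categorization.
#' @return A list with `ok` (logical), `n_mismatch`, and `mismatches`
#'   (tibble naming the patient, analyte, drawn and recomputed points).
#' @export
roundtrip_check <- function(cohort, ref = visual_reference()) {
  stopifnot(inherits(cohort, "visual_cohort"))
  if (nrow(cohort$patients) == 0) abort("Empty cohort.")
  rescored <- categorize_analytes(cohort$patients, ref)
  pts <- c("points_smb", "points_iga", "points_igm", "points_ab",
           "points_cd4")
  mism <- purrr::map_dfr(pts, function(col) {
    bad <- which(rescored[[col]] != cohort$truth[[col]])
    tibble::tibble(
      patient_id = cohort$patients$patient_id[bad],
      analyte = col,
      drawn = cohort$truth[[col]][bad],
      recomputed = rescored[[col]][bad]
    )
  })
  list(ok = nrow(mism) == 0, n_mismatch = nrow(mism), mismatches = mism)
}

#' @export
print.visual_cohort <- function(x, ...) {
  cat("Synthetic CVID cohort: n = ", nrow(x$patients),
      ", seed = ", x$config$seed, "\n", sep = "")
  cat(sprintf("  per-point log-odds %.4f, resolved intercept %.4f\n",
              x$config$beta, x$config$intercept))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `patients.csv`, `complications.csv` and `followup.csv` plus the
#' resolved generator configuration as `generator_config.yaml` into `dir`.
#'
#' @param cohort A `visual_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "visual_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "complications.csv",
                            "followup.csv", "generator_config.yaml"))
  readr::write_csv(cohort$patients, paths[1])
  readr::write_csv(cohort$complications, paths[2])
  readr::write_csv(cohort$followup, paths[3])
  cfg <- cohort$config
  cfg$intervals <- lapply(cfg$intervals, lapply, as.numeric)
  yaml::write_yaml(unclass(cfg), paths[4])
  invisible(paths)
}
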