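visual_lab_cols <- c("smb_pct", "iga_g_l", "igm_g_l", "poly_response",
                     "protein_response", "cd4_per_ul")

# Per-row validity check; returns NA_character_ for valid rows, else a reason.
lab_row_problem <- function(data) {
  n <- nrow(data)
  reason <- rep(NA_character_, n)
  missing <- rep(FALSE, n)
  for (col in visual_lab_cols) {
    missing <- missing | is.na(data[[col]])
  }
  reason[missing] <- "incomplete panel"
  bad_enum <- (!data$poly_response %in% c("adequate", "inadequate") |
                 !data$protein_response %in% c("adequate", "inadequate"))
  bad_enum[is.na(bad_enum)] <- FALSE
  reason[is.na(reason) & bad_enum] <- "invalid response value"
  rng <- (data$smb_pct < 0 | data$smb_pct > 100 |
            data$iga_g_l < 0 | data$igm_g_l < 0 | data$cd4_per_ul < 0)
  rng[is.na(rng)] <- FALSE
  reason[is.na(reason) & rng] <- "value out of range"
  reason
}

#' Categorize the five VISUAL analytes into point values
#'
#' Assigns each analyte its 1-4 point category: smB (% of B cells) at the
#' 6 / 2 / 1 % cut-offs (1/2/3/4 points, lower is worse); IgA at the 2-SD and
#' detectability limits (1/2/4; the 3-point cell does not exist); IgM above
#' the upper normal limit scores 4, otherwise 1; specific antibody responses
#' score 1 (both adequate), 2 (exactly one inadequate) or 4 (both
#' inadequate); CD4 counts at 700 / 500 / 200 cells/uL (1/2/3/4). Lower
#' bounds of better categories are inclusive (smB exactly 6% scores 1, CD4
#' exactly 500 scores 2, IgA exactly at the detectability limit scores 2).
#'
#' Values above the normal range (CD4 above `cd4_upper_normal_per_ul`, smB
#' above `smb_upper_normal_pct`) still score 1 point but raise the
#' corresponding `flag_*` column, since the grid defines no category above
#' normal.
#'
#' @param data Data frame with columns `smb_pct`, `iga_g_l`, `igm_g_l`,
#'   `poly_response`, `protein_response`, `cd4_per_ul` (one row per patient).
#' @param ref A [visual_reference()] configuration.
#' @return The input as a tibble with integer columns `points_smb`,
#'   `points_iga`, `points_igm`, `points_ab`, `points_cd4` and logical flags
#'   `flag_cd4_above_normal`, `flag_smb_above_normal` appended.
#' @examples
#' labs <- tibble::tibble(
#'   smb_pct = 1.5, iga_g_l = 0.05, igm_g_l = 1.0,
#'   poly_response = "inadequate", protein_response = "adequate",
#'   cd4_per_ul = 350
#' )
#' categorize_analytes(labs)
#' @export
categorize_analytes <- function(data, ref = visual_reference()) {
  validate_visual_reference(ref)
  miss <- setdiff(visual_lab_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing analyte columns: ", paste(miss, collapse = ", ")))
  }
  problem <- lab_row_problem(data)
  if (any(!is.na(problem))) {
    bad <- which(!is.na(problem))
    abort(paste0(
      "Cannot categorize ", length(bad), " row(s): ",
      paste(unique(problem[bad]), collapse = "; "),
      " (rows ", paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else "", ")"
    ))
  }

  smb_t <- ref$smb_thresholds_pct
  cd4_t <- ref$cd4_thresholds_per_ul
  n_inadequate <- (data$poly_response == "inadequate") +
    (data$protein_response == "inadequate")

  out <- dplyr::mutate(
    tibble::as_tibble(data),
    points_smb = dplyr::case_when(
      .data$smb_pct >= smb_t[1] ~ 1L,
      .data$smb_pct >= smb_t[2] ~ 2L,
      .data$smb_pct >= smb_t[3] ~ 3L,
      TRUE ~ 4L
    ),
    points_iga = dplyr::case_when(
      .data$iga_g_l >= ref$iga_2sd_g_l ~ 1L,
      .data$iga_g_l >= ref$iga_undetectable_g_l ~ 2L,
      TRUE ~ 4L
    ),
    points_igm = dplyr::if_else(
      .data$igm_g_l > ref$igm_normal_range_g_l[2], 4L, 1L
    ),
    points_ab = dplyr::case_when(
      n_inadequate == 0L ~ 1L,
      n_inadequate == 1L ~ 2L,
      TRUE ~ 4L
    ),
    points_cd4 = dplyr::case_when(
      .data$cd4_per_ul >= cd4_t[1] ~ 1L,
      .data$cd4_per_ul >= cd4_t[2] ~ 2L,
      .data$cd4_per_ul >= cd4_t[3] ~ 3L,
      TRUE ~ 4L
    ),
    flag_cd4_above_normal = .data$cd4_per_ul > ref$cd4_upper_normal_per_ul,
    flag_smb_above_normal = .data$smb_pct > ref$smb_upper_normal_pct
  )
  if (any(out$flag_cd4_above_normal)) {
    warn(paste0(sum(out$flag_cd4_above_normal),
                " patient(s) with CD4 above the normal range ",
                "(scored 1 point, flagged)."))
  }
  if (any(out$flag_smb_above_normal)) {
    warn(paste0(sum(out$flag_smb_above_normal),
                " patient(s) with smB above the normal range ",
                "(scored 1 point, flagged)."))
  }
  out
}

#' Compute the VISUAL score
#'
#' Sums the five analyte point values (each 1-4, so the total spans 5-20)
#' and dichotomizes at `cutoff` (inclusive: a total equal to the cutoff is
#' high risk). Rows with a missing or invalid analyte raise an error — the
#' score is never computed from an incomplete panel; use [score_cohort()] to
#' score the valid rows of a mixed table and collect rejects.
#'
#' @inheritParams categorize_analytes
#' @param cutoff High-risk threshold on the total; default 10.
#' @return A tibble: the input plus the five `points_*` columns,
#'   `visual_total` and `risk_class` (`"high"` / `"low"`).
#' @examples
#' labs <- tibble::tibble(
#'   patient_id = "p1", smb_pct = 0.5, iga_g_l = 0.03, igm_g_l = 3,
#'   poly_response = "inadequate", protein_response = "inadequate",
#'   cd4_per_ul = 150
#' )
#' score_visual(labs)$visual_total  # 20, the attainable maximum
#' @export
score_visual <- function(data, ref = visual_reference(), cutoff = 10) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  out <- categorize_analytes(data, ref)
  dplyr::mutate(
    out,
    visual_total = .data$points_smb + .data$points_iga + .data$points_igm +
      .data$points_ab + .data$points_cd4,
    risk_class = factor(
      dplyr::if_else(.data$visual_total >= cutoff, "high", "low"),
      levels = c("low", "high")
    )
  )
}

#' Score a cohort, collecting unscoreable rows as rejects
#'
#' Applies [score_visual()] to every valid row; rows failing the panel
#' preconditions (missing analyte, out-of-range value, invalid response
#' label) are excluded and reported, with reasons, in the `rejects`
#' attribute (retrievable with [scoring_rejects()]). Input order is
#' preserved among the scored rows.
#'
#' @inheritParams score_visual
#' @return A tibble of scored rows with attribute `rejects`, itself a tibble
#'   with columns `row`, `patient_id` (if present) and `reason`.
#' @export
score_cohort <- function(data, ref = visual_reference(), cutoff = 10) {
  if (nrow(data) == 0) {
    abort("Empty cohort: no rows to score.")
  }
  miss <- setdiff(visual_lab_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing analyte columns: ", paste(miss, collapse = ", ")))
  }
  problem <- lab_row_problem(data)
  rejects <- tibble::tibble(
    row = which(!is.na(problem)),
    patient_id = if ("patient_id" %in% names(data)) {
      as.character(data$patient_id[!is.na(problem)])
    } else {
      NA_character_
    },
    reason = problem[!is.na(problem)]
  )
  keep <- is.na(problem)
  if (!any(keep)) {
    abort("No scoreable rows in the cohort.")
  }
  out <- score_visual(data[keep, , drop = FALSE], ref, cutoff)
  attr(out, "rejects") <- rejects
  out
}

#' Rejected rows from a cohort scoring run
#'
#' @param x The tibble returned by [score_cohort()].
#' @return A tibble with columns `row`, `patient_id`, `reason` (zero rows
#'   when every input row was scored).
#' @export
scoring_rejects <- function(x) {
  rej <- attr(x, "rejects")
  if (is.null(rej)) {
    abort("`x` does not carry a rejects attribute; was it made by score_cohort()?")
  }
  rej
}

#' Enumerate every attainable VISUAL component combination
#'
#' The reachable point sets are \{1,2,3,4\} for smB and CD4, \{1,2,4\} for
#' IgA and antibody responses, and \{1,4\} for IgM; the cross product gives
#' every attainable score profile (288 combinations, totals 5 to 20).
#' Mainly useful for structural audits of the score.
#'
#' @return A tibble with the five `points_*` columns and `visual_total`.
#' @export
enumerate_visual_combinations <- function() {
  grid <- tidyr::expand_grid(
    points_smb = 1:4,
    points_iga = c(1L, 2L, 4L),
    points_igm = c(1L, 4L),
    points_ab = c(1L, 2L, 4L),
    points_cd4 = 1:4
  )
  dplyr::mutate(
    grid,
    visual_total = .data$points_smb + .data$points_iga + .data$points_igm +
      .data$points_ab + .data$points_cd4
  )
}
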