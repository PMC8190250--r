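#' Reference configuration for VISUAL analyte categorization
#'
#' Bundles the laboratory reference limits that drive the point assignment of
#' the five VISUAL analytes. Defaults follow the published scoring grid:
#' switched-memory B cells (smB) categorized at 6 / 2 / 1 % of B cells, serum
#' IgA at the 2-SD-below-normal limit and the 0.07 g/L detectability limit,
#' serum IgM flagged only when above the 2.3 g/L upper normal limit, and CD4+
#' T-cell counts staged at 700 / 500 / 200 cells/uL. All limits are
#' overridable so the score can be re-anchored to local, age-adjusted
#' reference ranges.
#'
#' @param smb_thresholds_pct Strictly decreasing triple of smB percentages
#'   separating categories 1|2, 2|3 and 3|4. Default `c(6, 2, 1)`.
#' @param smb_upper_normal_pct Upper limit of the smB normal range (percent);
#'   values above it still score 1 point but are flagged. Default 29.
#' @param iga_lower_normal_g_l Age-adjusted lower limit of normal serum IgA
#'   (g/L); informational, not used in categorization. Default 0.7.
#' @param iga_2sd_g_l IgA limit two standard deviations below normal (g/L);
#'   values at or above it score 1 point. Default 0.7.
#' @param iga_undetectable_g_l IgA detectability limit (g/L); values below it
#'   score 4 points. Default 0.07.
#' @param igm_normal_range_g_l Length-2 numeric, normal serum IgM range in
#'   g/L. Only the upper limit enters scoring (above it scores 4 points).
#'   Default `c(0.4, 2.3)`.
#' @param cd4_thresholds_per_ul Strictly decreasing triple of CD4 counts
#'   (cells/uL) separating categories 1|2, 2|3 and 3|4.
#'   Default `c(700, 500, 200)`.
#' @param cd4_upper_normal_per_ul Upper limit of the CD4 normal range
#'   (cells/uL); counts above it score 1 point with a flag. Default 1500.
#'
#' @return A list of class `visual_reference`.
#' @examples
#' ref <- visual_reference()
#' ref$smb_thresholds_pct
#' @export
visual_reference <- function(smb_thresholds_pct = c(6, 2, 1),
                             smb_upper_normal_pct = 29,
                             iga_lower_normal_g_l = 0.7,
                             iga_2sd_g_l = 0.7,
                             iga_undetectable_g_l = 0.07,
                             igm_normal_range_g_l = c(0.4, 2.3),
                             cd4_thresholds_per_ul = c(700, 500, 200),
                             cd4_upper_normal_per_ul = 1500) {
  ref <- list(
    smb_thresholds_pct = as.numeric(smb_thresholds_pct),
    smb_upper_normal_pct = as.numeric(smb_upper_normal_pct),
    iga_lower_normal_g_l = as.numeric(iga_lower_normal_g_l),
    iga_2sd_g_l = as.numeric(iga_2sd_g_l),
    iga_undetectable_g_l = as.numeric(iga_undetectable_g_l),
    igm_normal_range_g_l = as.numeric(igm_normal_range_g_l),
    cd4_thresholds_per_ul = as.numeric(cd4_thresholds_per_ul),
    cd4_upper_normal_per_ul = as.numeric(cd4_upper_normal_per_ul)
  )
  class(ref) <- "visual_reference"
  validate_visual_reference(ref)
  ref
}

validate_visual_reference <- function(ref) {
  stopifnot(inherits(ref, "visual_reference"))
  if (length(ref$smb_thresholds_pct) != 3 ||
      any(diff(ref$smb_thresholds_pct) >= 0)) {
    abort("`smb_thresholds_pct` must be a strictly decreasing triple.")
  }
  if (length(ref$cd4_thresholds_per_ul) != 3 ||
      any(diff(ref$cd4_thresholds_per_ul) >= 0)) {
    abort("`cd4_thresholds_per_ul` must be a strictly decreasing triple.")
  }
  if (length(ref$igm_normal_range_g_l) != 2 ||
      diff(ref$igm_normal_range_g_l) <= 0) {
    abort("`igm_normal_range_g_l` must be an increasing (lower, upper) pair.")
  }
  if (!(ref$iga_undetectable_g_l <= ref$iga_2sd_g_l &&
        ref$iga_2sd_g_l <= ref$iga_lower_normal_g_l)) {
    abort(paste("IgA limits must satisfy undetectable <= 2SD <=",
                "lower-normal."))
  }
  invisible(ref)
}

#' Read a reference configuration from YAML or JSON
#'
#' Any subset of the [visual_reference()] fields may be present; unspecified
#' fields keep their defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) file.
#' @return A `visual_reference` object.
#' @export
read_visual_reference <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(visual_reference))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown reference fields: ", paste(extra, collapse = ", ")))
  }
  do.call(visual_reference, raw)
}

#' Vaccine-response adequacy from pre/post titres
#'
#' Classifies a specific antibody response as adequate when the
#' post-vaccination titre shows at least the required fold-rise over the
#' pre-vaccination titre, or exceeds the absolute protective threshold.
#' Defaults encode the protein (tetanus toxoid: fourfold rise or
#' 0.15 IU/mL) and polysaccharide (pneumococcal: threefold rise or 11 mg/dL)
#' criteria via `antigen`.
#'
#' @param pre,post Numeric vectors of pre- and post-vaccination titres, in
#'   the same units as `abs_threshold`.
#' @param antigen `"protein"` or `"polysaccharide"`; sets default `fold` and
#'   `abs_threshold`.
#' @param fold Required fold-rise over `pre`; overrides the antigen default.
#' @param abs_threshold Absolute titre regarded as protective regardless of
#'   fold-rise; overrides the antigen default.
#' @return Character vector, `"adequate"` or `"inadequate"`.
#' @examples
#' ab_response(pre = 0.02, post = 0.1, antigen = "protein")    # fold rise
#' ab_response(pre = 5, post = 12, antigen = "polysaccharide") # absolute
#' @export
ab_response <- function(pre, post,
                        antigen = c("protein", "polysaccharide"),
                        fold = NULL, abs_threshold = NULL) {
  antigen <- match.arg(antigen)
  if (is.null(fold)) fold <- if (antigen == "protein") 4 else 3
  if (is.null(abs_threshold)) {
    abs_threshold <- if (antigen == "protein") 0.15 else 11
  }
  stopifnot(length(pre) == length(post))
  if (any(pre < 0 | post < 0, na.rm = TRUE)) {
    abort("Titres must be non-negative.")
  }
  adequate <- (post >= fold * pre) | (post >= abs_threshold)
  ifelse(adequate, "adequate", "inadequate")
}
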