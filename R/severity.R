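#' Load a clinical severity catalog
#'
#' A catalog names the complications that may be graded, the allowed grades
#' with their point weights, and the cluster cut-off that separates
#' non-severe (Cluster A) from severe (Cluster B) clinical evolution. Two
#' catalogs ship with the package: `"ameratunga"` (mild/moderate/severe
#' weighted 1/5/10, Cluster B at a total of 14 or more) and `"grimbacher"`
#' (15 complications graded 0-3, the grade being its own weight, Cluster B
#' at 5 or more). Both are editable YAML; pass a file path for a custom
#' catalog.
#'
#' @param catalog `"ameratunga"`, `"grimbacher"`, or a path to a catalog
#'   YAML file with fields `name`, `cluster_cutoff`, `grades` (grade ->
#'   weight map) and `items` (character vector of complication ids).
#' @return A list of class `severity_catalog`.
#' @examples
#' cat_a <- severity_catalog("ameratunga")
#' cat_a$cluster_cutoff
#' @export
severity_catalog <- function(catalog = c("ameratunga", "grimbacher")) {
  if (length(catalog) == 1 && file.exists(catalog) &&
      !catalog %in% c("ameratunga", "grimbacher")) {
    path <- catalog
  } else {
    catalog <- match.arg(catalog)
    path <- system.file("extdata", paste0(catalog, "_catalog.yaml"),
                        package = "visualcvid", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  for (field in c("name", "cluster_cutoff", "grades", "items")) {
    if (is.null(raw[[field]])) {
      abort(paste0("Catalog is missing field `", field, "`."))
    }
  }
  out <- list(
    name = raw$name,
    cluster_cutoff = as.integer(raw$cluster_cutoff),
    weights = setNames(as.numeric(unlist(raw$grades)), names(raw$grades)),
    items = as.character(unlist(raw$items))
  )
  if (anyDuplicated(out$items)) abort("Catalog items must be unique.")
  if (out$cluster_cutoff < 0) abort("`cluster_cutoff` must be non-negative.")
  class(out) <- "severity_catalog"
  out
}

#' Clinical severity totals and Cluster A/B assignment
#'
#' Sums the grade weights of each patient's complication records under a
#' severity catalog, and assigns Cluster B (severe clinical evolution) when
#' the total reaches the catalog's cluster cut-off, Cluster A otherwise.
#' A patient with no records scores 0 (absence of manifestations). Each
#' complication may be graded at most once per patient; an unknown
#' complication id or grade is an error, never silently dropped.
#'
#' @param data Data frame of complication records with columns `patient_id`,
#'   `item_id`, `grade`. Records for other catalogs can be pre-filtered via
#'   an optional `catalog` column, which is matched against
#'   `catalog$name` when present.
#' @param catalog A [severity_catalog()].
#' @param patients Optional character vector of patient ids that must appear
#'   in the result (patients without records receive total 0); defaults to
#'   the ids present in `data`.
#' @return A tibble with columns `patient_id`, `total` and `cluster`
#'   (factor `"A"`/`"B"`), one row per patient.
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = c("p1", "p1"), item_id = c("pneumonia", "bronchiectasis"),
#'   grade = c("severe", "mild")
#' )
#' score_severity(recs, severity_catalog("ameratunga"))  # total 11, Cluster A
#' @export
score_severity <- function(data, catalog, patients = NULL) {
  stopifnot(inherits(catalog, "severity_catalog"))
  need <- c("patient_id", "item_id", "grade")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if ("catalog" %in% names(data)) {
    data <- dplyr::filter(data, .data$catalog == !!catalog$name)
  }
  data$grade <- as.character(data$grade)
  data$patient_id <- as.character(data$patient_id)

  unknown <- setdiff(unique(data$item_id), catalog$items)
  if (length(unknown) > 0) {
    abort(paste0("Unknown complication id(s) for catalog `", catalog$name,
                 "`: ", paste(unknown, collapse = ", ")))
  }
  bad_grade <- setdiff(unique(data$grade), names(catalog$weights))
  if (length(bad_grade) > 0) {
    abort(paste0("Grade(s) not allowed by catalog `", catalog$name, "`: ",
                 paste(bad_grade, collapse = ", ")))
  }
  dup <- dplyr::count(data, .data$patient_id, .data$item_id)
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate grade for complication `", dup$item_id[1],
                 "` of patient `", dup$patient_id[1],
                 "`: one grade per complication."))
  }

  if (is.null(patients)) patients <- unique(data$patient_id)
  w <- catalog$weights
  totals <- dplyr::summarise(
    dplyr::group_by(data, .data$patient_id),
    total = sum(w[.data$grade]),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    tibble::tibble(patient_id = as.character(patients)),
    totals,
    by = "patient_id"
  )
  out$total[is.na(out$total)] <- 0
  dplyr::mutate(
    out,
    cluster = factor(
      dplyr::if_else(.data$total >= catalog$cluster_cutoff, "B", "A"),
      levels = c("A", "B")
    )
  )
}

#' Exact two-cluster partition of 1-D scores
#'
#' Optimal 1-D 2-means: the within-cluster sum of squares is minimized over
#' the n-1 split points of the sorted values (the optimal 2-partition in one
#' dimension is always an interval split, so the scan is exact). The
#' boundary is reported as the midpoint between the two clusters' nearest
#' members.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return A list with `labels` (integer 1 for the lower cluster, 2 for the
#'   upper, in input order), `boundary`, and `withinss`.
#' @examples
#' two_means_1d(c(1, 1, 2, 10, 11))$labels
#' @export
two_means_1d <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2) abort("Need at least two scores.")
  if (anyNA(scores)) abort("Scores must not contain NA.")
  if (length(unique(scores)) < 2) {
    abort("Degenerate clustering: all scores are identical.")
  }
  ord <- order(scores)
  x <- scores[ord]
  n <- length(x)
  wss_upto <- function(v) sum((v - mean(v))^2)
  wss <- vapply(seq_len(n - 1), function(k) {
    wss_upto(x[1:k]) + wss_upto(x[(k + 1):n])
  }, numeric(1))
  k <- which.min(wss)
  labels_sorted <- rep(c(1L, 2L), c(k, n - k))
  labels <- integer(n)
  labels[ord] <- labels_sorted
  list(
    labels = labels,
    boundary = (x[k] + x[k + 1]) / 2,
    withinss = wss[k]
  )
}

#' Silhouette widths for a two-cluster 1-D partition
#'
#' Computes the silhouette width s(i) = (b(i) - a(i)) / max(a(i), b(i)) with
#' absolute difference on the score line as the distance, where a(i) is the
#' mean distance to the other members of i's own cluster and b(i) the mean
#' distance to the other cluster. Members of a singleton cluster take
#' s(i) = 0 by convention.
#'
#' @param scores Numeric vector.
#' @param labels Vector with exactly two distinct values, same length as
#'   `scores`, both clusters non-empty.
#' @return A list with `widths` (tibble: `score`, `label`, `silhouette`),
#'   `cluster_means` (tibble) and `mean` (overall mean width).
#' @export
silhouette_1d <- function(scores, labels) {
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.")
  }
  lv <- unique(labels)
  if (length(lv) != 2) {
    abort("Exactly two non-empty clusters are required.")
  }
  s <- vapply(seq_along(scores), function(i) {
    own <- scores[labels == labels[i]]
    other <- scores[labels != labels[i]]
    if (length(own) == 1) return(0)  # singleton convention
    # a(i): mean distance to the other members of i's own cluster
    a <- sum(abs(scores[i] - own)) / (length(own) - 1)
    b <- mean(abs(scores[i] - other))
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  widths <- tibble::tibble(score = scores, label = labels, silhouette = s)
  cluster_means <- dplyr::summarise(
    dplyr::group_by(widths, .data$label),
    mean_silhouette = mean(.data$silhouette), n = dplyr::n(),
    .groups = "drop"
  )
  list(widths = widths, cluster_means = cluster_means, mean = mean(s))
}
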