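#' Select the top fraction of vertices by relevance
#'
#' Vertices are ranked by relevance in descending order and the top
#' `round(fraction * n)` are selected; ties at the cutoff are broken by
#' ascending vertex id. With all-equal relevance the first
#' `round(fraction * n)` ids are returned with a warning.
#'
#' @param vertex_relevance numeric vector of relevance scores indexed by
#'   vertex id.
#' @param fraction fraction to keep, in (0, 1] (default 0.03, the top 3%).
#' @return integer vector of selected vertex ids (ascending).
#' @export
top_fraction_mask <- function(vertex_relevance, fraction = 0.03) {
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  n <- length(vertex_relevance)
  k <- round(fraction * n)
  if (k < 1L) stop_("fraction selects no vertices (n = ", n, ")")
  if (length(unique(vertex_relevance)) == 1L) {
    warn_("all relevance values equal; selecting the first ", k, " vertex ids")
  }
  ord <- order(-vertex_relevance, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Critical regions from an aggregate relevance map
#'
#' Applies [top_fraction_mask()] to vertex relevance and groups the selected
#' vertices by the source space's hemisphere + region labels.
#'
#' @param vertex_relevance vertex relevance (from [pixel_to_vertex()] on an
#'   aggregated map).
#' @param space the `cortical_space`.
#' @param fraction top fraction (default 0.03).
#' @return object of class `critical_regions`: list with `vertex_ids`,
#'   `fraction`, and `regions` (data frame: hemisphere, region, n_selected),
#'   plus `groups`, a named list of selected vertex ids per
#'   hemisphere/region.
#' @export
critical_regions <- function(vertex_relevance, space, fraction = 0.03) {
  stopifnot(inherits(space, "cortical_space"))
  if (length(vertex_relevance) != space$n_vertices) {
    stop_("relevance length does not match the source space")
  }
  ids <- top_fraction_mask(vertex_relevance, fraction)
  v <- space$vertices[ids, ]
  key <- paste(v$hemisphere, v$region, sep = ".")
  groups <- split(v$vertex_id, key)
  regions <- data.frame(
    hemisphere = sub("\\..*$", "", names(groups)),
    region = sub("^[^.]*\\.", "", names(groups)),
    n_selected = vapply(groups, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(vertex_ids = ids, fraction = fraction, regions = regions,
         groups = groups),
    class = "critical_regions"
  )
}

#' @export
print.critical_regions <- function(x, ...) {
  cat("Critical regions: top", sprintf("%.1f%%", 100 * x$fraction), "=",
      length(x$vertex_ids), "vertices\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Per-subject mean activity over a vertex mask
#'
#' For each subject: the mean windowed current density over that subject's
#' retained trials and the masked vertices. Subjects without retained trials
#' are excluded with a warning.
#'
#' @param windowed a `windowed_trials` object.
#' @param vertex_ids vertices to average over (non-empty).
#' @param subjects optional subject subset/order; default all subjects
#'   present.
#' @return named numeric vector of per-subject means.
#' @export
region_activity <- function(windowed, vertex_ids, subjects = NULL) {
  stopifnot(inherits(windowed, "windowed_trials"))
  if (!length(vertex_ids)) stop_("vertex mask is empty")
  subjects <- subjects %||% unique(windowed$subject)
  present <- subjects %in% windowed$subject
  if (any(!present)) {
    warn_("excluding subjects with no retained trials: ",
          paste(subjects[!present], collapse = ", "))
    subjects <- subjects[present]
  }
  vals <- vapply(subjects, function(s) {
    rows <- which(windowed$subject == s)
    mean(windowed$data[rows, vertex_ids])
  }, numeric(1))
  names(vals) <- subjects
  vals
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees of freedom;
#' |rho| = 1 gives p = 0.
#'
#' @param x,y paired numeric vectors, n >= 3, finite values.
#' @return list with `rho`, `p`, `n`, and `defined` (FALSE when either
#'   variable has zero variance, in which case `rho` and `p` are NA).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Correlation table of critical-region activity and clinical scores
#'
#' One Spearman test per (critical region, clinical score) pair over the
#' patient-group subjects. Cells are flagged at p < 0.05 without
#' multiple-testing correction.
#'
#' @param regions a `critical_regions` object.
#' @param windowed a `windowed_trials` object (patient trials included).
#' @param clinical data frame with a `subject` column and the seven score
#'   columns of [clinical_score_names()].
#' @return object of class `correlation_table`: list with `rho`, `p`
#'   (matrices regions x scores), `n`, `flagged` (logical matrix, p < 0.05),
#'   `activity` (region x subject matrix) and `regions`.
#' @export
build_correlation_table <- function(regions, windowed, clinical) {
  stopifnot(inherits(regions, "critical_regions"),
            inherits(windowed, "windowed_trials"))
  patients <- clinical$subject
  if (length(patients) < 3L) stop_("need at least 3 patient subjects")
  scores <- intersect(clinical_score_names(), names(clinical))
  keys <- names(regions$groups)

  act <- t(vapply(keys, function(k) {
    region_activity(windowed, regions$groups[[k]], subjects = patients)
  }, numeric(length(patients))))
  rownames(act) <- keys; colnames(act) <- patients

  rho <- p <- matrix(NA_real_, length(keys), length(scores),
                     dimnames = list(keys, scores))
  for (i in seq_along(keys)) {
    for (j in seq_along(scores)) {
      sp <- spearman_cor(act[i, ], clinical[[scores[j]]])
      rho[i, j] <- sp$rho
      p[i, j] <- sp$p
    }
  }
  structure(
    list(rho = rho, p = p, n = length(patients),
         flagged = !is.na(p) & p < 0.05,
         activity = act, regions = regions),
    class = "correlation_table"
  )
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat("Spearman correlations (n =", x$n, "patients); * p < 0.05\n")
  txt <- matrix(sprintf("%.*f%s", digits, x$rho,
                        ifelse(x$flagged, " *", "")),
                nrow(x$rho), dimnames = dimnames(x$rho))
  print(txt, quote = FALSE)
  invisible(x)
}

#' Write a correlation table to CSV
#'
#' Rows are hemisphere + region, columns the seven clinical scores in the
#' canonical order; significant cells (p < 0.05) carry a trailing `*`.
#'
#' @param x a `correlation_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_correlation_csv <- function(x, path) {
  stopifnot(inherits(x, "correlation_table"))
  df <- data.frame(region = rownames(x$rho),
                   matrix(sprintf("%.3f%s", x$rho,
                                  ifelse(x$flagged, " *", "")),
                          nrow(x$rho)),
                   stringsAsFactors = FALSE)
  names(df) <- c("region", colnames(x$rho))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
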