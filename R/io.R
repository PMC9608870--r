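# Stage artifact containers. Trial sets, source spaces, images and models
# are stored as native RDS containers; tabular outputs (clinical scores,
# fold results, correlation tables) as CSV; manifests as JSON.

#' Save / load a simulated dataset
#'
#' Bundles the source space, trial set and clinical table in one RDS
#' container.
#'
#' @param sim result of [generate_trials()].
#' @param space the `cortical_space` the trials were generated on.
#' @param path file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(sim, space, path) {
  saveRDS(list(space = space, trials = sim$trials, clinical = sim$clinical),
          path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Write the clinical table to CSV
#'
#' One row per patient subject; columns `subject` plus the seven clinical
#' scores in canonical order.
#'
#' @param clinical clinical data frame from [generate_trials()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(clinical, path) {
  cols <- c("subject", intersect(clinical_score_names(), names(clinical)))
  write.csv(clinical[, cols], path, row.names = FALSE)
  invisible(path)
}
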