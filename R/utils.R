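# Run expr with a private RNG stream; the caller's .Random.seed is left
# untouched, so identical seeds give byte-identical results regardless of
# surrounding RNG use.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

#' Drop rows with missing predictor values
#'
#' Complete-case filter used before model fitting: any row with a missing
#' value in the supplied columns (default: all columns) is removed and the
#' number of dropped rows recorded in the `n_dropped` attribute.
#'
#' @param data trial dataset.
#' @param columns columns that must be non-missing; defaults to all.
#' @return filtered data frame with attribute `n_dropped`.
#' @export
complete_cases <- function(data, columns = names(data)) {
  keep <- stats::complete.cases(data[columns])
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read / write a trial dataset as CSV
#'
#' Datasets are plain UTF-8 CSV with a header row: one column per covariate,
#' `arm` (0 standard / 1 intensive), and per-outcome `time_cvd`/`event_cvd`
#' and `time_sae`/`event_sae` pairs, times in years.
#'
#' @param data trial dataset.
#' @param path file path.
#' @return `read_trial_data` returns a data frame; `write_trial_data`
#'   returns `path` invisibly.
#' @export
write_trial_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
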