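# Internal helpers: classed conditions and seed derivation.

.datatable.aware <- TRUE

mi_stop <- function(kind, msg, ...) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("miclass_error_", kind), "miclass_error"),
    call = sys.call(-1)))
}

mi_warn <- function(kind, msg, ...) {
  warning(warningCondition(
    sprintf(msg, ...),
    class = c(paste0("miclass_warning_", kind), "miclass_warning"),
    call = sys.call(-1)))
}

#' Derive a per-stage seed from a global seed
#'
#' Stages of the pipeline draw their randomness from seeds derived
#' deterministically from one global seed and a stage counter, so any stage can
#' be re-run in isolation with the same stream. The derived seed is kept below
#' 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Stage counter (non-negative integer) or stage name known to the
#'   pipeline.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(simulate = 1, denoise = 2, scalogram = 3, tune = 4,
                train = 5, features = 6, classify = 7, evaluate = 8,
                split = 9)
    if (!stage %in% names(stages)) mi_stop("config", "unknown stage '%s'", stage)
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mi_stop("config", "%s must be a finite number", name)
  if (x < lower || x > upper)
    mi_stop("config", "%s = %g outside [%g, %g]", name, x, lower, upper)
  if (integer && x != round(x))
    mi_stop("config", "%s must be an integer", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
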