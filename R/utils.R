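# Shared internal helpers: task-label coding, local RNG scoping, validation.

# Canonical class order everywhere: RHT = code 0, LHT = 1, FT = 2.
TASK_LEVELS <- c("RHT", "LHT", "FT")

#' Task labels for the three motor conditions
#'
#' Converts a character/integer/factor vector into the canonical task-label
#' factor with levels `RHT`, `LHT`, `FT` (right-hand tap, left-hand tap,
#' foot tap). Integer input uses the stable codes 0/1/2 for RHT/LHT/FT.
#'
#' @param x character, factor, or integer codes 0:2.
#' @return factor with levels `c("RHT", "LHT", "FT")`.
#' @export
#' @examples
#' task_label(c("RHT", "FT"))
#' task_label(0:2)
task_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(!x %in% 0:2)) stop("integer task codes must be 0, 1 or 2", call. = FALSE)
    x <- TASK_LEVELS[x + 1L]
  }
  bad <- setdiff(unique(x), TASK_LEVELS)
  if (length(bad) > 0) {
    stop("unknown task label(s): ", paste(bad, collapse = ", "),
         " (expected RHT, LHT or FT)", call. = FALSE)
  }
  factor(x, levels = TASK_LEVELS)
}

#' Integer codes of task labels
#' @param x anything `task_label()` accepts.
#' @return integer vector of codes 0/1/2.
#' @export
task_code <- function(x) as.integer(task_label(x)) - 1L

# Evaluate expr with a local, seeded RNG stream; the caller's RNG state is
# untouched. All stochastic package internals go through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage tag, staying < 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103515245 + h) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
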