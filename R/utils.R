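`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seed through here so
# that no function disturbs the global random state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < 1e-8
}

#' Timestamped structured log line
#'
#' Writes a single `[timestamp] LEVEL stage: message` line to the message
#' stream. Pipeline stages use this to surface progress and clamp warnings;
#' nothing is emitted for `level = "error"` free runs unless called.
#'
#' @param stage Character, name of the pipeline stage.
#' @param level One of `"info"`, `"warning"`, `"error"`.
#' @param message Character, the log message.
#' @return Invisibly, the formatted line.
#' @export
log_event <- function(stage, level = c("info", "warning", "error"), message) {
  level <- match.arg(level)
  line <- sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(level), stage, message)
  base::message(line)
  invisible(line)
}
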