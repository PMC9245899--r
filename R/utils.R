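#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores the caller's RNG stream afterwards so simulation helpers do not
# perturb user code. `seed = NULL` evaluates in the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a global seed and a stage name
#'
#' Stable string hash so that pipeline stages re-run in isolation see the
#' same stream as in a full run. Result is a positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h + 1) %% 2147480009 + 1)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf <- function(...) message(sprintf(...))

# Full-precision numeric formatting so TSV round-trips are bit-identical.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
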