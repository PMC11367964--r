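#' @keywords internal
"_PACKAGE"

#' @useDynLib replanar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix crossprod t
#' @importFrom stats rpois runif rbinom cor.test lm coef pt quantile sd
#' @importFrom utils write.csv read.csv
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards, so seeded stages never perturb each other.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Deterministic per-stage / per-subject seed derivation from one master seed.
## Arithmetic kept inside 2^31 so the result is a valid R integer seed.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  code <- sum(utf8ToInt(as.character(stage)))
  s <- (abs(master) %% 1000003) * 1009 + code * 131071 + index * 7919
  as.integer(s %% 2147483123 + 1)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}
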