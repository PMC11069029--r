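#' @keywords internal
"_PACKAGE"

#' @useDynLib oscidiff, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rpois rlnorm sd var qnorm pnorm pt
#'   fft mvfft quantile aov median complete.cases cor p.adjust t.test rexp
#'   aggregate
#' @importFrom utils read.csv write.csv head combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  seed = NULL runs under the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit polynomial rolling hash over a serialized object; provenance
# hashing for run manifests (not cryptographic).
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp cosines into [-1, 1] without losing matrix dimensions
clamp_cos <- function(m) {
  m[m > 1] <- 1
  m[m < -1] <- -1
  m
}

stop_param <- function(...) {
  stop(structure(class = c("oscidiff_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x))
    stop_param(name, " must be a positive integer, got ", deparse(x))
  as.integer(x)
}
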