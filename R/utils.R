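#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif approx fft mvfft runmed median sd
#' @importFrom utils head tail modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored afterwards. seed = NULL leaves the
# global stream untouched (draws advance it as usual).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash of an R object's serialization, as 8 hex
# characters. Used to stamp checkpoints and run manifests with their
# config; not cryptographic.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) {
    h <- (h * 31 + b + 1) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s", name, lower))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %s", name, upper))
  invisible(x)
}

is_scalar_int <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
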