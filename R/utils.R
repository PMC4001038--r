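# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic component draws from its own stream keyed by a fixed label,
#' so that e.g. regenerating the microarray noise does not perturb the genome.
#' The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 7919L
  as.integer((abs(as.numeric(master)) * 8191 + h * 131) %% 2147483647)
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Running median over a centered window of `w` elements; windows are truncated
# at the edges (no padding, no reflection), so the edge estimate uses fewer
# points but stays a genuine median of observed neighbours.
running_median <- function(x, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# Mode of a numeric vector, estimated as the argmax of a Gaussian kernel
# density on a 512-point grid (Silverman's rule-of-thumb bandwidth).
kde_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || stats::sd(x) == 0) return(stats::median(x))
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tn <- function(...) stop(sprintf(...), call. = FALSE)
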