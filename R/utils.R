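#' Derive a reproducible sub-seed from a master seed and a purpose label
#'
#' All randomness in the package flows through sub-streams derived from one
#' master seed, so that unrelated components (data shuffling, noise draws,
#' sampler noise, phantom rendering) do not perturb each other's streams when
#' one of them changes size.
#'
#' The derivation is a plain polynomial string hash reduced modulo a prime
#' below 2^31; it is deterministic across platforms and always yields a valid
#' `set.seed()` argument.
#'
#' @param master integer master seed.
#' @param purpose character scalar naming the consuming component, e.g.
#'   `"epoch-3-shuffle"`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "sampler-noise")
derive_seed <- function(master, purpose) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(purpose), length(purpose) == 1L)
  p <- 2147483629 # prime < 2^31
  h <- (as.numeric(master) %% p + p) %% p
  for (b in as.integer(charToRaw(purpose))) {
    h <- (h * 131 + b) %% p
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Structured key=value logging on stderr via message(); suppressible with
# suppressMessages().
log_info <- function(op, ...) {
  kv <- list(...)
  if (length(kv)) {
    vals <- vapply(kv, function(v) paste(format(v, digits = 6), collapse = ","),
                   character(1))
    tail <- paste(names(kv), vals, sep = "=", collapse = " ")
    message(sprintf("level=INFO op=%s %s", op, tail))
  } else {
    message(sprintf("level=INFO op=%s", op))
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# largest group count <= 8 dividing the channel count (group normalization)
gn_groups <- function(channels) {
  for (g in 8:1) if (channels %% g == 0L) return(g)
  1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
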