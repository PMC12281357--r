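# internal helpers shared across modules

# Run `expr` with a private RNG stream seeded by `seed`, restoring the global
# state afterwards so package functions never clobber a user's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# longest run of TRUE in a logical vector (0 if none)
max_run <- function(x) {
  x <- as.logical(x)
  if (!any(x, na.rm = TRUE)) return(0L)
  r <- rle(ifelse(is.na(x), FALSE, x))
  max(r$lengths[r$values])
}

# Spearman correlation that tolerates <3 pairs or zero variance (returns NA)
spearman_safe <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

# inverse of trigamma by Newton iteration on 1/x scale (monotone, stable)
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
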