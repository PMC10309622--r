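# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(paste0("domain error: ", ...), call. = FALSE)
}

stop_structural <- function(...) {
  stop(paste0("structural error: ", ...), call. = FALSE)
}

stop_config <- function(...) {
  stop(paste0("configuration error: ", ...), call. = FALSE)
}

# positivity check for scalar or vector numeric arguments
check_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    (if (allow_zero) all(x >= 0) else all(x > 0))
  if (!ok) {
    stop_domain(sprintf("`%s` must be %s and finite", name,
                        if (allow_zero) "non-negative" else "strictly positive"))
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a finite numeric scalar", name))
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Pre-factored tridiagonal (Thomas) solver.  The Graetz marching scheme
# re-solves the same matrix at every axial step, so the elimination
# coefficients are computed once.
thomas_factor <- function(lower, diag, upper) {
  n <- length(diag)
  cp <- numeric(n)
  dn <- numeric(n) # denominators
  cp[1] <- upper[1] / diag[1]
  dn[1] <- diag[1]
  if (n > 1) {
    for (j in 2:n) {
      dn[j] <- diag[j] - lower[j] * cp[j - 1]
      cp[j] <- if (j < n) upper[j] / dn[j] else 0
    }
  }
  list(lower = lower, cp = cp, dn = dn, n = n)
}

thomas_solve <- function(fac, rhs) {
  n <- fac$n
  g <- numeric(n)
  g[1] <- rhs[1] / fac$dn[1]
  if (n > 1) {
    for (j in 2:n) {
      g[j] <- (rhs[j] - fac$lower[j] * g[j - 1]) / fac$dn[j]
    }
    for (j in (n - 1):1) {
      g[j] <- g[j] - fac$cp[j] * g[j + 1]
    }
  }
  g
}

# full-precision numeric formatting for text round-trips
format_full <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
}
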