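# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Evaluate `code` under set.seed(seed) and restore the caller's RNG state,
# so each generator draws from its own independent stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Row variances with denominator n-1; rows with n < 2 give NA.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# Vectorized two-sided two-sample pooled-variance Student's t-test on the
# rows of two matrices (groups in columns). Degenerate rows (zero pooled
# variance) give p = 1 when the means agree, p = 0 otherwise.
row_t_test <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  sp2 <- ((na - 1L) * row_vars(xa) + (nb - 1L) * row_vars(xb)) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(tt), df = na + nb - 2L)
  degen <- se == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  tt[degen & ma == mb] <- 0
  list(estimate = mb - ma, statistic = tt, p = p, df = na + nb - 2L)
}
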