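# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of `n` units to `fractions`.
quota_counts <- function(fractions, n) {
  raw <- fractions * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

check_row_stochastic <- function(m, tol = 1e-9) {
  if (any(m < -tol) || any(abs(rowSums(m) - 1) > tol))
    stop("matrix is not row-stochastic", call. = FALSE)
  invisible(m)
}
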