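# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic 31-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 100003 +
                as.numeric(index) * 7919) %% 2147483629) + 1L
}

# Truncated-normal draws by inverse-CDF, exact at the stated bounds.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  deg <- sd == 0
  out[deg] <- pmin(pmax(mean[deg], lower), upper)
  if (any(!deg)) {
    m <- mean[!deg]; s <- sd[!deg]
    plo <- stats::pnorm(lower, m, s)
    phi <- stats::pnorm(upper, m, s)
    u <- stats::runif(sum(!deg), plo, phi)
    out[!deg] <- stats::qnorm(u, m, s)
  }
  pmin(pmax(out, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
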