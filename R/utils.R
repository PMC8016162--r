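# Internal helpers shared across modules.

# Wrap angles (degrees) into (-180, 180]; exact -180 maps to +180.
wrap_deg <- function(a) 180 - ((180 - a) %% 360)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched. seed = NULL uses the current
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Von Mises sampler (Best & Fisher 1979 rejection scheme), vectorised.
# mu in degrees, kappa >= 0; returns degrees in (-180, 180].
rvonmises_deg <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_deg(stats::runif(n, -180, 180) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    m <- length(need)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[need[ok]] <- theta
      need <- need[!ok]
    }
  }
  wrap_deg(rad2deg(out) + mu)
}

# Strong connectivity of the jump graph of a rate matrix (off-diagonal
# positive entries are edges).
ctmc_is_irreducible <- function(Q) {
  k <- nrow(Q)
  if (k == 1L) return(TRUE)
  adj <- (Q > 0) & !diag(TRUE, k)
  reach <- adj | diag(TRUE, k)
  for (i in seq_len(k)) {           # Floyd-Warshall style closure
    reach <- reach | (reach[, i] %o% reach[i, ] > 0)
  }
  all(reach) && all(t(reach))
}

# Stationary distribution of an irreducible CTMC rate matrix.
ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat / sum(pi_hat)
}

# Sample a continuous-time Markov jump path on [0, horizon] and return
# the state index at each requested time. Uses the current RNG stream.
ctmc_sample_path <- function(Q, init_state, times) {
  k <- nrow(Q)
  horizon <- max(times)
  jump_t <- 0
  s <- init_state
  jump_times <- 0
  jump_states <- s
  while (jump_t < horizon) {
    rate <- -Q[s, s]
    if (rate <= 0) break                     # absorbing (guarded upstream)
    jump_t <- jump_t + stats::rexp(1, rate)
    if (jump_t >= horizon) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(k, 1L, prob = probs)
    jump_times <- c(jump_times, jump_t)
    jump_states <- c(jump_states, s)
  }
  jump_states[findInterval(times, jump_times)]
}

# Round half away from zero to `digits` decimals (report formatting).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# FNV-1a hash of a character scalar, as 8 hex digits (config fingerprints).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply by 16777619 in double precision: split h to
    # keep intermediate products exactly representable
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  # h may exceed .Machine$integer.max, so format in two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
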