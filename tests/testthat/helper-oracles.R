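# Independent brute-force oracles used to validate the package's
# implementations on small fixtures. These deliberately share no code with
# the package: literal loops, direct likelihood evaluation, hand-rolled
# Kaplan-Meier.

# Log partial likelihood (Breslow ties) evaluated directly from its
# definition, for a single covariate.
oracle_log_pl <- function(beta, x, time, event) {
  ll <- 0
  for (j in which(event == 1)) {
    risk <- which(time >= time[j])
    ll <- ll + beta * x[j] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximize the log partial likelihood over a 1-d grid + golden section.
oracle_cox_beta <- function(x, time, event, interval = c(-20, 20)) {
  optimize(function(b) oracle_log_pl(b, x, time, event),
           interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Harrell C by exhaustive pair enumeration (no tied times in fixtures).
oracle_c_index <- function(pi, time, event) {
  num <- den <- 0
  n <- length(pi)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    short <- if (time[i] < time[j]) i else j
    long <- if (time[i] < time[j]) j else i
    if (event[short] != 1) next              # censored first: unusable
    den <- den + 1
    if (pi[short] > pi[long]) num <- num + 1
    else if (pi[short] == pi[long]) num <- num + 0.5
  }
  num / den
}

# Gonen-Heller CPE by literal double loop over ordered pairs.
oracle_cpe <- function(beta, x) {
  lp <- as.vector(x %*% beta)
  n <- length(lp)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- lp[j] - lp[i]
    s <- s + (d <= 0) / (1 + exp(d)) + (-d < 0) / (1 + exp(-d))
  }
  2 * s / (n * (n - 1))
}

# Hand-rolled Kaplan-Meier survival estimate as a step lookup.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    d <- sum(time == ut[k] & event == 1)
    r <- sum(time >= ut[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  function(t) {
    out <- numeric(length(t))
    for (i in seq_along(t)) {
      idx <- which(ut <= t[i])
      out[i] <- if (length(idx)) surv[max(idx)] else 1
    }
    out
  }
}

# IPCW Brier score at one time by literal summation (Graf weights).
oracle_brier_t <- function(t, p, time, event) {
  G <- oracle_km(time, 1 - event)
  n <- length(time)
  s <- 0
  for (i in seq_len(n)) {
    if (time[i] <= t && event[i] == 1) {
      w <- 1 / G(time[i] - 1e-12)
      s <- s + w * (p[i] - 0)^2
    } else if (time[i] > t) {
      w <- 1 / G(t)
      s <- s + w * (p[i] - 1)^2
    }
  }
  s / n
}

# Integrated Brier score: trapezoid over (0, grid), normalized by tau.
oracle_ibs <- function(p_mat, grid, time, event) {
  bs <- vapply(seq_along(grid),
               function(j) oracle_brier_t(grid[j], p_mat[, j], time, event),
               numeric(1))
  g <- c(0, grid); v <- c(0, bs)
  total <- 0
  for (k in seq_len(length(g) - 1))
    total <- total + (g[k + 1] - g[k]) * (v[k] + v[k + 1]) / 2
  total / max(grid)
}

# Small censored survival fixture with distinct times (deterministic).
toy_surv <- function() {
  list(time = c(2.1, 3.7, 1.4, 5.9, 4.2, 7.5, 0.8, 6.3),
       event = c(1, 0, 1, 1, 0, 1, 1, 0),
       pi = c(1.4, 0.2, 2.8, -0.7, 0.9, -1.5, 2.2, -0.3))
}
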