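# Independent brute-force oracles. Everything here is written as plain
# nested loops / full enumeration, deliberately not sharing code with the
# package implementations it checks.

oracle_is <- function(x, p = 24) {
  n <- length(x)
  d <- n / p
  xbar <- mean(x)
  tmpl <- numeric(p)
  for (h in seq_len(p)) {
    acc <- 0
    for (day in seq_len(d)) acc <- acc + x[(day - 1) * p + h]
    tmpl[h] <- acc / d
  }
  num <- 0
  for (h in seq_len(p)) num <- num + (tmpl[h] - xbar)^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  (n * num) / (p * den)
}

oracle_iv <- function(x) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  (n * num) / ((n - 1) * den)
}

# exhaustive scan of all fully-contained windows of one 1440-minute day
oracle_m10_l5 <- function(day) {
  stopifnot(length(day) == 1440)
  best10 <- -Inf; on10 <- NA
  for (s in 1:(1440 - 600 + 1)) {
    m <- mean(day[s:(s + 599)])
    if (m > best10) { best10 <- m; on10 <- s - 1 }
  }
  best5 <- Inf; on5 <- NA
  for (s in 1:(1440 - 300 + 1)) {
    m <- mean(day[s:(s + 299)])
    if (m < best5) { best5 <- m; on5 <- s - 1 }
  }
  list(m10 = best10, m10_onset = on10, l5 = best5, l5_onset = on5)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  stopifnot(!anyDuplicated(pool))
  r <- rank(pool)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  min(1, p)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# exact two-sided Spearman p over all n! pairings
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(all_perms(seq_along(y)), function(p) cor(rx, ry[p]), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# two-sided Fisher exact p for a 2x2 table by the point-probability rule
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); tot <- sum(tab)
  lo <- max(0, r1 + c1 - tot); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, tot - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, tot - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# epoch tibble from a bare count vector (whole days, from midnight UTC)
make_epochs <- function(counts, start = as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) {
  tibble::tibble(time = start + 60 * (seq_along(counts) - 1), counts = counts)
}
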