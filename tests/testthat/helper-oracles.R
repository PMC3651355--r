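# Independent brute-force oracles and small fixture builders used
# across the suite.  Each oracle recomputes the quantity from its
# definition with plain loops, never through the package's own code
# path.

random_matrix <- function(n_features, n_samples, seed = 1) {
  set.seed(seed)
  vals <- matrix(rlnorm(n_features * n_samples, log(500), 1.5),
                 n_features, n_samples,
                 dimnames = list(sprintf("p%03d", seq_len(n_features)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(vals)
}

random_chip <- function(n, seed = 1, meanlog = log(500), sdlog = 1.8) {
  set.seed(seed)
  v <- rlnorm(n, meanlog, sdlog)
  names(v) <- sprintf("p%05d", seq_len(n))
  v
}

# RMSD by direct loop
oracle_rmsd <- function(a, b, keep = seq_along(a)) {
  total <- 0
  for (i in keep) total <- total + (log2(a[[i]]) - log2(b[[i]]))^2
  sqrt(total / length(keep))
}

# density weights by nested loops over all windows
oracle_density_weights <- function(a, frac = 0.01, expo = 4) {
  n <- length(a)
  w <- max(2, round(frac * n))
  nw <- n - w + 1
  sds <- vapply(seq_len(nw), function(i) sd(a[i:(i + w - 1)]), numeric(1))
  vapply(seq_len(n), function(j) {
    ids <- max(1, j - w + 1):min(j, nw)
    mean(sds[ids])^expo
  }, numeric(1))
}

# sliding-window WLS fit by direct per-window closed form
oracle_fit_correction <- function(x, y, wts, frac = 0.10) {
  n <- length(x)
  A <- x + y; M <- x - y
  w2 <- max(3, round(frac * n))
  nw <- n - w2 + 1
  sl <- numeric(nw); ic <- numeric(nw)
  for (i in seq_len(nw)) {
    id <- i:(i + w2 - 1); w <- wts[id]
    am <- sum(w * A[id]) / sum(w)
    mm <- sum(w * M[id]) / sum(w)
    den <- sum(w * (A[id] - am)^2)
    sl[i] <- if (den > 0) sum(w * (A[id] - am) * (M[id] - mm)) / den else 0
    ic[i] <- mm - sl[i] * am
  }
  vapply(seq_len(n), function(j) {
    ids <- max(1, j - w2 + 1):min(j, nw)
    mean(sl[ids]) * A[j] + mean(ic[ids])
  }, numeric(1))
}

# one-step biweight evaluated directly from its definition
oracle_biweight <- function(v, cc = 5, eps = 1e-4) {
  if (length(v) == 1) return(v)
  M <- median(v)
  S <- median(abs(v - M))
  u <- (v - M) / (cc * S + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) M else sum(w * v) / sum(w)
}

# E[signal | observed] by numerical integration of the
# normal + exponential convolution
oracle_conditional_signal <- function(o, mu, sigma, alpha) {
  vapply(o, function(oo) {
    lo <- max(0, oo - mu - 12 * sigma)
    hi <- max(oo - mu + 12 * sigma, lo + 4 * sigma)
    num <- integrate(function(s) s * dexp(s, alpha) * dnorm(oo - s, mu, sigma),
                     lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
    den <- integrate(function(s) dexp(s, alpha) * dnorm(oo - s, mu, sigma),
                     lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
    num / den
  }, numeric(1))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
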