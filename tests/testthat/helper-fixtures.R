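# Shared fixtures and independent brute-force oracles.

make_exp <- function(counts, time, condition = NULL, replicate = NULL,
                     ...) {
  n <- ncol(counts)
  if (is.null(condition)) condition <- rep("A", n)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n), paste(time, condition),
                            FUN = seq_along)
  }
  tse(counts, time = time, condition = condition,
      replicate = replicate, ...)
}

# one condition, m time points, single replicate
single_series_exp <- function(values_by_gene, times) {
  counts <- do.call(rbind, values_by_gene)
  rownames(counts) <- names(values_by_gene)
  colnames(counts) <- paste0("s", seq_along(times))
  make_exp(counts, time = times)
}

# step-up FDR recursion, written independently of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Eq-style double loop for the lag-k residual autocorrelation
acf_oracle <- function(r, k, sigma2) {
  m <- length(r)
  total <- 0
  for (j in 1:(m - k)) total <- total + r[j] * r[j + k]
  total / ((m - k) * sigma2)
}

# two-sided Fisher p by full enumeration of the hypergeometric support
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# exhaustive path-sum HMM posteriors / loglik / viterbi for small S^m
hmm_enum_oracle <- function(logB, A, pi0) {
  m <- nrow(logB); S <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  logp <- apply(paths, 1L, function(s) {
    lp <- log(pi0[s[1]]) + logB[1, s[1]]
    if (m > 1) for (t in 2:m)
      lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    lp
  })
  w <- exp(logp - max(logp))
  post <- sapply(seq_len(S), function(k)
    sapply(seq_len(m), function(t) sum(w[paths[, t] == k]) / sum(w)))
  list(posterior = post,
       loglik = log(sum(w)) + max(logp),
       viterbi = paths[which.max(logp), ])
}

# nested-regression Granger F via explicit lm fits
granger_oracle <- function(x, y, lag) {
  n <- length(x)
  resp <- x[(lag + 1):n]
  own <- sapply(seq_len(lag), function(l) x[(lag + 1 - l):(n - l)])
  oth <- sapply(seq_len(lag), function(l) y[(lag + 1 - l):(n - l)])
  r <- stats::lm(resp ~ own)
  f <- stats::lm(resp ~ own + oth)
  rss_r <- sum(stats::resid(r)^2); rss_f <- sum(stats::resid(f)^2)
  df2 <- length(resp) - (2 * lag + 1)
  Fs <- ((rss_r - rss_f) / lag) / (rss_f / df2)
  list(F = Fs, p = stats::pf(Fs, lag, df2, lower.tail = FALSE))
}
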