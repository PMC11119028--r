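# Brute-force transfer-entropy oracle: direct sum of p * log-ratio over all
# observed (past, past, next) triples, built from base-R tables. Independent
# of the package's block-entropy path.
brute_te <- function(x, y, k) {
  n <- length(x) - k
  xp <- vapply(seq_len(n), function(i) paste(x[i:(i + k - 1)], collapse = ""),
               character(1))
  yp <- vapply(seq_len(n), function(i) paste(y[i:(i + k - 1)], collapse = ""),
               character(1))
  y0 <- vapply(seq_len(n), function(i) as.character(y[i + k]), character(1))
  tab <- table(xp, yp, y0) / n
  pxy <- apply(tab, c(1, 2), sum)  # p(x past, y past)
  pyy <- apply(tab, c(2, 3), sum)  # p(y past, y next)
  py <- apply(tab, 2, sum)         # p(y past)
  tot <- 0
  for (a in dimnames(tab)$xp) {
    for (b in dimnames(tab)$yp) {
      for (c0 in dimnames(tab)$y0) {
        p <- tab[a, b, c0]
        if (p > 0) {
          tot <- tot + p * log((p / pxy[a, b]) / (pyy[b, c0] / py[b]))
        }
      }
    }
  }
  unname(tot)
}

# random 0/1 pair with some cross- and auto-dependence, for property sweeps
random_dependent_pair <- function(n, k, coupling = 0.5) {
  x <- rbinom(n + k, 1, 0.5)
  y <- integer(n + k)
  y[1] <- rbinom(1, 1, 0.5)
  for (i in 2:(n + k)) {
    p <- 0.3 + 0.2 * y[i - 1] + coupling * 0.3 * x[i - 1]
    y[i] <- rbinom(1, 1, min(max(p, 0.05), 0.95))
  }
  tibble::tibble(x = as.integer(x), y = as.integer(y))
}

# k = 1 kernel of the copy chain: x iid Bernoulli(1/2), y_t = x_{t-1}
copy_chain_kernel <- function() {
  prob <- matrix(0, 4, 4)
  for (cx in 0:1) {
    for (cy in 0:1) {
      s <- cx * 2 + cy + 1
      for (x0 in 0:1) {
        y0 <- cx  # y copies the source's previous symbol
        prob[s, 2 * x0 + y0 + 1] <- 0.5
      }
    }
  }
  spiketer::vlmc_kernel(prob, k = 1)
}

# k = 1 product kernel of two independent iid Bernoulli chains
product_kernel <- function(px = 0.5, py = 0.5) {
  row <- c((1 - px) * (1 - py), (1 - px) * py, px * (1 - py), px * py)
  spiketer::vlmc_kernel(matrix(row, 4, 4, byrow = TRUE), k = 1)
}

# Monte-Carlo standard error of a mean with serial dependence (batch means)
batch_se <- function(v, batches = 100) {
  g <- ceiling(seq_along(v) * batches / length(v))
  m <- tapply(v, g, mean)
  sqrt(var(m) / length(m))
}
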