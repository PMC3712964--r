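# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementations they check.

# Exact HWE p-values via the heterozygote-count recurrence
# P(h+2)/P(h) = 4 nAA nBB / ((h+2)(h+1)), normalized by summation.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na_ <- 2 * n_hom_ref + n_het
  m <- min(na_, 2 * n - na_)
  hs <- seq.int(m %% 2, min(m, 2 * n - m), by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      a <- (m - h) / 2
      b <- n - (m + h) / 2
      probs[i + 1] <- probs[i] * 4 * a * b / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  pobs <- probs[match(n_het, hs)]
  min(sum(probs[probs <= pobs * (1 + 1e-9)]), 1)
}

# hwe_oracle p-values for every admissible heterozygote count given
# (n, minor allele count); returns data.frame(h, p)
hwe_oracle_all <- function(n, m) {
  hs <- seq.int(m %% 2, min(m, 2 * n - m), by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      a <- (m - h) / 2
      b <- n - (m + h) / 2
      probs[i + 1] <- probs[i] * 4 * a * b / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  s <- sort(probs)
  cs <- cumsum(s)
  pv <- pmin(cs[findInterval(probs * (1 + 1e-9), s)], 1)
  data.frame(h = hs, p = pv)
}

# Brute-force posterior donor probabilities by enumerating all H^L copying
# paths of the Li-Stephens chain.
fb_enum_oracle <- function(alleles, obs, no_switch, lambda) {
  H <- nrow(alleles)
  L <- ncol(alleles)
  E <- matrix(1, H, L)
  for (l in seq_len(L)) {
    o <- obs[l]
    if (is.na(o)) next
    for (k in seq_len(H)) {
      a <- alleles[k, l]
      E[k, l] <- if (is.na(a)) 0.5 else if (a == o) 1 - lambda else lambda
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))
  pr <- rep(1 / H, nrow(paths)) * E[cbind(paths[, 1], 1)]
  for (l in seq_len(L)[-1]) {
    p <- no_switch[l - 1]
    tr <- ifelse(paths[, l - 1] == paths[, l], p + (1 - p) / H, (1 - p) / H)
    pr <- pr * tr * E[cbind(paths[, l], l)]
  }
  post <- matrix(0, H, L)
  for (l in seq_len(L)) {
    tot <- tapply(pr, factor(paths[, l], levels = seq_len(H)), sum)
    tot[is.na(tot)] <- 0
    post[, l] <- tot
  }
  sweep(post, 2, colSums(post), "/")
}

# Direct sum-formula squared Pearson correlation (textbook oracle)
r2_formula_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}
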