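#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on a biallelic genotype count triple.
#' Given the total sample size and allele counts, the heterozygote count
#' follows an exact conditional distribution; the p-value is the total
#' probability mass of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Vectorized over triples;
#' triples sharing (sample size, minor allele count) reuse one enumeration
#' of the conditional distribution.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (recycled to a common
#'   length). All must be non-negative with positive totals.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)   # HWE-proportional counts: large p
#' hwe_exact_test(50, 0, 50)    # total heterozygote deficit: tiny p
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  k <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  naa <- rep_len(as.numeric(n_hom_ref), k)
  nab <- rep_len(as.numeric(n_het), k)
  nbb <- rep_len(as.numeric(n_hom_alt), k)
  cnt <- c(naa, nab, nbb)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("genotype counts must be non-negative integers")
  n <- naa + nab + nbb
  if (any(n < 1)) stop("total genotype count must be >= 1")

  m <- pmin(2 * naa + nab, 2 * nbb + nab)  # minor allele count
  out <- numeric(k)
  key <- paste(n, m)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    ni <- n[idx[1]]
    mi <- m[idx[1]]
    hs <- seq.int(mi %% 2, min(mi, 2 * ni - mi), by = 2)
    # log conditional probability of each admissible heterozygote count
    lp <- lfactorial(ni) - lfactorial((mi - hs) / 2) - lfactorial(hs) -
      lfactorial(ni - (mi + hs) / 2) + hs * log(2) +
      lfactorial(mi) + lfactorial(2 * ni - mi) - lfactorial(2 * ni)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    s <- sort(p)
    cs <- cumsum(s)
    pobs <- p[match(nab[idx], hs)]
    # mass of outcomes no more probable than the observed one; the small
    # relative tolerance keeps exact probability ties together in floats
    pv <- cs[findInterval(pobs * (1 + 1e-9), s)]
    out[idx] <- pmin(pv, 1)
  }
  out
}
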