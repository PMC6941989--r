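# Independent brute-force oracles. Each is coded directly from the
# defining formulas, separately from the package implementation, and is
# deliberately slow and literal.

# Weir-Cockerham variance components for one site, two diploid samples
oracle_wc_site <- function(geno1, geno2) {
  g1 <- geno1[!is.na(geno1)]; g2 <- geno2[!is.na(geno2)]
  r <- 2
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# ratio-of-sums F_ST over a set of sites
oracle_wc_fst <- function(m1, m2) {
  num <- den <- 0
  for (j in seq_len(ncol(m1))) {
    g1 <- m1[, j]; g2 <- m2[, j]
    if (sum(!is.na(g1)) < 2 || sum(!is.na(g2)) < 2) next
    p1 <- sum(g1, na.rm = TRUE) / (2 * sum(!is.na(g1)))
    p2 <- sum(g2, na.rm = TRUE) / (2 * sum(!is.na(g2)))
    pbar <- (p1 * sum(!is.na(g1)) + p2 * sum(!is.na(g2))) /
      (sum(!is.na(g1)) + sum(!is.na(g2)))
    if (is.na(pbar) || pbar == 0 || pbar == 1) next
    comp <- oracle_wc_site(g1, g2)
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  unname(num / den)
}

# Tajima's D from a haplotype 0/1 matrix by direct summation
oracle_tajima <- function(H) {
  n <- nrow(H)
  freqs <- colSums(H)
  seg <- freqs > 0 & freqs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # mean pairwise differences by explicit pair enumeration
  pi <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi <- pi + sum(H[i, ] != H[j, ])
  pi <- pi / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Benjamini-Hochberg step-up by explicit sort-and-cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, rs[1], rs[2], cs[1])
  p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# D, D', r2 from explicit haplotype counts
oracle_ld <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pAB <- nAB / n
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# maximal-scoring subarray by O(n^2) enumeration
oracle_max_subarray <- function(x) {
  best <- 0; bs <- 0; be <- -1
  for (i in seq_along(x)) for (j in i:length(x)) {
    s <- sum(x[i:j])
    if (s > best) { best <- s; bs <- i; be <- j }
  }
  list(start = bs, end = be, score = best)
}

# haplotypes over site blocks realizing a chosen additive quartet metric:
# ((A,B),(C,D)) with external branches ea, eb, ec, ed and internal m,
# in units of derived-site counts over n_sites columns
oracle_additive_quartet <- function(ea, eb, ec, ed, m) {
  n_sites <- ea + eb + ec + ed + m
  H <- matrix(0L, 4, n_sites,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  off <- 0
  put <- function(rows, k) {
    if (k > 0) H[rows, off + seq_len(k)] <<- 1L
    off <<- off + k
  }
  put("A", ea); put("B", eb); put("C", ec); put("D", ed)
  put(c("A", "B"), m)   # internal edge: sites shared by the (A,B) side
  list(H = H, n_sites = n_sites,
       d = matrix(c(0, ea + eb, ea + m + ec, ea + m + ed,
                    ea + eb, 0, eb + m + ec, eb + m + ed,
                    ea + m + ec, eb + m + ec, 0, ec + ed,
                    ea + m + ed, eb + m + ed, ec + ed, 0) / n_sites,
                  4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D"))))
}
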