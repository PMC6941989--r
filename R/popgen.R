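#' Per-site Weir-Cockerham variance components
#'
#' Computes the among-population (a), among-individual-within-population
#' (b), and within-individual (c) variance components of the
#' Weir-Cockerham F_ST estimator for two populations of diploids, per
#' site. Missing calls are excluded site-wise.
#'
#' @param g a `genotype_matrix`
#' @param pop1,pop2 individual ids of the two populations
#' @param site_idx optional site subset (default all)
#' @return a tibble with columns `site`, `a`, `b`, `c`, `usable`
#' @export
wc_components <- function(g, pop1, pop2, site_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(ncol(g$calls))
  m1 <- g$calls[pop1, site_idx, drop = FALSE]
  m2 <- g$calls[pop2, site_idx, drop = FALSE]
  r <- 2
  n1 <- colSums(!is.na(m1)); n2 <- colSums(!is.na(m2))
  p1 <- colSums(m1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(m2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(m1 == 1L, na.rm = TRUE)
  h2 <- colMeans(m2 == 1L, na.rm = TRUE)

  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  tibble(site = site_idx, a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Per window, the weighted (ratio-of-sums) estimator
#' \eqn{\sum a / \sum (a+b+c)} over the usable sites in the window — the
#' convention of VCFtools' windowed "weighted" F_ST. Sites monomorphic
#' across both populations contribute nothing; windows with zero usable
#' sites are flagged undefined (`NA`), never reported as 0. Negative
#' estimates are reported as computed, not clamped.
#'
#' @param g a `genotype_matrix`
#' @param pop1,pop2 individual ids of the two populations
#' @param windows a window tibble (see [make_windows()])
#' @return the window tibble with columns `n_used` and `value` (F_ST)
#' @export
fst_windows <- function(g, pop1, pop2, windows) {
  comp <- wc_components(g, pop1, pop2)
  wid <- site_window_map(g, windows)
  ok <- comp$usable & !is.na(wid)
  num <- den <- rep(0, nrow(windows))
  cnt <- rep(0L, nrow(windows))
  if (any(ok)) {
    w <- wid[ok]
    num <- num + as.vector(tapply2(comp$a[ok], w, nrow(windows)))
    den <- den + as.vector(tapply2(comp$a[ok] + comp$b[ok] + comp$c[ok], w,
                                   nrow(windows)))
    cnt <- cnt + as.vector(tapply2(rep(1L, sum(ok)), w, nrow(windows)))
  }
  value <- ifelse(cnt > 0 & den != 0, num / den, NA_real_)
  dplyr::bind_cols(windows, tibble(n_used = cnt, value = value))
}

# grouped sum over a fixed number of bins
#' @noRd
tapply2 <- function(x, bin, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, group = bin)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Tajima normalization constants
#'
#' The standard constants for `n` sampled haplotypes:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`, and the derived
#' `b1, b2, c1, c2, e1, e2` used in the variance of `pi - S/a1`.
#'
#' @param n haplotype count (>= 4)
#' @return a named list of constants
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` per window, computed from
#' dosages by treating each individual as two haplotypes. `pi` uses the
#' allele-frequency formula with the `n/(n-1)` unbiased correction, so it
#' is robust to unphased input. Windows with `S = 0` are undefined (`NA`)
#' and excluded from genome-wide distributions downstream.
#'
#' @param g a `genotype_matrix`
#' @param ind individual ids to use (default all)
#' @param windows a window tibble
#' @return the window tibble with columns `S` and `value` (Tajima's D)
#' @export
tajima_windows <- function(g, ind = NULL, windows = NULL) {
  if (is.null(ind)) ind <- individuals(g)
  m <- g$calls[ind, , drop = FALSE]
  ncall <- colSums(!is.na(m))
  nh <- 2 * ncall
  p <- colSums(m, na.rm = TRUE) / nh
  seg <- !is.na(p) & p > 0 & p < 1 & nh >= 4
  pi_site <- ifelse(seg, nh / (nh - 1) * 2 * p * (1 - p), 0)

  wid <- site_window_map(g, windows)
  ok <- seg & !is.na(wid)
  S <- as.integer(tapply2(rep(1L, sum(ok)), wid[ok], nrow(windows)))
  piw <- tapply2(pi_site[ok], wid[ok], nrow(windows))

  n_eff <- round(mean(nh[seg]))
  value <- rep(NA_real_, nrow(windows))
  if (any(S > 0) && !is.na(n_eff) && n_eff >= 4) {
    k <- tajima_constants(n_eff)
    idx <- which(S > 0)
    vv <- k$e1 * S[idx] + k$e2 * S[idx] * (S[idx] - 1)
    value[idx] <- (piw[idx] - S[idx] / k$a1) / sqrt(vv)
  }
  dplyr::bind_cols(windows, tibble(S = S, value = value))
}

#' Percentile rank of a focal region in the genome-wide distribution
#'
#' The rank of the maximum focal-window value among all windows, under the
#' strictly-below tie convention: the fraction of genome-wide windows
#' whose value is strictly below the focal maximum, times 100.
#'
#' @param stat_windows a window-statistic tibble with a `value` column
#' @param chrom,start,end the focal interval (1-based inclusive)
#' @param value column name holding the statistic (default "value")
#' @return a one-row tibble: `focal_max`, `percentile`, `n_focal`, `n_genome`
#' @export
percentile_rank <- function(stat_windows, chrom, start, end,
                            value = "value") {
  v <- stat_windows[[value]]
  focal <- stat_windows$chrom == chrom & stat_windows$start <= end &
    stat_windows$end >= start & !is.na(v)
  if (!any(focal)) stop("no focal windows overlap the interval")
  genome <- !is.na(v)
  fmax <- max(v[focal])
  pct <- 100 * mean(v[genome] < fmax)
  tibble(focal_max = fmax, percentile = pct,
         n_focal = sum(focal), n_genome = sum(genome))
}
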