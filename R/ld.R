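#' Pairwise linkage disequilibrium with the Haploview colour classification
#'
#' Computes D, D', r2 and a base-10 LOD score for every pair of retained
#' sites in a region. Haplotype frequencies are taken directly from phased
#' haplotypes when available, otherwise estimated by two-locus EM over the
#' double-heterozygote ambiguity. `D' = D / D_max` with
#' `D_max = min(p_A p_b, p_a p_B)` for `D > 0` and
#' `D_max = min(p_A p_B, p_a p_b)` for `D < 0`. The LOD score is the
#' multinomial log10 likelihood ratio of the estimated haplotype
#' frequencies against linkage equilibrium, as Haploview computes it.
#'
#' @param g a `genotype_matrix`
#' @param ind individual ids (default all)
#' @param chrom,start,end optional region restriction (1-based inclusive)
#' @param thin_to if more sites than this remain after filtering, a seeded
#'   uniform subsample of this many is taken (default 1000)
#' @param min_genotyping minimum per-site genotyping rate (default 0.75)
#' @param min_maf minimum minor allele frequency (default 0.001)
#' @param seed seed for the thinning subsample (default 1)
#' @return a tibble of site pairs: `i`, `j` (site indices), `pos_i`,
#'   `pos_j`, `D`, `Dprime`, `r2`, `LOD`, `color_class`; pairs involving a
#'   monomorphic site are excluded up front
#' @export
ld_matrix <- function(g, ind = NULL, chrom = NULL, start = NULL, end = NULL,
                      thin_to = 1000L, min_genotyping = 0.75,
                      min_maf = 0.001, seed = 1L) {
  if (is.null(ind)) ind <- individuals(g)
  site_idx <- seq_len(ncol(g$calls))
  if (!is.null(chrom))
    site_idx <- sites_in_region(g, chrom, start, end)
  m <- g$calls[ind, site_idx, drop = FALSE]

  called <- colMeans(!is.na(m))
  p <- colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
  maf <- pmin(p, 1 - p)
  keep <- called >= min_genotyping & !is.na(maf) & maf >= min_maf & maf > 0
  site_idx <- site_idx[keep]
  if (length(site_idx) < 2) stop("fewer than two sites pass the LD filters")
  if (length(site_idx) > thin_to)
    site_idx <- sort(with_seed(seed, sample(site_idx, thin_to)))

  if (g$phased) {
    H <- haplotypes(g, ind)[, site_idx, drop = FALSE]
    res <- ld_from_haplotypes(H)
  } else {
    res <- ld_from_genotypes(g$calls[ind, site_idx, drop = FALSE])
  }
  res$i <- site_idx[res$i_loc]
  res$j <- site_idx[res$j_loc]
  res$pos_i <- g$sites$pos[res$i]
  res$pos_j <- g$sites$pos[res$j]
  res$color_class <- classify_ld(res$Dprime, res$LOD)
  dplyr::select(res, "i", "j", "pos_i", "pos_j", "D", "Dprime", "r2",
                "LOD", "color_class")
}

#' @noRd
ld_pair_stats <- function(pAB, pA, pB, nhap) {
  D <- pAB - pA * pB
  Dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  Dprime <- ifelse(Dmax > 0, abs(D) / Dmax, NA_real_)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, Dprime = Dprime, r2 = r2)
}

# direct haplotype counts (phased input)
#' @noRd
ld_from_haplotypes <- function(H) {
  nh <- nrow(H); mm <- ncol(H)
  n11 <- crossprod(H)
  cs <- colSums(H)
  n1. <- matrix(cs, mm, mm)            # allele-1 count at site i (rows)
  n.1 <- matrix(cs, mm, mm, byrow = TRUE)
  pAB <- n11 / nh
  pA <- n1. / nh; pB <- n.1 / nh
  st <- ld_pair_stats(pAB, pA, pB, nh)
  # multinomial LOD over the four haplotype classes
  nAB <- n11; nAb <- n1. - n11; naB <- n.1 - n11; nab <- nh - n1. - n.1 + n11
  l10 <- function(x) { x[!is.finite(x) | x <= 0] <- 1; log10(x) }
  ll1 <- nAB * l10(pAB) + nAb * l10(pA - pAB) + naB * l10(pB - pAB) +
    nab * l10(1 - pA - pB + pAB)
  ll0 <- nAB * l10(pA * pB) + nAb * l10(pA * (1 - pB)) +
    naB * l10((1 - pA) * pB) + nab * l10((1 - pA) * (1 - pB))
  LOD <- ll1 - ll0
  pair_tibble(st, LOD, mm)
}

# two-locus EM over double-heterozygote ambiguity (unphased input)
#' @noRd
ld_from_genotypes <- function(m) {
  mm <- ncol(m)
  I <- lapply(0:2, function(k) {
    x <- (m == k); x[is.na(x)] <- FALSE; storage.mode(x) <- "numeric"; x
  })
  cc <- !is.na(m); storage.mode(cc) <- "numeric"
  # pairwise complete individuals only
  Npair <- crossprod(cc)
  N <- vector("list", 9)
  for (a in 0:2) for (b in 0:2)
    N[[a * 3 + b + 1]] <- crossprod(I[[a + 1]], I[[b + 1]])
  g2 <- function(a, b) N[[a * 3 + b + 1]]

  # deterministic haplotype contributions
  nAB0 <- 2 * g2(2, 2) + g2(2, 1) + g2(1, 2)
  nAb0 <- 2 * g2(2, 0) + g2(2, 1) + g2(1, 0)
  naB0 <- 2 * g2(0, 2) + g2(1, 2) + g2(0, 1)
  nab0 <- 2 * g2(0, 0) + g2(1, 0) + g2(0, 1)
  ndh <- g2(1, 1)
  tot <- 2 * Npair

  pAB <- (nAB0 + ndh / 2) / tot
  pAb <- (nAb0 + ndh / 2) / tot
  paB <- (naB0 + ndh / 2) / tot
  pab <- (nab0 + ndh / 2) / tot
  for (it in 1:512) {
    num <- pAB * pab
    den <- num + pAb * paB
    w <- ifelse(den > 0, num / den, 0.5)
    new_pAB <- (nAB0 + ndh * w) / tot
    delta <- max(abs(new_pAB - pAB))
    pAB <- new_pAB
    pab <- (nab0 + ndh * w) / tot
    pAb <- (nAb0 + ndh * (1 - w)) / tot
    paB <- (naB0 + ndh * (1 - w)) / tot
    if (delta < 1e-12) break
  }
  pA <- pAB + pAb; pB <- pAB + paB
  st <- ld_pair_stats(pAB, pA, pB, tot)
  l10 <- function(x) { x[!is.finite(x) | x <= 0] <- 1; log10(x) }
  gl <- function(hAB, hAb, haB, hab) {
    # genotype-class probabilities under given haplotype frequencies
    ll <- g2(2, 2) * l10(hAB^2) + g2(0, 0) * l10(hab^2) +
      g2(2, 0) * l10(hAb^2) + g2(0, 2) * l10(haB^2) +
      g2(2, 1) * l10(2 * hAB * hAb) + g2(1, 2) * l10(2 * hAB * haB) +
      g2(1, 0) * l10(2 * hAb * hab) + g2(0, 1) * l10(2 * haB * hab) +
      ndh * l10(2 * (hAB * hab + hAb * haB))
    ll
  }
  LOD <- gl(pAB, pAb, paB, pab) -
    gl(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  pair_tibble(st, LOD, mm)
}

#' @noRd
pair_tibble <- function(st, LOD, mm) {
  ut <- upper.tri(matrix(0, mm, mm))
  idx <- which(ut, arr.ind = TRUE)
  tibble(i_loc = idx[, 1], j_loc = idx[, 2],
         D = st$D[ut], Dprime = st$Dprime[ut], r2 = st$r2[ut],
         LOD = LOD[ut])
}

#' Haploview colour classification of an LD pair
#'
#' `white` when D' < 1 and LOD < 2; `blue` when D' = 1 and LOD < 2;
#' `pink_red` when LOD >= 2. D' is compared to 1 with tolerance 1e-9.
#'
#' @param dprime,lod numeric vectors
#' @param tol tolerance for the D' = 1 comparison
#' @return character vector in `{white, blue, pink_red}`
#' @export
classify_ld <- function(dprime, lod, tol = 1e-9) {
  dplyr::case_when(
    lod >= 2 ~ "pink_red",
    !is.na(dprime) & abs(dprime - 1) <= tol ~ "blue",
    TRUE ~ "white"
  )
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
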