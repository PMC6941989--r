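test_that("D, D' and r2 match the direct two-locus frequency oracle", {
  g <- g_from_hap_counts(40, 10, 10, 40)
  ld <- ld_matrix(g, min_maf = 0, thin_to = 10L)
  expect_equal(ld$D, 0.15, tolerance = 1e-12)
  expect_equal(ld$Dprime, 0.6, tolerance = 1e-12)
  expect_equal(ld$r2, 0.36, tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:30) {
    n <- sample(c(40, 60), 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    if (any(cnt + c(cnt[2], cnt[1], cnt[4], cnt[3]) == 0)) next
    g2 <- g_from_hap_counts(cnt[1], cnt[2], cnt[3], cnt[4],
                            shuffle_seed = rep)
    pA <- (cnt[1] + cnt[2]) / n; pB <- (cnt[1] + cnt[3]) / n
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
    ld2 <- ld_matrix(g2, min_maf = 0, thin_to = 10L)
    want <- oracle_ld(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(ld2$D, want$D, tolerance = 1e-12)
    expect_equal(ld2$Dprime, want$Dprime, tolerance = 1e-12)
    expect_equal(ld2$r2, want$r2, tolerance = 1e-12)
  }
})

test_that("complete association gives D' = 1; equilibrium gives D = 0", {
  g <- g_from_hap_counts(30, 0, 0, 30)
  ld <- ld_matrix(g, min_maf = 0, thin_to = 10L)
  expect_equal(ld$Dprime, 1, tolerance = 1e-12)
  expect_gte(ld$LOD, 2)

  # p_AB = p_A * p_B exactly
  geq <- g_from_hap_counts(25, 25, 25, 25)
  ldeq <- ld_matrix(geq, min_maf = 0, thin_to = 10L)
  expect_equal(ldeq$D, 0, tolerance = 1e-12)
  expect_equal(ldeq$r2, 0, tolerance = 1e-12)
  expect_lt(abs(ldeq$LOD), 1e-9)
  expect_equal(ldeq$color_class, "white")
})

test_that("colour classification follows the Haploview scheme", {
  expect_equal(classify_ld(1.0, 0.5), "blue")
  expect_equal(classify_ld(0.3, 0.5), "white")
  expect_equal(classify_ld(0.9, 3.2), "pink_red")
  expect_equal(classify_ld(1.0, 2.0), "pink_red")
  expect_equal(classify_ld(1 - 1e-12, 0.1), "blue")  # tolerance at D' = 1
})

test_that("EM equals direct counts without double-het ambiguity, and the
          maximum-likelihood solution otherwise", {
  # no double heterozygotes (every individual pairs identical
  # haplotypes): phase is fully determined, so the EM result must equal
  # the phased direct counts exactly
  H <- rbind(matrix(c(1, 1), 20, 2, byrow = TRUE),
             matrix(c(1, 0), 14, 2, byrow = TRUE),
             matrix(c(0, 0), 26, 2, byrow = TRUE))
  a <- H[seq(1, 60, 2), ]; b <- H[seq(2, 60, 2), ]
  rownames(a) <- rownames(b) <- paste0("i", 1:30)
  g <- genotype_matrix(a + b, tibble::tibble(chrom = "c",
                                             pos = c(100L, 200L),
                                             ref = "A", alt = "T"), a, b)
  stopifnot(sum(g$calls[, 1] == 1 & g$calls[, 2] == 1) == 0)
  ph <- ld_matrix(g, min_maf = 0, thin_to = 10L)
  em <- ld_matrix(genotype_matrix(g$calls, g$sites), min_maf = 0,
                  thin_to = 10L)
  expect_equal(em$D, ph$D, tolerance = 1e-9)
  expect_equal(em$r2, ph$r2, tolerance = 1e-9)

  # with ambiguity, the EM solution maximizes the genotype likelihood:
  # compare against a grid-search oracle
  grid_mle_D <- function(m) {
    cnt <- function(a, b) sum(m[, 1] == a & m[, 2] == b)
    pA <- mean(m[, 1]) / 2; pB <- mean(m[, 2]) / 2
    ll <- function(pAB) {
      pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
      if (min(pAB, pAb, paB, pab) < -1e-12) return(-Inf)
      l <- function(x) log(pmax(x, 1e-300))
      cnt(2, 2) * l(pAB^2) + cnt(0, 0) * l(pab^2) +
        cnt(2, 0) * l(pAb^2) + cnt(0, 2) * l(paB^2) +
        cnt(2, 1) * l(2 * pAB * pAb) + cnt(1, 2) * l(2 * pAB * paB) +
        cnt(1, 0) * l(2 * pAb * pab) + cnt(0, 1) * l(2 * paB * pab) +
        cnt(1, 1) * l(2 * (pAB * pab + pAb * paB))
    }
    gr <- seq(max(0, pA + pB - 1), min(pA, pB), length.out = 20001)
    gr[which.max(vapply(gr, ll, 1.0))] - pA * pB
  }
  set.seed(17)
  for (rep in 1:8) {
    g2 <- make_test_genotypes(n_ind = 40, n_site = 2, seed = rep + 140,
                              phased = FALSE)
    p <- colMeans(g2$calls) / 2
    if (any(p <= 0.05 | p >= 0.95)) next
    em2 <- ld_matrix(g2, min_maf = 0.01, thin_to = 10L)
    if (nrow(em2) != 1) next
    # absolute agreement to the oracle's grid resolution
    expect_lt(abs(em2$D - grid_mle_D(g2$calls)), 5e-5)
  }
})

test_that("genotyping-rate, MAF filters and seeded thinning apply", {
  g <- make_test_genotypes(n_ind = 20, n_site = 30, seed = 99,
                           missing = 0.3)
  expect_error(ld_matrix(g, min_genotyping = 1.0), "fewer than two")
  ld1 <- ld_matrix(g, min_genotyping = 0.5, thin_to = 10L, seed = 3)
  ld2 <- ld_matrix(g, min_genotyping = 0.5, thin_to = 10L, seed = 3)
  expect_identical(ld1, ld2)
  expect_lte(length(unique(c(ld1$i, ld1$j))), 10L)
})
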