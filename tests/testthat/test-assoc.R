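test_that("fixed-difference site is associated with exact Fisher p", {
  calls <- rbind(matrix(2L, 10, 1), matrix(0L, 10, 1))
  rownames(calls) <- paste0("i", 1:20)
  g <- genotype_matrix(calls, tibble::tibble(chrom = "c", pos = 1L,
                                             ref = "A", alt = "T"))
  st <- sample_table(paste0("i", 1:20), "sp",
                     rep(c("mA", "mB"), each = 10))
  res <- gwas(g, st)
  expect_equal(res$test, "fisher")
  want <- oracle_fisher_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$p, want, tolerance = 1e-9)
  expect_true(res$associated)
  expect_equal(res$freq_diff, 1)
})

test_that("identical morph allele frequencies give p = 1 under Fisher", {
  calls <- matrix(rep(c(0L, 1L, 1L, 2L), 2), 8, 1)
  rownames(calls) <- paste0("i", 1:8)
  g <- genotype_matrix(calls, tibble::tibble(chrom = "c", pos = 1L,
                                             ref = "A", alt = "T"))
  st <- sample_table(paste0("i", 1:8), "sp", rep(c("x", "y"), each = 4))
  expect_equal(gwas(g, st)$p, 1)
})

test_that("q-values match the independent BH step-up oracle", {
  # the canonical worked example
  expect_equal(oracle_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  set.seed(23)
  for (rep in 1:20) {
    g <- make_test_genotypes(n_ind = 30, n_site = 40, seed = rep + 60,
                             phased = FALSE)
    st <- sample_table(paste0("ind", 1:30), "sp",
                       rep(c("a", "b"), 15))
    res <- gwas(g, st, max_missing = 1)
    ok <- !is.na(res$p)
    expect_equal(res$q[ok], oracle_bh(res$p[ok]), tolerance = 1e-12)
    expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
  }
  g1 <- make_test_genotypes(n_ind = 6, n_site = 5, seed = 1)
  st1 <- sample_table(paste0("ind", 1:6), "sp", rep("only", 6))
  expect_error(gwas(g1, st1), "two phenotype classes")
})

test_that("locus PCA places heterozygotes between homozygote clusters", {
  set.seed(8)
  n_site <- 30
  hom1 <- matrix(0L, 5, n_site)
  hom2 <- matrix(2L, 5, n_site)
  het <- matrix(1L, 1, n_site)
  noise <- matrix(rbinom(11 * n_site, 1, 0.05), 11, n_site)
  calls <- pmin(pmax(rbind(hom1, het, hom2) + noise, 0L), 2L)
  rownames(calls) <- paste0("i", 1:11)
  g <- genotype_matrix(calls, tibble::tibble(chrom = "c",
                                             pos = seq_len(n_site) * 10L,
                                             ref = "A", alt = "T"))
  pc <- snp_pca(g)
  s <- pc$scores[, 1]
  m1 <- mean(s[1:5]); m2 <- mean(s[7:11])
  expect_true(s[6] > min(m1, m2) && s[6] < max(m1, m2))

  calls_const <- matrix(1L, 5, 10, dimnames = list(paste0("i", 1:5), NULL))
  gc <- genotype_matrix(calls_const,
                        tibble::tibble(chrom = "c", pos = 1:10 * 5L,
                                       ref = "A", alt = "T"))
  expect_error(snp_pca(gc), "polymorphic")
})

test_that("PCA scores reproduce an SVD oracle up to sign", {
  g <- make_test_genotypes(n_ind = 15, n_site = 25, seed = 77,
                           phased = FALSE)
  pc <- snp_pca(g, max_site_missing = 1)
  x <- scale(g$calls, center = TRUE, scale = FALSE)
  sv <- svd(x)
  want <- sv$u %*% diag(sv$d)
  for (k in 1:2) {
    got <- pc$scores[, k]
    expect_true(max(abs(got - want[, k])) < 1e-8 ||
                  max(abs(got + want[, k])) < 1e-8)
  }
  expect_true(all(abs(colMeans(pc$scores)) < 1e-8))
  expect_lte(sum(pc$explained), 1)
  # broom-style accessors
  expect_equal(nrow(tidy(pc)), 15)
  expect_equal(glance(pc)$n_individuals, 15)
})

test_that("locus genotype calling labels the middle PC1 class het", {
  fake <- structure(list(scores = matrix(c(-5, -5, 0, 0, 5, 5), 6, 1,
                                         dimnames = list(paste0("i", 1:6),
                                                         "PC1")),
                         explained = 1, site_set = "locus", n_sites = 10),
                    class = "pca_result")
  calls <- call_locus_genotypes(fake)
  expect_equal(calls$locus_class,
               c("hom_ref_morph", "hom_ref_morph", "het", "het",
                 "hom_alt_morph", "hom_alt_morph"))
  flat <- structure(list(scores = matrix(0, 6, 1,
                                         dimnames = list(paste0("i", 1:6),
                                                         "PC1"))),
                    class = "pca_result")
  expect_error(call_locus_genotypes(flat), "constant")
})

test_that("shared SNP intersections and proximity correlation", {
  mk <- function(pos, q = 1e-4, fd = 1) tibble::tibble(
    site = seq_along(pos), chrom = "c", pos = pos, stat = 1,
    p = q, q = q, freq_diff = fd, test = "fisher", associated = TRUE)
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  rep <- shared_snps(list(s1 = mk(c(100, 200, 300)), s2 = mk(c(200, 400)),
                          s3 = mk(c(999))),
                     d, freq_diff_min = 0.8)
  pr <- rep$pairs
  expect_equal(pr$n_shared[pr$species1 == "s1" & pr$species2 == "s2"], 1L)
  expect_equal(pr$n_shared[pr$species1 == "s1" & pr$species2 == "s3"], 0L)
  # closest pair shares most -> positive proximity correlation
  expect_gt(rep$proximity_cor, 0)
  # below-threshold frequency difference removes sites from the sets
  rep2 <- shared_snps(list(s1 = mk(c(100), fd = 0.3), s2 = mk(c(100))),
                      d[1:2, 1:2], freq_diff_min = 0.8)
  expect_equal(rep2$pairs$n_shared, 0L)
})
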