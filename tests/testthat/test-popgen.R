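one_window <- function(g) make_windows(g, 1e6L)

test_that("windowed F_ST limits: fixed difference 1, identical pops <= 0", {
  calls <- rbind(matrix(0L, 5, 1), matrix(2L, 5, 1))
  rownames(calls) <- paste0("i", 1:10)
  g <- genotype_matrix(calls, tibble::tibble(chrom = "c", pos = 1L,
                                             ref = "A", alt = "T"))
  f <- fst_windows(g, paste0("i", 1:5), paste0("i", 6:10), one_window(g))
  expect_equal(f$value, 1)

  gi <- make_test_genotypes(n_ind = 12, n_site = 15, seed = 7,
                            phased = FALSE)
  # population 2 duplicates population 1's genotype array
  calls2 <- rbind(gi$calls[1:6, ], gi$calls[1:6, ])
  rownames(calls2) <- paste0("i", 1:12)
  g2 <- genotype_matrix(calls2, gi$sites)
  f2 <- fst_windows(g2, paste0("i", 1:6), paste0("i", 7:12), one_window(g2))
  expect_lte(f2$value, 0)
})

test_that("windowed F_ST equals the variance-components oracle", {
  set.seed(11)
  for (rep in 1:25) {
    g <- make_test_genotypes(n_ind = 12, n_site = 20, seed = rep + 100,
                             missing = ifelse(rep %% 2, 0, 0.1),
                             phased = FALSE)
    pop1 <- paste0("ind", 1:6); pop2 <- paste0("ind", 7:12)
    got <- fst_windows(g, pop1, pop2, one_window(g))$value
    want <- oracle_wc_fst(g$calls[pop1, ], g$calls[pop2, ])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("F_ST is invariant under ref/alt allele swap", {
  g <- make_test_genotypes(n_ind = 10, n_site = 12, seed = 21,
                           phased = FALSE)
  sw <- genotype_matrix(2L - g$calls, g$sites)
  p1 <- paste0("ind", 1:5); p2 <- paste0("ind", 6:10)
  expect_equal(fst_windows(g, p1, p2, one_window(g))$value,
               fst_windows(sw, p1, p2, one_window(sw))$value,
               tolerance = 1e-12)
})

test_that("Tajima constants and windowed D match direct summation", {
  k <- tajima_constants(10)
  expect_equal(k$a1, sum(1 / 1:9), tolerance = 1e-12)
  expect_equal(k$a1, 2.828968, tolerance = 1e-6)

  set.seed(4)
  for (rep in 1:25) {
    g <- make_test_genotypes(n_ind = 8, n_site = 25, seed = rep + 300)
    got <- tajima_windows(g, windows = one_window(g))$value
    want <- oracle_tajima(haplotypes(g))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("singleton-only windows give negative D; S = 0 is flagged NA", {
  # n = 10 haplotypes, 5 segregating singleton sites
  hap_a <- matrix(0L, 5, 5); hap_b <- matrix(0L, 5, 5)
  for (j in 1:5) hap_a[j, j] <- 1L
  calls <- hap_a + hap_b
  rownames(calls) <- rownames(hap_a) <- rownames(hap_b) <- paste0("i", 1:5)
  g <- genotype_matrix(calls, tibble::tibble(chrom = "c", pos = 1:5 * 100L,
                                             ref = "A", alt = "T"),
                       hap_a, hap_b)
  expect_lt(tajima_windows(g, windows = one_window(g))$value, 0)

  g0 <- genotype_matrix(matrix(0L, 5, 2, dimnames = list(paste0("i", 1:5),
                                                         NULL)),
                        tibble::tibble(chrom = "c", pos = c(10L, 20L),
                                       ref = "A", alt = "T"))
  t0 <- tajima_windows(g0, windows = one_window(g0))
  expect_true(is.na(t0$value))
  expect_equal(t0$S, 0L)
})

test_that("Tajima's D is invariant to site permutation within a window", {
  g <- make_test_genotypes(n_ind = 8, n_site = 30, seed = 31)
  perm <- sample(30)
  sites2 <- g$sites
  gp <- genotype_matrix(g$calls[, perm], sites2,
                        g$hap_a[, perm], g$hap_b[, perm])
  expect_equal(tajima_windows(g, windows = one_window(g))$value,
               tajima_windows(gp, windows = one_window(gp))$value,
               tolerance = 1e-12)
})

test_that("percentile rank uses the strictly-below convention", {
  w <- tibble::tibble(chrom = "c", start = (0:99) * 10 + 1,
                      end = (1:100) * 10, value = as.numeric(1:100))
  w$value[100] <- 99.5
  pr <- percentile_rank(w, "c", 991, 1000)
  expect_equal(pr$percentile, 99)

  # focal below the genome minimum -> 0
  w2 <- w; w2$value[100] <- 0
  expect_equal(percentile_rank(w2, "c", 991, 1000)$percentile, 0)

  # ties at the focal max, checked against a sort-based oracle
  set.seed(9)
  for (rep in 1:20) {
    w3 <- w
    w3$value <- sample(1:8, 100, replace = TRUE)
    pr3 <- percentile_rank(w3, "c", 991, 1000)
    expect_equal(pr3$percentile,
                 100 * sum(sort(w3$value) < w3$value[100]) / 100)
  }

  expect_error(percentile_rank(w, "c", 5000, 6000), "focal")
})
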