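# haplotypes realizing an additive quartet: NJ must recover topology and
# branch lengths (four-point condition)
test_that("NJ recovers additive quartets exactly", {
  set.seed(41)
  for (rep in 1:20) {
    e <- sample(2:8, 4, replace = TRUE)
    m <- sample(3:9, 1)
    q <- oracle_additive_quartet(e[1], e[2], e[3], e[4], m)
    tr <- distance_tree(q$H)
    # recovered pairwise path distances equal the generating metric
    cd <- ape::cophenetic.phylo(tr)[rownames(q$d), colnames(q$d)]
    expect_equal(cd, q$d, tolerance = 1e-9)
    # (A,B) vs (C,D) split present
    parts <- ape::prop.part(tr)
    splits <- lapply(parts, function(p) sort(tr$tip.label[p]))
    expect_true(list(c("A", "B")) %in% splits ||
                  list(c("C", "D")) %in% splits)
  }
})

test_that("identical tips form a zero-length cherry; site order is moot", {
  H <- rbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1),
             c = c(1, 1, 0, 0), d = c(1, 0, 0, 1))
  tr <- distance_tree(H)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["a", "b"], 0)

  perm <- c(3, 1, 4, 2)
  tr2 <- distance_tree(H[, perm])
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(cd), colnames(cd)], cd)

  H0 <- matrix(0, 4, 5, dimnames = list(letters[1:4], NULL))
  expect_true(attr(distance_tree(H0), "degenerate"))
})

mk_tree <- function(newick, species, morph) {
  tr <- ape::read.tree(text = newick)
  td <- tibble::tibble(tip = tr$tip.label, individual = tr$tip.label,
                       species = species[tr$tip.label],
                       morph = morph[tr$tip.label])
  attr(tr, "tip_data") <- td
  tr
}

test_that("clustering mode detects species and phenotype grouping", {
  sp <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  mo <- c(a1 = "red", a2 = "blue", b1 = "red", b2 = "blue")
  tr <- mk_tree("((a1:1,a2:1):1,(b1:1,b2:1):1);", sp, mo)
  expect_equal(clustering_mode(tr)$mode, "by_species")

  mo2 <- c(a1 = "red", b1 = "red", a2 = "blue", b2 = "blue")
  tr2 <- mk_tree("((a1:1,b1:1):1,(a2:1,b2:1):1);", sp, mo2)
  res2 <- clustering_mode(tr2)
  expect_equal(res2$mode, "by_phenotype")
  expect_equal(res2$support, 1)
})

test_that("sister-pair nesting is recorded as a by_species exception", {
  sp <- c(a1 = "a", a2 = "a", a3 = "a", b1 = "b", b2 = "b", c1 = "c",
          c2 = "c")
  mo <- setNames(rep("m", 7), names(sp))
  tr <- mk_tree("(((a1:1,(b1:1,b2:1):1):1,(a2:1,a3:1):1):1,(c1:1,c2:1):2);",
                sp, mo)
  res <- clustering_mode(tr, sister_pairs = list(c("a", "b")))
  expect_equal(res$mode, "by_species")
  expect_equal(res$nesting_events$inner, "b")
  expect_equal(res$nesting_events$outer, "a")
  # without the sister declaration the exception is not allowed
  expect_equal(clustering_mode(tr)$mode, "mixed")
})

test_that("clustering mode is invariant to re-rooting", {
  sp <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b", c1 = "c", c2 = "c")
  mo <- c(a1 = "x", a2 = "y", b1 = "x", b2 = "y", c1 = "x", c2 = "y")
  tr <- mk_tree("(((a1:1,a2:1):2,(b1:1,b2:1):2):1,(c1:1,c2:1):3);", sp, mo)
  base <- clustering_mode(tr)$mode
  for (tip in c("a1", "b2", "c1")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    attr(rr, "tip_data") <- attr(tr, "tip_data")
    expect_equal(clustering_mode(rr)$mode, base)
  }
})

test_that("elongation ratio has the closed-form value on built trees", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(elongation_ratio(tr, tr), 1.0)

  # doubling terminal branches: ratio from the definition directly
  tr2 <- tr
  term <- tr2$edge[, 2] <= 4
  tr2$edge.length[term] <- 2 * tr2$edge.length[term]
  mt1 <- mean(tr$edge.length[term]) / sum(tr$edge.length)
  mt2 <- mean(tr2$edge.length[term]) / sum(tr2$edge.length)
  expect_equal(elongation_ratio(tr2, tr), mt2 / mt1, tolerance = 1e-12)
  expect_gt(elongation_ratio(tr2, tr), 1)

  tr0 <- tr; tr0$edge.length[] <- 0
  expect_error(elongation_ratio(tr0, tr), "zero total")
})

test_that("discriminator follows the four-hypothesis decision tree", {
  by_sp <- list(mode = "by_species", support = 1,
                nesting_events = tibble::tibble())
  by_ph <- list(mode = "by_phenotype", support = 1,
                nesting_events = tibble::tibble())

  call1 <- discriminate(by_sp, elongation = 1.6, tajima_percentile = 99,
                        proximity_cor = 0.6, divergence_ratio = 2)
  expect_equal(call1$label, "turnover")

  call2 <- discriminate(by_sp, elongation = 1.0, tajima_percentile = 50,
                        proximity_cor = NA_real_, divergence_ratio = 2)
  expect_equal(call2$label, "independent")

  call3 <- discriminate(by_ph, elongation = 1.0, tajima_percentile = 95,
                        proximity_cor = 0.2, divergence_ratio = 0.5)
  expect_equal(call3$label, "introgression")

  call4 <- discriminate(by_ph, elongation = 0.6, tajima_percentile = 99,
                        proximity_cor = 0.2, divergence_ratio = 1.9)
  expect_equal(call4$label, "ils")

  mixed <- list(mode = "mixed", support = 0.4,
                nesting_events = tibble::tibble())
  call5 <- discriminate(mixed, 1.5, 99, 0.5, 1)
  expect_equal(call5$label, "mixed/uncertain")

  # an evidence vector always accompanies the label
  expect_gt(nrow(call1$evidence), 3)
  expect_equal(glance(call1)$label, "turnover")
  # a by_species clustering can never yield introgression
  for (e in c(0.5, 1.5)) for (t in c(10, 99))
    expect_false(discriminate(by_sp, e, t, 0.9, 0.1)$label ==
                   "introgression")
})

test_that("haplotype class clustering finds diverged classes, not noise", {
  fx <- make_diverged_classes(n_per_class = 5, n_cols = 200, seed = 15)
  cl <- haplotype_class_clusters(fx$haps)
  expect_equal(length(unique(cl)), 2L)
  expect_true(all(table(cl, fx$classes) %in% c(0L, 5L)))

  set.seed(16)
  flat <- matrix(rbinom(10 * 200, 1, 0.5), 10, 200)
  rownames(flat) <- paste0("h", 1:10)
  expect_equal(length(unique(haplotype_class_clusters(flat))), 1L)
})
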