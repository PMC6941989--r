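tiny_cfg <- function(N = 10, n_gen = 150, s = 0, seed = 1, mu = 0,
                     n_anc = 2, mu_allele = 0, xover = 0, gc = 0,
                     n_sample = N) {
  sim_config(n_diploids_per_species = N, n_gen = n_gen,
             genome_length = 10000, n_sites = 20,
             locus_interval = c(4001, 6000), locus_site_count = 5,
             mu_neutral = mu, mu_allele = mu_allele, n_markers = 2,
             n_anc_classes = n_anc, anc_marker_sites = 2,
             s = s, crossover_rate = xover, gc_rate = gc,
             n_sample = n_sample, log_interval = 50, seed = seed)
}

final_class_freq <- function(res, class_id = 0) {
  lg <- res$generation_log
  last <- lg[lg$generation == max(lg$generation), ]
  f <- last$freq[last$class == class_id]
  if (length(f)) f else 0
}

test_that("neutral class fixation probability equals the initial frequency", {
  freqs <- vapply(1:300, function(i)
    final_class_freq(simulate_supergene(tiny_cfg(seed = i))), 1.0)
  # E[final frequency] = initial frequency 0.5 (drift martingale);
  # 99% CI half-width for 300 replicates of a bounded [0,1] outcome
  expect_lt(abs(mean(freqs) - 0.5), 2.58 * 0.5 / sqrt(300))
  expect_gt(mean(freqs %in% c(0, 1)), 0.8)   # mostly fixed by 15N gens
})

test_that("NFDS maintains a two-class polymorphism that drift would lose", {
  both <- vapply(1:60, function(i) {
    res <- simulate_supergene(tiny_cfg(N = 200, n_gen = 1000, s = 0.5,
                                       seed = 1000 + i, n_sample = 20))
    length(unique(res$true_allele_class$allele_class)) == 2
  }, TRUE)
  expect_gte(mean(both), 0.95)
})

test_that("no mutational input yields zero segregating sites", {
  res <- simulate_supergene(tiny_cfg(n_anc = 1, seed = 3))
  expect_equal(ncol(res$genotypes$calls), 0L)
})

test_that("identical seeds give identical end-to-end output", {
  a <- simulate_supergene(tiny_cfg(N = 20, mu = 1e-3, s = 0.3,
                                   mu_allele = 1e-3, xover = 0.5,
                                   gc = 0.5, seed = 42))
  b <- simulate_supergene(tiny_cfg(N = 20, mu = 1e-3, s = 0.3,
                                   mu_allele = 1e-3, xover = 0.5,
                                   gc = 0.5, seed = 42))
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$samples, b$samples)
  expect_identical(a$true_allele_class, b$true_allele_class)
})

test_that("phenotype is a pure function of allele classes and dominance", {
  res <- simulate_supergene(tiny_cfg(N = 30, mu = 1e-3, s = 0.3,
                                     mu_allele = 2e-3, seed = 9,
                                     n_sample = 30))
  tac <- res$true_allele_class
  cls_by_ind <- split(tac$allele_class, tac$individual)
  want <- vapply(res$samples$individual, function(id)
    paste0("m", max(cls_by_ind[[id]])), "")
  expect_equal(res$samples$morph, unname(want))
  # haplotype count = 2 x individuals
  expect_equal(nrow(tac), 2L * nrow(res$samples))
})

test_that("allele-class count never exceeds classes founded", {
  res <- simulate_supergene(tiny_cfg(N = 40, mu = 1e-3, s = 0.4,
                                     mu_allele = 5e-3, seed = 11,
                                     n_sample = 40))
  n_classes <- length(unique(res$true_allele_class$allele_class))
  expect_lte(n_classes, 2 + res$n_innovations)
})

test_that("scenario presets encode their defining structure", {
  ne <- scenario_preset("neutral")
  expect_equal(ne$s, 0)
  expect_equal(nrow(ne$migration), 0L)
  tu <- scenario_preset("turnover")
  expect_gt(tu$s, 0)
  expect_gt(tu$mu_allele, 0)
  intro <- scenario_preset("introgression")
  expect_gt(nrow(intro$migration), 0L)
  ils <- scenario_preset("ils")
  expect_equal(ils$mu_allele, 0)
  expect_equal(ils$n_anc_classes, 2L)
  expect_error(scenario_preset("wat"))
  # four-species tree with staggered splits in every preset
  for (p in c("neutral", "ils", "turnover", "independent",
              "introgression")) {
    cfg <- scenario_preset(p)
    expect_equal(length(cfg$species), 4L)
    expect_equal(nrow(cfg$splits), 3L)
    expect_true(all(diff(sort(cfg$splits$gen)) > 0))
  }
})

test_that("simulation outputs round-trip through the file formats", {
  res <- simulate_supergene(tiny_cfg(N = 10, mu = 2e-3, seed = 21,
                                     n_sample = 10))
  pre <- tempfile()
  paths <- write_sim_outputs(res, pre)
  vcf_lines <- readLines(paths["vcf"])
  body <- vcf_lines[!grepl("^#", vcf_lines)]
  expect_equal(length(body), ncol(res$genotypes$calls))
  expect_equal(length(strsplit(body[1], "\t")[[1]]), 9 + 10)

  g2 <- read_vcf(paths["vcf"])
  expect_identical(unname(g2$calls), unname(res$genotypes$calls))
  expect_identical(unname(g2$hap_a), unname(res$genotypes$hap_a))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$true_scenario, "custom")
  st <- read_sample_table(paths["samples"])
  expect_equal(st$individual, res$samples$individual)

  # empty matrix -> header-only VCF
  res0 <- simulate_supergene(tiny_cfg(n_anc = 1, seed = 4))
  p0 <- write_sim_outputs(res0, tempfile())
  expect_false(any(!grepl("^#", readLines(p0["vcf"]))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(locus_interval = c(-5, 100)), "locus_interval")
  expect_error(sim_config(gc_tract_mean = 0.5))
  expect_error(sim_config(s = 1.5))
  expect_error(sim_config(splits = tibble::tibble(gen = 10L, parent = "Z",
                                                  child = "B"),
                          species = c("A", "B"), n_gen = 20),
               "does not exist")
})
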