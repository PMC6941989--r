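# Programmatic fixtures; no data files.

# random genotype matrix, optionally phased and with missingness
make_test_genotypes <- function(n_ind = 10, n_site = 20, seed = 1,
                                missing = 0, phased = TRUE,
                                chrom = "chr1", spacing = 500L) {
  set.seed(seed)
  p <- runif(n_site, 0.05, 0.95)
  hap_a <- sapply(p, function(pp) rbinom(n_ind, 1, pp))
  hap_b <- sapply(p, function(pp) rbinom(n_ind, 1, pp))
  calls <- hap_a + hap_b
  rownames(calls) <- paste0("ind", seq_len(n_ind))
  if (missing > 0) {
    idx <- which(runif(length(calls)) < missing)
    calls[idx] <- NA_integer_
    hap_a[idx] <- 0L; hap_b[idx] <- 0L
  }
  sites <- tibble::tibble(chrom = chrom,
                          pos = seq_len(n_site) * spacing,
                          ref = "A", alt = "T")
  if (phased)
    genotype_matrix(calls, sites, hap_a, hap_b)
  else
    genotype_matrix(calls, sites)
}

# write VCF text lines to a temp file
write_vcf_text <- function(body_lines, samples = c("s1", "s2")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

# two sequence-diverged haplotype classes for conversion-tract tests
make_diverged_classes <- function(n_per_class = 3, n_cols = 240,
                                  div = 0.35, seed = 1) {
  set.seed(seed)
  anc <- rbinom(n_cols, 1, 0.5)
  der <- anc
  flip <- which(runif(n_cols) < div)
  der[flip] <- 1 - der[flip]
  jitter <- function(hap, rate = 0.02) {
    f <- which(runif(n_cols) < rate)
    hap[f] <- 1 - hap[f]
    hap
  }
  H <- rbind(t(replicate(n_per_class, jitter(anc))),
             t(replicate(n_per_class, jitter(der))))
  rownames(H) <- c(paste0("anc", seq_len(n_per_class)),
                   paste0("der", seq_len(n_per_class)))
  list(haps = H, classes = rep(c("anc", "der"), each = n_per_class))
}

# build a phased two-site genotype matrix from haplotype counts
g_from_hap_counts <- function(nAB, nAb, naB, nab, shuffle_seed = 1) {
  blk <- function(h1, h2, n) matrix(c(rep(h1, n), rep(h2, n)), n, 2)
  H <- rbind(blk(1, 1, nAB), blk(1, 0, nAb), blk(0, 1, naB),
             blk(0, 0, nab))
  set.seed(shuffle_seed)
  H <- H[sample(nrow(H)), , drop = FALSE]
  stopifnot(nrow(H) %% 2 == 0)
  a <- H[seq(1, nrow(H), 2), , drop = FALSE]
  b <- H[seq(2, nrow(H), 2), , drop = FALSE]
  rownames(a) <- rownames(b) <- paste0("i", seq_len(nrow(a)))
  genotype_matrix(a + b, tibble::tibble(chrom = "c", pos = c(100L, 200L),
                                        ref = "A", alt = "T"),
                  a, b)
}

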