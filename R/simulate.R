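#' Run the forward Wright-Fisher supergene simulation
#'
#' Simulates diverging diploid species carrying a mimicry supergene under
#' NFDS per the configuration, then samples `n_sample` individuals per
#' species. The founding population is initialized at mutation-drift
#' equilibrium (site frequencies drawn from the neutral frequency
#' spectrum, assigned at linkage equilibrium) and burnt in before the
#' first split so that linkage structure can build up.
#'
#' @param config a [sim_config()]
#' @return a `sim_result`: `genotypes` (phased `genotype_matrix` over the
#'   segregating sites of the pooled sample), `samples` (sample table with
#'   true morphs), `true_scenario`, `true_allele_class` (tibble with one
#'   row per haplotype), `generation_log`, `n_innovations`, `config`
#' @export
simulate_supergene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_diploids_per_species
  nhap <- 2L * N
  ns <- config$n_sites

  pos <- site_positions(config)
  in_locus <- which(pos >= config$locus_interval[1] &
                      pos <= config$locus_interval[2])
  if (length(in_locus) == 0)
    stop("locus_interval contains no candidate sites")
  locus_sites <- range(in_locus)
  lo <- locus_sites[1] - 1L            # 0-based [lo, hi)
  hi <- locus_sites[2]

  # stationary neutral initialization: P(derived count = c) ~ theta / c
  theta <- 4 * N * config$mu_neutral
  a1 <- sum(1 / seq_len(nhap - 1))
  pseg <- min(theta * a1, 0.95)
  H <- matrix(0L, nhap, ns)
  segsites <- which(runif(ns) < pseg)
  if (length(segsites)) {
    counts <- sample(seq_len(nhap - 1), length(segsites), replace = TRUE,
                     prob = 1 / seq_len(nhap - 1))
    for (k in seq_along(segsites))
      H[sample.int(nhap, counts[k]), segsites[k]] <- 1L
  }

  cls <- rep(0L, nhap)
  next_class <- 1L
  if (config$n_anc_classes >= 2) {
    cls <- as.integer(sample(rep(0:1, length.out = nhap)))
    next_class <- 2L
    # diagnostic sites separating the ancestral classes
    diag_sites <- sample(seq(lo + 1L, hi), config$anc_marker_sites)
    H[cls == 1L, diag_sites] <- 1L
    H[cls == 0L, diag_sites] <- 0L
  }

  # species name -> population index, in order of appearance
  sp_index <- stats::setNames(0L, config$species[1])
  splits <- config$splits[order(config$splits$gen), , drop = FALSE]
  smat <- matrix(0L, nrow(splits), 3)
  for (i in seq_len(nrow(splits))) {
    sp_index[splits$child[i]] <- length(sp_index)
    smat[i, ] <- c(splits$gen[i], sp_index[[splits$parent[i]]],
                   sp_index[[splits$child[i]]])
  }
  mig <- config$migration
  migdf <- data.frame(gen_start = as.integer(mig$gen_start),
                      gen_end = as.integer(mig$gen_end),
                      donor = as.integer(sp_index[mig$donor]),
                      recipient = as.integer(sp_index[mig$recipient]),
                      rate = as.numeric(mig$rate))
  fi <- config$forced_innovations
  imat <- cbind(as.integer(fi$gen), as.integer(sp_index[fi$species]),
                as.integer(fi$n_copies))
  if (nrow(fi) == 0) imat <- matrix(0L, 0, 3)

  raw <- .wf_simulate(H, cls, as.integer(pos), config$genome_length,
                      lo, hi,
                      config$locus_interval[1], config$locus_interval[2],
                      config$mu_neutral, config$mu_allele,
                      config$n_markers,
                      config$s, config$dominance == "derived",
                      config$crossover_rate, config$suppress_locus_xover,
                      config$gc_rate, config$gc_tract_mean,
                      config$n_gen, length(sp_index), smat, migdf, imat,
                      config$log_interval, next_class)

  # sample individuals per species
  hapA <- hapB <- NULL
  ind_id <- ind_sp <- character(0)
  cls_a <- cls_b <- integer(0)
  for (spn in config$species) {
    p <- raw$pops[[sp_index[[spn]] + 1L]]
    pick <- sort(sample.int(N, config$n_sample))
    r1 <- 2L * pick - 1L; r2 <- 2L * pick
    hapA <- rbind(hapA, p$H[r1, , drop = FALSE])
    hapB <- rbind(hapB, p$H[r2, , drop = FALSE])
    ind_id <- c(ind_id, paste0(spn, sprintf("_%02d", seq_len(config$n_sample))))
    ind_sp <- c(ind_sp, rep(spn, config$n_sample))
    cls_a <- c(cls_a, p$cls[r1]); cls_b <- c(cls_b, p$cls[r2])
  }
  rownames(hapA) <- rownames(hapB) <- ind_id

  seg <- which(colSums(hapA) + colSums(hapB) > 0 &
                 colSums(hapA) + colSums(hapB) < 2L * length(ind_id))
  sites <- tibble(chrom = "chr1", pos = pos[seg], ref = "A", alt = "T")
  hapA <- hapA[, seg, drop = FALSE]; hapB <- hapB[, seg, drop = FALSE]
  g <- genotype_matrix(hapA + hapB, sites, hapA, hapB)

  expressed <- if (config$dominance == "derived") pmax(cls_a, cls_b) else
    pmin(cls_a, cls_b)
  samples <- sample_table(ind_id, ind_sp, paste0("m", expressed),
                          locus_class = ifelse(cls_a == cls_b, "hom", "het"))

  lg <- as_tibble(raw$log)
  lg$species <- names(sp_index)[lg$pop + 1L]

  tac <- tibble(
    tip = as.vector(rbind(paste0(ind_id, "_h1"), paste0(ind_id, "_h2"))),
    individual = rep(ind_id, each = 2),
    species = rep(ind_sp, each = 2),
    allele_class = as.vector(rbind(cls_a, cls_b)))

  structure(list(genotypes = g, samples = samples,
                 true_scenario = config$scenario_preset,
                 true_allele_class = tac,
                 generation_log = lg,
                 n_innovations = raw$n_innovations,
                 config = config),
            class = "sim_result")
}

#' @exportS3Method base::print
print.sim_result <- function(x, ...) {
  cat("<sim_result> scenario:", x$true_scenario, "\n")
  print(x$genotypes)
  cat("  innovations:", x$n_innovations, "; allele classes in sample:",
      length(unique(x$true_allele_class$allele_class)), "\n")
  invisible(x)
}

#' Candidate site positions: locus sites denser than background
#' @noRd
site_positions <- function(config) {
  li <- config$locus_interval
  n_loc <- config$locus_site_count
  n_out <- config$n_sites - n_loc
  left_len <- li[1] - 1
  right_len <- config$genome_length - li[2]
  n_left <- round(n_out * left_len / (left_len + right_len))
  n_right <- n_out - n_left
  pos <- c(round(seq(1, left_len, length.out = n_left)),
           round(seq(li[1], li[2], length.out = n_loc)),
           round(seq(li[2] + 1, config$genome_length, length.out = n_right)))
  pos <- as.integer(pos)
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  pos
}

#' Write simulation outputs to files
#'
#' Writes `<prefix>.vcf` (phased VCFv4.2), `<prefix>_samples.tsv`, and
#' `<prefix>_truth.json` (scenario, per-haplotype allele classes, locus
#' interval, innovation count).
#'
#' @param result a `sim_result`
#' @param out_prefix output path prefix
#' @return named character vector of the written paths, invisibly
#' @export
write_sim_outputs <- function(result, out_prefix) {
  paths <- c(vcf = paste0(out_prefix, ".vcf"),
             samples = paste0(out_prefix, "_samples.tsv"),
             truth = paste0(out_prefix, "_truth.json"))
  write_vcf(result$genotypes, paths["vcf"])
  write_sample_table(result$samples, paths["samples"])
  jsonlite::write_json(
    list(true_scenario = result$true_scenario,
         locus_interval = result$config$locus_interval,
         n_innovations = result$n_innovations,
         allele_classes = result$true_allele_class),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Plant a gene-conversion tract between diverged haplotypes
#'
#' Copies a contiguous tract from a donor haplotype of one allele class
#' onto a recipient haplotype of another, spanning a requested number of
#' columns that are variable between the two classes — the ground-truth
#' generator for conversion-detection power checks.
#'
#' @param haps 0/1 haplotype matrix
#' @param class_labels class per row
#' @param donor_class,recipient_class the two classes
#' @param n_poly_cols tract length in between-class variable columns
#' @param positions bp per column (default column index)
#' @return list: `haps` (modified matrix), `recipient` (row name),
#'   `donor` (row name), `columns` (absolute column indices of the
#'   tract), `bp_start`, `bp_end`
#' @export
plant_conversion_tract <- function(haps, class_labels, donor_class,
                                   recipient_class, n_poly_cols = 20,
                                   positions = seq_len(ncol(haps))) {
  rows <- which(class_labels %in% c(donor_class, recipient_class))
  v <- matrixStats_colVar(haps[rows, , drop = FALSE]) > 0
  poly <- which(v)
  if (length(poly) < n_poly_cols)
    stop("not enough variable columns to plant the tract")
  start_k <- sample.int(length(poly) - n_poly_cols + 1L, 1)
  cols <- poly[start_k]:poly[start_k + n_poly_cols - 1L]
  donor <- sample(which(class_labels == donor_class), 1)
  recip <- sample(which(class_labels == recipient_class), 1)
  haps[recip, cols] <- haps[donor, cols]
  list(haps = haps, recipient = rownames(haps)[recip],
       donor = rownames(haps)[donor], columns = cols,
       bp_start = positions[min(cols)], bp_end = positions[max(cols)])
}
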