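#' Per-SNP genotype-phenotype association with BH FDR
#'
#' Allelic 2-x-K contingency test per site between allele counts and
#' phenotype classes: chi-square by default, with a Fisher exact fallback
#' whenever any expected or observed cell count is below 5 (sparse
#' observed cells make the chi-square approximation unreliable even when
#' the expectations are large, e.g. at a fixed difference).
#' Benjamini-Hochberg
#' q-values are computed over all tested sites, and sites are flagged
#' associated at the configured q cutoff.
#'
#' @param g a `genotype_matrix`
#' @param samples a sample table (`individual`, `morph`, ...)
#' @param morphs optional subset of morph labels to compare (default: all
#'   morphs present among the genotyped individuals)
#' @param max_missing sites with missing-call fraction above this are
#'   excluded (default 0.20)
#' @param q_cutoff q-value threshold for the `associated` flag
#'   (default 0.01; 0.001 is the stricter conventional cutoff)
#' @return a tibble: `site`, `chrom`, `pos`, `stat`, `p`, `q`,
#'   `freq_diff` (max absolute allele-frequency difference between morph
#'   pairs), `test` ("chisq" or "fisher"), `associated`
#' @export
gwas <- function(g, samples, morphs = NULL, max_missing = 0.20,
                 q_cutoff = 0.01) {
  samples <- samples[samples$individual %in% individuals(g), , drop = FALSE]
  if (!is.null(morphs))
    samples <- samples[samples$morph %in% morphs, , drop = FALSE]
  classes <- split(samples$individual, samples$morph)
  classes <- classes[vapply(classes, length, 1L) >= 2]
  if (length(classes) < 2)
    stop("need at least two phenotype classes with >= 2 individuals")

  m <- g$calls[unlist(classes), , drop = FALSE]
  keep <- which(colMeans(is.na(m)) <= max_missing)

  # per-class allele counts at each kept site
  alt <- sapply(classes, function(idv)
    colSums(g$calls[idv, keep, drop = FALSE], na.rm = TRUE))
  tot <- sapply(classes, function(idv)
    2 * colSums(!is.na(g$calls[idv, keep, drop = FALSE])))
  alt <- matrix(alt, ncol = length(classes))
  tot <- matrix(tot, ncol = length(classes))
  ref <- tot - alt
  freq <- alt / tot

  res <- vapply(seq_along(keep), function(r) {
    tab <- rbind(alt[r, ], ref[r, ])
    ok <- tot[r, ] > 0
    tab <- tab[, ok, drop = FALSE]
    if (ncol(tab) < 2 || sum(tab) == 0 || all(tab[1, ] == 0) ||
        all(tab[2, ] == 0))
      return(c(NA_real_, NA_real_, 0))
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 5) || any(tab < 5)) {
      p <- fisher.test(tab, workspace = 2e6)$p.value
      c(NA_real_, p, 1)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      c(unname(ct$statistic), ct$p.value, 0)
    }
  }, numeric(3))

  p <- res[2, ]
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- p.adjust(p[tested], method = "BH")
  fd <- apply(freq, 1, function(f) {
    f <- f[!is.na(f)]
    if (length(f) < 2) NA_real_ else max(f) - min(f)
  })
  tibble(site = keep,
         chrom = g$sites$chrom[keep], pos = g$sites$pos[keep],
         stat = res[1, ], p = p, q = q, freq_diff = fd,
         test = ifelse(res[3, ] == 1, "fisher", "chisq"),
         associated = !is.na(q) & q < q_cutoff)
}

#' PCA result container
#' @noRd
new_pca_result <- function(scores, explained, site_set, n_sites) {
  structure(list(scores = scores, explained = explained,
                 site_set = site_set, n_sites = n_sites),
            class = "pca_result")
}

#' @exportS3Method base::print
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " individuals, ", x$n_sites,
      " sites (", x$site_set, ")\n", sep = "")
  cat("  PC1..PC3 variance: ",
      paste(sprintf("%.1f%%", 100 * head(x$explained, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of SNP dosages
#'
#' Eigendecomposition of the covariance of the mean-centred dosage matrix.
#' Missing dosages are mean-imputed per site (imputation is confined to
#' the PCA; no other statistic imputes). Run once on genome-wide SNPs and
#' once on locus-restricted SNPs to contrast global population structure
#' with local supergene genotype, the standard local-PCA test for
#' inversion-like architectures.
#'
#' @param g a `genotype_matrix`
#' @param ind individual ids (default all; at least 3)
#' @param chrom,start,end optional locus restriction; omit for genome-wide
#' @param max_site_missing sites with a higher missing fraction are
#'   excluded first (default 0.1)
#' @param n_comp number of components to return (default 4)
#' @return a `pca_result`: `scores` (individuals x components),
#'   `explained` (variance fractions), `site_set`, `n_sites`
#' @export
snp_pca <- function(g, ind = NULL, chrom = NULL, start = NULL, end = NULL,
                    max_site_missing = 0.1, n_comp = 4L) {
  if (is.null(ind)) ind <- individuals(g)
  if (length(ind) < 3) stop("need at least 3 individuals")
  site_set <- if (is.null(chrom)) "genome" else "locus"
  site_idx <- if (is.null(chrom)) seq_len(ncol(g$calls)) else
    sites_in_region(g, chrom, start, end)
  m <- g$calls[ind, site_idx, drop = FALSE]
  m <- m[, colMeans(is.na(m)) <= max_site_missing, drop = FALSE]
  mu <- colMeans(m, na.rm = TRUE)
  for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- mu[j]
  v <- apply(m, 2, var)
  m <- m[, v > 0, drop = FALSE]
  if (ncol(m) < 2) stop("fewer than 2 polymorphic sites after filtering")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_comp, ncol(pc$x))
  ev <- pc$sdev^2
  new_pca_result(pc$x[, seq_len(k), drop = FALSE],
                 (ev / sum(ev))[seq_len(k)], site_set, ncol(m))
}

#' @export
tidy.pca_result <- function(x, ...) {
  s <- as_tibble(x$scores, .name_repair = "minimal")
  names(s) <- paste0("PC", seq_len(ncol(s)))
  dplyr::bind_cols(tibble(individual = rownames(x$scores)), s)
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(site_set = x$site_set, n_sites = x$n_sites,
         n_individuals = nrow(x$scores),
         pc1_var = x$explained[1], pc2_var = x$explained[2])
}

#' Call locus genotype classes from a locus PCA
#'
#' One-dimensional k-means (k = 3) on PC1 scores with ordered centroids:
#' the two outer classes are the homozygote clusters, the middle class is
#' called heterozygous — mirroring the intermediate PC1 placement of
#' supergene heterozygotes.
#'
#' @param pca a `pca_result` from a locus-restricted [snp_pca()]
#' @param k number of classes (fixed at 3: hom / het / hom)
#' @return a tibble: `individual`, `pc1`, `locus_class` in
#'   `{hom_ref_morph, het, hom_alt_morph}`, with attribute `reliable`
#'   (FALSE, with a warning, when PC1 supports only two clusters —
#'   e.g. when one homozygote class is absent from the sample)
#' @export
call_locus_genotypes <- function(pca, k = 3L) {
  pc1 <- pca$scores[, 1]
  if (length(pc1) < k) stop("need at least 3 individuals")
  if (sd(pc1) == 0) stop("PC1 is constant; locus PCA carries no structure")
  centers <- sort(with_seed(1L, kmeans(pc1, centers = k, nstart = 10)$centers)[, 1])
  km <- kmeans(pc1, centers = matrix(centers, ncol = 1))
  lab <- c("hom_ref_morph", "het", "hom_alt_morph")[km$cluster]

  # three classes are only callable when PC1 actually shows three
  # clusters; with a dominant allele one homozygote class can be absent
  # from the sample, leaving two clusters that k = 3 would split
  # arbitrarily. Compare silhouettes of the 3- and 2-cluster readings.
  sil <- function(cl) {
    d <- abs(outer(pc1, pc1, "-"))
    mean_silhouette(d, cl)
  }
  cl2 <- with_seed(1L, kmeans(pc1, centers = 2, nstart = 10)$cluster)
  reliable <- isTRUE(sil(km$cluster) >= sil(cl2))
  if (!reliable)
    warning("locus PC1 shows two clusters, not three; ",
            "heterozygote calls are unreliable")
  out <- tibble(individual = rownames(pca$scores), pc1 = pc1,
                locus_class = lab)
  attr(out, "reliable") <- reliable
  out
}

#' Shared associated SNPs across species
#'
#' Formalizes trans-species association sharing: a SNP is "associated"
#' within a species when its BH q-value is below `q_cutoff` AND the
#' absolute allele-frequency difference between morphs is at least
#' `freq_diff_min`. Pairwise intersections are taken by exact reference
#' position (optionally requiring the same alternate allele), and the
#' Spearman correlation between intersection counts and phylogenetic
#' proximity (negative distance) is reported.
#'
#' @param per_species_assoc named list (species -> [gwas()] tibble)
#' @param species_distances symmetric matrix (or dist) of phylogenetic
#'   distances between the species
#' @param freq_diff_min minimum between-morph allele-frequency difference
#'   (default 0.8)
#' @param q_cutoff q-value cutoff (default 0.05)
#' @param match_allele if TRUE, shared SNPs must match on position and
#'   alternate allele identity, not position alone
#' @param alt_alleles optional named list (species -> alt allele per site)
#'   used when `match_allele = TRUE`
#' @return list with `sets` (per-species associated keys), `pairs` tibble
#'   (`species1`, `species2`, `n_shared`, `distance`), and
#'   `proximity_cor` (Spearman rho of `n_shared` vs -distance)
#' @export
shared_snps <- function(per_species_assoc, species_distances,
                        freq_diff_min = 0.8, q_cutoff = 0.05,
                        match_allele = FALSE, alt_alleles = NULL) {
  d <- as.matrix(species_distances)
  sp <- names(per_species_assoc)
  stopifnot(all(sp %in% rownames(d)))
  chroms <- unique(unlist(lapply(per_species_assoc, function(a) a$chrom)))

  key_of <- function(a, species) {
    sel <- !is.na(a$q) & a$q < q_cutoff & !is.na(a$freq_diff) &
      a$freq_diff >= freq_diff_min
    k <- paste(a$chrom[sel], a$pos[sel], sep = ":")
    if (match_allele && !is.null(alt_alleles))
      k <- paste(k, alt_alleles[[species]][a$site[sel]], sep = ":")
    unique(k)
  }
  sets <- lapply(sp, function(s) key_of(per_species_assoc[[s]], s))
  names(sets) <- sp

  pr <- utils::combn(sp, 2)
  pairs <- tibble(
    species1 = pr[1, ], species2 = pr[2, ],
    n_shared = vapply(seq_len(ncol(pr)), function(i)
      length(intersect(sets[[pr[1, i]]], sets[[pr[2, i]]])), 1L),
    distance = vapply(seq_len(ncol(pr)), function(i)
      d[pr[1, i], pr[2, i]], 1.0))
  rho <- if (nrow(pairs) >= 3 && sd(pairs$n_shared) > 0 &&
             sd(pairs$distance) > 0)
    suppressWarnings(cor(pairs$n_shared, -pairs$distance,
                         method = "spearman")) else NA_real_
  list(sets = sets, pairs = pairs, proximity_cor = rho)
}
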