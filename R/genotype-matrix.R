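#' Genotype matrix container
#'
#' The universal substrate for every analysis in the package: an
#' individuals-by-sites matrix of alt-allele dosages in \{0, 1, 2, NA\}
#' over biallelic SNPs, with optional phase (a pair of 0/1 haplotype
#' matrices whose sum reproduces the dosage).
#'
#' @param calls integer matrix, individuals x sites, dosages 0/1/2 with NA
#'   for missing; rownames are individual ids.
#' @param sites tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   positions must be strictly increasing within a chromosome.
#' @param hap_a,hap_b optional 0/1 haplotype matrices (same shape as
#'   `calls`) for phased data; `hap_a + hap_b` must equal `calls` wherever
#'   the dosage is non-missing.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, hap_a = NULL, hap_b = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- as_tibble(sites)
  stopifnot(ncol(calls) == nrow(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within a chromosome")
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  phased <- !is.null(hap_a)
  if (phased) {
    hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
    storage.mode(hap_a) <- "integer"; storage.mode(hap_b) <- "integer"
    stopifnot(identical(dim(hap_a), dim(calls)),
              identical(dim(hap_b), dim(calls)))
    rownames(hap_a) <- rownames(hap_b) <- rownames(calls)
    ok <- is.na(calls) | (hap_a + hap_b == calls)
    if (!all(ok)) stop("dosage must equal haplotype sum where phased")
  }
  structure(list(calls = calls, sites = sites,
                 hap_a = hap_a, hap_b = hap_b, phased = phased),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " individuals x ",
      ncol(x$calls), " sites (", if (x$phased) "phased" else "unphased",
      ")\n", sep = "")
  cat("  chrom(s): ", paste(unique(x$sites$chrom), collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Individual ids of a genotype matrix
#' @param g a `genotype_matrix`
#' @return character vector of individual ids
#' @export
individuals <- function(g) rownames(g$calls)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`
#' @param ind individual ids or indices (default all)
#' @param site_idx site indices (default all)
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(g, ind = NULL, site_idx = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(g$calls))
  if (is.null(site_idx)) site_idx <- seq_len(ncol(g$calls))
  genotype_matrix(g$calls[ind, site_idx, drop = FALSE],
                  g$sites[site_idx, , drop = FALSE],
                  if (g$phased) g$hap_a[ind, site_idx, drop = FALSE],
                  if (g$phased) g$hap_b[ind, site_idx, drop = FALSE])
}

#' Restrict a genotype matrix to a genomic interval
#'
#' @param g a `genotype_matrix`
#' @param chrom chromosome name
#' @param start,end 1-based inclusive interval bounds
#' @return a `genotype_matrix` (possibly with zero sites)
#' @export
region_genotypes <- function(g, chrom, start, end) {
  keep <- which(g$sites$chrom == chrom & g$sites$pos >= start &
                  g$sites$pos <= end)
  subset_genotypes(g, site_idx = keep)
}

#' Site indices overlapping an interval
#' @param g a `genotype_matrix`
#' @param chrom chromosome name
#' @param start,end 1-based inclusive bounds
#' @return integer vector of site indices
#' @export
sites_in_region <- function(g, chrom, start, end) {
  which(g$sites$chrom == chrom & g$sites$pos >= start & g$sites$pos <= end)
}

#' Drop sites by missing-call fraction
#'
#' Retains sites whose fraction of missing genotype calls is at most
#' `max_missing_fraction` (the `--max-missing`/`--geno` convention:
#' a cutoff of 0.25 keeps sites genotyped in at least 75% of individuals).
#'
#' @param g a `genotype_matrix`
#' @param max_missing_fraction maximum tolerated missing fraction in \[0, 1\]
#' @return a filtered `genotype_matrix`
#' @export
filter_site_missingness <- function(g, max_missing_fraction) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- colMeans(is.na(g$calls))
  subset_genotypes(g, site_idx = which(frac <= max_missing_fraction))
}

#' Per-site alternate allele frequency
#'
#' Missing calls are excluded site-wise (never imputed).
#'
#' @param g a `genotype_matrix`
#' @param ind optional individual subset
#' @return numeric vector of alt-allele frequencies (NaN where no calls)
#' @export
allele_freq <- function(g, ind = NULL) {
  m <- if (is.null(ind)) g$calls else g$calls[ind, , drop = FALSE]
  colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
}

#' Haplotype matrix of a phased genotype matrix
#'
#' Interleaves the two haplotypes of each individual into a
#' (2 x individuals) x sites 0/1 matrix with rownames `<id>_h1`, `<id>_h2`.
#'
#' @param g a phased `genotype_matrix`
#' @param ind optional individual subset
#' @return integer 0/1 matrix of haplotypes
#' @export
haplotypes <- function(g, ind = NULL) {
  if (!g$phased) stop("genotype matrix is not phased")
  if (is.null(ind)) ind <- individuals(g)
  if (!is.character(ind)) ind <- individuals(g)[ind]
  a <- g$hap_a[ind, , drop = FALSE]
  b <- g$hap_b[ind, , drop = FALSE]
  out <- matrix(0L, 2 * length(ind), ncol(a))
  out[seq(1, 2 * length(ind), 2), ] <- a
  out[seq(2, 2 * length(ind), 2), ] <- b
  rownames(out) <- as.vector(rbind(paste0(ind, "_h1"), paste0(ind, "_h2")))
  out
}

#' Build a sample table
#'
#' @param individual character ids (unique)
#' @param species species label per individual
#' @param morph discrete wing-pattern phenotype label per individual
#' @param locus_class optional inferred locus genotype class
#' @return a tibble with class `sample_table` semantics
#' @export
sample_table <- function(individual, species, morph, locus_class = NA) {
  stopifnot(!anyDuplicated(individual))
  tibble(individual = as.character(individual),
         species = as.character(species),
         morph = as.character(morph),
         locus_class = locus_class)
}
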