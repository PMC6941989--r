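#' Detect putative gene-conversion/recombination tracts between haplotype
#' classes
#'
#' Sawyer-style inner-fragment search: for each between-class haplotype
#' pair, over polymorphic columns only, the fragment score is
#' `(#matching columns) - penalty * (#mismatching columns)`; the
#' maximal-scoring segment is found by a linear max-subarray scan, and its
#' significance is the fraction of random column-order permutations whose
#' global maximum score reaches the observed one. P-values are
#' Bonferroni-corrected across the pairs tested; tracts are reported only
#' below `alpha` after correction.
#'
#' The default mismatch penalty for a pair with mismatch fraction `q` is
#' `q / (1 - q)`, which makes the expected per-column score zero under the
#' null of no local homogenization.
#'
#' @param haps 0/1 haplotype matrix (rows = haplotypes) or a phased
#'   `genotype_matrix`
#' @param class_labels haplotype class per row (length = rows of `haps`)
#' @param positions optional reference bp per column (default: column
#'   index); taken from the genotype matrix when one is supplied
#' @param mismatch_penalty positive penalty; default per-pair `q/(1-q)`
#' @param n_permutations permutations per pair (default 10000)
#' @param alpha corrected significance level (default 0.05)
#' @param seed RNG seed (default 1)
#' @param max_pairs_per_class_pair cap on haplotype pairs examined per
#'   class pair (a seeded subsample is taken above it; default 50)
#' @return a tibble of significant tracts: `hap1`, `hap2`, `class1`,
#'   `class2`, `col_start`, `col_end` (polymorphic-column index),
#'   `bp_start`, `bp_end`, `n_columns`, `score`, `p`, `p_corrected`;
#'   attribute `n_pairs_tested` records the Bonferroni denominator and
#'   attribute `degenerate` lists pairs with < 2 polymorphic columns
#' @export
detect_conversion_tracts <- function(haps, class_labels, positions = NULL,
                                     mismatch_penalty = NULL,
                                     n_permutations = 10000L, alpha = 0.05,
                                     seed = 1L,
                                     max_pairs_per_class_pair = 50L) {
  if (inherits(haps, "genotype_matrix")) {
    positions <- haps$sites$pos
    haps <- haplotypes(haps)
  }
  stopifnot(length(class_labels) == nrow(haps))
  if (is.null(positions)) positions <- seq_len(ncol(haps))
  classes <- unique(class_labels)
  if (length(classes) < 2) stop("need at least two haplotype classes")

  with_seed(seed, {
    cls_pairs <- utils::combn(as.character(classes), 2, simplify = FALSE)
    jobs <- list(); degen <- list()
    for (cp in cls_pairs) {
      r1 <- which(class_labels == cp[1]); r2 <- which(class_labels == cp[2])
      grid <- expand.grid(h1 = r1, h2 = r2)
      if (nrow(grid) > max_pairs_per_class_pair)
        grid <- grid[sample(nrow(grid), max_pairs_per_class_pair), ]
      for (r in seq_len(nrow(grid)))
        jobs[[length(jobs) + 1]] <- c(grid$h1[r], grid$h2[r])
    }

    results <- list()
    n_tested <- 0L
    for (jb in jobs) {
      x <- haps[jb[1], ]; y <- haps[jb[2], ]
      # columns variable among the two compared classes' haplotypes; a
      # conversion tract is a run of pairwise identity bounded by them
      rows <- which(class_labels %in% class_labels[jb])
      sub <- haps[rows, , drop = FALSE]
      poly <- which(matrixStats_colVar(sub) > 0)
      if (length(poly) < 2) {
        degen[[length(degen) + 1]] <- jb
        next
      }
      m <- as.integer(x[poly] == y[poly])
      q <- 1 - mean(m)
      if (q == 0) { degen[[length(degen) + 1]] <- jb; next }
      if (q == 1) { n_tested <- n_tested + 1L; next }  # no matching columns
      pen <- if (is.null(mismatch_penalty)) q / (1 - q) else mismatch_penalty
      sc <- .gc_scan(m, pen, as.integer(n_permutations))
      n_tested <- n_tested + 1L
      if (sc$score <= 0) next
      results[[length(results) + 1]] <- tibble(
        hap1 = rownames(haps)[jb[1]], hap2 = rownames(haps)[jb[2]],
        class1 = as.character(class_labels[jb[1]]),
        class2 = as.character(class_labels[jb[2]]),
        col_start = sc$start, col_end = sc$end,
        bp_start = positions[poly[sc$start]],
        bp_end = positions[poly[sc$end]],
        n_columns = sc$end - sc$start + 1L,
        score = sc$score, p = sc$p)
    }

    out <- if (length(results)) bind_rows(results) else
      tibble(hap1 = character(), hap2 = character(), class1 = character(),
             class2 = character(), col_start = integer(),
             col_end = integer(), bp_start = numeric(), bp_end = numeric(),
             n_columns = integer(), score = numeric(), p = numeric())
    out$p_corrected <- pmin(1, out$p * max(n_tested, 1L))
    out <- out[!is.na(out$p_corrected) & out$p_corrected < alpha, ,
               drop = FALSE]
    attr(out, "n_pairs_tested") <- n_tested
    attr(out, "degenerate") <- degen
    out
  })
}

# column-wise variability without matrixStats: TRUE -> variance > 0
#' @noRd
matrixStats_colVar <- function(m) {
  cm <- colMeans(m)
  colMeans(m^2) - cm^2
}

#' Silent-site column mask
#'
#' When exon intervals are supplied, restricts candidate columns to
#' non-coding positions — a proxy for a silent-site restriction on a
#' mostly non-coding region, used to reduce false-positive conversion
#' signals from coding-sequence constraint. Without annotation the mask
#' is the identity.
#'
#' @param positions reference bp per column
#' @param exons optional tibble/data.frame with `start`, `end` (1-based
#'   inclusive) exon intervals
#' @return integer vector of retained column indices
#' @export
silent_site_mask <- function(positions, exons = NULL) {
  if (is.null(exons) || nrow(exons) == 0) return(seq_along(positions))
  inside <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(exons)))
    inside <- inside | (positions >= exons$start[i] &
                          positions <= exons$end[i])
  which(!inside)
}
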