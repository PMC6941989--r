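#' Neighbour-joining genealogy from SNP data
#'
#' Builds an unrooted NJ tree from normalized Hamming (p-) distances over
#' shared non-missing sites — the distance counterpart of the gene trees
#' used to compare locus and genome-wide genealogies. Tip order is fixed
#' by label sort, so ties resolve deterministically.
#'
#' @param x a `genotype_matrix` (phased: tips are haplotypes; unphased:
#'   tips are individuals with dosage mismatch counted as half) or a 0/1
#'   haplotype matrix with rownames
#' @param tip_data optional tibble (`tip`, `individual`, `species`,
#'   `morph`) attached to the result; built automatically from a sample
#'   table via [tree_tip_data()]
#' @param chrom,start,end optional region restriction (genotype input)
#' @return an [ape::phylo] with attribute `tip_data`; a `degenerate`
#'   attribute flags an all-identical input (star tree)
#' @export
distance_tree <- function(x, tip_data = NULL, chrom = NULL, start = NULL,
                          end = NULL) {
  if (inherits(x, "genotype_matrix")) {
    if (!is.null(chrom)) x <- region_genotypes(x, chrom, start, end)
    H <- if (x$phased) haplotypes(x) else x$calls / 2
  } else {
    H <- x
  }
  if (nrow(H) < 4) stop("need at least 4 tips")
  H <- H[order(rownames(H)), , drop = FALSE]
  d <- p_distance(H)
  degenerate <- all(d == 0)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(tip_data)) {
    tip_data <- tip_data[match(tr$tip.label, tip_data$tip), , drop = FALSE]
    attr(tr, "tip_data") <- tip_data
  }
  attr(tr, "degenerate") <- degenerate
  tr
}

#' Normalized Hamming distance between rows, excluding missing entries
#' @noRd
p_distance <- function(H) {
  M <- !is.na(H)
  H0 <- H; H0[!M] <- 0
  storage.mode(H0) <- "numeric"; storage.mode(M) <- "numeric"
  shared <- M %*% t(M)
  # sum over shared sites of |x - y| for 0/1 data: x(1-y) + y(1-x)
  cross <- H0 %*% t(M - H0) + (M - H0) %*% t(H0)
  d <- ifelse(shared > 0, cross / shared, 0)
  rownames(d) <- colnames(d) <- rownames(H)
  d
}

#' Tip metadata for haplotype trees
#'
#' @param samples a sample table
#' @param haplotype if TRUE, two tips per individual (`_h1`, `_h2`)
#' @param morph_by_hap optional named vector of per-haplotype labels (e.g.
#'   true or inferred allele classes) overriding the individual morph
#' @return tibble with `tip`, `individual`, `species`, `morph`
#' @export
tree_tip_data <- function(samples, haplotype = TRUE, morph_by_hap = NULL) {
  if (!haplotype)
    return(tibble(tip = samples$individual, individual = samples$individual,
                  species = samples$species, morph = samples$morph))
  tips <- as.vector(rbind(paste0(samples$individual, "_h1"),
                          paste0(samples$individual, "_h2")))
  out <- tibble(tip = tips,
                individual = rep(samples$individual, each = 2),
                species = rep(samples$species, each = 2),
                morph = rep(samples$morph, each = 2))
  if (!is.null(morph_by_hap))
    out$morph <- unname(morph_by_hap[out$tip])
  out
}

#' Clustering mode of a labeled genealogy
#'
#' Tests whether haplotypes group by species or by phenotype class on the
#' (unrooted) tree, via bipartitions: a label group is monophyletic when
#' some edge separates exactly that group. `by_phenotype` requires a morph
#' class that spans two non-sister species to form a clade (the hallmark
#' of introgressed or ancestrally shared alleles). `by_species` tolerates
#' declared exceptions confined to a sister pair — one species nested
#' within, or interleaved with, its sister — the pattern expected when the
#' youngest lineages still share an allele class. The result is invariant
#' to re-rooting.
#'
#' @param tree an [ape::phylo] with a `tip_data` attribute (or pass
#'   `tip_data` explicitly)
#' @param tip_data tibble with `tip`, `species`, `morph`
#' @param sister_pairs list of length-2 character vectors naming sister
#'   species (from the genome-wide tree); exceptions are only allowed
#'   within these pairs
#' @param mono_tol per-group tolerance: a group still counts as
#'   monophyletic when at most `floor(mono_tol * group size)` tips
#'   violate the split (default 0.1), absorbing occasional conversion
#'   mosaics or phase-label errors
#' @return list: `mode` in `{by_species, by_phenotype, mixed}`, `support`
#'   (fraction of label groups strictly monophyletic under the chosen
#'   mode), `nesting_events` tibble, `species_mono`, `morph_mono`
#' @export
clustering_mode <- function(tree, tip_data = NULL, sister_pairs = NULL,
                            mono_tol = 0.1) {
  if (is.null(tip_data)) tip_data <- attr(tree, "tip_data")
  if (is.null(tip_data)) stop("tip labels (species, morph) are required")
  stopifnot(all(tree$tip.label %in% tip_data$tip))
  tip_data <- tip_data[match(tree$tip.label, tip_data$tip), ]

  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  part_sets <- lapply(parts, function(p) sort(p))
  is_split <- function(tips_idx, tol = 0L) {
    k <- length(tips_idx)
    if (k <= 1 || k >= n - 1) return(TRUE)
    g <- sort(tips_idx); comp <- sort(setdiff(seq_len(n), g))
    any(vapply(part_sets, function(p) {
      length(setdiff(g, p)) + length(setdiff(p, g)) <= tol ||
        length(setdiff(comp, p)) + length(setdiff(p, comp)) <= tol
    }, TRUE))
  }
  group_idx <- function(labels, value) which(labels == value)

  species <- unique(tip_data$species)
  near <- function(idx) is_split(idx, tol = floor(mono_tol * length(idx)))
  sp_mono <- vapply(species, function(s)
    near(group_idx(tip_data$species, s)), TRUE)
  names(sp_mono) <- species
  morphs <- unique(tip_data$morph)
  mo_mono <- vapply(morphs, function(m)
    near(group_idx(tip_data$morph, m)), TRUE)
  names(mo_mono) <- morphs

  is_sister <- function(a, b) {
    if (is.null(sister_pairs)) return(FALSE)
    any(vapply(sister_pairs, function(p) setequal(p, c(a, b)), TRUE))
  }

  # exceptions for non-monophyletic species, confined to sister pairs
  nesting <- list()
  sp_ok <- sp_mono
  for (s in species[!sp_mono]) {
    for (s2 in setdiff(species, s)) {
      if (!is_sister(s, s2)) next
      both <- which(tip_data$species %in% c(s, s2))
      if (is_split(both)) {
        type <- if (sp_mono[[s2]]) "nested" else "interleaved"
        nesting[[length(nesting) + 1]] <-
          tibble(inner = s2, outer = s, type = type)
        sp_ok[[s]] <- TRUE
        break
      }
    }
  }

  # a morph class spanning non-sister species and forming a clade signals
  # allele sharing deeper than sister-pair retention; only polymorphic
  # species count as spanned (a background morph covering monomorphic
  # relatives is not evidence of allele sharing)
  sp_polym <- vapply(species, function(s)
    length(unique(tip_data$morph[tip_data$species == s])) >= 2, TRUE)
  names(sp_polym) <- species
  span_nonsister <- vapply(morphs, function(m) {
    sps <- unique(tip_data$species[tip_data$morph == m])
    sps <- sps[sp_polym[sps]]
    if (length(sps) < 2) return(FALSE)
    prs <- utils::combn(sps, 2)
    any(!vapply(seq_len(ncol(prs)), function(i)
      is_sister(prs[1, i], prs[2, i]), TRUE))
  }, TRUE)

  mode <- if (length(morphs) >= 2 && all(mo_mono) &&
              any(span_nonsister & mo_mono)) {
    "by_phenotype"
  } else if (all(sp_ok)) {
    "by_species"
  } else if (length(morphs) >= 2 && all(mo_mono) &&
             any(vapply(morphs, function(m) {
               sps <- unique(tip_data$species[tip_data$morph == m])
               sum(sp_polym[sps]) >= 2
             }, TRUE))) {
    "by_phenotype"
  } else {
    "mixed"
  }
  support <- if (mode == "by_phenotype") mean(mo_mono) else mean(sp_mono)
  nest_tbl <- if (length(nesting)) bind_rows(nesting) else
    tibble(inner = character(), outer = character(), type = character())
  list(mode = mode, support = support, nesting_events = nest_tbl,
       species_mono = sp_mono, morph_mono = mo_mono)
}

#' Terminal-branch elongation of a locus genealogy
#'
#' Ratio of (mean terminal branch length / total tree length) at the locus
#' to the same quantity genome-wide, on trees sharing a tip set. Values
#' above 1 indicate terminal-branch elongation, the signature expected of
#' a locus under long-term multiallelic balancing selection.
#'
#' @param locus_tree,genome_tree [ape::phylo] objects with identical tips
#' @return a positive number
#' @export
elongation_ratio <- function(locus_tree, genome_tree) {
  stopifnot(setequal(locus_tree$tip.label, genome_tree$tip.label))
  frac <- function(tr) {
    term <- tr$edge[, 2] <= length(tr$tip.label)
    tot <- sum(tr$edge.length)
    if (tot <= 0) stop("tree has zero total branch length")
    mean(tr$edge.length[term]) / tot
  }
  frac(locus_tree) / frac(genome_tree)
}

#' Mean inter-group path distance on a tree
#' @noRd
between_group_divergence <- function(tree, groups) {
  cd <- ape::cophenetic.phylo(tree)
  labs <- unique(groups[tree$tip.label])
  if (length(labs) < 2) return(NA_real_)
  prs <- utils::combn(labs, 2)
  mean(vapply(seq_len(ncol(prs)), function(i) {
    a <- names(groups)[groups == prs[1, i]]
    b <- names(groups)[groups == prs[2, i]]
    mean(cd[a, b])
  }, 1.0))
}

#' Locus divergence between phenotype classes relative to species depth
#'
#' The mean locus-tree path distance between morph classes divided by the
#' deepest mean genome-tree path distance between species. Shallow values
#' (allele divergence younger than the species radiation) indicate
#' introgression; values at or beyond the species depth indicate ancestral
#' (trans-species) divergence.
#'
#' @param locus_tree,genome_tree labeled trees (with `tip_data`)
#' @return a single ratio
#' @export
phenotype_divergence_ratio <- function(locus_tree, genome_tree) {
  td_l <- attr(locus_tree, "tip_data")
  td_g <- attr(genome_tree, "tip_data")
  morph <- setNames(td_l$morph, td_l$tip)
  div_pheno <- between_group_divergence(locus_tree, morph)
  cd <- ape::cophenetic.phylo(genome_tree)
  sp <- setNames(td_g$species, td_g$tip)
  labs <- unique(sp)
  depth <- max(vapply(utils::combn(labs, 2, simplify = FALSE), function(p) {
    mean(cd[names(sp)[sp == p[1]], names(sp)[sp == p[2]]])
  }, 1.0))
  div_pheno / depth
}

#' Cluster locus haplotypes into allele-class groups
#'
#' Average-linkage clustering of haplotype p-distances with the number of
#' clusters (1..`k_max`) chosen by mean silhouette; below `sil_min` the
#' haplotypes are treated as a single class (no meaningful structure, the
#' neutral expectation).
#'
#' @param H 0/1 haplotype matrix over locus sites
#' @param k_max maximum number of classes considered (default 4)
#' @param sil_min minimum mean silhouette to accept a split (default 0.5)
#' @return integer cluster id per haplotype row
#' @export
haplotype_class_clusters <- function(H, k_max = 4L, sil_min = 0.5) {
  d <- p_distance(H)
  n <- nrow(d)
  if (n < 3 || max(d) == 0) return(rep(1L, n))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  best_k <- 1L; best_s <- -Inf
  for (k in 2:min(k_max, n - 1)) {
    cl <- stats::cutree(hc, k)
    s <- mean_silhouette(d, cl)
    if (!is.na(s) && s > best_s) { best_s <- s; best_k <- k }
  }
  if (best_s < sil_min) return(rep(1L, n))
  stats::cutree(hc, best_k)
}

#' @noRd
mean_silhouette <- function(d, cl) {
  n <- nrow(d)
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- cl[i]
    same <- which(cl == own); same <- setdiff(same, i)
    a <- if (length(same)) mean(d[i, same]) else 0
    b <- min(vapply(setdiff(ks, own), function(k)
      mean(d[i, cl == k]), 1.0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 1.0)
  mean(s)
}

#' One representative haplotype per inferred allele class per species
#'
#' Clusters each species' locus haplotypes into allele classes
#' ([haplotype_class_clusters()]) and returns the medoid haplotype of each
#' class. Summarizing the genealogy by class representatives turns
#' allele-class stems into terminal branches, which is where multiallelic
#' balancing selection leaves its elongation signature.
#'
#' @param g a phased `genotype_matrix`
#' @param samples sample table
#' @param ind individuals to consider
#' @param chrom,start,end the locus interval
#' @return character vector of representative haplotype tip names
#' @export
class_representative_haplotypes <- function(g, samples, ind, chrom, start,
                                            end) {
  loc <- sites_in_region(g, chrom, start, end)
  reps <- character(0)
  for (sp in unique(samples$species)) {
    idv <- intersect(ind, samples$individual[samples$species == sp])
    if (!length(idv)) next
    H <- haplotypes(g, idv)[, loc, drop = FALSE]
    cl <- haplotype_class_clusters(H)
    d <- p_distance(H)
    for (k in unique(cl)) {
      rows <- which(cl == k)
      med <- rows[which.min(rowSums(d[rows, rows, drop = FALSE]))]
      reps <- c(reps, rownames(H)[med])
    }
  }
  reps
}

#' Per-haplotype morph labels inferred from allele-class clusters
#'
#' Clusters each species' locus haplotypes into allele classes
#' ([haplotype_class_clusters()]) and maps each class to a morph label:
#' the modal morph of individuals whose two haplotypes fall in the same
#' class (sequence homozygotes), falling back to the modal morph of all
#' carriers. This labels both haplotypes of heterozygous individuals
#' correctly, which the individual-level morph cannot.
#'
#' @param g a phased `genotype_matrix`
#' @param samples sample table
#' @param chrom,start,end the locus interval
#' @param calls optional named list (species -> [call_locus_genotypes()]
#'   tibble); when present, individuals called homozygous contribute
#'   extra weight to the class-to-morph mapping
#' @return named character vector: haplotype tip -> morph label
#' @export
haplotype_morph_labels <- function(g, samples, chrom, start, end,
                                   calls = list()) {
  loc <- sites_in_region(g, chrom, start, end)
  out <- character(0)
  for (sp in unique(samples$species)) {
    idv <- samples$individual[samples$species == sp]
    morph <- setNames(samples$morph[samples$species == sp], idv)
    H <- haplotypes(g, idv)[, loc, drop = FALSE]
    cl <- haplotype_class_clusters(H)
    names(cl) <- rownames(H)
    lab <- setNames(rep(NA_character_, nrow(H)), rownames(H))
    for (k in unique(cl)) {
      members <- names(cl)[cl == k]
      ind <- sub("_h[12]$", "", members)
      hom <- names(which(table(ind) == 2))
      pool <- if (length(hom)) morph[hom] else morph[unique(ind)]
      lab[members] <- names(sort(table(pool), decreasing = TRUE))[1]
    }
    out <- c(out, lab)
  }
  out
}
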