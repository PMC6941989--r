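#' Configuration for a full supergene scan
#'
#' Exactly one input mode: a simulator preset, or a VCF plus sample table
#' (with a locus interval in reference coordinates). Every stochastic
#' stage receives a sub-seed derived from the master seed via a counter,
#' so adding a stage never perturbs earlier stages' randomness.
#'
#' @param preset scenario preset name (simulate mode), or NULL
#' @param vcf,samples paths to a VCF and sample TSV (ingest mode)
#' @param locus `list(chrom=, start=, end=)`; defaults to the simulator's
#'   locus in simulate mode
#' @param window_size window size in bp (default 10000)
#' @param sparse_quantile bottom quantile of variant-sparse windows to
#'   drop (default 0.10)
#' @param flank LD flank around the locus in bp (default 1e5)
#' @param run_ld compute the LD stage (default TRUE)
#' @param gwas_max_missing,pca_max_missing,shared_max_missing per-stage
#'   missingness cutoffs (defaults 0.20, 0.10, 0.25)
#' @param shared_freq_diff between-morph allele-frequency difference
#'   required to call a SNP associated in the shared-SNP stage (default
#'   0.6: with a dominant balanced allele near frequency 1/2 the
#'   observable contrast tops out around 2/3, so the conventional 0.8
#'   would discard fully associated dominant markers)
#' @param n_tree_per_species individuals per species used for genealogies
#'   (default 8)
#' @param preset_overrides named list of [sim_config()] fields overriding
#'   the preset's defaults (simulate mode only)
#' @param thresholds discriminator thresholds, see [discriminate()]
#' @param seed master seed
#' @param out_dir optional output directory for the report bundle
#' @return a `scan_config` list
#' @export
scan_config <- function(preset = NULL, vcf = NULL, samples = NULL,
                        locus = NULL, window_size = 10000L,
                        sparse_quantile = 0.10, flank = 1e5,
                        run_ld = TRUE, gwas_max_missing = 0.20,
                        pca_max_missing = 0.10, shared_max_missing = 0.25,
                        shared_freq_diff = 0.6,
                        n_tree_per_species = 8L, preset_overrides = list(),
                        thresholds = list(),
                        seed = 1L, out_dir = NULL) {
  simulate_mode <- !is.null(preset)
  ingest_mode <- !is.null(vcf)
  if (simulate_mode == ingest_mode)
    stop("exactly one input mode: preset OR vcf+samples")
  if (ingest_mode && (is.null(samples) || is.null(locus)))
    stop("ingest mode needs samples and locus")
  structure(list(preset = preset, vcf = vcf, samples = samples,
                 locus = locus, window_size = as.integer(window_size),
                 sparse_quantile = sparse_quantile, flank = flank,
                 run_ld = run_ld, gwas_max_missing = gwas_max_missing,
                 pca_max_missing = pca_max_missing,
                 shared_max_missing = shared_max_missing,
                 shared_freq_diff = shared_freq_diff,
                 n_tree_per_species = as.integer(n_tree_per_species),
                 preset_overrides = preset_overrides,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "scan_config")
}

#' Run the full scan
#'
#' Orchestrates the whole workflow: simulate or ingest, filter, windowed
#' F_ST and Tajima's D with locus percentiles, LD, GWAS, genome-versus-
#' locus PCA with heterozygote calling, cross-species shared-SNP analysis,
#' genome and locus genealogies, and the scenario discriminator. Identical
#' config and seed give a byte-identical summary JSON.
#'
#' @param config a [scan_config()]
#' @return a `scan_report` list; if `out_dir` is set, writes
#'   `summary.json`, `manifest.json` and per-stage TSV tables there
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  sub_seed <- function(k) (config$seed + k * 10007L) %% 2147483647L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- NULL
  if (!is.null(config$preset)) {
    sim <- stage("simulate", {
      cfg <- scenario_preset(config$preset, seed = sub_seed(1))
      if (length(config$preset_overrides)) {
        cfg[names(config$preset_overrides)] <- config$preset_overrides
        cfg <- validate_sim_config(cfg)
      }
      simulate_supergene(cfg)
    })
    g <- sim$genotypes
    samples <- sim$samples
    locus <- list(chrom = "chr1",
                  start = sim$config$locus_interval[1],
                  end = sim$config$locus_interval[2])
  } else {
    g <- stage("read_vcf", read_vcf(config$vcf))
    samples <- stage("read_samples", read_sample_table(config$samples))
    locus <- config$locus
  }
  species <- unique(samples$species)

  windows <- stage("windows", make_windows(g, config$window_size))

  # per-species F_ST between the two commonest morphs, and Tajima's D
  per_species <- lapply(species, function(sp) {
    idv <- samples$individual[samples$species == sp]
    morph <- samples$morph[samples$species == sp]
    tab <- sort(table(morph), decreasing = TRUE)
    polym <- length(tab) >= 2 && tab[2] >= 2

    taj <- tajima_windows(g, idv, windows)
    taj_kept <- drop_sparse_by(taj, "S", config$sparse_quantile)
    taj_pct <- tryCatch(
      percentile_rank(taj_kept, locus$chrom, locus$start, locus$end)$percentile,
      error = function(e) NA_real_)

    fst <- fst_pct <- NULL
    if (polym) {
      m1 <- idv[morph == names(tab)[1]]; m2 <- idv[morph == names(tab)[2]]
      fst <- fst_windows(g, m1, m2, windows)
      fst_kept <- drop_sparse_by(fst, "n_used", config$sparse_quantile)
      fst_pct <- tryCatch(
        percentile_rank(fst_kept, locus$chrom, locus$start,
                        locus$end)$percentile,
        error = function(e) NA_real_)
    }
    list(species = sp, polymorphic = polym, tajima = taj,
         tajima_percentile = taj_pct, fst = fst,
         fst_percentile = if (polym) fst_pct else NA_real_)
  })
  names(per_species) <- species

  # LD around the locus per polymorphic species
  ld_summary <- NULL
  if (config$run_ld) {
    ld_summary <- stage("ld", {
      rows <- lapply(per_species, function(ps) {
        if (!ps$polymorphic) return(NULL)
        idv <- samples$individual[samples$species == ps$species]
        ld <- tryCatch(
          ld_matrix(g, idv, locus$chrom,
                    max(1, locus$start - config$flank),
                    locus$end + config$flank,
                    thin_to = 400L, seed = sub_seed(3)),
          error = function(e) NULL)
        if (is.null(ld)) return(NULL)
        inside <- ld$pos_i >= locus$start & ld$pos_j <= locus$end
        tibble(species = ps$species,
               mean_dprime_locus = mean(ld$Dprime[inside], na.rm = TRUE),
               mean_dprime_flank = mean(ld$Dprime[!inside], na.rm = TRUE),
               frac_high_ld = mean(ld$color_class[inside] != "white"))
      })
      bind_rows(rows)
    })
  }

  # per-species GWAS and locus PCA / heterozygote calling
  assoc_list <- list()
  pca_calls <- list()
  for (sp in species) {
    ps <- per_species[[sp]]
    if (!ps$polymorphic) next
    idv <- samples$individual[samples$species == sp]
    # locus-region SNPs are extracted first, then scored for association
    assoc_list[[sp]] <- stage("gwas", {
      gl <- region_genotypes(g, locus$chrom, locus$start, locus$end)
      gwas(gl, samples[samples$individual %in% idv, ],
           max_missing = config$shared_max_missing, q_cutoff = 0.05)
    })
    pca_calls[[sp]] <- tryCatch(stage("pca", {
      pl <- snp_pca(g, idv, locus$chrom, locus$start, locus$end,
                    max_site_missing = config$pca_max_missing)
      suppressWarnings(call_locus_genotypes(pl))
    }), error = function(e) NULL)
  }

  # genealogies on a per-species subsample of individuals; haplotype tips
  # carry morph labels inferred from locus-homozygous individuals
  trees <- stage("trees", {
    pick <- with_seed(sub_seed(5), {
      unlist(lapply(species, function(sp) {
        idv <- samples$individual[samples$species == sp]
        sample(idv, min(config$n_tree_per_species, length(idv)))
      }))
    })
    st <- samples[match(pick, samples$individual), ]
    gs <- subset_genotypes(g, pick)
    td <- tree_tip_data(st)
    if (g$phased) {
      # anchor morph labels on all individuals, not just the tree subsample
      hm <- haplotype_morph_labels(g, samples, locus$chrom, locus$start,
                                   locus$end)
      td$morph <- unname(hm[td$tip])
    }
    gt <- distance_tree(gs, td)
    lt <- distance_tree(gs, td, chrom = locus$chrom, start = locus$start,
                        end = locus$end)

    # allelic genealogy: one representative haplotype per inferred class
    rl <- rg <- NULL
    if (gs$phased) {
      reps <- class_representative_haplotypes(gs, st, pick, locus$chrom,
                                              locus$start, locus$end)
      if (length(reps) >= 4) {
        loc_idx <- sites_in_region(gs, locus$chrom, locus$start, locus$end)
        Hall <- haplotypes(gs)
        rl <- distance_tree(Hall[reps, loc_idx, drop = FALSE])
        rg <- distance_tree(Hall[reps, , drop = FALSE])
      }
    }
    list(genome = gt, locus = lt, rep_locus = rl, rep_genome = rg)
  })

  sp_dist <- species_distance_matrix(trees$genome)
  sisters <- mutual_nearest_pairs(sp_dist)
  clus <- clustering_mode(trees$locus, sister_pairs = sisters)
  elong <- if (!is.null(trees$rep_locus))
    elongation_ratio(trees$rep_locus, trees$rep_genome)
  else elongation_ratio(trees$locus, trees$genome)
  divr <- phenotype_divergence_ratio(trees$locus, trees$genome)

  shared <- NULL
  if (length(assoc_list) >= 2) {
    shared <- stage("shared_snps",
                    shared_snps(assoc_list, sp_dist,
                                freq_diff_min = config$shared_freq_diff))
  }
  # balancing-selection signatures are read from the polymorphic species,
  # as in the empirical workflow (monomorphic relatives carry no morph
  # contrast); fall back to all species if none is polymorphic
  taj_pcts <- vapply(per_species, function(x) x$tajima_percentile, 1.0)
  polym <- vapply(per_species, function(x) x$polymorphic, TRUE)
  if (any(polym)) taj_pcts <- taj_pcts[polym]

  call <- stage("discriminate", discriminate(
    clustering = clus, elongation = elong,
    tajima_percentile = taj_pcts,
    proximity_cor = if (is.null(shared)) NA_real_ else shared$proximity_cor,
    divergence_ratio = divr, thresholds = config$thresholds))

  summary <- list(
    input = if (is.null(config$preset)) "vcf" else config$preset,
    seed = config$seed,
    locus = locus,
    n_individuals = nrow(samples), n_sites = ncol(g$calls),
    fst_percentile = lapply(per_species, function(x) x$fst_percentile),
    tajima_percentile = as.list(taj_pcts),
    ld = if (is.null(ld_summary)) NULL else as.list(ld_summary),
    shared_pairs = if (is.null(shared)) NULL else as.list(shared$pairs),
    proximity_cor = if (is.null(shared)) NA else shared$proximity_cor,
    clustering_mode = clus$mode,
    elongation_ratio = elong,
    divergence_ratio = divr,
    scenario_call = list(label = call$label,
                         evidence = as.list(
                           setNames(call$evidence$value,
                                    call$evidence$criterion))))

  report <- structure(
    list(summary = summary, call = call, genotypes = g, samples = samples,
         per_species = per_species, ld = ld_summary, assoc = assoc_list,
         locus_calls = pca_calls, shared = shared, trees = trees,
         sim = sim, config = config),
    class = "scan_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @exportS3Method base::print
print.scan_report <- function(x, ...) {
  cat("<scan_report> input:", x$summary$input, "\n")
  cat("  scenario call:", x$call$label, "(clustering",
      x$summary$clustering_mode, ")\n")
  cat("  locus Tajima percentile (median):",
      round(median(unlist(x$summary$tajima_percentile), na.rm = TRUE), 1),
      "\n")
  invisible(x)
}

#' @noRd
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  manifest <- list(
    config_hash = rlang::hash(report$config),
    seed = report$config$seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("supergene")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (sp in names(report$per_species)) {
    ps <- report$per_species[[sp]]
    utils::write.table(ps$tajima, file.path(out_dir,
                                            paste0("tajima_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ps$fst))
      utils::write.table(ps$fst, file.path(out_dir,
                                           paste0("fst_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ape::write.tree(report$trees$genome, file.path(out_dir, "genome_tree.nwk"))
  ape::write.tree(report$trees$locus, file.path(out_dir, "locus_tree.nwk"))
  invisible(out_dir)
}

#' Drop windows in the bottom quantile of a count column
#' @noRd
drop_sparse_by <- function(stat_windows, count_col, quantile) {
  w <- stat_windows
  names(w)[names(w) == count_col] <- "n_variants"
  out <- suppressWarnings(drop_sparse_windows(w, quantile))
  names(out)[names(out) == "n_variants"] <- count_col
  out
}

#' Mean between-species path distance on a labeled tree
#' @noRd
species_distance_matrix <- function(tree) {
  td <- attr(tree, "tip_data")
  cd <- ape::cophenetic.phylo(tree)
  sp <- unique(td$species)
  d <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    a <- td$tip[td$species == sp[i]]; b <- td$tip[td$species == sp[j]]
    d[i, j] <- d[j, i] <- mean(cd[a, b])
  }
  d
}

#' Mutual-nearest-neighbour species pairs (candidate sisters)
#' @noRd
mutual_nearest_pairs <- function(d) {
  sp <- rownames(d)
  if (length(sp) < 2) return(list())
  nn <- vapply(sp, function(s) {
    others <- setdiff(sp, s)
    others[which.min(d[s, others])]
  }, "")
  out <- list()
  for (s in sp)
    if (nn[[nn[[s]]]] == s && s < nn[[s]])
      out[[length(out) + 1]] <- c(s, nn[[s]])
  out
}
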