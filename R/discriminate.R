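#' Discriminate evolutionary scenarios for a shared locus
#'
#' Combines the genealogical and population-genetic signatures into a call
#' among the four hypotheses for a mimicry locus shared across species:
#'
#' * alleles clustering **by phenotype** across non-sister species means
#'   allele sharing: *introgression* when the between-phenotype locus
#'   divergence is shallow relative to the species radiation, *incomplete
#'   lineage sorting* when it is at least as deep;
#' * alleles clustering **by species** means distinct alleles per lineage:
#'   *allelic turnover* when a weighted majority of the balancing-selection
#'   signatures fires (terminal-branch elongation above `r_star`, locus
#'   Tajima's D percentile at or above `p_star`, and a positive
#'   sharing-versus-proximity correlation), otherwise *independent* origin;
#' * contradictory evidence yields `mixed/uncertain`, never a silently
#'   coerced label.
#'
#' @param clustering result of [clustering_mode()] on the locus tree
#' @param elongation result of [elongation_ratio()]
#' @param tajima_percentile per-species locus Tajima's D percentile(s);
#'   summarized by their median
#' @param proximity_cor Spearman correlation between shared associated
#'   SNP counts and phylogenetic proximity (from [shared_snps()])
#' @param divergence_ratio result of [phenotype_divergence_ratio()]
#' @param thresholds list with `r_star` (default 1.2), `p_star` (default
#'   90), `depth_ratio` (default 1.25), `cor_min` (default 0)
#' @return a `scenario_call`: `label` in `{introgression, ils, turnover,
#'   independent, mixed/uncertain}` plus the per-criterion evidence
#' @export
discriminate <- function(clustering, elongation, tajima_percentile,
                         proximity_cor, divergence_ratio,
                         thresholds = list()) {
  th <- modifyList(list(r_star = 1.2, p_star = 90, depth_ratio = 1.25,
                        cor_min = 0), thresholds)
  pct <- median(tajima_percentile, na.rm = TRUE)

  votes <- c(
    elongation = isTRUE(elongation > th$r_star),
    tajima = isTRUE(pct >= th$p_star),
    sharing = isTRUE(!is.na(proximity_cor) && proximity_cor > th$cor_min))

  label <- switch(
    clustering$mode,
    by_phenotype = if (isTRUE(divergence_ratio < th$depth_ratio))
      "introgression" else "ils",
    by_species = if (sum(votes) >= 2) "turnover" else "independent",
    "mixed/uncertain")

  evidence <- tibble(
    criterion = c("clustering_mode", "clustering_support",
                  "divergence_ratio", "elongation_ratio",
                  "tajima_percentile", "proximity_cor",
                  "votes_turnover"),
    value = c(clustering$mode, format(clustering$support),
              format(divergence_ratio), format(elongation),
              format(pct), format(proximity_cor),
              format(sum(votes))))

  structure(list(label = label, evidence = evidence, votes = votes,
                 thresholds = th, clustering = clustering),
            class = "scenario_call")
}

#' @exportS3Method base::print
print.scenario_call <- function(x, ...) {
  cat("<scenario_call> label:", x$label, "\n")
  print(x$evidence, n = Inf)
  invisible(x)
}

#' @export
tidy.scenario_call <- function(x, ...) x$evidence

#' @export
glance.scenario_call <- function(x, ...) {
  tibble(label = x$label, clustering_mode = x$clustering$mode,
         votes_turnover = sum(x$votes))
}
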