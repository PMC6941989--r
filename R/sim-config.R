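#' Simulation configuration
#'
#' Parameters of the forward-time Wright-Fisher simulator: multiple
#' diploid species diverging along a rooted species tree, each carrying a
#' recombination-suppressed mimicry supergene window under negative
#' frequency-dependent selection (NFDS). An individual expressing
#' phenotype class `k` at within-species frequency `f_k` has fitness
#' `w = 1 - s * f_k`; `s = 0` recovers neutrality.
#'
#' @param n_diploids_per_species population size N of every species
#' @param n_gen total simulated generations (burn-in included)
#' @param splits tibble with columns `gen`, `parent`, `child`: at `gen`
#'   the `child` species is an instantaneous copy of `parent`. An empty
#'   tibble simulates a single population.
#' @param species species labels; the first is the founding lineage
#' @param genome_length chromosome length in bp
#' @param n_sites number of candidate SNP positions on the chromosome
#' @param locus_interval length-2 vector, 1-based inclusive bp interval
#'   of the mimicry locus
#' @param locus_site_count how many of the candidate sites to place inside
#'   the locus (locus SNP density is typically higher than background)
#' @param mu_neutral per-site per-generation mutation probability
#' @param mu_allele per-haplotype per-generation probability of spawning a
#'   new mimicry allele class (turnover innovation)
#' @param n_markers linked variants seeded by each innovation event,
#'   emulating the multi-substitution divergence of functional alleles
#' @param n_anc_classes allele classes segregating in the founding
#'   population (1 = monomorphic ancestor, 2 = ancestral polymorphism)
#' @param anc_marker_sites diagnostic locus sites distinguishing the two
#'   ancestral classes
#' @param s NFDS selection coefficient in \[0, 1\]
#' @param dominance `"derived"` (newer allele classes dominant, the
#'   default) or `"ancestral"`; heterozygote phenotype is the
#'   higher-ranked class
#' @param crossover_rate expected crossovers per haplotype per generation
#' @param suppress_locus_xover drop crossover breakpoints falling inside
#'   the locus (the supergene's recombination suppression)
#' @param gc_rate gene-conversion initiations per haplotype per generation
#' @param gc_tract_mean mean conversion tract length in bp (geometric)
#' @param migration tibble (`gen_start`, `gen_end`, `donor`, `recipient`,
#'   `rate`): per generation in the interval, Binomial(2N, rate) recipient
#'   haplotypes are replaced by random donor haplotypes
#' @param forced_innovations tibble (`gen`, `species`, `n_copies`): a new
#'   allele class founded at `gen` and seeded in `n_copies` haplotypes
#' @param n_sample individuals sampled per species at the end
#' @param log_interval generations between allele-frequency log records
#' @param seed RNG seed
#' @param scenario_preset label recording which preset built the config
#' @return a `sim_config`
#' @export
sim_config <- function(n_diploids_per_species = 100,
                       n_gen = 1000,
                       splits = empty_splits(),
                       species = "A",
                       genome_length = 2.5e6,
                       n_sites = 5000,
                       locus_interval = c(1200001, 1300000),
                       locus_site_count = 600,
                       mu_neutral = 1e-4,
                       mu_allele = 0,
                       n_markers = 5,
                       n_anc_classes = 1,
                       anc_marker_sites = 60,
                       s = 0,
                       dominance = c("derived", "ancestral"),
                       crossover_rate = 1.0,
                       suppress_locus_xover = TRUE,
                       gc_rate = 0.3,
                       gc_tract_mean = 500,
                       migration = empty_migration(),
                       forced_innovations = empty_innovations(),
                       n_sample = 20,
                       log_interval = 100,
                       seed = 1,
                       scenario_preset = "custom") {
  dominance <- match.arg(dominance)
  cfg <- list(n_diploids_per_species = n_diploids_per_species,
              n_gen = as.integer(n_gen),
              splits = as_tibble(splits), species = species,
              genome_length = genome_length, n_sites = as.integer(n_sites),
              locus_interval = locus_interval,
              locus_site_count = as.integer(locus_site_count),
              mu_neutral = mu_neutral, mu_allele = mu_allele,
              n_markers = as.integer(n_markers),
              n_anc_classes = as.integer(n_anc_classes),
              anc_marker_sites = as.integer(anc_marker_sites),
              s = s, dominance = dominance,
              crossover_rate = crossover_rate,
              suppress_locus_xover = suppress_locus_xover,
              gc_rate = gc_rate, gc_tract_mean = gc_tract_mean,
              migration = as_tibble(migration),
              forced_innovations = as_tibble(forced_innovations),
              n_sample = as.integer(n_sample),
              log_interval = as.integer(log_interval),
              seed = as.integer(seed), scenario_preset = scenario_preset)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @noRd
empty_splits <- function() tibble(gen = integer(), parent = character(),
                                  child = character())
#' @noRd
empty_migration <- function() tibble(gen_start = integer(),
                                     gen_end = integer(),
                                     donor = character(),
                                     recipient = character(),
                                     rate = numeric())
#' @noRd
empty_innovations <- function() tibble(gen = integer(), species = character(),
                                       n_copies = integer())

#' @noRd
validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_diploids_per_species >= 2, n_gen >= 1,
              mu_neutral >= 0, mu_neutral <= 1,
              mu_allele >= 0, mu_allele <= 1,
              s >= 0, s <= 1,
              gc_tract_mean >= 1, crossover_rate >= 0, gc_rate >= 0,
              n_sample <= n_diploids_per_species)
    if (locus_interval[1] < 1 || locus_interval[2] > genome_length ||
        locus_interval[1] >= locus_interval[2])
      stop("locus_interval must lie within [1, genome_length]")
    if (nrow(splits)) {
      stopifnot(all(splits$gen > 0), all(splits$gen <= n_gen))
      known <- species[1]
      for (i in order(splits$gen)) {
        if (!splits$parent[i] %in% known)
          stop("split parent '", splits$parent[i],
               "' does not exist at generation ", splits$gen[i])
        known <- c(known, splits$child[i])
      }
      if (!setequal(known, species)) stop("species/splits mismatch")
    }
    if (nrow(migration))
      stopifnot(all(migration$rate >= 0), all(migration$rate <= 1))
  })
  cfg
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config> preset:", x$scenario_preset, "\n")
  cat("  ", length(x$species), " species (",
      paste(x$species, collapse = ","), "), N=",
      x$n_diploids_per_species, ", ", x$n_gen, " generations\n", sep = "")
  cat("  s=", x$s, " mu=", x$mu_neutral, " mu_allele=", x$mu_allele,
      " xover=", x$crossover_rate, " gc=", x$gc_rate, "\n", sep = "")
  invisible(x)
}

#' Scenario presets for the four-hypothesis contrast
#'
#' Fully-populated configurations for a four-species tree with topology
#' `((A,B),(C,D))` and staggered splits (the phylogenetic-proximity
#' gradient), each designed to realize one evolutionary scenario for the
#' mimicry locus:
#'
#' * `neutral` — ancestral two-allele polymorphism, `s = 0`, no
#'   migration: the drift control (N = 200).
#' * `ils` — ancestral balanced polymorphism (`s > 0`, `mu_allele = 0`)
#'   with recent splits, so every descendant retains the ancestral
#'   alleles.
#' * `turnover` — ancestral balanced polymorphism with ongoing innovation
#'   (`mu_allele > 0`) over a deep tree, so extant alleles are
#'   species-specific descendants of the ancestral ones.
#' * `independent` — monomorphic ancestor; each species founds its own
#'   allele after its final split.
#' * `introgression` — monomorphic ancestor; a young allele arises in
#'   species A and crosses into non-sister species C by migration.
#'
#' @param name one of `neutral`, `introgression`, `ils`, `turnover`,
#'   `independent`
#' @param seed RNG seed stored in the config
#' @return a `sim_config`
#' @export
scenario_preset <- function(name = c("neutral", "introgression", "ils",
                                     "turnover", "independent"),
                            seed = 1) {
  name <- match.arg(name)
  four <- function(root, ab, cd)
    tibble(gen = c(root, ab, cd),
           parent = c("A", "A", "C"),
           child = c("C", "B", "D"))
  sp <- c("A", "C", "B", "D")

  switch(name,
    neutral = sim_config(
      n_diploids_per_species = 200, n_gen = 1100,
      splits = four(300, 700, 900), species = sp,
      s = 0, mu_allele = 0, n_anc_classes = 2,
      locus_site_count = 200,  # uniform SNP density: the locus is a
                               # plain window in the drift control
      seed = seed, scenario_preset = "neutral"),
    ils = sim_config(
      n_diploids_per_species = 100, n_gen = 850,
      splits = four(500, 650, 750), species = sp,
      s = 0.6, mu_allele = 0, n_anc_classes = 2,
      seed = seed, scenario_preset = "ils"),
    turnover = sim_config(
      n_diploids_per_species = 100, n_gen = 2200,
      splits = four(400, 1400, 1800), species = sp,
      s = 0.7, mu_allele = 3e-4, n_anc_classes = 2,
      gc_rate = 2, gc_tract_mean = 1000,
      seed = seed, scenario_preset = "turnover"),
    independent = sim_config(
      n_diploids_per_species = 100, n_gen = 2200,
      splits = four(400, 1400, 1800), species = sp,
      s = 0.35, mu_allele = 0, n_anc_classes = 1,
      forced_innovations = tibble(gen = rep(2150L, 4),
                                  species = c("A", "B", "C", "D"),
                                  n_copies = rep(10L, 4)),
      seed = seed, scenario_preset = "independent"),
    introgression = sim_config(
      n_diploids_per_species = 100, n_gen = 2200,
      splits = four(400, 1400, 1800), species = sp,
      s = 0.5, mu_allele = 0, n_anc_classes = 1,
      forced_innovations = tibble(gen = 1850L, species = "A",
                                  n_copies = 10L),
      migration = tibble(gen_start = 1900L, gen_end = 1950L,
                         donor = "A", recipient = "C", rate = 0.002),
      seed = seed, scenario_preset = "introgression"))
}
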