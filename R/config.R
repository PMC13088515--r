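#' Simulation configuration for a pedigreed population with a planted lethal
#'
#' Collects every tunable of the forward simulator: population structure
#' (founders, generations, matings per generation, popular-sire usage), the
#' marker panel (count, genome length), the planted lethal haplotype (founder
#' frequency, region span, stage at which homozygotes die), and the breeding
#' record process (baseline insemination success, stillbirth and juvenile
#' mortality base rates, re-mating and registration behaviour).
#'
#' The planted lethal is realised as an off-chip causal variant in the middle
#' of a multi-marker haplotype region; recombination can separate the two, so
#' a small number of haplotype-homozygous but variant-heterozygous animals
#' (recombinants) arise naturally, as observed in real data.
#'
#' @param n_founders number of founder animals (half of each sex).
#' @param n_generations number of non-founder generations bred (>= 2 gives
#'   maternal grandsires known for risk2 classification).
#' @param n_matings_per_generation breeding attempts per generation; defaults
#'   to `n_founders`.
#' @param popular_sire_fraction fraction of males designated heavily used
#'   sires; they receive the bulk of matings (popular-sire effect).
#' @param n_markers number of chip markers, uniformly spaced.
#' @param genome_length_bp simulated autosome length in bp (>= 2 Mb).
#' @param q_lethal founder frequency of the lethal haplotype, in (0, 0.5).
#' @param lethal_region_bp span of the planted haplotype region (>= 1 Mb).
#' @param penetrance_stage when homozygotes die: `"embryonic"` (conception
#'   lost, mating fails), `"stillbirth"`, `"juvenile"` (death < 365 d) or
#'   `"none"` (neutral haplotype).
#' @param baseline_insemination_success per-mating success probability absent
#'   lethality (horses: roughly 0.6-0.77 per cycle).
#' @param baseline_stillbirth base stillbirth probability among born foals.
#' @param baseline_juvenile_mortality base probability a live-born foal dies
#'   within its first year.
#' @param remating_prob probability a failed insemination is re-attempted
#'   within 10 days (same sire and dam).
#' @param registration_completeness probability a mating is present in the
#'   exported mating records.
#' @param rng_seed integer seed; identical config implies identical output.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 5,
                       n_matings_per_generation = n_founders,
                       popular_sire_fraction = 0.10,
                       n_markers = 120,
                       genome_length_bp = 10e6,
                       q_lethal = 0.08,
                       lethal_region_bp = 1.5e6,
                       penetrance_stage = c("embryonic", "stillbirth",
                                            "juvenile", "none"),
                       baseline_insemination_success = 0.65,
                       baseline_stillbirth = 0.04,
                       baseline_juvenile_mortality = 0.05,
                       remating_prob = 0.5,
                       registration_completeness = 0.9,
                       rng_seed = 1L) {
  penetrance_stage <- match.arg(penetrance_stage)
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_matings_per_generation = as.integer(n_matings_per_generation),
    popular_sire_fraction = popular_sire_fraction,
    n_markers = as.integer(n_markers),
    genome_length_bp = as.numeric(genome_length_bp),
    q_lethal = q_lethal,
    lethal_region_bp = as.numeric(lethal_region_bp),
    penetrance_stage = penetrance_stage,
    baseline_insemination_success = baseline_insemination_success,
    baseline_stillbirth = baseline_stillbirth,
    baseline_juvenile_mortality = baseline_juvenile_mortality,
    remating_prob = remating_prob,
    registration_completeness = registration_completeness,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c("popular_sire_fraction", "baseline_insemination_success",
             "baseline_stillbirth", "baseline_juvenile_mortality",
             "remating_prob", "registration_completeness")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a probability in [0, 1]", p))
  }
  if (!(cfg$q_lethal > 0 && cfg$q_lethal < 0.5))
    stop("q_lethal must lie in (0, 0.5)")
  if (cfg$n_markers < 2L)
    stop("n_markers must be >= 2")
  if (cfg$genome_length_bp < 2e6)
    stop("genome_length_bp must be >= 2,000,000 (at least one 2-Mb window)")
  if (cfg$lethal_region_bp < 1e6 || cfg$lethal_region_bp >= cfg$genome_length_bp)
    stop("lethal_region_bp must be >= 1 Mb and smaller than the genome")
  if (cfg$n_founders < 2L)
    stop("n_founders must be >= 2")
  if (cfg$n_generations < 2L)
    stop("n_generations must be >= 2 (no informative matings otherwise)")
  if (cfg$n_matings_per_generation < 1L)
    stop("n_matings_per_generation must be >= 1")
  n_lethal <- round(2L * cfg$n_founders * cfg$q_lethal)
  if (n_lethal < 1)
    stop("q_lethal implies zero lethal founder chromosomes at this n_founders")
  invisible(cfg)
}

#' Read a simulation config from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [sim_config()]; absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(sim_config, raw)
}
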