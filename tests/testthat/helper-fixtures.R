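# Shared fixtures: small simulations (cached per test run) and hand-built
# phased genotype objects.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_population(config)
  .sim_cache[[key]]
}

small_cfg <- function(seed = 1, ...) {
  sim_config(n_founders = 150, n_generations = 3,
             n_matings_per_generation = 150, n_markers = 60,
             genome_length_bp = 6e6, rng_seed = seed, ...)
}

# config used for detection-power style checks: ~5,000 genotyped animals from
# a large founder base and two offspring generations, so the planted
# frequency stays near its founder value
detection_cfg <- function(seed, n_founders = 3000,
                          n_matings = 2500) {
  # 18 markers/Mb matches the post-QC density of a 70K equine chip
  sim_config(n_founders = n_founders, n_generations = 2,
             n_matings_per_generation = n_matings, q_lethal = 0.07,
             n_markers = 180, genome_length_bp = 10e6, rng_seed = seed)
}

# tiny phased set: 3 animals x 2 markers with diplotypes
# (AB|AB), (AB|ab), (ab|ab) coded 0 = A/B-first alleles
toy_phased <- function() {
  map <- data.frame(chrom = "1", marker_id = c("m1", "m2"),
                    pos_bp = c(100L, 200L), allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  h1 <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L))
  h2 <- rbind(c(0L, 0L), c(1L, 1L), c(1L, 1L))
  phased_genotypes(c("a1", "a2", "a3"), map, h1, h2)
}

random_phased <- function(n = 20, m = 6, seed = 42) {
  set.seed(seed)
  map <- data.frame(chrom = "1", marker_id = sprintf("m%02d", 1:m),
                    pos_bp = seq(1, 3e6, length.out = m),
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  phased_genotypes(sprintf("a%02d", 1:n), map,
                   matrix(rbinom(n * m, 1, 0.5), n),
                   matrix(rbinom(n * m, 1, 0.5), n))
}

# independent lower-tail binomial oracle: direct term-by-term summation in
# log space (never calls pbinom)
binom_lower_tail_oracle <- function(obs, n, p) {
  if (p == 0) return(1)
  if (p == 1) return(if (obs >= n) 1 else 0)
  i <- 0:obs
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}
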