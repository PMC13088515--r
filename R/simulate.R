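## Forward gene-drop simulator: pedigree, phased genotypes with a planted
## recessive lethal, and breeding records. One interleaved engine backs the
## staged accessors (simulate_pedigree / gene_drop / simulate_matings),
## because embryonic removals must be known before later parents are drawn.

#' Simulate a pedigreed population segregating a planted recessive lethal
#'
#' Runs the full forward simulation: founders receive phased haplotypes with
#' the lethal haplotype at frequency `q_lethal` (an exact count of founder
#' chromosomes), each non-founder inherits one recombined haplotype per parent
#' (one crossover per meiosis at a uniform position), homozygotes for the
#' causal variant die at the configured stage, and every breeding attempt is
#' logged with success, optional re-mating within 10 days and probabilistic
#' registration.
#'
#' @param config a [sim_config()].
#' @return an object of class `lethal_sim`: a list with `pedigree` (born
#'   animals), `genotypes` (a `phased_genotypes` object for animals alive at
#'   one year), `map` marker map, `matings`/`foals` (registered records),
#'   `all_matings` (ground-truth mating outcomes incl. unregistered ones) and
#'   `true_state` (planted region, causal genotypes, embryonic removals).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)

  L <- config$genome_length_bp
  M <- config$n_markers
  map <- data.frame(
    chrom = "1",
    marker_id = sprintf("M%04d", seq_len(M)),
    pos_bp = round(seq(1, L, length.out = M)),
    allele1 = "A",
    allele2 = "B",
    stringsAsFactors = FALSE
  )

  ## planted region: centred, spanning lethal_region_bp; causal variant is an
  ## off-chip locus at the region centre
  region_start <- round(L / 2 - config$lethal_region_bp / 2)
  region_end <- region_start + config$lethal_region_bp
  causal_pos <- round((region_start + region_end) / 2) + 1L
  while (causal_pos %in% map$pos_bp) causal_pos <- causal_pos + 1L

  pos_all <- sort(c(map$pos_bp, causal_pos))
  causal_idx <- match(causal_pos, pos_all)
  chip_idx <- which(pos_all != causal_pos)
  n_loci <- length(pos_all)
  region_marker_idx <- which(map$pos_bp >= region_start & map$pos_bp < region_end)
  if (length(region_marker_idx) < 2L)
    stop("planted region spans fewer than 2 chip markers; increase n_markers")

  ## founder haplotypes: neutral allele frequencies Uniform(0.05, 0.95);
  ## lethal chromosomes get a fixed random allele string over region markers
  ## plus the causal allele
  F <- config$n_founders
  G <- config$n_generations
  Mt <- config$n_matings_per_generation
  max_animals <- F + G * Mt
  H <- matrix(0L, nrow = 2L * max_animals, ncol = n_loci)

  freqs <- stats::runif(n_loci, 0.05, 0.95)
  n_chr <- 2L * F
  H[seq_len(n_chr), ] <- matrix(
    as.integer(stats::runif(n_chr * n_loci) < rep(freqs, each = n_chr)),
    nrow = n_chr
  )
  lethal_string <- as.integer(stats::runif(length(region_marker_idx)) < 0.5)
  n_lethal <- as.integer(round(2L * F * config$q_lethal))
  if (config$penetrance_stage == "none") {
    lethal_rows <- sample.int(n_chr, n_lethal)
  } else {
    ## founders are living animals, so none may be homozygous for the lethal:
    ## one lethal chromosome in each of n_lethal distinct founders
    founder_pick <- sample.int(F, n_lethal)
    lethal_rows <- 2L * founder_pick - sample(c(0L, 1L), n_lethal,
                                              replace = TRUE)
  }
  H[lethal_rows, chip_idx[region_marker_idx]] <-
    matrix(lethal_string, nrow = n_lethal, ncol = length(lethal_string),
           byrow = TRUE)
  H[, causal_idx] <- 0L
  H[lethal_rows, causal_idx] <- 1L

  ## animal table (preallocated); founders are generation 0
  ids <- sprintf("A%06d", seq_len(max_animals))
  sex <- character(max_animals)
  sire <- dam <- rep(NA_character_, max_animals)
  birth <- rep(NA_real_, max_animals)
  gen <- integer(max_animals)
  dead_at_birth <- logical(max_animals)
  death_date <- rep(NA_real_, max_animals)
  popular <- logical(max_animals)
  causal_dose <- integer(max_animals)

  sex[seq_len(F)] <- rep(c("M", "F"), length.out = F)
  birth[seq_len(F)] <- sample(0:200, F, replace = TRUE)
  gen[seq_len(F)] <- 0L
  popular[seq_len(F)] <- sex[seq_len(F)] == "M" &
    stats::runif(F) < config$popular_sire_fraction
  causal_dose[seq_len(F)] <- H[2L * seq_len(F) - 1L, causal_idx] +
    H[2L * seq_len(F), causal_idx]

  n_animals <- F
  embryonic <- config$penetrance_stage == "embryonic"

  mat_list <- vector("list", G)
  removal_list <- vector("list", G)

  gamete_rows <- function(parent_ids_idx) {
    ## one gamete per parent index: coin-flip strand order, single crossover
    ## at a position uniform on (0, L)
    k <- length(parent_ids_idx)
    r1 <- 2L * parent_ids_idx - 1L
    r2 <- 2L * parent_ids_idx
    flip <- stats::runif(k) < 0.5
    a <- ifelse(flip, r2, r1)
    b <- ifelse(flip, r1, r2)
    cross <- stats::runif(k, 0, L)
    mask <- outer(cross, pos_all, ">=")   # TRUE: take strand a
    H[a, , drop = FALSE] * mask + H[b, , drop = FALSE] * (1 - mask)
  }

  for (g in seq_len(G)) {
    adult <- seq_len(n_animals)
    adult <- adult[!dead_at_birth[adult] &
                     (is.na(death_date[adult]) |
                        death_date[adult] - birth[adult] > 365)]
    males <- adult[sex[adult] == "M"]
    females <- adult[sex[adult] == "F"]
    if (!length(males) || !length(females))
      stop("population died out: no adult of one sex in generation ", g)

    ## one breeding attempt per dam and season: a mare cannot carry two
    ## overlapping conceptions
    Mt_g <- min(Mt, length(females))
    w <- ifelse(popular[males], 21, 1)  # popular sires take ~70% of matings
    sires_g <- males[sample.int(length(males), Mt_g, replace = TRUE,
                                prob = w / sum(w))]
    dams_g <- females[sample.int(length(females), Mt_g)]
    dates_g <- 1000 * g + sample(0:200, Mt_g, replace = TRUE)

    conceived <- stats::runif(Mt_g) < config$baseline_insemination_success
    kc <- sum(conceived)
    foal_of <- rep(NA_character_, Mt_g)
    lethal_conc <- logical(Mt_g)

    if (kc > 0) {
      gs <- gamete_rows(sires_g[conceived])
      gd <- gamete_rows(dams_g[conceived])
      dose <- gs[, causal_idx] + gd[, causal_idx]
      lethal_conc[conceived] <- dose == 2L

      born_sub <- if (embryonic) dose < 2L else rep(TRUE, kc)
      nb <- sum(born_sub)
      if (nb > 0) {
        idx_new <- n_animals + seq_len(nb)
        H[2L * idx_new - 1L, ] <- gs[born_sub, , drop = FALSE]
        H[2L * idx_new, ] <- gd[born_sub, , drop = FALSE]

        which_conc <- which(conceived)[born_sub]
        sex[idx_new] <- ifelse(stats::runif(nb) < 0.5, "M", "F")
        sire[idx_new] <- ids[sires_g[which_conc]]
        dam[idx_new] <- ids[dams_g[which_conc]]
        birth[idx_new] <- dates_g[which_conc] + 340
        gen[idx_new] <- g
        popular[idx_new] <- sex[idx_new] == "M" &
          stats::runif(nb) < config$popular_sire_fraction
        causal_dose[idx_new] <- dose[born_sub]

        lethal_born <- dose[born_sub] == 2L
        sb <- stats::runif(nb) < config$baseline_stillbirth
        if (config$penetrance_stage == "stillbirth") sb <- sb | lethal_born
        dead_at_birth[idx_new] <- sb
        death_date[idx_new][sb] <- birth[idx_new][sb]

        jv <- !sb & stats::runif(nb) < config$baseline_juvenile_mortality
        jday <- sample(1:365, nb, replace = TRUE)
        if (config$penetrance_stage == "juvenile") {
          jl <- !sb & lethal_born
          jday[jl] <- sample(1:364, sum(jl), replace = TRUE)
          jv <- jv | jl
        }
        death_date[idx_new][jv] <- birth[idx_new][jv] + jday[jv]

        foal_of[which_conc] <- ids[idx_new]
        n_animals <- n_animals + nb
      }
    }

    success <- !is.na(foal_of)
    mat_g <- data.frame(
      sire_id = ids[sires_g], dam_id = ids[dams_g], date = dates_g,
      generation = g, is_remating = FALSE, success = success,
      foal_id = foal_of, stringsAsFactors = FALSE
    )
    failed <- which(!success)
    redo <- failed[stats::runif(length(failed)) < config$remating_prob]
    if (length(redo)) {
      re <- mat_g[redo, ]
      re$date <- re$date + sample(1:10, length(redo), replace = TRUE)
      re$is_remating <- TRUE
      re$success <- FALSE
      mat_g <- rbind(mat_g, re)
    }
    mat_list[[g]] <- mat_g
    rem <- conceived & lethal_conc & embryonic
    removal_list[[g]] <- data.frame(
      sire_id = ids[sires_g[rem]], dam_id = ids[dams_g[rem]],
      date = dates_g[rem], generation = rep(g, sum(rem)),
      stringsAsFactors = FALSE
    )
  }

  keep <- seq_len(n_animals)
  pedigree <- data.frame(
    animal_id = ids[keep], sire_id = sire[keep], dam_id = dam[keep],
    birth_date = birth[keep], sex = sex[keep], generation = gen[keep],
    stringsAsFactors = FALSE
  )
  all_matings <- do.call(rbind, mat_list)
  all_matings$registered <-
    stats::runif(nrow(all_matings)) < config$registration_completeness
  removals <- do.call(rbind, removal_list)

  ## genotyped animals: alive at one year (stillborn and juvenile deaths are
  ## never sampled, which is what creates the homozygote deficit for
  ## later-acting stages too)
  geno_keep <- keep[!dead_at_birth[keep] &
                      (is.na(death_date[keep]) |
                         death_date[keep] - birth[keep] > 365)]
  rows1 <- 2L * geno_keep - 1L
  rows2 <- 2L * geno_keep
  h1 <- H[rows1, chip_idx, drop = FALSE]
  h2 <- H[rows2, chip_idx, drop = FALSE]
  rownames(h1) <- rownames(h2) <- ids[geno_keep]
  genotypes <- phased_genotypes(ids[geno_keep], map, h1, h2)

  is_foal <- keep[gen[keep] > 0L]
  foals <- data.frame(
    foal_id = ids[is_foal], dam_id = dam[is_foal], sire_id = sire[is_foal],
    birth_date = birth[is_foal],
    dead_at_birth = as.integer(dead_at_birth[is_foal]),
    death_date = death_date[is_foal], stringsAsFactors = FALSE
  )

  causal_geno <- causal_dose[keep]
  names(causal_geno) <- ids[keep]
  carrier_hap <- hap_strand_matches(
    H[2L * keep - 1L, chip_idx[region_marker_idx], drop = FALSE],
    H[2L * keep, chip_idx[region_marker_idx], drop = FALSE],
    lethal_string
  )
  names(carrier_hap) <- ids[keep]

  true_state <- list(
    region = list(chrom = "1", start = region_start, end = region_end),
    causal_pos = causal_pos,
    lethal_string = paste(lethal_string, collapse = ""),
    region_marker_ids = map$marker_id[region_marker_idx],
    causal_genotype = causal_geno,        # 0/1/2 copies of the causal allele
    haplotype_matches = carrier_hap,      # strands matching the lethal string
    embryonic_removals = removals,
    founder_lethal_chromosomes = n_lethal
  )

  out <- list(
    config = config, map = map, pedigree = pedigree, genotypes = genotypes,
    matings = all_matings[all_matings$registered,
                          c("sire_id", "dam_id", "date")],
    foals = foals, all_matings = all_matings, true_state = true_state
  )
  class(out) <- "lethal_sim"
  out
}

## number of strands per animal equal to the planted string (0, 1 or 2)
hap_strand_matches <- function(h1, h2, string) {
  m1 <- rowSums(h1 != matrix(string, nrow(h1), length(string), byrow = TRUE)) == 0
  m2 <- rowSums(h2 != matrix(string, nrow(h2), length(string), byrow = TRUE)) == 0
  as.integer(m1) + as.integer(m2)
}

#' @export
print.lethal_sim <- function(x, ...) {
  cat("lethal_sim:", nrow(x$pedigree), "animals,",
      length(x$genotypes$animal_ids), "genotyped,",
      nrow(x$all_matings), "mating records,",
      nrow(x$true_state$embryonic_removals), "embryonic removals\n")
  invisible(x)
}

#' Simulate a multi-generation pedigree with a popular-sire structure
#'
#' Convenience accessor over [simulate_population()]: returns the pedigree of
#' born animals. Founders have unknown parents; heavily used sires take the
#' majority of matings. The full simulation is cached in the `"sim"`
#' attribute so [gene_drop()] and [simulate_matings()] can reuse it.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` pedigree (animal_id, sire_id, dam_id, birth_date,
#'   sex, generation).
#' @export
simulate_pedigree <- function(config) {
  sim <- simulate_population(config)
  ped <- sim$pedigree
  attr(ped, "sim") <- sim
  ped
}

#' Drop founder haplotypes through a pedigree
#'
#' Returns the phased genotypes of animals alive at one year plus the ground
#' truth (planted region, causal-variant genotypes, embryonic removals).
#' If `pedigree` was produced by [simulate_pedigree()] the cached simulation
#' is reused; otherwise the engine is re-run from `config` (identical seed,
#' identical result).
#'
#' @param pedigree pedigree from [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (a `phased_genotypes`) and `true_state`.
#' @export
gene_drop <- function(pedigree, config) {
  sim <- attr(pedigree, "sim")
  if (is.null(sim)) sim <- simulate_population(config)
  list(genotypes = sim$genotypes, true_state = sim$true_state)
}

#' Extract registered mating and foal records from a simulation
#'
#' Matings succeed with the baseline probability, except that conceptions
#' homozygous for the causal variant are lost before birth under embryonic
#' penetrance (a 25% conditional failure for carrier-by-carrier matings).
#' Failed matings spawn a re-mating record 1-10 days later with probability
#' `remating_prob`; each mating enters the output with probability
#' `registration_completeness`.
#'
#' @param pedigree pedigree from [simulate_pedigree()].
#' @param true_state the `true_state` from [gene_drop()] (unused when the
#'   cached simulation is available; kept for the staged call signature).
#' @param config the same [sim_config()].
#' @return list with `matings` (sire_id, dam_id, date) and `foals`
#'   (foal_id, dam_id, sire_id, birth_date, dead_at_birth, death_date).
#' @export
simulate_matings <- function(pedigree, true_state = NULL, config) {
  sim <- attr(pedigree, "sim")
  if (is.null(sim)) sim <- simulate_population(config)
  list(matings = sim$matings, foals = sim$foals)
}

#' Emulate whole-genome sequencing of influential sires
#'
#' Picks the `n_sires` males with the most registered offspring among the
#' genotyped animals, labels them haplotype carriers from the planted-region
#' ground truth, and builds a variant table holding the planted causal
#' variant (a frameshift indel at its true position) plus `n_neutral`
#' unlinked neutral variants with Hardy-Weinberg genotypes at random allele
#' frequencies.
#'
#' @param sim a `lethal_sim`.
#' @param n_sires number of sequenced sires.
#' @param n_neutral number of neutral variants.
#' @param seed RNG seed for the neutral variants.
#' @return list with `variants` (data.frame), `genotypes` (sires x variants
#'   matrix of alt-allele dosages) and `carrier` (named logical vector of
#'   haplotype-carrier flags).
#' @export
simulate_sequenced_sires <- function(sim, n_sires = 25, n_neutral = 200,
                                     seed = 1L) {
  stopifnot(inherits(sim, "lethal_sim"))
  set.seed(seed)
  counts <- table(sim$foals$sire_id)
  genotyped <- sim$genotypes$animal_ids
  cand <- names(sort(counts[names(counts) %in% genotyped], decreasing = TRUE))
  if (length(cand) < n_sires)
    n_sires <- length(cand)
  sires <- cand[seq_len(n_sires)]

  matches <- sim$true_state$haplotype_matches[sires]
  carrier <- matches >= 1L

  L <- sim$config$genome_length_bp
  pos_neutral <- sort(sample.int(L, n_neutral))
  variants <- data.frame(
    variant_id = c("causal", sprintf("neu%04d", seq_len(n_neutral))),
    chrom = "1",
    pos = c(sim$true_state$causal_pos, pos_neutral),
    ref = "C",
    alt = c("CA", rep("T", n_neutral)),
    class = c("indel", rep("SNP", n_neutral)),
    sv_end = NA_real_,
    consequence = c("frameshift", sample(
      c("intron", "intergenic", "synonymous", "missense"),
      n_neutral, replace = TRUE)),
    sift = NA_real_,
    known_hom = FALSE,
    conserved = NA,
    stringsAsFactors = FALSE
  )
  variants$sift[variants$consequence == "missense"] <-
    round(stats::runif(sum(variants$consequence == "missense")), 2)

  gt <- matrix(NA_integer_, n_sires, n_neutral + 1L,
               dimnames = list(sires, variants$variant_id))
  gt[, "causal"] <- sim$true_state$causal_genotype[sires]
  pneu <- stats::runif(n_neutral, 0.01, 0.5)
  gt[, -1L] <- matrix(
    stats::rbinom(n_sires * n_neutral, 2L, rep(pneu, each = n_sires)),
    nrow = n_sires
  )
  list(variants = variants, genotypes = gt, carrier = carrier)
}
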