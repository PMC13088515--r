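# Carrier-concordance filter, consequence tiers, ranking and the
# haplotype-versus-variant discordance report.

region_fixture <- function() {
  structure(list(chrom = "1", start = 10e6, end = 12e6,
                 records = NULL, representative = NULL),
            class = "lethal_region")
}

# sires: 6 carriers + 10 non-carriers; variants crafted per criterion
filter_fixture <- function() {
  sires <- c(paste0("c", 1:6), paste0("n", 1:10))
  carrier <- setNames(c(rep(TRUE, 6), rep(FALSE, 10)), sires)
  variants <- data.frame(
    variant_id = c("good", "toofar", "fourNC", "twoHom", "misscall"),
    chrom = "1",
    pos = c(11e6, 20e6, 11e6, 11e6, 11e6),
    ref = "C", alt = "T",
    class = "SNP", sv_end = NA_real_,
    consequence = "missense", sift = 0.01, known_hom = FALSE,
    conserved = NA,
    stringsAsFactors = FALSE
  )
  gt <- matrix(0L, 16, 5, dimnames = list(sires, variants$variant_id))
  gt[1:6, "good"] <- 1L; gt[7:9, "good"] <- 1L     # all carriers het + 3 NC
  gt[1:6, "toofar"] <- 1L                          # concordant but outside
  gt[1:6, "fourNC"] <- 1L; gt[7:10, "fourNC"] <- 1L
  gt[1:6, "twoHom"] <- 1L; gt[7:8, "twoHom"] <- 2L
  gt[1:5, "misscall"] <- 1L; gt[6, "misscall"] <- NA
  list(variants = variants, genotypes = gt, carrier = carrier)
}

test_that("concordance criteria pass and fail on the constructed cases", {
  fx <- filter_fixture()
  out <- concordance_filter(fx$variants, fx$genotypes, fx$carrier,
                            region_fixture())
  expect_identical(attr(out, "status"), "ok")
  res <- setNames(out$pass, out$variant_id)
  expect_true(res[["good"]])       # 6 carrier hets + 3 non-carrier hets
  expect_false(res[["toofar"]])    # > 4 Mb from the region boundary
  expect_false(res[["fourNC"]])    # 4 non-carrier sires carry the allele
  expect_false(res[["twoHom"]])    # 2 homozygous sequenced sires
  expect_false(res[["misscall"]])  # missing carrier call fails conservatively
  # audit counts behind each decision
  g <- out[out$variant_id == "good", ]
  expect_equal(g$n_carrier_het, 6)
  expect_equal(g$n_noncarrier_with_alt, 3)
  expect_equal(out$n_hom_alt[out$variant_id == "twoHom"], 2)
})

test_that("filter output is independent of variant order and margin is half-open", {
  fx <- filter_fixture()
  perm <- c(3, 1, 5, 2, 4)
  out1 <- concordance_filter(fx$variants, fx$genotypes, fx$carrier,
                             region_fixture())
  out2 <- concordance_filter(fx$variants[perm, ],
                             fx$genotypes[, perm], fx$carrier,
                             region_fixture())
  expect_equal(out1$pass[perm], out2$pass)
  # position window is [start - margin, end + margin)
  v <- fx$variants[1, ]; v$pos <- 16e6   # exactly end + margin
  g1 <- fx$genotypes[, 1, drop = FALSE]; colnames(g1) <- v$variant_id
  expect_false(concordance_filter(v, g1, fx$carrier, region_fixture())$pass_position)
  v$pos <- 16e6 - 1
  expect_true(concordance_filter(v, g1, fx$carrier, region_fixture())$pass_position)
})

test_that("a region with no sequenced carriers is skipped with a status", {
  fx <- filter_fixture()
  none <- setNames(rep(FALSE, length(fx$carrier)), names(fx$carrier))
  expect_warning(
    out <- concordance_filter(fx$variants, fx$genotypes, none,
                              region_fixture()),
    "no sequenced carrier")
  expect_identical(attr(out, "status"), "skipped_no_carriers")
})

test_that("consequence classes map to the expected tiers", {
  variants <- data.frame(
    variant_id = paste0("v", 1:8),
    chrom = "1",
    pos = c(rep(1000L, 6), 5000L, 9000L),
    ref = "C", alt = "T",
    class = c(rep("SNP", 5), "indel", "SV", "SV"),
    sv_end = c(rep(NA, 6), 6000, 9500),
    consequence = c("frameshift", "stop_gained", "missense", "missense",
                    "synonymous", "inframe_deletion", "DEL", "DEL"),
    sift = c(NA, NA, 0.2, 0.03, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(chrom = "1", start = 5500, end = 5800)
  tiers <- classify_consequence(variants, exons)
  expect_identical(tiers, c("LoF", "LoF", "tolerated", "deleterious-missense",
                            "other", "LoF", "LoF", "other"))
  # missense without a SIFT score is 'other', with a warning
  nos <- variants[3, ]; nos$sift <- NA
  expect_warning(t2 <- classify_consequence(nos), "SIFT")
  expect_identical(t2, "other")
})

test_that("ranking puts LoF first and demotes database-homozygote/non-conserved sites", {
  cand <- data.frame(
    variant_id = c("tol", "lofB", "misHom", "mis", "lofA"),
    chrom = "1", pos = c(5, 4, 3, 2, 10),
    tier = c("tolerated", "LoF", "deleterious-missense",
             "deleterious-missense", "LoF"),
    known_hom = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    conserved = c(NA, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ranked <- rank_candidates(cand)
  # lofA is non-conserved -> demoted below lofB; misHom demoted below mis
  expect_identical(ranked$variant_id, c("lofB", "lofA", "mis", "misHom", "tol"))
  expect_identical(rank_candidates(cand[0, ]), cand[0, ])
})

test_that("discordance report flags recombinants and excludes missing calls", {
  status <- data.frame(
    animal_id = c("homRec", "homOK", "hetHidden", "het", "non", "nocall"),
    status = c("homozygous", "homozygous", "carrier", "carrier",
               "non-carrier", "carrier")
  )
  gt <- c(homRec = 1L, homOK = 2L, hetHidden = 2L, het = 1L, non = 0L,
          nocall = NA)
  rep <- check_haplotype_variant_discordance(status, gt)
  expect_identical(rep$recombinants, "homRec")
  expect_identical(rep$hidden_homozygotes, "hetHidden")
  expect_equal(rep$n_compared, 5)
  # concordant: homOK, het, non; discordant: homRec, hetHidden
  expect_equal(rep$concordance, 3 / 5)
  empty <- check_haplotype_variant_discordance(status[0, ], gt)
  expect_equal(empty$n_compared, 0)
})

test_that("simulated recombinants are flagged against the planted truth", {
  # neutral planting with a large region on a short genome makes
  # haplotype-homozygous / variant-heterozygous recombinants common
  found <- FALSE
  for (s in 1:10) {
    cfg <- sim_config(n_founders = 600, n_generations = 3,
                      n_matings_per_generation = 900, q_lethal = 0.3,
                      n_markers = 16, genome_length_bp = 4e6,
                      lethal_region_bp = 1.6e6, penetrance_stage = "none",
                      rng_seed = s)
    sim <- simulate_population(cfg)
    ids <- sim$genotypes$animal_ids
    hm <- sim$true_state$haplotype_matches[ids]
    cg <- sim$true_state$causal_genotype[ids]
    truth_rec <- ids[hm == 2L & cg < 2L]
    if (!length(truth_rec)) next
    found <- TRUE
    status <- assign_carrier_status(sim$genotypes, truth_region(sim))
    rep <- check_haplotype_variant_discordance(status, cg)
    expect_setequal(rep$recombinants, truth_rec)
    break
  }
  expect_true(found)

  # perfect LD: founders only, no meiosis, so zero discordance
  cfg0 <- sim_config(n_founders = 300, n_generations = 2,
                     n_matings_per_generation = 2, q_lethal = 0.2,
                     n_markers = 60, genome_length_bp = 4e6,
                     penetrance_stage = "none", rng_seed = 1)
  sim0 <- simulate_population(cfg0)
  founders <- sim0$pedigree$animal_id[sim0$pedigree$generation == 0]
  status0 <- assign_carrier_status(sim0$genotypes, truth_region(sim0))
  status0 <- status0[status0$animal_id %in% founders, ]
  cg0 <- sim0$true_state$causal_genotype[founders]
  rep0 <- check_haplotype_variant_discordance(status0, cg0)
  expect_length(rep0$recombinants, 0)
  expect_equal(rep0$concordance, 1)
})
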