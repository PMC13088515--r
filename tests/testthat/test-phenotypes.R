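# Risk-mating classification and the three fertility phenotypes.

make_status <- function(...) {
  s <- c(...)
  data.frame(animal_id = names(s), status = unname(s),
             stringsAsFactors = FALSE)
}

test_that("mating classification follows the risk1/risk2 rules", {
  ped <- data.frame(
    animal_id = c("damC", "damN", "damU1", "damU2", "damU3"),
    sire_id = c("mgsN", "mgsC", "mgsC", "mgsN", "mgsC"),
    dam_id = NA_character_
  )
  status <- make_status(
    sireC = "carrier", sireN = "non-carrier", sireU = "unknown",
    damC = "carrier", damN = "non-carrier",
    mgsC = "carrier", mgsN = "non-carrier"
  )
  matings <- data.frame(
    sire_id = c("sireC", "sireC", "sireC", "sireC", "sireN", "sireN", "sireU"),
    dam_id = c("damC", "damU1", "damN", "damU2", "damC", "damU3", "damC"),
    date = 1:7
  )
  cls <- classify_matings(matings, status, ped)
  expect_identical(cls$risk_category,
                   c("risk1",     # carrier sire x genotyped carrier dam
                     "risk2",     # carrier sire x ungenotyped dam, carrier MGS
                     "none",      # genotyped non-carrier dam: excluded
                     "none",      # ungenotyped dam, non-carrier MGS
                     "non-risk",  # non-carrier sire x carrier dam
                     "non-risk",  # non-carrier sire x carrier MGS
                     "excluded")) # sire status unknown
  expect_identical(cls$sire_group,
                   c(rep("carrier-sire", 4), rep("non-carrier-sire", 2),
                     "unknown-sire"))
})

test_that("every included mating falls in exactly one risk and one sire group", {
  sim <- cached_sim("small2", small_cfg(seed = 2))
  region <- truth_region(sim)
  status <- assign_carrier_status(sim$genotypes, region,
                                  all_animals = sim$pedigree$animal_id)
  cls <- classify_matings(sim$matings, status, sim$pedigree)
  expect_true(all(cls$risk_category %in%
                    c("risk1", "risk2", "non-risk", "none", "excluded")))
  expect_true(all(cls$sire_group %in%
                    c("carrier-sire", "non-carrier-sire", "unknown-sire")))
  expect_true(all((cls$risk_category == "excluded") ==
                    (cls$sire_group == "unknown-sire")))
})

test_that("re-mating chains collapse and success is counted by hand", {
  # 10 mating records; 2 are day-5 re-matings of the same pair -> 8 events;
  # 6 foals -> 6/8 = 75%
  matings <- data.frame(
    sire_id = c(paste0("s", 1:8), "s1", "s2"),
    dam_id = c(paste0("d", 1:8), "d1", "d2"),
    date = c(rep(0, 8), 5, 5)
  )
  foals <- data.frame(
    foal_id = paste0("f", 1:6), dam_id = paste0("d", 1:6),
    birth_date = rep(340, 6)
  )
  res <- insemination_success(matings, foals)
  expect_equal(res$n, 8)
  expect_equal(res$successes, 6)
  # collapsed events keep the first date of the chain
  expect_true(all(res$events$date[res$events$dam_id %in% c("d1", "d2")] == 0))

  # a re-mating at day 11 is a separate event
  m2 <- data.frame(sire_id = c("s1", "s1"), dam_id = c("d1", "d1"),
                   date = c(0, 11))
  expect_equal(insemination_success(m2, foals[0, ])$n, 2)
  m3 <- data.frame(sire_id = c("s1", "s1"), dam_id = c("d1", "d1"),
                   date = c(0, 10))
  expect_equal(insemination_success(m3, foals[0, ])$n, 1)
})

test_that("insemination success recovers the simulator's own outcome labels", {
  cfg <- sim_config(n_founders = 120, n_generations = 3,
                    n_matings_per_generation = 150, n_markers = 20,
                    genome_length_bp = 4e6, registration_completeness = 1,
                    rng_seed = 6)
  sim <- simulate_population(cfg)
  res <- insemination_success(sim$matings, sim$foals)
  am <- sim$all_matings[!sim$all_matings$is_remating, ]
  expect_equal(res$n, nrow(am))
  expect_equal(res$successes, sum(am$success))
})

test_that("stillbirth and juvenile mortality boundaries are exact", {
  foals <- data.frame(
    foal_id = paste0("f", 1:5),
    dam_id = "d", sire_id = "s",
    birth_date = c(100, 100, 100, 100, 100),
    dead_at_birth = c(1, 0, 0, 0, 0),
    death_date = c(NA, 100, 101, 465, 466)
  )
  sb <- stillbirth_rate(foals)
  expect_equal(sb$stillbirths, 2)   # flag set; death on birth day
  expect_equal(sb$n, 5)
  jm <- juvenile_mortality(foals)
  expect_equal(jm$deaths, 4)        # day 0, 0, 1 and 365; day 366 excluded
  expect_equal(jm$n, 5)
  alive <- foals; alive$dead_at_birth <- 0; alive$death_date <- NA
  expect_equal(juvenile_mortality(alive)$deaths, 0)

  # 20 foals with 3 qualifying stillbirths -> 15%
  f20 <- data.frame(foal_id = paste0("f", 1:20), dam_id = "d", sire_id = "s",
                    birth_date = 0,
                    dead_at_birth = c(rep(1, 2), rep(0, 18)),
                    death_date = c(NA, NA, 0, rep(NA, 17)))
  sb20 <- stillbirth_rate(f20)
  expect_equal(sb20$stillbirths / sb20$n, 0.15)
})

test_that("two-proportion z-test matches the closed form and is symmetric", {
  zt <- two_proportion_ztest(75, 100, 60, 100)
  # closed form: pooled p = 135/200, z = 0.15 / sqrt(p(1-p)/50)
  z_hand <- 0.15 / sqrt(0.675 * 0.325 * (1 / 100 + 1 / 100))
  expect_equal(zt$z, z_hand, tolerance = 1e-12)
  expect_equal(round(zt$z, 4), 2.2646)
  expect_equal(zt$p_value, 2 * pnorm(-z_hand), tolerance = 1e-6)
  # agrees with the continuity-uncorrected chi-square test
  pt <- prop.test(c(75, 60), c(100, 100), correct = FALSE)
  expect_equal(zt$p_value, pt$p.value, tolerance = 1e-12)

  expect_equal(two_proportion_ztest(50, 100, 50, 100)$p_value, 1)
  swap <- two_proportion_ztest(60, 100, 75, 100)
  expect_equal(swap$p_value, zt$p_value)
  expect_equal(swap$z, -zt$z)
  expect_equal(two_proportion_ztest(0, 10, 0, 20)$p_value, 1)
})

test_that("relative differences reproduce the published worked examples", {
  # reference 76.4% with comparison 47.2% is a 38.2% relative reduction
  expect_equal(round(relative_difference(76.4, 47.2), 1), 38.2)
  expect_equal(round(76.4 * (1 - 0.382), 1), 47.2)
  # reference 61.0% with comparison 60.4% is a 1.0% relative reduction
  expect_equal(round(relative_difference(61.0, 60.4), 1), 1.0)
  expect_equal(relative_difference(50, 50), 0)
  expect_error(relative_difference(0, 10), "rate_ref")
})

test_that("expected carrier-sire reduction follows 0.25 x carrier frequency", {
  expect_equal(round(expected_sire_reduction(0.165), 1), 4.1)
  expect_equal(expected_sire_reduction(0), 0)
  expect_equal(expected_sire_reduction(0.20), 5.0)
})

test_that("semen-quality comparison matches the exact rank-sum tail", {
  vals <- list(par1 = c(1:10, 11:20), par2 = c(1:10, 1:10))
  flags <- rep(c(TRUE, FALSE), each = 10)
  # par2 has tied values across groups: the rank-sum test falls back to the
  # normal approximation there (with a warning), which is fine for p ~ 1
  out <- suppressWarnings(compare_semen_quality(vals, flags))
  # exhaustive tail: both allocations of {1..20} into two groups of 10 with
  # rank sums at least as extreme as the observed split
  expect_equal(out$p_value[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(out$median_carrier[1], 5.5)
  expect_equal(out$median_noncarrier[1], 15.5)
  # identical multisets: no shift detectable
  expect_gt(out$p_value[2], 0.99)
  # Bonferroni across parameters, capped at 1
  expect_equal(out$p_adj, pmin(1, out$p_value * 2))
})

test_that("semen comparison skips a parameter with an empty group", {
  expect_warning(
    out <- compare_semen_quality(list(a = c(1, 2, 3, 4), b = c(NA, NA, 3, 4)),
                                 carrier_flags = c(TRUE, TRUE, FALSE, FALSE)),
    "skipped")
  expect_equal(nrow(out), 1)
})

test_that("risk1 contrast on simulated data approaches the 25% reduction", {
  cfg <- sim_config(n_founders = 3000, n_generations = 2,
                    n_matings_per_generation = 4500, q_lethal = 0.3,
                    n_markers = 36, genome_length_bp = 3e6,
                    lethal_region_bp = 1.2e6, registration_completeness = 1,
                    remating_prob = 0, rng_seed = 8)
  sim <- simulate_population(cfg)
  region <- truth_region(sim)
  status <- assign_carrier_status(sim$genotypes, region,
                                  all_animals = sim$pedigree$animal_id)
  cls <- classify_matings(sim$matings, status, sim$pedigree)
  tab <- mating_category_table(cls, sim$foals)
  row <- tab$contrasts[tab$contrasts$comparison == "risk1 vs non-risk" &
                         tab$contrasts$phenotype == "insemination_success", ]
  n1 <- tab$categories$n_matings[tab$categories$category == "risk1"]
  # binomial 95% interval half-width on the relative scale
  p1 <- row$rate_cmp
  half <- 1.96 * sqrt(p1 * (1 - p1) / n1) / row$rate_ref * 100
  expect_gt(n1, 200)
  expect_lt(abs(row$delta_rel_pct - 25), half + 5)
  expect_lt(row$p_value, 1e-4)
})

test_that("phenotype recomputation is order-independent", {
  sim <- cached_sim("small2", small_cfg(seed = 2))
  res1 <- insemination_success(sim$matings, sim$foals)
  perm <- sample(nrow(sim$matings))
  res2 <- insemination_success(sim$matings[perm, ], sim$foals)
  expect_equal(res1$successes, res2$successes)
  expect_equal(res1$n, res2$n)
})
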