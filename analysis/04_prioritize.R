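#!/usr/bin/env Rscript
# Stage 4: candidate causal variants from sequenced sires.
#
# Emulates whole-genome sequencing of the most influential sires, applies the
# carrier-concordance filter (variant within 4 Mb of the region, every
# sequenced carrier heterozygous with at most one homozygote, at most three
# non-carrier allele carriers), classifies consequences into impact tiers,
# ranks the candidates and reports haplotype-versus-variant discordance.

library(haplolethal)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

# the simulation is regenerated from its seed (cheaper than serialising the
# full truth) so sequenced-sire genotypes stay consistent with the VCF
cfg <- sim_config(
  n_founders = 3000, n_generations = 2, n_matings_per_generation = 2500,
  q_lethal = 0.07, n_markers = 180, genome_length_bp = 10e6,
  rng_seed = seed
)
sim <- simulate_population(cfg)
phased <- sim$genotypes

records <- scan_haplotypes(phased)
regions <- merge_significant_windows(records[records$significant, ])
ss <- simulate_sequenced_sires(sim, n_sires = 25, n_neutral = 200,
                               seed = seed)
cat(sprintf("%d sequenced sires, %d haplotype carriers among them\n",
            nrow(ss$genotypes), sum(ss$carrier)))

dir.create("results/prioritize", recursive = TRUE, showWarnings = FALSE)
for (i in seq_along(regions)) {
  filt <- concordance_filter(ss$variants, ss$genotypes, ss$carrier,
                             regions[[i]])
  cand <- filt[filt$pass, , drop = FALSE]
  cand$tier <- classify_consequence(cand)
  cand <- rank_candidates(cand)
  write.table(filt, sprintf("results/prioritize/R%d_audit.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cand, sprintf("results/prioritize/R%d_candidates.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("region R%d: %d/%d variants pass the concordance filter\n",
              i, nrow(cand), nrow(filt)))
  if (nrow(cand))
    cat(sprintf("  top candidate: %s at %s:%d (%s, tier %s)\n",
                cand$variant_id[1], cand$chrom[1], cand$pos[1],
                cand$consequence[1], cand$tier[1]))

  # how reliable is haplotype-based carrier status for this region?
  status <- assign_carrier_status(phased, regions[[i]])
  cg <- sim$true_state$causal_genotype[phased$animal_ids]
  disc <- check_haplotype_variant_discordance(status, cg)
  cat(sprintf("  haplotype/variant concordance %.4f over %d animals; %d recombinant(s)\n",
              disc$concordance, disc$n_compared, length(disc$recombinants)))
}
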