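## Candidate causal variant triage from sequenced-sire genotypes: the
## carrier-concordance filter, consequence classification, ranking, and the
## haplotype-versus-variant discordance report.

LOF_CLASSES <- c("frameshift", "stop_gained", "stop_lost", "start_lost",
                 "splice_acceptor", "splice_donor",
                 "inframe_insertion", "inframe_deletion", "inframe_indel")

#' Carrier-concordance filter for candidate causal variants
#'
#' A variant is a concordant candidate for a homozygote-deficient region when
#' (i) it lies within `margin` of the region boundaries, (ii) every sequenced
#' haplotype-carrier sire is heterozygous for it (a missing call fails) and
#' at most `max_hom` sequenced sires are homozygous for the alternate allele,
#' and (iii) at most `max_noncarrier` sequenced non-carrier sires carry the
#' alternate allele at all. Every variant is returned with per-criterion
#' flags and the counts behind each decision; candidates are the rows with
#' `pass = TRUE`.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `class` and annotation columns.
#' @param genotypes sires x variants matrix of alt-allele dosages (0/1/2,
#'   `NA` = missing), rownames = sire ids, colnames = variant ids.
#' @param carrier named logical vector: haplotype-carrier flag per sequenced
#'   sire.
#' @param region a `lethal_region` (or a list with `chrom`, `start`, `end`).
#' @param margin distance in bp added to each region boundary.
#' @param max_hom maximum homozygous-alt sequenced sires tolerated (allows
#'   one false genotype assignment).
#' @param max_noncarrier maximum non-carrier sires carrying the allele.
#' @return `variants` with added count and pass columns, ordered as input;
#'   attribute `"status"` is `"ok"` or `"skipped_no_carriers"`.
#' @export
concordance_filter <- function(variants, genotypes, carrier, region,
                               margin = 4e6, max_hom = 1,
                               max_noncarrier = 3) {
  stopifnot(identical(colnames(genotypes), variants$variant_id))
  sires <- rownames(genotypes)
  stopifnot(all(sires %in% names(carrier)))
  carrier <- carrier[sires]
  n_car <- sum(carrier)
  if (n_car == 0L) {
    attr(variants, "status") <- "skipped_no_carriers"
    warning("no sequenced carrier sires for this region; filter skipped")
    return(variants)
  }
  if (n_car < 2L)
    warning("only one sequenced carrier sire; concordance has little power")

  gt_car <- genotypes[carrier, , drop = FALSE]
  gt_non <- genotypes[!carrier, , drop = FALSE]

  variants$n_carrier_het <- colSums(gt_car == 1L, na.rm = TRUE)
  variants$n_carrier_nonhet <- n_car - variants$n_carrier_het
  variants$n_hom_alt <- colSums(genotypes == 2L, na.rm = TRUE)
  variants$n_noncarrier_with_alt <- colSums(gt_non >= 1L, na.rm = TRUE)

  variants$pass_position <- variants$chrom == region$chrom &
    variants$pos >= region$start - margin &
    variants$pos < region$end + margin
  variants$pass_carriers <- variants$n_carrier_nonhet == 0L &
    variants$n_hom_alt <= max_hom
  variants$pass_noncarriers <- variants$n_noncarrier_with_alt <= max_noncarrier
  variants$pass <- variants$pass_position & variants$pass_carriers &
    variants$pass_noncarriers
  attr(variants, "status") <- "ok"
  variants
}

#' Classify variant consequences into impact tiers
#'
#' Loss-of-function classes are splice acceptor/donor, inframe indels,
#' frameshift, stop lost, stop gained and start lost; a structural variant
#' overlapping at least one bp of any exon is also loss-of-function. Missense
#' variants are `deleterious-missense` at SIFT <= `sift_threshold` and
#' `tolerated` above it; a missense variant without a SIFT score falls to
#' `other` with a warning (never silently deleterious). Everything else is
#' `other`.
#'
#' @param variants data.frame with `class`, `consequence`, `sift`, and for
#'   SVs `pos`/`sv_end`.
#' @param exons optional data.frame of exon intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive) for the SV overlap rule.
#' @param sift_threshold deleteriousness cut-off.
#' @return character vector of tiers, one per variant:
#'   `"LoF"`, `"deleterious-missense"`, `"tolerated"` or `"other"`.
#' @export
classify_consequence <- function(variants, exons = NULL,
                                 sift_threshold = 0.05) {
  cons <- tolower(gsub("[ -]", "_", variants$consequence))
  tier <- rep("other", nrow(variants))

  is_lof <- vapply(cons, function(x)
    any(vapply(LOF_CLASSES, grepl, logical(1), x = x)), logical(1))
  tier[is_lof] <- "LoF"

  is_sv <- variants$class == "SV"
  if (any(is_sv)) {
    if (!is.null(exons) && nrow(exons)) {
      ov <- vapply(which(is_sv), function(i) {
        any(exons$chrom == variants$chrom[i] &
              exons$start <= variants$sv_end[i] &
              exons$end >= variants$pos[i])
      }, logical(1))
      tier[which(is_sv)[ov]] <- "LoF"
    }
  }

  is_mis <- grepl("missense", cons) & !is_lof & !is_sv
  has_sift <- !is.na(variants$sift)
  tier[is_mis & has_sift & variants$sift <= sift_threshold] <-
    "deleterious-missense"
  tier[is_mis & has_sift & variants$sift > sift_threshold] <- "tolerated"
  if (any(is_mis & !has_sift))
    warning(sum(is_mis & !has_sift),
            " missense variant(s) without a SIFT score classified as 'other'")
  tier
}

#' Rank concordant candidate variants
#'
#' Ordering: loss-of-function first, then deleterious missense, then
#' tolerated/other. Within a tier, variants with a known homozygote in
#' variant databases or at a non-conserved site are demoted (such evidence
#' argues against causality). Ties break deterministically by chromosome and
#' position.
#'
#' @param candidates data.frame of variants that passed
#'   [concordance_filter()]; needs `tier` (from [classify_consequence()]),
#'   `known_hom`, `conserved`, `chrom`, `pos`.
#' @return `candidates` reordered, with a `demoted` column.
#' @export
rank_candidates <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  tier_rank <- match(candidates$tier,
                     c("LoF", "deleterious-missense", "tolerated", "other"))
  tier_rank[tier_rank >= 3] <- 3
  demoted <- (!is.na(candidates$known_hom) & candidates$known_hom) |
    (!is.na(candidates$conserved) & !candidates$conserved)
  candidates$demoted <- demoted
  candidates[order(tier_rank, demoted, candidates$chrom, candidates$pos), ,
             drop = FALSE]
}

#' Haplotype-versus-variant discordance report
#'
#' Animals homozygous for the haplotype but not homozygous for the candidate
#' variant are recombinants (the haplotype test overcalls them); animals
#' heterozygous for the haplotype but homozygous for the variant are the
#' converse. Animals with a missing variant genotype are excluded from all
#' denominators.
#'
#' @param carrier_status data.frame (`animal_id`, `status`) from
#'   [assign_carrier_status()].
#' @param variant_genotypes named integer vector of alt dosages (0/1/2/NA)
#'   per animal.
#' @return list with `recombinants` (haplotype-homozygous, variant
#'   non-homozygous animal ids), `hidden_homozygotes` (haplotype-carrier,
#'   variant-homozygous ids), `n_compared` and `concordance` (fraction of
#'   compared animals whose variant dosage matches the haplotype status).
#' @export
check_haplotype_variant_discordance <- function(carrier_status,
                                                variant_genotypes) {
  common <- intersect(carrier_status$animal_id, names(variant_genotypes))
  gt <- variant_genotypes[common]
  st <- carrier_status$status[match(common, carrier_status$animal_id)]
  keep <- !is.na(gt) & st != "unknown"
  gt <- gt[keep]; st <- st[keep]; common <- common[keep]
  if (!length(common))
    return(list(recombinants = character(), hidden_homozygotes = character(),
                n_compared = 0L, concordance = NA_real_))
  expected <- c(`non-carrier` = 0L, carrier = 1L, homozygous = 2L)[st]
  list(
    recombinants = common[st == "homozygous" & gt != 2L],
    hidden_homozygotes = common[st == "carrier" & gt == 2L],
    n_compared = length(common),
    concordance = mean(gt == expected)
  )
}
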