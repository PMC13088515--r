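## Marker and animal quality control for unphased genotype tables, mirroring
## standard chip-QC practice: animal call rate first, then per-marker MAF,
## call rate and exact Hardy-Weinberg filters.

#' Exact Hardy-Weinberg equilibrium test for one diallelic marker
#'
#' Conditional-on-allele-counts exact test: the p-value is the summed
#' probability of all heterozygote counts (with the observed allele counts)
#' whose conditional probability does not exceed that of the observed count.
#' This is the classic exact test used by chip-QC software.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  ## log P(n_het | allele counts), up to a constant that cancels on
  ## normalisation: multinomial weight times 2^het
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Apply chip quality-control filters
#'
#' Filters an unphased dosage table (animals x markers, entries 0/1/2/NA) the
#' way a chip pipeline does: animals with call rate <= `animal_call_min` are
#' removed first, then markers failing minor allele frequency >
#' `maf_min`, genotype call frequency > `marker_call_min`, or the exact
#' Hardy-Weinberg test at `p < hwe_p_min` are removed. Defaults follow common
#' chip-QC practice (MAF > 1%, marker call > 90%, animal call > 70%,
#' HWE P < 1e-8).
#'
#' @param genotypes numeric matrix of allele dosages with animal rownames and
#'   marker colnames (matching `map$marker_id`); `NA` marks missing calls.
#' @param map marker map aligned to the columns.
#' @param maf_min,marker_call_min,animal_call_min,hwe_p_min thresholds.
#' @return list with `genotypes`, `map`, and a `summary` of per-filter
#'   removal counts.
#' @export
apply_qc_filters <- function(genotypes, map,
                             maf_min = 0.01,
                             marker_call_min = 0.90,
                             animal_call_min = 0.70,
                             hwe_p_min = 1e-8) {
  stopifnot(is.matrix(genotypes), nrow(map) == ncol(genotypes))
  n0 <- nrow(genotypes); m0 <- ncol(genotypes)

  animal_cr <- rowMeans(!is.na(genotypes))
  keep_animal <- animal_cr > animal_call_min
  genotypes <- genotypes[keep_animal, , drop = FALSE]

  marker_cr <- colMeans(!is.na(genotypes))
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0

  hwe_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE),
                   sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))

  fail_maf <- maf <= maf_min
  fail_cr <- marker_cr <= marker_call_min
  fail_hwe <- hwe_p < hwe_p_min
  keep_marker <- !(fail_maf | fail_cr | fail_hwe)

  out <- genotypes[, keep_marker, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop("quality control removed all animals or all markers")
  list(
    genotypes = out,
    map = map[keep_marker, , drop = FALSE],
    summary = data.frame(
      filter = c("animal_call_rate", "marker_maf", "marker_call_rate",
                 "marker_hwe"),
      removed = c(n0 - sum(keep_animal), sum(fail_maf), sum(fail_cr),
                  sum(fail_hwe)),
      kept = c(sum(keep_animal), NA, NA, sum(keep_marker))
    )
  )
}
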