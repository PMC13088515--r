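## Sliding-window scan for homozygote-deficient haplotypes: enumerate 1- and
## 2-Mb windows, tally window haplotypes from phased strands, test each
## common haplotype for a deficit of homozygotes against the Hardy-Weinberg
## expectation with an exact binomial test, Bonferroni-correct over all
## tests, and merge adjacent significant windows into regions.

#' Enumerate sliding windows over a marker map
#'
#' For each chromosome and each window size, windows start at the first
#' marker position and advance by `step` while the start does not pass the
#' last marker. Windows are half-open `[start, end)`; windows containing
#' fewer than 2 markers are dropped (a single marker does not define a
#' haplotype).
#'
#' @param map marker map.
#' @param sizes window sizes in bp (default 1 Mb and 2 Mb).
#' @param step advance in bp, or `NULL` for half the window size.
#' @return data.frame of windows: chrom, start, end, size, n_markers and the
#'   member marker index range (`first_marker`, `last_marker`, indices into
#'   `map`).
#' @export
enumerate_windows <- function(map, sizes = c(1e6, 2e6), step = NULL) {
  validate_marker_map(map)
  if (!is.null(step) && step <= 0) stop("step must be > 0")
  out <- list()
  for (size in sizes) {
    st <- if (is.null(step)) size / 2 else step
    if (st <= 0) stop("step must be > 0")
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr)
      pos <- map$pos_bp[idx]
      last <- pos[length(pos)]
      s <- pos[1]
      repeat {
        in_win <- idx[pos >= s & pos < s + size]
        if (length(in_win) >= 2L)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chr, start = s, end = s + size, size = size,
            n_markers = length(in_win),
            first_marker = in_win[1], last_marker = in_win[length(in_win)]
          )
        if (s + size > last) break   # this window already covered the end
        s <- s + st
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = numeric(),
                      n_markers = integer(), first_marker = integer(),
                      last_marker = integer()))
  unique(do.call(rbind, out))
}

#' Tally the haplotypes of one window
#'
#' Every one of the 2N strand strings over the window's markers is counted
#' exactly. An animal is homozygous for a haplotype iff both its strands
#' equal it; a heterozygous carrier has exactly one matching strand.
#'
#' @param phased a `phased_genotypes`.
#' @param marker_idx integer indices (into the map) of the window's markers.
#' @return data.frame with columns `haplotype` (allele string), `k` (strand
#'   count, summing to 2N), `het_carriers` and `obs_hom`.
#' @export
count_window_haplotypes <- function(phased, marker_idx) {
  stopifnot(inherits(phased, "phased_genotypes"))
  if (!length(marker_idx)) stop("window contains no markers")
  s1 <- do.call(paste0, as.data.frame(phased$h1[, marker_idx, drop = FALSE]))
  s2 <- do.call(paste0, as.data.frame(phased$h2[, marker_idx, drop = FALSE]))
  k <- table(c(s1, s2))
  hom <- table(s1[s1 == s2])
  haps <- names(k)
  obs_hom <- as.integer(hom[match(haps, names(hom))])
  obs_hom[is.na(obs_hom)] <- 0L
  data.frame(
    haplotype = haps,
    k = as.integer(k),
    het_carriers = as.integer(k) - 2L * obs_hom,
    obs_hom = obs_hom,
    stringsAsFactors = FALSE
  )
}

#' Expected homozygote count under Hardy-Weinberg
#'
#' @param q haplotype frequency (strand copies / 2N).
#' @param n_animals N.
#' @return N * q^2.
#' @export
expected_homozygotes <- function(q, n_animals) {
  stopifnot(all(q >= 0 & q <= 1), all(n_animals >= 0))
  n_animals * q^2
}

#' Haplotype frequency from a heterozygous-carrier frequency
#'
#' Solves `c = 2 q (1 - q)` for the minor root, the convention under which a
#' reported carrier frequency (heterozygous animals / N) converts to a
#' haplotype frequency.
#'
#' @param carrier_freq heterozygous-animal fraction, in [0, 0.5].
#' @return q in [0, 0.5].
#' @export
q_from_carrier_freq <- function(carrier_freq) {
  stopifnot(all(carrier_freq >= 0 & carrier_freq <= 0.5))
  (1 - sqrt(1 - 2 * carrier_freq)) / 2
}

#' Exact binomial test for a deficit of homozygotes
#'
#' One-sided lower-tail probability `P(X <= O)` with
#' `X ~ Binomial(N, q^2)`: only a deficit of homozygotes relative to the
#' Hardy-Weinberg expectation signals a linked lethal, so the upper tail is
#' not tested.
#'
#' @param obs_hom observed homozygote count O.
#' @param n_animals N.
#' @param q haplotype frequency.
#' @return raw p-value in (0, 1].
#' @export
deficit_binomial_test <- function(obs_hom, n_animals, q) {
  stopifnot(all(obs_hom >= 0), all(obs_hom <= n_animals),
            all(q >= 0 & q <= 1))
  stats::pbinom(obs_hom, n_animals, q^2)
}

#' Scan phased genotypes for homozygote-deficient haplotypes
#'
#' Enumerates 1- and 2-Mb sliding windows (step = half the window size by
#' default), tallies every window haplotype, and tests each haplotype with
#' frequency > `min_haplotype_freq` and at most `max_obs_hom` observed
#' homozygotes for a deficit against the Hardy-Weinberg expectation. The
#' Bonferroni denominator is the number of haplotypes actually tested, pooled
#' over both window sizes.
#'
#' @param phased a `phased_genotypes`.
#' @param sizes window sizes in bp.
#' @param step window step in bp (`NULL`: half the size).
#' @param min_haplotype_freq haplotype frequency floor (exclusive).
#' @param max_obs_hom ceiling on observed homozygotes (inclusive).
#' @param alpha familywise significance level on the adjusted p-value.
#' @return data.frame of haplotype records sorted by adjusted p-value:
#'   window coordinates, haplotype string, `k`, `q`, `het_carriers`,
#'   `carrier_freq` (heterozygous animals / N), `obs_hom`, `exp_hom`,
#'   `p_value`, `p_adj`, `significant`; the number of tests is in
#'   attribute `"n_tests"`.
#' @export
scan_haplotypes <- function(phased, sizes = c(1e6, 2e6), step = NULL,
                            min_haplotype_freq = 0.005, max_obs_hom = 30,
                            alpha = 0.05) {
  stopifnot(inherits(phased, "phased_genotypes"))
  n <- length(phased$animal_ids)
  windows <- enumerate_windows(phased$map, sizes, step)
  recs <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    idx <- seq.int(w$first_marker, w$last_marker)
    tal <- count_window_haplotypes(phased, idx)
    tal$q <- tal$k / (2 * n)
    tal <- tal[tal$q > min_haplotype_freq & tal$obs_hom <= max_obs_hom, ,
               drop = FALSE]
    if (!nrow(tal)) next
    tal$chrom <- w$chrom
    tal$start <- w$start
    tal$end <- w$end
    tal$size <- w$size
    recs[[i]] <- tal
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = numeric(),
                      haplotype = character(), k = integer(), q = numeric(),
                      het_carriers = integer(), carrier_freq = numeric(),
                      obs_hom = integer(), exp_hom = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      significant = logical())
    attr(out, "n_tests") <- 0L
    return(out)
  }
  m <- nrow(recs)
  recs$carrier_freq <- recs$het_carriers / n
  recs$exp_hom <- expected_homozygotes(recs$q, n)
  recs$p_value <- deficit_binomial_test(recs$obs_hom, n, recs$q)
  recs$p_adj <- pmin(1, m * recs$p_value)
  recs$significant <- recs$p_adj < alpha
  recs <- recs[order(recs$p_adj, recs$chrom, recs$start, recs$haplotype),
               c("chrom", "start", "end", "size", "haplotype", "k", "q",
                 "het_carriers", "carrier_freq", "obs_hom", "exp_hom",
                 "p_value", "p_adj", "significant")]
  rownames(recs) <- NULL
  attr(recs, "n_tests") <- m
  recs
}

#' Merge significant windows into candidate regions
#'
#' Windows on the same chromosome that overlap or abut are interpreted as
#' the same underlying region. Each region keeps its constituent haplotype
#' records and a representative haplotype (the smallest adjusted p-value;
#' ties broken by coordinate, then haplotype string).
#'
#' @param records significant haplotype records from [scan_haplotypes()].
#' @return list of regions; each region is a list with `chrom`, `start`,
#'   `end`, `records` (data.frame) and `representative` (one-row data.frame).
#' @export
merge_significant_windows <- function(records) {
  if (!nrow(records)) return(list())
  regions <- list()
  for (chr in unique(records$chrom)) {
    rc <- records[records$chrom == chr, , drop = FALSE]
    rc <- rc[order(rc$start, rc$end), , drop = FALSE]
    cur_start <- rc$start[1]; cur_end <- rc$end[1]; cur_rows <- 1L
    flush <- function(start, end, rows) {
      sub <- rc[rows, , drop = FALSE]
      rep_row <- sub[order(sub$p_adj, sub$start, sub$haplotype), ][1, ]
      structure(list(chrom = chr, start = start, end = end,
                     records = sub, representative = rep_row),
                class = "lethal_region")
    }
    if (nrow(rc) > 1) {
      for (i in 2:nrow(rc)) {
        if (rc$start[i] <= cur_end) {
          cur_end <- max(cur_end, rc$end[i])
          cur_rows <- c(cur_rows, i)
        } else {
          regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, cur_rows)
          cur_start <- rc$start[i]; cur_end <- rc$end[i]; cur_rows <- i
        }
      }
    }
    regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, cur_rows)
  }
  regions
}

#' @export
print.lethal_region <- function(x, ...) {
  cat(sprintf("region %s:%.0f-%.0f (%d windows, top p_adj = %.3g)\n",
              x$chrom, x$start, x$end, nrow(x$records),
              x$representative$p_adj))
  invisible(x)
}

#' Region object for the planted haplotype of a simulation
#'
#' Builds a `lethal_region` whose representative haplotype is the planted
#' lethal allele string over the planted region's markers, so carrier calls
#' can be made against the ground truth rather than a scan result.
#'
#' @param sim a `lethal_sim`.
#' @return a `lethal_region`.
#' @export
truth_region <- function(sim) {
  stopifnot(inherits(sim, "lethal_sim"))
  ts <- sim$true_state
  rep_row <- data.frame(
    chrom = ts$region$chrom, start = ts$region$start, end = ts$region$end,
    haplotype = ts$lethal_string, p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(chrom = ts$region$chrom, start = ts$region$start,
                 end = ts$region$end, records = rep_row,
                 representative = rep_row),
            class = "lethal_region")
}

#' Carrier status of every animal for a region's representative haplotype
#'
#' An animal is `homozygous` when both strands over the representative
#' window's markers equal the representative haplotype, `carrier` when
#' exactly one does, `non-carrier` otherwise. Animals listed in
#' `all_animals` but absent from the genotype data are `unknown`.
#'
#' @param phased a `phased_genotypes`.
#' @param region a region from [merge_significant_windows()].
#' @param all_animals optional character vector of ids to report (e.g. every
#'   animal in the pedigree).
#' @return data.frame with `animal_id` and `status`.
#' @export
assign_carrier_status <- function(phased, region, all_animals = NULL) {
  stopifnot(inherits(phased, "phased_genotypes"),
            inherits(region, "lethal_region"))
  rep_row <- region$representative
  idx <- which(phased$map$chrom == rep_row$chrom &
                 phased$map$pos_bp >= rep_row$start &
                 phased$map$pos_bp < rep_row$end)
  target <- as.integer(strsplit(rep_row$haplotype, "")[[1]])
  stopifnot(length(idx) == length(target))
  nmatch <- hap_strand_matches(phased$h1[, idx, drop = FALSE],
                               phased$h2[, idx, drop = FALSE], target)
  status <- c("non-carrier", "carrier", "homozygous")[nmatch + 1L]
  out <- data.frame(animal_id = phased$animal_ids, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(all_animals)) {
    missing <- setdiff(all_animals, phased$animal_ids)
    if (length(missing))
      out <- rbind(out, data.frame(animal_id = missing, status = "unknown",
                                   stringsAsFactors = FALSE))
    out <- out[match(union(all_animals, phased$animal_ids), out$animal_id), ]
    rownames(out) <- NULL
  }
  out
}
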