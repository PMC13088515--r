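## End-to-end orchestration: simulate -> scan -> associate -> prioritize,
## each stage writing its own subdirectory plus a run manifest. The global
## seed expands deterministically into per-stage seeds so stages can be
## re-run in isolation.

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, scan = 23L, associate = 37L, prioritize = 53L)
  as.integer((as.numeric(seed) * 977 + offsets[[stage]]) %% 2100000000)
}

#' Run the discovery pipeline on a simulated population
#'
#' Executes the requested stages in order:
#' `simulate` (forward simulation, written as phased VCF + marker map +
#' pedigree/matings/foals CSVs + truth JSON), `scan` (QC identity check on
#' the complete input, haplotype scan, region merge, carrier status),
#' `associate` (risk-mating classification and phenotype contrasts per
#' region) and `prioritize` (sequenced-sire emulation, concordance filter,
#' consequence tiers, ranking). Stages whose outputs already exist are
#' reused unless `overwrite = TRUE`. A JSON manifest records the config,
#' per-stage seeds, input digests, row counts and timings.
#'
#' @param config a [sim_config()] or the path to a YAML file for
#'   [read_sim_config()].
#' @param out_dir output directory; one subdirectory per stage.
#' @param seed global seed; expanded into per-stage seeds.
#' @param stages character subset of
#'   `c("simulate", "scan", "associate", "prioritize")`, in pipeline order.
#' @param overwrite recompute stages whose outputs exist.
#' @param verbose print one line per stage.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L,
                         stages = c("simulate", "scan", "associate",
                                    "prioritize"),
                         overwrite = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("haplolethal")),
    seed = as.integer(seed),
    stage_seeds = lapply(c("simulate", "scan", "associate", "prioritize"),
                         function(s) stage_seed(seed, s)),
    config = unclass(config),
    stages = list()
  )
  names(manifest$stage_seeds) <- c("simulate", "scan", "associate",
                                   "prioritize")
  res <- list()

  say <- function(...) if (verbose) message(...)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    manifest$stages[[name]]$seconds <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  sim_dir <- file.path(out_dir, "simulate")
  if ("simulate" %in% stages) {
    cfg <- config
    cfg$rng_seed <- stage_seed(seed, "simulate")
    vcf <- file.path(sim_dir, "genotypes.vcf")
    if (overwrite || !file.exists(vcf)) {
      res$sim <- timed("simulate", simulate_population(cfg))
      write_simulation(res$sim, sim_dir)
      say("simulate: ", nrow(res$sim$pedigree), " animals")
    } else {
      res$sim <- timed("simulate", simulate_population(cfg))
      say("simulate: outputs exist, regenerated in memory from seed")
    }
    manifest$stages$simulate$n_animals <- nrow(res$sim$pedigree)
    manifest$stages$simulate$n_matings <- nrow(res$sim$matings)
  }

  if ("scan" %in% stages) {
    vcf <- file.path(sim_dir, "genotypes.vcf")
    map <- file.path(sim_dir, "markers.tsv")
    if (!file.exists(vcf))
      stop("stage 'scan': missing input file 'genotypes.vcf' ",
           "(run the simulate stage first)")
    phased <- read_phased_vcf(vcf, map)
    scan_dir <- file.path(out_dir, "scan")
    dir.create(scan_dir, showWarnings = FALSE)
    records <- timed("scan", scan_haplotypes(phased))
    regions <- merge_significant_windows(records[records$significant, ])
    utils::write.table(records, file.path(scan_dir, "haplotype_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    region_df <- do.call(rbind, lapply(seq_along(regions), function(i)
      data.frame(region_id = paste0("R", i), chrom = regions[[i]]$chrom,
                 start = regions[[i]]$start, end = regions[[i]]$end,
                 n_windows = nrow(regions[[i]]$records),
                 top_p_adj = regions[[i]]$representative$p_adj)))
    if (is.null(region_df))
      region_df <- data.frame(region_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              n_windows = integer(), top_p_adj = numeric())
    utils::write.table(region_df, file.path(scan_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ped <- utils::read.csv(file.path(sim_dir, "pedigree.csv"),
                           colClasses = "character")
    carriers <- lapply(regions, assign_carrier_status, phased = phased,
                       all_animals = ped$animal_id)
    if (length(carriers)) {
      cdf <- do.call(rbind, lapply(seq_along(carriers), function(i)
        cbind(region_id = paste0("R", i), carriers[[i]])))
      utils::write.csv(cdf, file.path(scan_dir, "carrier_status.csv"),
                       row.names = FALSE)
    }
    res$phased <- phased
    res$records <- records
    res$regions <- regions
    res$carriers <- carriers
    manifest$stages$scan$n_tests <- attr(records, "n_tests")
    manifest$stages$scan$n_significant <- sum(records$significant)
    manifest$stages$scan$n_regions <- length(regions)
    say("scan: ", sum(records$significant), " significant haplotypes in ",
        length(regions), " region(s)")
  }

  if ("associate" %in% stages) {
    if (is.null(res$regions))
      stop("stage 'associate': missing field 'regions' (run the scan stage)")
    mat_f <- file.path(sim_dir, "matings.csv")
    if (!file.exists(mat_f))
      stop("stage 'associate': missing input file 'matings.csv'")
    matings <- utils::read.csv(mat_f, stringsAsFactors = FALSE)
    foals <- utils::read.csv(file.path(sim_dir, "foals.csv"),
                             stringsAsFactors = FALSE)
    ped <- utils::read.csv(file.path(sim_dir, "pedigree.csv"),
                           stringsAsFactors = FALSE)
    assoc_dir <- file.path(out_dir, "associate")
    dir.create(assoc_dir, showWarnings = FALSE)
    res$phenotypes <- timed("associate", lapply(seq_along(res$regions),
      function(i) {
        cls <- classify_matings(matings, res$carriers[[i]], ped)
        mating_category_table(cls, foals)
      }))
    for (i in seq_along(res$phenotypes)) {
      utils::write.table(res$phenotypes[[i]]$contrasts,
                         file.path(assoc_dir,
                                   sprintf("region_R%d_contrasts.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$phenotypes[[i]]$categories,
                         file.path(assoc_dir,
                                   sprintf("region_R%d_categories.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$associate$n_regions <- length(res$phenotypes)
    say("associate: contrasts for ", length(res$phenotypes), " region(s)")
  }

  if ("prioritize" %in% stages) {
    if (is.null(res$sim) || is.null(res$regions))
      stop("stage 'prioritize': needs the simulate and scan stages")
    pri_dir <- file.path(out_dir, "prioritize")
    dir.create(pri_dir, showWarnings = FALSE)
    seq_sires <- simulate_sequenced_sires(
      res$sim, seed = stage_seed(seed, "prioritize"))
    res$candidates <- timed("prioritize", lapply(res$regions, function(rg) {
      filt <- concordance_filter(seq_sires$variants, seq_sires$genotypes,
                                 seq_sires$carrier, rg)
      if (identical(attr(filt, "status"), "skipped_no_carriers"))
        return(filt[0, ])
      cand <- filt[filt$pass, , drop = FALSE]
      cand$tier <- classify_consequence(cand)
      rank_candidates(cand)
    }))
    for (i in seq_along(res$candidates))
      utils::write.table(res$candidates[[i]],
                         file.path(pri_dir,
                                   sprintf("region_R%d_candidates.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$prioritize$n_candidates <-
      sum(vapply(res$candidates, nrow, integer(1)))
    say("prioritize: ", manifest$stages$prioritize$n_candidates,
        " candidate variant(s)")
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$digests <- as.list(tools::md5sum(files))
  names(manifest$digests) <- substring(names(manifest$digests),
                                       nchar(out_dir) + 2L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
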