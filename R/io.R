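## Containers and file formats: phased genotypes, phased VCF + marker map,
## pedigree/mating/foal CSVs.

#' Phased genotype container
#'
#' Holds the two chromosome strands of N animals over M diallelic markers,
#' aligned to a marker map. Entries are 0 (allele1) or 1 (allele2); no
#' missing calls are allowed (input is post-phasing).
#'
#' @param animal_ids character vector of N animal ids.
#' @param map marker map data.frame with columns `chrom`, `marker_id`,
#'   `pos_bp`, `allele1`, `allele2`; positions strictly increasing within a
#'   chromosome.
#' @param h1,h2 N x M integer matrices of strand alleles in \{0, 1\}.
#' @return an object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(animal_ids, map, h1, h2) {
  stopifnot(is.character(animal_ids), length(animal_ids) > 0)
  stopifnot(nrow(h1) == length(animal_ids), nrow(h2) == length(animal_ids))
  stopifnot(ncol(h1) == nrow(map), ncol(h2) == nrow(map))
  if (anyNA(h1) || anyNA(h2))
    stop("phased genotypes must be complete: missing strand alleles found")
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    stop("strand alleles must be 0/1")
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  validate_marker_map(map)
  if (nrow(map) < 2L) stop("need at least 2 markers")
  structure(list(animal_ids = animal_ids, map = map,
                 h1 = h1, h2 = h2),
            class = "phased_genotypes")
}

#' Validate a marker map
#'
#' Checks the required columns, unique marker ids, and strictly increasing
#' positions within each chromosome.
#'
#' @param map marker map data.frame.
#' @return the map, invisibly; errors on violation.
#' @export
validate_marker_map <- function(map) {
  need <- c("chrom", "marker_id", "pos_bp", "allele1", "allele2")
  if (!all(need %in% names(map)))
    stop("marker map must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("marker ids must be unique")
  by_chr <- split(map$pos_bp, map$chrom)
  ok <- vapply(by_chr, function(p) all(diff(p) > 0), logical(1))
  if (!all(ok))
    stop("marker positions must be strictly increasing within a chromosome")
  invisible(map)
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", length(x$animal_ids), "animals x",
      nrow(x$map), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write phased genotypes as a phased VCF plus a marker-map TSV
#'
#' The VCF carries one `GT` field per animal with a `|` phase separator
#' (allele1 = REF, allele2 = ALT). The marker map is a PLINK-BIM-style TSV
#' with columns chrom, marker_id, pos_bp, allele1, allele2 (1-based
#' positions). Refuses incomplete (unphased) input by construction of
#' [phased_genotypes()].
#'
#' @param phased a `phased_genotypes`.
#' @param vcf_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_phased_vcf <- function(phased, vcf_path, map_path = NULL) {
  stopifnot(inherits(phased, "phased_genotypes"))
  map <- phased$map
  gt <- matrix(paste0(phased$h1, "|", phased$h2),
               nrow = nrow(phased$h1))
  body <- cbind(map$chrom, map$pos_bp, map$marker_id,
                map$allele1, map$allele2, ".", "PASS", ".", "GT",
                t(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplolethal",
    sprintf("##contig=<ID=%s>", unique(map$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", phased$animal_ids), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), vcf_path)
  if (!is.null(map_path))
    utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(vcf = vcf_path, map = map_path))
}

#' Read a phased VCF (and optional marker-map TSV) into `phased_genotypes`
#'
#' Uses vcfR for parsing. Every genotype must be phased (`|` separator) and
#' called; anything else is an error, because the scan assumes complete
#' phased input.
#'
#' @param vcf_path phased VCF path.
#' @param map_path optional marker-map TSV; when given it must agree with the
#'   VCF records and supplies the allele symbols.
#' @return a `phased_genotypes`.
#' @export
read_phased_vcf <- function(vcf_path, map_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt) || any(!grepl("^[01]\\|[01]$", gt)))
    stop("input VCF contains unphased or missing genotypes")
  map <- data.frame(
    chrom = fix[, "CHROM"],
    marker_id = fix[, "ID"],
    pos_bp = as.numeric(fix[, "POS"]),
    allele1 = fix[, "REF"],
    allele2 = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  if (!is.null(map_path)) {
    tsv <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "numeric", "character",
                                            "character"))
    if (!identical(tsv$marker_id, map$marker_id) ||
        !identical(tsv$pos_bp, map$pos_bp))
      stop("marker-map TSV does not match the VCF records")
    map <- tsv
  }
  h1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  h2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  ids <- colnames(gt)
  rownames(h1) <- rownames(h2) <- ids
  phased_genotypes(ids, map, h1, h2)
}

#' Write the chip view of a simulation: phased VCF, marker map and records
#'
#' Emits the formats the scan and phenotype modules consume: phased VCF +
#' marker-map TSV, pedigree CSV, matings CSV, foals CSV and a ground-truth
#' JSON (planted region, causal position, carrier list).
#'
#' @param sim a `lethal_sim` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lethal_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    map = file.path(dir, "markers.tsv"),
    pedigree = file.path(dir, "pedigree.csv"),
    matings = file.path(dir, "matings.csv"),
    foals = file.path(dir, "foals.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_phased_vcf(sim$genotypes, paths["vcf"], paths["map"])
  utils::write.csv(sim$pedigree, paths["pedigree"], row.names = FALSE)
  utils::write.csv(sim$matings, paths["matings"], row.names = FALSE)
  utils::write.csv(sim$foals, paths["foals"], row.names = FALSE)
  ts <- sim$true_state
  jsonlite::write_json(
    list(region = ts$region, causal_pos = ts$causal_pos,
         lethal_string = ts$lethal_string,
         carriers = names(ts$causal_genotype)[ts$causal_genotype == 1L]),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Unphased dosage matrix from phased genotypes
#'
#' @param phased a `phased_genotypes`.
#' @return N x M integer matrix of allele2 dosages (0/1/2), animals in rows.
#' @export
genotype_dosage <- function(phased) {
  stopifnot(inherits(phased, "phased_genotypes"))
  d <- phased$h1 + phased$h2
  dimnames(d) <- list(phased$animal_ids, phased$map$marker_id)
  d
}
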