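#' Read a VCF into the variant records used for diagnostic-SNP calling
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a data.frame of records
#' with `contig`, `pos`, `ref`, `alt`, `is_indel`, `is_multiallelic`,
#' `MQ`, `DP` plus per-individual genotype base calls (e.g. `"A/A"`).
#'
#' @param path VCF path (plain text or bgzipped).
#' @return List: `records` (data.frame), `genotypes` (site x individual
#'   character matrix of slash-separated base calls, `NA` when missing).
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fx)) else x
  }
  rec <- data.frame(contig = fx$CHROM, pos = as.integer(fx$POS),
                    ref = fx$REF, alt = fx$ALT,
                    stringsAsFactors = FALSE)
  alts <- strsplit(ifelse(is.na(rec$alt), "", rec$alt), ",", fixed = TRUE)
  rec$is_multiallelic <- lengths(alts) > 1L
  rec$is_indel <- mapply(function(r, aa) {
    nchar(r) != 1L || any(nchar(aa) != 1L & nzchar(aa))
  }, rec$ref, alts)
  rec$MQ <- info_num("MQ")
  rec$DP <- info_num("DP")
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1) {
    idx <- vcfR::extract.gt(v, element = "GT")
    gt <- matrix(NA_character_, nrow(rec), ncol(idx),
                 dimnames = list(NULL, colnames(idx)))
    for (i in seq_len(nrow(rec))) {
      bases <- c(rec$ref[i], alts[[i]])
      for (j in seq_len(ncol(idx))) {
        g <- idx[i, j]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) next
        codes <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
        if (anyNA(codes) || any(codes > length(bases))) next
        gt[i, j] <- paste(bases[codes], collapse = "/")
      }
    }
  }
  list(records = rec, genotypes = gt)
}

#' Quality filtering of SNP records
#'
#' Retains biallelic SNP records with mapping quality `MQ >= min_mq`,
#' depth `DP >= min_dp`, and position more than `indel_margin` bases away
#' from every indel record on the same contig. Indel records themselves
#' are consumed for the proximity test and dropped from the output.
#'
#' @param records Record data.frame from [read_vcf_records()] (may carry
#'   the genotype matrix as attribute or be the full list).
#' @param min_mq,min_dp Quality thresholds.
#' @param indel_margin SNPs at distance `<= indel_margin` from an indel
#'   are removed (either side).
#' @return The filtered records (and congruently subset genotypes when a
#'   list was supplied).
#' @export
filter_variants <- function(records, min_mq = 20, min_dp = 10,
                            indel_margin = 3) {
  gt <- NULL
  if (is.list(records) && !is.data.frame(records)) {
    gt <- records$genotypes
    records <- records$records
  }
  snp <- !records$is_indel
  if (any(snp & (is.na(records$MQ) | is.na(records$DP)))) {
    bad <- which(snp & (is.na(records$MQ) | is.na(records$DP)))[1]
    stop(sprintf("missing MQ/DP annotation at record %s:%d",
                 records$contig[bad], records$pos[bad]))
  }
  keep <- snp & records$MQ >= min_mq & records$DP >= min_dp
  indels <- records[records$is_indel, c("contig", "pos")]
  if (nrow(indels)) {
    near <- vapply(which(keep), function(i) {
      same <- indels$contig == records$contig[i]
      any(abs(indels$pos[same] - records$pos[i]) <= indel_margin)
    }, logical(1))
    keep[which(keep)[near]] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gt)) return(list(records = out,
                                genotypes = gt[keep, , drop = FALSE]))
  out
}

# split "A/G" style calls into the set of distinct alleles; NA -> NULL
.gt_alleles <- function(g) {
  if (is.na(g)) return(NULL)
  unique(strsplit(g, "/", fixed = TRUE)[[1]])
}

#' Call species-diagnostic SNPs
#'
#' A site is diagnostic when (1) at least `min_individuals` individuals of
#' each species have a successful call, (2) all scored conspecifics share
#' one and the same allele (heterozygous individuals disqualify the site),
#' and (3) that allele differs between the species. Multi-allelic records
#' are skipped.
#'
#' @param records Record data.frame (or [read_vcf_records()] /
#'   [filter_variants()] list with genotypes).
#' @param genotypes Site x individual matrix of base calls (`"A/A"`),
#'   omitted when `records` is a list carrying it.
#' @param species Named character vector mapping individual (column) names
#'   to `"E"` or `"T"`.
#' @param min_individuals Criterion (1) threshold per species.
#' @return data.frame of diagnostic sites: `contig`, `pos` (1-based),
#'   `allele_E`, `allele_T`.
#' @export
call_diagnostic_snps <- function(records, genotypes = NULL, species,
                                 min_individuals = 2) {
  if (is.list(records) && !is.data.frame(records)) {
    genotypes <- records$genotypes
    records <- records$records
  }
  if (is.null(genotypes)) stop("genotype matrix required")
  miss <- setdiff(colnames(genotypes), names(species))
  if (length(miss)) stop("species label absent for individual(s): ",
                         paste(miss, collapse = ", "))
  sp <- species[colnames(genotypes)]
  if (!all(sp %in% c("E", "T"))) stop("species labels must be 'E' or 'T'")
  eCol <- sp == "E"; tCol <- sp == "T"
  if (sum(eCol) < min_individuals || sum(tCol) < min_individuals)
    stop("need >= ", min_individuals, " individuals per species in the call set")
  out <- list()
  for (i in seq_len(nrow(records))) {
    if (isTRUE(records$is_multiallelic[i])) next
    if (isTRUE(records$is_indel[i])) next
    fixed_allele <- function(cols) {
      gs <- genotypes[i, cols]
      gs <- gs[!is.na(gs)]
      if (length(gs) < min_individuals) return(NULL)      # criterion 1
      als <- unique(unlist(lapply(gs, .gt_alleles)))
      if (length(als) != 1L) return(NULL)                 # criterion 2
      als
    }
    aE <- fixed_allele(eCol)
    aT <- fixed_allele(tCol)
    if (is.null(aE) || is.null(aT) || aE == aT) next      # criterion 3
    out[[length(out) + 1L]] <- data.frame(
      contig = records$contig[i], pos = records$pos[i],
      allele_E = aE, allele_T = aT, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(0), pos = integer(0),
                      allele_E = character(0), allele_T = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write diagnostic SNPs as TSV and BED
#'
#' The TSV holds `contig`, `pos` (1-based, as in VCF), `allele_E`,
#' `allele_T`; the BED mirror uses 0-based half-open coordinates.
#'
#' @param snps Diagnostic-SNP data.frame.
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_diagnostic_snps <- function(snps, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(snps, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(snps$contig, snps$pos - 1L, snps$pos,
                      paste0(snps$allele_E, "/", snps$allele_T))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}
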