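# small programmatic fixtures shared across test files

tiny_meta <- function(biotypes, tissue = "liver") {
  data.frame(sample_id = paste0("s", seq_along(biotypes)),
             individual_id = paste0("i", seq_along(biotypes)),
             biotype = biotypes, tissue = tissue,
             stringsAsFactors = FALSE)
}

tiny_counts <- function(mat, biotypes, tissue = "liver") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  gene_counts(mat, tiny_meta(biotypes, tissue))
}

# null two-group NB table: no group effect
null_table <- function(n_genes, n_per_group, mu = 200, disp = 0.1,
                       seed = 1) {
  set.seed(seed)
  m <- 2 * n_per_group
  base <- 2^stats::rnorm(n_genes, log2(mu / 4), 1)
  cnt <- sapply(seq_len(m), function(j)
    stats::rnbinom(n_genes, mu = 4 * base, size = 1 / disp))
  rownames(cnt) <- sprintf("g%04d", seq_len(n_genes))
  tiny_counts(cnt, rep(c("EE", "TT"), each = n_per_group))
}

# relabel biotypes under an E/T role swap (EE<->TT, EET<->ETT)
within_swap <- function(meta) {
  map <- c(EE = "TT", TT = "EE", ET = "ET", EET = "ETT", ETT = "EET")
  meta$biotype <- unname(map[meta$biotype])
  meta
}

# write a minimal VCF with given body lines
write_test_vcf <- function(body, individuals = c("e1", "e2", "t1", "t2")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vcf_line <- function(contig, pos, ref, alt, gts, mq = 60, dp = 40) {
  paste(c(contig, pos, ".", ref, alt, "50", ".",
          sprintf("MQ=%s;DP=%s", mq, dp), "GT", gts), collapse = "\t")
}
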