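.check_count_matrix <- function(m, what = "counts") {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
  if (any(m < 0)) stop(what, " contains negative values")
  if (any(abs(m - round(m)) > 1e-8)) stop(what, " contains non-integer values")
  storage.mode(m) <- "integer"
  m
}

#' Gene-by-sample count table
#'
#' Container coupling an integer count matrix (genes in rows, samples in
#' columns) with the validated sample metadata; columns are reordered to
#' follow the metadata.
#'
#' @param counts Integer matrix, rownames are gene ids, colnames sample ids.
#' @param samples Metadata data.frame (see [make_sample_meta()]).
#' @return An object of class `gene_counts`.
#' @export
gene_counts <- function(counts, samples) {
  samples <- make_sample_meta(samples)
  counts <- .check_count_matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) == 0L) rownames(counts) <- character(0)
    else stop("counts must have gene ids as rownames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene id in counts")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  un <- setdiff(colnames(counts), samples$sample_id)
  if (length(un)) stop("unmatched sample: ", paste(un, collapse = ", "))
  un2 <- setdiff(samples$sample_id, colnames(counts))
  if (length(un2)) stop("metadata sample missing from counts: ",
                        paste(un2, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat(sprintf("<gene_counts: %d genes x %d samples (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$biotype)), collapse = ",")))
  invisible(x)
}

#' @export
dim.gene_counts <- function(x) dim(x$counts)

#' @export
`[.gene_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  gene_counts(x$counts[i, j, drop = FALSE], x$samples[j, , drop = FALSE])
}

#' Allele-resolved count table
#'
#' Two congruent gene-by-sample layers holding reads attributable to the
#' E- and T-derived allele. For pure parental samples the allospecific
#' layer must be structurally zero (an EE individual carries no T allele).
#'
#' @param counts_E,counts_T Integer matrices of identical shape/dimnames.
#' @param samples Metadata data.frame.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(counts_E, counts_T, samples) {
  samples <- make_sample_meta(samples)
  counts_E <- .check_count_matrix(counts_E, "counts_E")
  counts_T <- .check_count_matrix(counts_T, "counts_T")
  if (!identical(dim(counts_E), dim(counts_T)) ||
      !identical(dimnames(counts_E), dimnames(counts_T)))
    stop("counts_E and counts_T must have identical shape and dimnames")
  if (is.null(rownames(counts_E))) {
    if (nrow(counts_E) == 0L)
      rownames(counts_E) <- rownames(counts_T) <- character(0)
    else stop("allele counts must have gene id rownames")
  }
  if (anyDuplicated(rownames(counts_E))) stop("duplicate gene id in allele counts")
  un <- setdiff(colnames(counts_E), samples$sample_id)
  if (length(un)) stop("unmatched sample: ", paste(un, collapse = ", "))
  counts_E <- counts_E[, samples$sample_id, drop = FALSE]
  counts_T <- counts_T[, samples$sample_id, drop = FALSE]
  ee <- samples$biotype == "EE"
  tt <- samples$biotype == "TT"
  if (any(counts_T[, ee, drop = FALSE] != 0L))
    stop("nonzero T-allele counts in a pure EE sample")
  if (any(counts_E[, tt, drop = FALSE] != 0L))
    stop("nonzero E-allele counts in a pure TT sample")
  structure(list(counts_E = counts_E, counts_T = counts_T, samples = samples),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts: %d genes x %d samples>\n",
              nrow(x$counts_E), ncol(x$counts_E)))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$counts_E)

#' @export
`[.allele_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts_E))
  if (missing(j)) j <- seq_len(ncol(x$counts_E))
  allele_counts(x$counts_E[i, j, drop = FALSE], x$counts_T[i, j, drop = FALSE],
                x$samples[j, , drop = FALSE])
}

#' Total counts of an allele table
#' @param a An `allele_counts` object.
#' @return `gene_counts` of the per-cell sums `counts_E + counts_T`.
#' @export
allele_totals <- function(a) {
  gene_counts(a$counts_E + a$counts_T, a$samples)
}

#' Read a TSV count table with its sample metadata
#'
#' The count file is a TSV with a header row; the first column holds the
#' gene id, the remaining columns are sample ids that must all occur in
#' the metadata. Samples are reordered to follow the metadata.
#'
#' @param path Count TSV path.
#' @param metadata Metadata data.frame, or path to a metadata TSV with
#'   columns `sample_id`, `individual_id`, `biotype`, `tissue`.
#' @return A [gene_counts] object.
#' @export
read_counts <- function(path, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene id column plus >=1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  gene_counts(m, metadata)
}

#' Read a sample metadata TSV
#' @param path TSV path with the four required metadata columns.
#' @return Validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  make_sample_meta(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a count table to canonical TSV
#'
#' The canonical dialect is tab-separated, header row, first column named
#' `gene_id`, no quoting; [read_counts()] on the written file round-trips
#' losslessly.
#'
#' @param x A `gene_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata to TSV
#' @param samples Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-resolved table from two TSV layers
#' @param path_E,path_T Paths of the E- and T-layer count TSVs.
#' @param metadata Metadata data.frame or TSV path.
#' @return An [allele_counts] object.
#' @export
read_allele_counts <- function(path_E, path_T, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  e <- read_counts(path_E, metadata)
  t <- read_counts(path_T, metadata)
  if (!identical(rownames(e$counts), rownames(t$counts)))
    stop("allele layers disagree on gene ids")
  allele_counts(e$counts, t$counts, metadata)
}
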