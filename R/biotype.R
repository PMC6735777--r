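#' @keywords internal
"_PACKAGE"

# genome copy numbers per biotype; total is 2 (diploid) or 3 (triploid)
.BIOTYPE_COPIES <- list(
  EE  = c(E = 2L, T = 0L),
  TT  = c(E = 0L, T = 2L),
  ET  = c(E = 1L, T = 1L),
  EET = c(E = 2L, T = 1L),
  ETT = c(E = 1L, T = 2L)
)

#' Biotype labels known to the package
#'
#' @return Character vector of the five genome-composition classes:
#'   the two parental species (`EE`, `TT`), the diploid hybrid (`ET`)
#'   and the two triploid hybrids (`EET`, `ETT`).
#' @export
biotype_labels <- function() names(.BIOTYPE_COPIES)

#' Construct a biotype
#'
#' A biotype is a genome-composition class: how many copies of the
#' E (\emph{C. elongatoides}-derived) and T (\emph{C. taenia}-derived)
#' genomes an individual carries. Reproduction mode and ploidy are
#' derived from it, never stored independently.
#'
#' @param label One of `"EE"`, `"TT"`, `"ET"`, `"EET"`, `"ETT"`.
#' @return An object of class `biotype` with fields `label`, `copies_E`,
#'   `copies_T`.
#' @examples
#' b <- biotype("EET")
#' e_genome_fraction(b)  # 2/3
#' @export
biotype <- function(label) {
  label <- as.character(label)
  if (length(label) != 1L || !label %in% names(.BIOTYPE_COPIES))
    stop("unknown biotype label: ", paste(label, collapse = ", "),
         " (expected one of ", paste(names(.BIOTYPE_COPIES), collapse = ", "), ")")
  cp <- .BIOTYPE_COPIES[[label]]
  structure(list(label = label, copies_E = cp[["E"]], copies_T = cp[["T"]]),
            class = "biotype")
}

#' @export
print.biotype <- function(x, ...) {
  cat(sprintf("<biotype %s: %dE + %dT, %s, %s>\n", x$label, x$copies_E,
              x$copies_T, biotype_ploidy(x$label), biotype_reproduction(x$label)))
  invisible(x)
}

.biotype_label <- function(b) if (inherits(b, "biotype")) b$label else as.character(b)

#' Genome copy numbers of a biotype
#'
#' @param b A `biotype` object or label (vectorized over labels).
#' @return For a single biotype, a named integer vector `c(E=, T=)`;
#'   for a vector of labels, a two-column matrix.
#' @export
biotype_copies <- function(b) {
  lab <- .biotype_label(b)
  bad <- setdiff(unique(lab), names(.BIOTYPE_COPIES))
  if (length(bad)) stop("unknown biotype label: ", paste(bad, collapse = ", "))
  if (length(lab) == 1L) return(.BIOTYPE_COPIES[[lab]])
  t(vapply(lab, function(l) .BIOTYPE_COPIES[[l]], integer(2)))
}

#' Fraction of the genome contributed by the E parental species
#'
#' `copies_E / (copies_E + copies_T)`: 1 for EE, 2/3 for EET, 1/2 for ET,
#' 1/3 for ETT and 0 for TT. This is the "E-genomic ratio" used to order
#' biotypes along the genomic dose gradient.
#'
#' @param b A `biotype` object or character vector of labels.
#' @return Numeric in \[0, 1\], vectorized over labels.
#' @export
e_genome_fraction <- function(b) {
  lab <- .biotype_label(b)
  cp <- biotype_copies(lab)
  if (is.matrix(cp)) unname(cp[, "E"] / rowSums(cp)) else
    unname(cp[["E"]] / sum(cp))
}

#' Ploidy implied by a biotype
#' @param b biotype object or label vector.
#' @return `"diploid"` or `"triploid"`.
#' @export
biotype_ploidy <- function(b) {
  lab <- .biotype_label(b)
  cp <- biotype_copies(lab)
  tot <- if (is.matrix(cp)) rowSums(cp) else sum(cp)
  unname(ifelse(tot == 3L, "triploid", "diploid"))
}

#' Reproduction mode implied by a biotype
#'
#' Hybrid biotypes (ET, EET, ETT) reproduce clonally by gynogenesis;
#' the parental species are sexual.
#' @param b biotype object or label vector.
#' @return `"sexual"` or `"asexual"`.
#' @export
biotype_reproduction <- function(b) {
  lab <- .biotype_label(b)
  cp <- biotype_copies(lab)
  hyb <- if (is.matrix(cp)) cp[, "E"] > 0L & cp[, "T"] > 0L else
    cp[["E"]] > 0L && cp[["T"]] > 0L
  unname(ifelse(hyb, "asexual", "sexual"))
}

#' Validate and complete a sample metadata table
#'
#' Requires columns `sample_id`, `individual_id`, `biotype`, `tissue`;
#' the derived columns `reproduction` and `ploidy` are (re)computed from
#' `biotype` so the metadata can never be internally inconsistent.
#'
#' @param df A data.frame with at least the four required columns.
#' @return The validated data.frame with derived columns appended.
#' @export
make_sample_meta <- function(df) {
  req <- c("sample_id", "individual_id", "biotype", "tissue")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$individual_id <- as.character(df$individual_id)
  df$biotype <- as.character(df$biotype)
  df$tissue <- as.character(df$tissue)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$biotype), biotype_labels())
  if (length(bad)) stop("unknown biotype label: ", paste(bad, collapse = ", "))
  badt <- setdiff(unique(df$tissue), c("oocyte", "liver"))
  if (length(badt)) stop("unknown tissue: ", paste(badt, collapse = ", "))
  df$reproduction <- biotype_reproduction(df$biotype)
  df$ploidy <- biotype_ploidy(df$biotype)
  rownames(df) <- NULL
  df
}
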