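#' Dose-adjusted homoeolog modulation ratios
#'
#' Per gene, the log2 ratio of the hybrid allele's per-copy normalized
#' mean to the corresponding parental per-copy mean:
#' `log2((E_hyb/nE) / (E_par/2))` and `log2((T_hyb/nT) / (T_par/2))`.
#' Negative values indicate downregulation of the homoeolog by the other
#' genome's trans factors; per-copy adjustment removes the trivial dose
#' effect in triploids.
#'
#' @param tbl An [ase_table()] data.frame (genes past the coverage
#'   filter, normalized counts).
#' @param pseudo Continuity constant used when a mean is zero; such genes
#'   are flagged.
#' @return data.frame: `gene_id`, `biotype`, `log2_Ehyb_over_E`,
#'   `log2_Thyb_over_T`, `continuity`.
#' @export
modulation_ratios <- function(tbl, pseudo = 0.5) {
  cc <- function(x) ifelse(x == 0, pseudo, x)
  le <- log2((cc(tbl$E_hyb) / tbl$nE) / (cc(tbl$E_par) / 2))
  lt <- log2((cc(tbl$T_hyb) / tbl$nT) / (cc(tbl$T_par) / 2))
  data.frame(gene_id = tbl$gene_id, biotype = tbl$biotype,
             log2_Ehyb_over_E = le, log2_Thyb_over_T = lt,
             continuity = tbl$E_hyb == 0 | tbl$T_hyb == 0 |
               tbl$E_par == 0 | tbl$T_par == 0,
             stringsAsFactors = FALSE)
}

#' Sample skewness
#'
#' Moment-based skewness `g1 = m3 / m2^(3/2)`; the adjusted
#' Fisher-Pearson variant rescales by
#' `sqrt(n(n-1))/(n-2)`.
#'
#' @param x Numeric vector, `n >= 3`, non-constant.
#' @param type `"g1"` (default) or `"adjusted"`.
#' @return Skewness value.
#' @export
skewness <- function(x, type = c("g1", "adjusted")) {
  type <- match.arg(type)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant input: skewness undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  if (type == "adjusted") g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Fligner-Killeen test of dispersion difference between two samples
#'
#' Rank-based normal-scores test on absolute deviations from the group
#' median; robust to non-normality. Also reports the two MAD values.
#'
#' @param x,y Numeric vectors (each `n >= 5`).
#' @return List: `statistic`, `p`, `mad` (named pair).
#' @export
fligner_killeen <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 5 || length(y) < 5) stop("need n >= 5 per sample")
  if (stats::sd(c(abs(x - stats::median(x)), abs(y - stats::median(y)))) == 0)
    stop("degenerate input: all absolute deviations identical")
  ht <- stats::fligner.test(list(x, y))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       mad = c(x = stats::mad(x), y = stats::mad(y)))
}

#' Permutation test on the skewness difference of two samples
#'
#' Observed statistic `D = |g1(x) - g1(y)|`; under each replicate the
#' pooled values are re-divided at random into pseudo-samples of the
#' original sizes (permutation, i.e. resampling without replacement;
#' bootstrap resampling available via `replace = TRUE`) and the
#' smoothed p-value `(1 + #\{D* >= D\}) / (n_perm + 1)` is returned.
#'
#' @param x,y Numeric vectors (each `n >= 10`).
#' @param n_perm Number of randomizations.
#' @param seed Optional seed.
#' @param replace Resample the pool with replacement instead of permuting.
#' @return List: `D`, `p`, `skew` (named pair).
#' @export
permutation_skewness_test <- function(x, y, n_perm = 1000, seed = NULL,
                                      replace = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 10 || length(y) < 10) stop("need n >= 10 per sample")
  if (!is.null(seed)) set.seed(seed)
  gx <- skewness(x); gy <- skewness(y)
  D <- abs(gx - gy)
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (replace) {
      xs <- sample(pool, nx, replace = TRUE)
      ys <- sample(pool, length(y), replace = TRUE)
    } else {
      idx <- sample.int(length(pool))
      xs <- pool[idx[seq_len(nx)]]
      ys <- pool[idx[-seq_len(nx)]]
    }
    if (abs(skewness(xs) - skewness(ys)) >= D) hits <- hits + 1L
  }
  list(D = D, p = (1 + hits) / (n_perm + 1), skew = c(x = gx, y = gy))
}

#' Cross-tissue correlation of homoeolog modulation
#'
#' Pearson correlation of the matched per-gene log2 modulation ratios
#' between two tissues, separately for each allele axis.
#'
#' @param ratios_a,ratios_b [modulation_ratios()] data.frames of the two
#'   tissues (matched by `gene_id`).
#' @return data.frame with one row per axis: `axis`, `n`, `r`, `r2`, `p`.
#' @export
cross_tissue_correlation <- function(ratios_a, ratios_b) {
  m <- merge(ratios_a, ratios_b, by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 10) stop("need >= 10 shared genes")
  one <- function(axis) {
    va <- m[[paste0(axis, "_a")]]; vb <- m[[paste0(axis, "_b")]]
    ht <- stats::cor.test(va, vb)
    data.frame(axis = axis, n = nrow(m), r = unname(ht$estimate),
               r2 = unname(ht$estimate)^2, p = ht$p.value,
               stringsAsFactors = FALSE)
  }
  rbind(one("log2_Ehyb_over_E"), one("log2_Thyb_over_T"))
}

#' Centroids of the dominance categories in modulation space
#'
#' Mean position of genes of each expression-level dominance category in
#' the plane (x = `log2_Thyb_over_T`, y = `log2_Ehyb_over_E`), reporting
#' which axis deviates more from 0; categories with fewer than `min_n`
#' genes are skipped.
#'
#' @param ratios [modulation_ratios()] data.frame.
#' @param calls Inheritance calls ([classify_inheritance()]).
#' @param min_n Minimum genes per category.
#' @return data.frame: `category`, `n`, `x`, `y`, `major_axis`.
#' @export
dominance_centroids <- function(ratios, calls, min_n = 5) {
  m <- merge(ratios, calls[, c("gene_id", "category")], by = "gene_id")
  dom <- c("II", "IV", "IX", "XI")
  out <- do.call(rbind, lapply(dom, function(cc) {
    d <- m[m$category == cc, ]
    if (nrow(d) < min_n) return(NULL)
    x <- mean(d$log2_Thyb_over_T); y <- mean(d$log2_Ehyb_over_E)
    data.frame(category = cc, n = nrow(d), x = x, y = y,
               major_axis = if (abs(y) > abs(x)) "Ehyb_over_E" else
                 "Thyb_over_T", stringsAsFactors = FALSE)
  }))
  out
}
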