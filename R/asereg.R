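#' Total-count normalization factors for an allele table
#'
#' The "total count" approach: a sample's factor is its total read count
#' (both alleles) divided by the mean total across samples; dividing by
#' the factor puts samples on a common depth scale.
#'
#' @param a An [allele_counts] object.
#' @return Named positive numeric vector per sample.
#' @export
total_count_factors <- function(a) {
  stopifnot(inherits(a, "allele_counts"))
  tot <- colSums(a$counts_E) + colSums(a$counts_T)
  if (any(tot == 0)) stop("sample with zero total counts")
  sf <- tot / mean(tot)
  names(sf) <- a$samples$sample_id
  sf
}

#' Coverage filter for allele-specific analysis
#'
#' Keeps genes whose allele-specific coverage (E + T reads) is strictly
#' above `min_cov` in at least `min_individuals` hybrid samples.
#'
#' @param a An [allele_counts] object.
#' @param min_cov Coverage threshold (strict >).
#' @param min_individuals Minimum number of qualifying hybrid samples.
#' @return Filtered [allele_counts].
#' @export
ase_filter <- function(a, min_cov = 30, min_individuals = 2) {
  stopifnot(inherits(a, "allele_counts"))
  hyb <- a$samples$reproduction == "asexual"
  if (!any(hyb)) return(a[integer(0), ])
  cov <- a$counts_E[, hyb, drop = FALSE] + a$counts_T[, hyb, drop = FALSE]
  keep <- rowSums(cov > min_cov) >= min_individuals
  a[keep, ]
}

#' Per-gene allele-specific summary for one hybrid biotype
#'
#' Aggregates an allele table into the per-gene quantities used by the
#' regulatory classification: normalized mean allelic expression in the
#' hybrid (`E_hyb`, `T_hyb`) and in the respective parents (`E_par`,
#' `T_par`, total expression of the pure species), raw pooled integer
#' counts for proportion tests, relative allelic expression
#' `rae_percent = 100 E_hyb / (E_hyb + T_hyb)`, the dose-adjusted hybrid
#' ratio `(E_hyb/nE) / (T_hyb/nT)` and the parental per-copy ratio
#' `(E_par/2) / (T_par/2)`.
#'
#' @param a An [allele_counts] containing parental (EE, TT) and hybrid
#'   samples; normally the output of [ase_filter()].
#' @param hybrid Hybrid biotype label.
#' @param pseudo Continuity constant added to both alleles of a ratio
#'   whenever one side is zero (Haldane correction); flagged per gene.
#' @return data.frame, one row per gene.
#' @export
ase_table <- function(a, hybrid = "ET", pseudo = 0.5) {
  stopifnot(inherits(a, "allele_counts"))
  b <- a$samples$biotype
  if (!all(c("EE", "TT", hybrid) %in% b))
    stop("allele table must contain EE, TT and ", hybrid, " samples")
  sf <- total_count_factors(a)
  nE <- sweep(a$counts_E, 2, sf, "/")
  nT <- sweep(a$counts_T, 2, sf, "/")
  hj <- b == hybrid; ee <- b == "EE"; tt <- b == "TT"
  cp <- biotype_copies(hybrid)
  E_hyb <- rowMeans(nE[, hj, drop = FALSE])
  T_hyb <- rowMeans(nT[, hj, drop = FALSE])
  E_par <- rowMeans(nE[, ee, drop = FALSE])
  T_par <- rowMeans(nT[, tt, drop = FALSE])
  # quasi-binomial design effect of pooled parental counts: biological
  # replicate dispersion (alpha, moment estimate pooled across genes)
  # inflates the variance of a gene's pooled reads by ~ 1 + alpha * mu.
  # One common deflator per gene (alpha times the harmonic mean of the
  # two parental means) preserves the E:T proportion while matching the
  # variance of the parental log ratio.
  # pooled weighted least-squares fit of var = mu + alpha mu^2 across
  # genes and both parental species (per-gene moment estimates at k ~ 4
  # replicates are too noisy and their median is biased low)
  row_var <- function(m) apply(m, 1, stats::var)
  mvE <- cbind(E_par, row_var(nE[, ee, drop = FALSE]))
  mvT <- cbind(T_par, row_var(nT[, tt, drop = FALSE]))
  mv <- rbind(mvE, mvT)
  mv <- mv[is.finite(mv[, 2]) & mv[, 1] > 0, , drop = FALSE]
  alpha_hat <- if (nrow(mv) < 2) 0 else
    max(sum(mv[, 2] - mv[, 1]) / sum(mv[, 1]^2), 0)
  hmean <- 2 / (1 / pmax(E_par, 1e-8) + 1 / pmax(T_par, 1e-8))
  phi_par <- 1 + alpha_hat * hmean
  flag <- E_hyb == 0 | T_hyb == 0 | E_par == 0 | T_par == 0
  cc <- function(x, y) ifelse(x == 0 | y == 0, pseudo, 0)
  adj <- ((E_hyb + cc(E_hyb, T_hyb)) / cp[["E"]]) /
         ((T_hyb + cc(E_hyb, T_hyb)) / cp[["T"]])
  rpar <- ((E_par + cc(E_par, T_par)) / 2) / ((T_par + cc(E_par, T_par)) / 2)
  data.frame(
    gene_id = rownames(a$counts_E), biotype = hybrid,
    n_hyb = sum(hj), n_par_E = sum(ee), n_par_T = sum(tt),
    nE = cp[["E"]], nT = cp[["T"]],
    E_hyb = E_hyb, T_hyb = T_hyb, E_par = E_par, T_par = T_par,
    E_hyb_n = rowSums(a$counts_E[, hj, drop = FALSE]),
    T_hyb_n = rowSums(a$counts_T[, hj, drop = FALSE]),
    E_par_n = round(rowSums(nE[, ee, drop = FALSE])),
    T_par_n = round(rowSums(nT[, tt, drop = FALSE])),
    E_par_eff = round(rowSums(nE[, ee, drop = FALSE]) / phi_par),
    T_par_eff = round(rowSums(nT[, tt, drop = FALSE]) / phi_par),
    alpha_par = alpha_hat,
    rae_percent = 100 * E_hyb / (E_hyb + T_hyb),
    adj_ratio_hyb = adj, ratio_par = rpar,
    log2fc_par = log2(rpar), continuity = flag,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect complete silencing of a parental allele
#'
#' An allele counts as silenced when its reads summed over the hybrid
#' samples are exactly zero (for genes that passed the coverage filter).
#'
#' @param tbl An [ase_table()] data.frame.
#' @return Factor per gene: `both_expressed`, `E_silenced`, `T_silenced`.
#' @export
detect_silencing <- function(tbl) {
  s <- ifelse(tbl$E_hyb_n == 0, "E_silenced",
       ifelse(tbl$T_hyb_n == 0, "T_silenced", "both_expressed"))
  factor(s, levels = c("both_expressed", "E_silenced", "T_silenced"))
}

#' Regression of hybrid allelic ratio on parental divergence
#'
#' NB log-link GLM of the hybrid E-allele counts with offset
#' `log(T_hyb * nE / nT)` (so the linear predictor models the
#' dose-adjusted log allelic ratio) and single predictor
#' `log(E_par / T_par)`. Under pure cis regulation the slope is 1; under
#' pure trans regulation with full cross-talk it is 0.
#'
#' @param tbl An [ase_table()] data.frame (>= 10 genes).
#' @param correct_attenuation Also report a slope corrected for
#'   regression dilution: the predictor is the parental log ratio
#'   *estimated* from finitely many replicates, and its measurement
#'   variance (delta method from the replicate dispersion) attenuates the
#'   naive slope by the reliability ratio.
#' @return List: `slope`, `se`, `r2` (deviance-based pseudo-R-squared),
#'   `p` (Wald), `n`, `reliability`, `slope_corrected`, `fit`.
#' @export
regress_hybrid_on_parent <- function(tbl, correct_attenuation = TRUE) {
  if (nrow(tbl) < 10) stop("need >= 10 genes for the ratio regression")
  y <- tbl$E_hyb_n
  toff <- ifelse(tbl$T_hyb_n == 0, 0.5, tbl$T_hyb_n)
  off <- log(toff * tbl$nE / tbl$nT)
  x <- log(tbl$ratio_par)
  fit <- suppressWarnings(MASS::glm.nb(y ~ x + offset(off)))
  cf <- summary(fit)$coefficients
  r2 <- 1 - fit$deviance / fit$null.deviance
  out <- list(slope = cf["x", "Estimate"], se = cf["x", "Std. Error"],
              r2 = r2, p = cf["x", "Pr(>|z|)"], n = nrow(tbl), fit = fit)
  if (correct_attenuation) {
    kE <- max(tbl$n_par_E[1] %||% 4, 2)
    a <- tbl$alpha_par[1] %||% 0
    s2x <- (2 * a + 1 / pmax(tbl$E_par, 0.5) + 1 / pmax(tbl$T_par, 0.5)) / kE
    rel <- max(1 - mean(s2x) / stats::var(x), 0.1)
    out$reliability <- rel
    out$slope_corrected <- out$slope / rel
  }
  out
}

#' Does the cis slope differ between inheritance categories?
#'
#' Likelihood-ratio comparison of the ratio regression with and without a
#' slope-by-category interaction, over genes annotated to expression-level
#' dominance UP vs DOWN. Categories with fewer than 5 genes are excluded
#' with a warning; a single remaining category is an error.
#'
#' @param tbl An [ase_table()] data.frame.
#' @param calls Inheritance call data.frame ([classify_inheritance()]).
#' @return List: `p_lrt`, `slopes` (per category), `r2` (full model), `n`.
#' @export
regress_with_inheritance_interaction <- function(tbl, calls) {
  m <- merge(tbl, calls[, c("gene_id", "group")], by = "gene_id")
  m <- m[m$group %in% c("dominance_up", "dominance_down"), ]
  m$group <- droplevels(factor(m$group))
  sizes <- table(m$group)
  small <- names(sizes)[sizes < 5]
  if (length(small)) {
    warning("excluding category with < 5 genes: ", paste(small, collapse = ", "))
    m <- m[!m$group %in% small, ]
    m$group <- droplevels(m$group)
  }
  if (nlevels(m$group) < 2)
    stop("need >= 2 dominance categories with >= 5 genes")
  y <- m$E_hyb_n
  toff <- ifelse(m$T_hyb_n == 0, 0.5, m$T_hyb_n)
  off <- log(toff * m$nE / m$nT)
  x <- log(m$ratio_par)
  g <- m$group
  full_nb <- suppressWarnings(MASS::glm.nb(y ~ x * g + offset(off)))
  theta <- full_nb$theta
  full <- stats::glm(y ~ x * g + offset(off),
                     family = MASS::negative.binomial(theta))
  red <- stats::glm(y ~ x + offset(off),
                    family = MASS::negative.binomial(theta))
  stat <- as.numeric(2 * (stats::logLik(full) - stats::logLik(red)))
  dfd <- length(stats::coef(full)) - length(stats::coef(red))
  cf <- stats::coef(full)
  base <- cf["x"]
  slopes <- c(base, base + cf[grep("^x:g", names(cf))])
  names(slopes) <- levels(g)
  list(p_lrt = stats::pchisq(max(stat, 0), dfd, lower.tail = FALSE),
       slopes = slopes, r2 = 1 - full$deviance / full$null.deviance,
       n = nrow(m))
}

#' Cis/trans regulatory divergence classification
#'
#' Three two-sided proportion tests (chi-square with continuity
#' correction), each BH-corrected across genes within its own family:
#' \itemize{
#'  \item `T_A` parental divergence: the pooled normalized parental counts
#'    against the dose-neutral expectation 1/2;
#'  \item `T_B` hybrid-vs-parent: the hybrid allelic proportion against
#'    the parental proportion re-weighted to the hybrid's genomic dose
#'    (`p0 = nE e / (nE e + nT t)` with `e`, `t` the parental per-copy
#'    means), as a two-sample test on the pooled counts;
#'  \item `T_C` hybrid balance: the hybrid allelic proportion against the
#'    pure-dose expectation `nE / (nE + nT)`.
#' }
#' Assignment: `T_A` and `T_C` significant with `T_B` not: `Cis`; `T_A`
#' and `T_B` significant with `T_C` not: `Trans`; `T_B` and `T_C` both
#' significant: combined cis + trans, split into `Compensating` when the
#' dose-adjusted hybrid ratio exceeds 1 and the parental ratio lies below
#' it (or the mirrored pattern below 1), `Enhancing` in the same-direction
#' patterns; everything else: `NoCisNoTrans`.
#'
#' @param tbl An [ase_table()] data.frame.
#' @param alpha_q Significance threshold on BH-adjusted q.
#' @param use_effective Deflate the pooled parental counts by the
#'   estimated quasi-binomial design effect (`1 + alpha mu`, biological
#'   replicate overdispersion) before the proportion tests; `FALSE`
#'   pools raw reads across replicates.
#' @return `tbl` with columns `q_A`, `q_B`, `q_C` and `category` appended.
#' @export
classify_cis_trans <- function(tbl, alpha_q = 0.05, use_effective = TRUE) {
  n <- nrow(tbl)
  pA <- pB <- pC <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    eh <- tbl$E_hyb_n[i]; th <- tbl$T_hyb_n[i]
    ep <- if (use_effective) tbl$E_par_eff[i] else tbl$E_par_n[i]
    tp <- if (use_effective) tbl$T_par_eff[i] else tbl$T_par_n[i]
    nE <- tbl$nE[i]; nT <- tbl$nT[i]
    pA[i] <- tryCatch(suppressWarnings(
      stats::prop.test(ep, ep + tp, p = 0.5)$p.value), error = function(e) NA)
    pC[i] <- tryCatch(suppressWarnings(
      stats::prop.test(eh, eh + th, p = nE / (nE + nT))$p.value),
      error = function(e) NA)
    # parental counts re-weighted to the hybrid dose for the two-sample test
    ep2 <- round(ep * nE / 2); tp2 <- round(tp * nT / 2)
    pB[i] <- tryCatch(suppressWarnings(
      stats::prop.test(c(eh, ep2), c(eh + th, ep2 + tp2))$p.value),
      error = function(e) NA)
  }
  qA <- stats::p.adjust(pA, "BH")
  qB <- stats::p.adjust(pB, "BH")
  qC <- stats::p.adjust(pC, "BH")
  sA <- !is.na(qA) & qA < alpha_q
  sB <- !is.na(qB) & qB < alpha_q
  sC <- !is.na(qC) & qC < alpha_q
  R <- tbl$adj_ratio_hyb
  P <- tbl$ratio_par
  comp <- (R > 1 & P < R) | (R < 1 & P > R)
  enh <- (R > 1 & P > R) | (R < 1 & P < R)
  cat <- rep("NoCisNoTrans", n)
  cat[sA & sC & !sB] <- "Cis"
  cat[sA & sB & !sC] <- "Trans"
  cat[sB & sC & comp] <- "Compensating"
  cat[sB & sC & enh] <- "Enhancing"
  tbl$q_A <- qA; tbl$q_B <- qB; tbl$q_C <- qC
  tbl$category <- factor(cat, levels = c("Cis", "Trans", "Enhancing",
                                         "Compensating", "NoCisNoTrans",
                                         "NotAvailable"))
  tbl
}

#' Full regulatory call table including unavailable genes
#'
#' Runs [ase_filter()], [ase_table()] and [classify_cis_trans()] and pads
#' the result with `NotAvailable` rows for every gene of `gene_universe`
#' that lacks a diagnostic SNP or failed the coverage filter, mirroring
#' the layout of a per-biotype regulatory category summary.
#'
#' @param a An (unfiltered) [allele_counts].
#' @param hybrid Hybrid biotype label.
#' @param gene_universe Character vector of all analyzed genes; defaults
#'   to the genes of `a`.
#' @param alpha_q Significance threshold.
#' @param min_cov,min_individuals Passed to [ase_filter()].
#' @return data.frame with `gene_id`, `biotype`, `category` (and the test
#'   columns for genes that were classifiable).
#' @export
regulatory_calls <- function(a, hybrid = "ET", gene_universe = NULL,
                             alpha_q = 0.05, min_cov = 30,
                             min_individuals = 2) {
  if (is.null(gene_universe)) gene_universe <- rownames(a$counts_E)
  keep <- a$samples$biotype %in% c("EE", "TT", hybrid)
  f <- ase_filter(a[, keep], min_cov = min_cov,
                  min_individuals = min_individuals)
  cl <- if (nrow(f$counts_E)) classify_cis_trans(ase_table(f, hybrid),
                                                 alpha_q = alpha_q) else NULL
  out <- data.frame(gene_id = gene_universe, biotype = hybrid,
                    category = factor("NotAvailable",
                                      levels = levels(cl$category %||%
                                        factor(NULL, levels = c("Cis", "Trans",
                                          "Enhancing", "Compensating",
                                          "NoCisNoTrans", "NotAvailable")))),
                    stringsAsFactors = FALSE)
  if (!is.null(cl)) {
    idx <- match(cl$gene_id, out$gene_id)
    ok <- !is.na(idx)
    out$category[idx[ok]] <- cl$category[ok]
  }
  attr(out, "detail") <- cl
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regulatory category summary table
#'
#' Per-biotype counts over the six regulatory categories, in the layout of
#' a biotype-by-category frequency table.
#' @param ... Named call data.frames from [regulatory_calls()]; names are
#'   used as row labels.
#' @return Integer matrix biotypes x categories.
#' @export
regulatory_summary <- function(...) {
  calls <- list(...)
  t(sapply(calls, function(d) table(d$category)))
}

#' Parental expression divergence across regulatory categories
#'
#' Compares |log2 parental fold change| between regulatory categories by
#' two-sided Wilcoxon rank-sum tests, BH-corrected across the pairs.
#' Categories with fewer than `min_n` genes are skipped.
#'
#' @param tbl Output of [classify_cis_trans()].
#' @param categories Categories to compare.
#' @param min_n Minimum genes per category.
#' @return data.frame of pairwise results (`cat1`, `cat2`, `n1`, `n2`,
#'   `W`, `p`, `q`).
#' @export
divergence_by_category <- function(tbl, categories = c("Cis", "Trans",
                                                       "Compensating"),
                                   min_n = 5) {
  v <- abs(tbl$log2fc_par)
  groups <- lapply(categories, function(cc) v[tbl$category == cc])
  names(groups) <- categories
  keep <- lengths(groups) >= min_n
  groups <- groups[keep]
  if (length(groups) < 2) stop("need >= 2 categories with >= ", min_n, " genes")
  prs <- utils::combn(names(groups), 2)
  res <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    ht <- stats::wilcox.test(groups[[a]], groups[[b]], exact = FALSE)
    data.frame(cat1 = a, cat2 = b, n1 = length(groups[[a]]),
               n2 = length(groups[[b]]), W = unname(ht$statistic),
               p = ht$p.value, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, "BH")
  res
}
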