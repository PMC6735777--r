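#' Remove genes with low cumulated counts
#'
#' Retains genes whose counts summed over all samples are strictly above
#' `min_total`, suppressing background expression noise before DE testing.
#'
#' @param x A [gene_counts] object.
#' @param min_total Threshold; the default keeps genes with total > 100.
#' @return Filtered [gene_counts].
#' @export
filter_low_expression <- function(x, min_total = 100) {
  stopifnot(inherits(x, "gene_counts"))
  keep <- rowSums(x$counts) > min_total
  x[keep, ]
}

# median-of-ratios factor of one sample against a reference pseudo-sample
.mor_factor <- function(col, ref) {
  use <- ref > 0
  if (!any(use)) return(NA_real_)
  stats::median(col[use] / ref[use])
}

#' Median-of-ratios size factors
#'
#' Standard median-of-ratios normalization: the reference pseudo-sample is
#' the gene-wise geometric mean, and a sample's factor is the median count
#' ratio against it over genes expressed in all samples of the reference
#' set. `mode = "per_condition"` computes a reference within each
#' biotype-by-tissue condition, evaluates every sample against every
#' condition's reference, and conservatively takes the per-sample maximum
#' factor; factors are then rescaled to geometric mean 1.
#'
#' @param x A [gene_counts] object.
#' @param mode `"global"` or `"per_condition"`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x, mode = c("global", "per_condition")) {
  stopifnot(inherits(x, "gene_counts"))
  mode <- match.arg(mode)
  m <- x$counts
  geo_ref <- function(mm) {
    ok <- rowSums(mm > 0) == ncol(mm)
    ref <- numeric(nrow(mm))
    ref[ok] <- exp(rowMeans(log(mm[ok, , drop = FALSE])))
    ref
  }
  if (mode == "global") {
    ref <- geo_ref(m)
    if (!any(ref > 0))
      stop("no gene expressed in all samples; median-of-ratios needs a ",
           "positive geometric reference (consider a pseudo-reference fallback)")
    sf <- apply(m, 2, .mor_factor, ref = ref)
  } else {
    cond <- interaction(x$samples$biotype, x$samples$tissue, drop = TRUE)
    refs <- lapply(levels(cond), function(l)
      geo_ref(m[, cond == l, drop = FALSE]))
    if (all(vapply(refs, function(r) !any(r > 0), logical(1))))
      stop("no gene expressed in all samples of any condition")
    fac <- sapply(refs, function(ref) apply(m, 2, .mor_factor, ref = ref))
    sf <- apply(as.matrix(fac), 1, max, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor")
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Size-factor-normalized count matrix
#' @param x A [gene_counts] object.
#' @param sf Optional precomputed factors (default [size_factors()] global).
#' @return Numeric matrix of counts divided by their sample's factor.
#' @export
normalized_counts <- function(x, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(x)
  sweep(x$counts, 2, sf[colnames(x$counts)], "/")
}

# 1-D Newton for the NB group mean on the log scale: solves
# sum (y - mu)/(1 + mu/theta) = 0 with mu = exp(b + off).
.nb_group_coef <- function(y, off, theta) {
  tot <- sum(y)
  if (tot == 0) return(log(0.5 / sum(exp(off))))  # continuity for empty group
  b <- log(tot / sum(exp(off)))
  for (it in 1:50) {
    mu <- exp(b + off)
    denom <- 1 + mu / theta
    score <- sum((y - mu) / denom)
    info <- sum(mu / denom)
    step <- score / info
    b <- b + step
    if (abs(step) < 1e-10) break
  }
  b
}

# Two-group NB fit with Cox-Reid adjusted-profile-likelihood dispersion.
# The CR adjustment (-1/2 log det of the Fisher information of the mean
# parameters) removes the downward ML bias of the dispersion at small n,
# which would otherwise make the Wald test anticonservative. The Wald
# statistic is referred to a t distribution with n - 2 df. Plain ML
# dispersion (glm.nb) is available via disp = "ml".
.fit_nb_two_group <- function(y, g2, off, test = "wald", disp = "cr") {
  i0 <- g2 == 0L; i1 <- !i0
  lth_lo <- log(1e-2); lth_hi <- log(1e8)
  profile <- function(lth, adjust = TRUE) {
    th <- exp(lth)
    b0 <- .nb_group_coef(y[i0], off[i0], th)
    b1 <- .nb_group_coef(y[i1], off[i1], th)
    mu <- exp(ifelse(i0, b0, b1) + off)
    ll <- sum(stats::dnbinom(y, size = th, mu = mu, log = TRUE))
    if (adjust) {
      w <- mu / (1 + mu / th)
      ll <- ll - 0.5 * (log(sum(w[i0])) + log(sum(w[i1])))
    }
    ll
  }
  if (disp == "cr") {
    opt <- stats::optimize(profile, c(lth_lo, lth_hi), maximum = TRUE,
                           tol = 1e-4)
    theta <- exp(opt$maximum)
  } else {
    opt <- stats::optimize(profile, c(lth_lo, lth_hi), adjust = FALSE,
                           maximum = TRUE, tol = 1e-4)
    theta <- exp(opt$maximum)
  }
  theta <- min(theta, 1e8)  # dispersion floor 1e-8
  b0 <- .nb_group_coef(y[i0], off[i0], theta)
  b1 <- .nb_group_coef(y[i1], off[i1], theta)
  mu <- exp(ifelse(i0, b0, b1) + off)
  w <- mu / (1 + mu / theta)
  se <- sqrt(1 / sum(w[i0]) + 1 / sum(w[i1]))
  delta <- b1 - b0
  n <- length(y)
  if (test == "wald") {
    stat <- delta / se
    p <- 2 * stats::pt(-abs(stat), df = n - 2)
  } else {
    bC <- .nb_group_coef(y, off, theta)
    muC <- exp(bC + off)
    ll1 <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
    ll0 <- sum(stats::dnbinom(y, size = theta, mu = muC, log = TRUE))
    stat <- 2 * (ll1 - ll0)
    p <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  c(stat = stat, log2fc = delta / log(2), p = p, disp = 1 / theta)
}

#' Negative-binomial two-group contrast per gene
#'
#' Fits, per gene, a NB log-link model with a group indicator and a
#' log(size factor) offset, estimating the per-gene dispersion by
#' Cox-Reid adjusted profile likelihood (dispersion floor 1e-8; plain
#' maximum likelihood available via `disp = "ml"`) and testing the group
#' coefficient by a Wald statistic referred to a t distribution with
#' `n - 2` degrees of freedom (or by likelihood-ratio chi-square with
#' `test = "lrt"`). Reports BH-adjusted q across genes and the log2 fold
#' change of the second group level over the first.
#'
#' @param x A [gene_counts] object (typically after
#'   [filter_low_expression()]).
#' @param group Factor (or coercible) of length `ncol(x)` with exactly two
#'   levels, or a list of two character vectors of biotype labels defining
#'   the grouping, e.g. `list(c("EE","TT"), c("ET","EET","ETT"))`.
#' @param sf Optional size factors; default global median-of-ratios.
#' @param test `"wald"` or `"lrt"`.
#' @param disp Dispersion estimator: `"cr"` (Cox-Reid adjusted profile
#'   likelihood, default) or `"ml"`.
#' @return data.frame with columns `gene_id`, `statistic`, `log2fc`, `p`,
#'   `q`, `dispersion`, `method`.
#' @export
nb_contrast <- function(x, group, sf = NULL, test = c("wald", "lrt"),
                        disp = c("cr", "ml")) {
  stopifnot(inherits(x, "gene_counts"))
  test <- match.arg(test)
  disp <- match.arg(disp)
  if (is.list(group)) {
    b <- x$samples$biotype
    g <- ifelse(b %in% group[[1]], "g1", ifelse(b %in% group[[2]], "g2", NA))
    if (anyNA(g)) stop("samples with biotype outside both groups: ",
                       paste(unique(b[is.na(g)]), collapse = ", "))
    group <- factor(g, levels = c("g1", "g2"))
  }
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) < 2L)) stop("need >= 2 samples per group")
  if (is.null(sf)) sf <- size_factors(x)
  off <- log(sf[colnames(x$counts)])
  n <- nrow(x$counts)
  out <- data.frame(gene_id = rownames(x$counts), statistic = NA_real_,
                    log2fc = NA_real_, p = NA_real_, q = NA_real_,
                    dispersion = NA_real_, method = NA_character_,
                    stringsAsFactors = FALSE)
  g2 <- as.integer(group == levels(group)[2])
  for (i in seq_len(n)) {
    y <- x$counts[i, ]
    if (all(y == 0)) { out$method[i] <- "all_zero"; next }
    fit <- tryCatch(.fit_nb_two_group(y, g2, off, test, disp),
                    error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit))) { out$method[i] <- "failed"; next }
    out$statistic[i] <- fit["stat"]
    out$log2fc[i] <- fit["log2fc"]
    out$p[i] <- fit["p"]
    out$dispersion[i] <- fit["disp"]
    out$method[i] <- disp
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Design factors derived from biotype
#'
#' The three confounded factors of the study design: `species_status`
#' (EE / TT / hybrid), `ploidy` (2n / 3n) and `reproduction`
#' (sexual / asexual), all computed from biotype.
#'
#' @param samples Sample metadata data.frame.
#' @return data.frame of the three factors.
#' @export
design_factors <- function(samples) {
  b <- samples$biotype
  data.frame(
    species_status = factor(ifelse(b == "EE", "EE",
                            ifelse(b == "TT", "TT", "hybrid")),
                            levels = c("EE", "TT", "hybrid")),
    ploidy = factor(biotype_ploidy(b), levels = c("diploid", "triploid")),
    reproduction = factor(biotype_reproduction(b),
                          levels = c("sexual", "asexual")))
}

#' Per-gene type-II ANOVA over the design factors
#'
#' Fits, per gene, a NB GLM with all estimable main effects and tests each
#' factor by a likelihood-ratio chi-square against the model with that
#' factor removed while retaining all others (principle of marginality,
#' main effects only). The study design aliases `reproduction` with the
#' hybrid level of `species_status` (every hybrid is asexual); aliased
#' terms are flagged `"aliased"` rather than silently dropped.
#'
#' @param x A [gene_counts] object.
#' @param factors Which factors to test (subset of
#'   `species_status`, `ploidy`, `reproduction`).
#' @param sf Optional size factors.
#' @return List with `table` (per-gene data.frame of `p_*`/`q_*` columns)
#'   and `aliased` (character vector of factor names aliased by design).
#' @export
anova_type2 <- function(x, factors = c("species_status", "ploidy",
                                       "reproduction"), sf = NULL) {
  stopifnot(inherits(x, "gene_counts"))
  fac <- design_factors(x$samples)[, factors, drop = FALSE]
  fac <- droplevels(fac)
  if (is.null(sf)) sf <- size_factors(x)
  off <- log(sf[colnames(x$counts)])

  # aliasing by design: build the full model matrix once and drop factors
  # whose columns add no rank beyond the other factors
  terms_of <- function(keep) {
    keep <- keep[vapply(keep, function(f) nlevels(fac[[f]]) > 1, logical(1))]
    if (!length(keep)) return(NULL)
    stats::model.matrix(stats::as.formula(paste("~", paste(keep, collapse = "+"))),
                        data = fac)
  }
  full_rank <- function(mm) if (is.null(mm)) 0L else qr(mm)$rank
  usable <- names(fac)
  aliased <- character(0)
  for (f in names(fac)) {
    if (nlevels(fac[[f]]) < 2) { aliased <- c(aliased, f); next }
    others <- setdiff(usable, f)
    r_with <- full_rank(terms_of(usable))
    r_without <- full_rank(terms_of(others))
    if (r_with == r_without) aliased <- c(aliased, f)
  }
  est <- setdiff(usable, aliased)
  # drop aliased factors from the fitted model but keep them flagged
  mm_full <- terms_of(est)
  if (is.null(mm_full)) stop("no estimable factor in the design")

  n <- nrow(x$counts)
  res <- data.frame(gene_id = rownames(x$counts), stringsAsFactors = FALSE)
  for (f in factors) res[[paste0("p_", f)]] <- NA_real_

  col_assign <- attr(mm_full, "assign")
  term_labels <- attr(stats::terms(
    stats::as.formula(paste("~", paste(est, collapse = "+")))), "term.labels")
  for (i in seq_len(n)) {
    y <- x$counts[i, ]
    if (all(y == 0)) next
    full <- tryCatch(suppressWarnings(
      MASS::glm.nb(y ~ 0 + mm_full + offset(off),
                   control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(full)) next
    theta <- full$theta
    ll_full <- stats::logLik(full)
    for (f in est) {
      keep_cols <- col_assign %in% c(0, which(term_labels != f))
      mm_red <- mm_full[, keep_cols, drop = FALSE]
      red <- tryCatch(suppressWarnings(
        stats::glm(y ~ 0 + mm_red + offset(off),
                   family = MASS::negative.binomial(theta))),
        error = function(e) NULL)
      if (is.null(red)) next
      dfd <- qr(mm_full)$rank - qr(mm_red)$rank
      stat <- as.numeric(2 * (ll_full - stats::logLik(red)))
      res[[paste0("p_", f)]][i] <- stats::pchisq(max(stat, 0), df = dfd,
                                                 lower.tail = FALSE)
    }
  }
  for (f in factors) {
    res[[paste0("q_", f)]] <- if (f %in% aliased) NA_real_ else
      stats::p.adjust(res[[paste0("p_", f)]], method = "BH")
    if (f %in% aliased) res[[paste0("p_", f)]] <- NA_real_
  }
  list(table = res, aliased = aliased)
}

#' Exact binomial test of up/down regulation asymmetry
#'
#' Two-sided exact test of the null that a significant gene is equally
#' likely to be up- or down-regulated.
#'
#' @param n_up,n_down Counts of significantly up- and down-regulated genes.
#' @return p-value.
#' @export
updown_asymmetry <- function(n_up, n_down) {
  if (n_up + n_down == 0) {
    warning("no significant genes; returning p = 1")
    return(1)
  }
  stats::binom.test(n_up, n_up + n_down, p = 0.5,
                    alternative = "two.sided")$p.value
}
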