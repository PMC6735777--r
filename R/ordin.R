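#' Generalized Procrustes alignment of landmark configurations
#'
#' Translates every configuration to a common centroid, scales each to
#' unit centroid size, and iteratively rotates all configurations onto the
#' evolving consensus (orthogonal Procrustes superimposition) until the
#' consensus changes by less than `tol`.
#'
#' @param shapes List of k x m landmark matrices (same k, m for all), or a
#'   3-D array k x m x n.
#' @param tol Convergence tolerance on the consensus (Frobenius norm).
#' @param max_iter Iteration cap.
#' @return List: `aligned` (k x m x n array), `consensus`, `iterations`.
#' @export
generalized_procrustes <- function(shapes, tol = 1e-8, max_iter = 100) {
  if (is.array(shapes) && length(dim(shapes)) == 3)
    shapes <- lapply(seq_len(dim(shapes)[3]), function(i) shapes[, , i])
  n <- length(shapes)
  if (n < 2) stop("need >= 2 shapes")
  d <- dim(shapes[[1]])
  if (any(!vapply(shapes, function(s) identical(dim(s), d), logical(1))))
    stop("all shapes must share the same landmark count")
  norm_shape <- function(s) {
    s <- sweep(s, 2, colMeans(s))
    cs <- sqrt(sum(s^2))
    if (cs < 1e-12 || qr(s)$rank < 2) stop("degenerate (collinear) shape")
    s / cs
  }
  al <- lapply(shapes, norm_shape)
  rotate_to <- function(s, ref) {
    # proper rotation only (no reflection), so alignment is unique and
    # order-invariant
    sv <- svd(crossprod(s, ref))
    d <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(rep(1, ncol(s) - 1), d)) %*% t(sv$v)
    s %*% R
  }
  consensus <- al[[1]]
  for (it in seq_len(max_iter)) {
    al <- lapply(al, rotate_to, ref = consensus)
    newc <- Reduce(`+`, al) / n
    newc <- newc / sqrt(sum(newc^2))
    delta <- sqrt(sum((newc - consensus)^2))
    consensus <- newc
    if (delta < tol) break
  }
  arr <- array(unlist(al), dim = c(d, n),
               dimnames = list(NULL, NULL, names(shapes)))
  list(aligned = arr, consensus = consensus, iterations = it)
}

#' Procrustes distance between two configurations
#'
#' Root summed squared landmark distance after optimal translation,
#' scaling and rotation of `b` onto `a`.
#' @param a,b Landmark matrices of identical shape.
#' @return Non-negative distance.
#' @export
procrustes_distance <- function(a, b) {
  g <- generalized_procrustes(list(a, b))
  sqrt(sum((g$aligned[, , 1] - g$aligned[, , 2])^2))
}

.new_ordination <- function(scores, eigenvalues, method, negative = NULL) {
  prop <- eigenvalues / sum(eigenvalues)
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 proportion_explained = prop,
                 significant_axes = broken_stick(eigenvalues),
                 negative_eigenvalues = negative, method = method),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<%s ordination: %d individuals, %d axes, %d significant (broken stick)>\n",
              x$method, nrow(x$scores), length(x$eigenvalues),
              x$significant_axes))
  invisible(x)
}

#' Principal component analysis
#'
#' Centered (unscaled) covariance eigen-decomposition; axis significance
#' by the broken-stick model.
#'
#' @param X Numeric individuals x features matrix.
#' @return An `ordination` object (`scores`, `eigenvalues`,
#'   `proportion_explained`, `significant_axes`, `method = "PCA"`).
#' @export
pca_ordination <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("NaN or non-finite entries in X")
  if (nrow(X) < 2) stop("need >= 2 individuals")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  keep <- eig > max(eig) * 1e-12
  .new_ordination(pc$x[, keep, drop = FALSE], eig[keep], "PCA")
}

#' Principal coordinates analysis
#'
#' Gower double-centering eigen-decomposition of a distance matrix;
#' negative eigenvalues are reported but excluded from the scores and
#' the proportions explained.
#'
#' @param D A `dist` or symmetric zero-diagonal distance matrix.
#' @return An `ordination` object (`method = "PCoA"`).
#' @export
pcoa_ordination <- function(D) {
  Dm <- as.matrix(D)
  if (any(!is.finite(Dm))) stop("NaN or non-finite entries in D")
  if (!isSymmetric(unname(Dm)) || any(abs(diag(Dm)) > 1e-12))
    stop("D must be symmetric with zero diagonal")
  n <- nrow(Dm)
  A <- -0.5 * Dm^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ev <- eigen(G, symmetric = TRUE)
  tolv <- max(abs(ev$values)) * 1e-9
  pos <- ev$values > tolv
  if (!any(pos)) stop("degenerate decomposition: no positive eigenvalue")
  neg <- ev$values[ev$values < -tolv]
  scores <- ev$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev$values[pos]), sum(pos))
  rownames(scores) <- rownames(Dm)
  colnames(scores) <- sprintf("PCo%d", seq_len(ncol(scores)))
  .new_ordination(scores, ev$values[pos], "PCoA", negative = neg)
}

#' Broken-stick count of significant ordination axes
#'
#' Null expectation for the k-th eigenvalue proportion:
#' `b_k = (1/p) * sum_{i=k..p} 1/i`. An axis is significant when its
#' observed proportion strictly exceeds `b_k` and all earlier axes are
#' significant (contiguity from the first axis).
#'
#' @param eigenvalues Positive eigenvalues (length `p >= 1`).
#' @return Integer count of significant leading axes.
#' @export
broken_stick <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p == 0) stop("empty eigenvalue list")
  bk <- rev(cumsum(1 / rev(seq_len(p)))) / p
  prop <- eigenvalues / sum(eigenvalues)
  sig <- prop > bk
  if (!sig[1]) return(0L)
  which.min(c(sig, FALSE)) - 1L
}

#' PERMANOVA of group differences with pairwise follow-up
#'
#' Permutational multivariate ANOVA (pseudo-F from among/within sums of
#' squared distances) of a grouping factor, with optional preceding
#' covariate factor fitted sequentially, plus pairwise group comparisons.
#' Groups with a single member are excluded with a warning.
#'
#' @param D `dist` object or distance matrix.
#' @param groups Grouping vector.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param covariate Optional second factor fitted before `groups`.
#' @param pairwise Run pairwise comparisons of group levels.
#' @return List: `F`, `R2`, `p`, `table` (full PERMANOVA table), and
#'   `pairwise` (data.frame with BH-adjusted q) when requested.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL,
                      covariate = NULL, pairwise = TRUE) {
  Dm <- as.matrix(D)
  groups <- factor(groups)
  if (length(groups) != nrow(Dm)) stop("groups length must match D")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding group(s) with a single member: ",
            paste(drop, collapse = ", "))
    keep <- !groups %in% drop
    Dm <- Dm[keep, keep]
    groups <- droplevels(groups[keep])
    if (!is.null(covariate)) covariate <- covariate[keep]
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(group = groups)
  if (is.null(covariate)) {
    tab <- vegan::adonis2(stats::as.dist(Dm) ~ group, data = dat,
                          permutations = n_perm, by = "terms")
    row <- "group"
  } else {
    dat$covariate <- factor(covariate)
    tab <- vegan::adonis2(stats::as.dist(Dm) ~ covariate + group, data = dat,
                          permutations = n_perm, by = "terms")
    row <- "group"
  }
  res <- list(F = tab[row, "F"], R2 = tab[row, "R2"],
              p = tab[row, "Pr(>F)"], table = tab)
  if (pairwise) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      sel <- groups %in% prs[, k]
      t2 <- vegan::adonis2(stats::as.dist(Dm[sel, sel]) ~ g,
                           data = data.frame(g = droplevels(groups[sel])),
                           permutations = n_perm)
      data.frame(group1 = prs[1, k], group2 = prs[2, k],
                 F = t2[1, "F"], R2 = t2[1, "R2"], p = t2[1, "Pr(>F)"],
                 stringsAsFactors = FALSE)
    }))
    pw$q <- stats::p.adjust(pw$p, "BH")
    res$pairwise <- pw
  }
  res
}

#' Jackknifed canonical variate analysis
#'
#' Linear discriminant classification with leave-one-out cross-validation.
#' High-dimensional inputs are first reduced by PCA to the axes explaining
#' `var_retain` of the variance (capped so the pooled within-group
#' covariance stays nonsingular).
#'
#' @param X Individuals x features matrix.
#' @param groups Grouping vector.
#' @param var_retain Variance fraction retained by the PCA reduction step.
#' @return List: `accuracy` (percent correct), `kappa` (Cohen's kappa),
#'   `confusion` (matrix, rows = true), `n_axes_used`.
#' @export
cva_jackknife <- function(X, groups, var_retain = 0.95) {
  X <- as.matrix(X)
  groups <- factor(groups)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  k95 <- which(cumsum(eig) / sum(eig) >= var_retain)[1]
  kmax <- nrow(X) - nlevels(groups) - 1L
  k <- max(1L, min(k95, kmax, sum(eig > max(eig) * 1e-9)))
  Xr <- pc$x[, seq_len(k), drop = FALSE]
  fit <- MASS::lda(Xr, grouping = groups, CV = TRUE)
  conf <- table(true = groups, predicted = fit$class)
  list(accuracy = 100 * sum(diag(conf)) / sum(conf),
       kappa = cohens_kappa(conf), confusion = conf, n_axes_used = k)
}

#' Cohen's kappa of a confusion matrix
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and chance
#' agreement `pe` from the row/column marginals.
#' @param conf Square confusion matrix (rows = true, columns = predicted).
#' @return Kappa value.
#' @export
cohens_kappa <- function(conf) {
  conf <- as.matrix(conf)
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  (po - pe) / (1 - pe)
}

#' Fit the genomic-dose gradient into an ordination plane
#'
#' Least-squares fit of the per-individual E-genome fraction on the
#' selected axis scores. The fitted direction is the normalized
#' coefficient vector (pointing toward increasing E fraction), R-squared
#' is the squared multiple correlation, and significance comes from
#' permuting the E-fraction values
#' (`p = (1 + #\{R2* >= R2\}) / (1 + n_perm)`).
#'
#' @param ord An `ordination` object (or a bare score matrix).
#' @param e_fractions Per-individual E-genome fraction.
#' @param axes Indices of the (significant) axes to use.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return Object of class `gradient_fit`: `direction`, `r2`, `p_perm`,
#'   `scores` (the axis subspace), `axes`, `e_fractions`.
#' @export
fit_genome_gradient <- function(ord, e_fractions, axes = c(1, 2),
                                n_perm = 9999, seed = NULL) {
  S <- if (inherits(ord, "ordination")) ord$scores else as.matrix(ord)
  if (max(axes) > ncol(S)) stop("requested axis beyond available scores")
  S <- S[, axes, drop = FALSE]
  ef <- as.numeric(e_fractions)
  if (length(ef) != nrow(S)) stop("e_fractions length must match scores")
  if (stats::sd(ef) == 0) stop("constant e_fraction: gradient undefined")
  if (!is.null(seed)) set.seed(seed)
  Sc <- scale(S, center = TRUE, scale = FALSE)
  qrS <- qr(Sc)
  Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
  r2_of <- function(v) {
    vc <- v - mean(v)
    sum(crossprod(Q, vc)^2) / sum(vc^2)
  }
  r2 <- r2_of(ef)
  beta <- qr.coef(qrS, ef - mean(ef))
  beta[is.na(beta)] <- 0
  dir <- beta / sqrt(sum(beta^2))
  hits <- 0L
  for (b in seq_len(n_perm)) if (r2_of(sample(ef)) >= r2) hits <- hits + 1L
  structure(list(direction = dir, r2 = r2,
                 p_perm = (1 + hits) / (1 + n_perm),
                 scores = S, axes = axes, e_fractions = ef),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient fit on axes %s: R2 = %.3f, p = %.4g>\n",
              paste(x$axes, collapse = ","), x$r2, x$p_perm))
  invisible(x)
}

#' Rotate an ordination biplot onto the dose gradient
#'
#' Rotates the fitted 2-D axis pair by `-atan2(dy, dx)` so the first
#' rotated axis aligns with the gradient direction (an isometry), and runs
#' a one-way permutational ANOVA of the grouping on the first rotated
#' axis.
#'
#' @param fit A 2-D [fit_genome_gradient()] result.
#' @param groups Grouping vector (biotypes) for the permutational ANOVA.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return List: `angle` (radians), `rotated_scores`, `anova`
#'   (`F`, `p`, group means on rotated axis 1).
#' @export
rotate_to_gradient <- function(fit, groups = NULL, n_perm = 999,
                               seed = NULL) {
  stopifnot(inherits(fit, "gradient_fit"))
  if (ncol(fit$scores) != 2) stop("rotation needs a 2-D axis pair")
  ang <- atan2(fit$direction[2], fit$direction[1])
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  rot <- fit$scores %*% R
  colnames(rot) <- c("rot1", "rot2")
  out <- list(angle = ang, rotated_scores = rot)
  if (!is.null(groups)) {
    out$anova <- perm_anova(rot[, 1], groups, n_perm = n_perm, seed = seed)
  }
  out
}

#' One-way permutational ANOVA
#'
#' Classical F statistic of a grouping on a single response, with
#' significance from label permutations.
#'
#' @param y Numeric response.
#' @param groups Grouping vector.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return List: `F`, `p`, `group_means`.
#' @export
perm_anova <- function(y, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  if (!is.null(seed)) set.seed(seed)
  f_of <- function(yy) {
    m <- tapply(yy, groups, mean)
    nW <- tapply(yy, groups, length)
    ssb <- sum(nW * (m - mean(yy))^2)
    ssw <- sum((yy - m[groups])^2)
    dfb <- nlevels(groups) - 1
    dfw <- length(yy) - nlevels(groups)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- f_of(y)
  hits <- 0L
  for (b in seq_len(n_perm)) if (f_of(sample(y)) >= f_obs) hits <- hits + 1L
  list(F = f_obs, p = (1 + hits) / (1 + n_perm),
       group_means = tapply(y, groups, mean))
}
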