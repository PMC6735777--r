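test_that("Procrustes alignment removes similarity transforms", {
  set.seed(81)
  sh <- matrix(stats::rnorm(42), 21, 2)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sh2 <- 2.5 * sh %*% R + 7
  expect_lt(procrustes_distance(sh, sh2), 1e-10)

  # consensus of two shapes is their Procrustes midpoint
  a <- matrix(stats::rnorm(42), 21, 2)
  b <- matrix(stats::rnorm(42), 21, 2)
  g <- generalized_procrustes(list(a, b))
  d1 <- sqrt(sum((g$aligned[, , 1] - g$consensus)^2))
  d2 <- sqrt(sum((g$aligned[, , 2] - g$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-6)

  # input order leaves interindividual distances unchanged
  shapes <- lapply(1:5, function(i) matrix(stats::rnorm(42), 21, 2))
  g1 <- generalized_procrustes(shapes)
  g2 <- generalized_procrustes(shapes[c(3, 1, 5, 2, 4)])
  dmat <- function(g, ord) {
    flat <- t(apply(g$aligned, 3, identity))
    as.matrix(stats::dist(flat))[ord, ord]
  }
  expect_equal(unname(dmat(g1, 1:5)),
               unname(dmat(g2, order(c(3, 1, 5, 2, 4)))), tolerance = 1e-6)

  degen <- matrix(rep(c(1, 2), each = 21), 21, 2)
  degen[, 2] <- degen[, 1]  # collinear
  expect_error(generalized_procrustes(list(degen, a)), "degenerate")
})

test_that("PCA finds the dominant direction and PCoA matches it on Euclidean input", {
  set.seed(82)
  t <- stats::rnorm(40)
  X <- cbind(t, t) + matrix(stats::rnorm(80, 0, 0.01), 40, 2)
  ord <- pca_ordination(X)
  expect_gt(ord$proportion_explained[1], 0.99)
  expect_gt(abs(stats::cor(ord$scores[, 1], X %*% c(1, 1))), 0.999)

  Y <- matrix(stats::rnorm(60), 12, 5)
  pa <- pca_ordination(Y)
  pb <- pcoa_ordination(stats::dist(Y))
  expect_equal(pb$eigenvalues[1:5], pa$eigenvalues * (12 - 1),
               tolerance = 1e-8)
  for (k in 1:3)
    expect_equal(abs(pb$scores[, k]), abs(pa$scores[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)

  expect_error(pca_ordination(matrix(c(1, NaN, 2, 3), 2, 2)), "finite")
  # all-identical rows: degenerate decomposition is refused
  Z <- matrix(1, 6, 4)
  expect_error(pcoa_ordination(vegan::vegdist(Z, "bray")), "degenerate")
})

test_that("broken-stick counts match the closed-form thresholds", {
  # p = 2: b = (0.75, 0.25)
  expect_equal(broken_stick(c(0.8, 0.2)), 1L)
  expect_equal(broken_stick(c(0.75, 0.25)), 0L)  # equality is not enough
  # p = 3: b = (0.611, 0.278, 0.111); first axis below threshold
  expect_equal(broken_stick(c(0.5, 0.3, 0.2)), 0L)
  # b_2 = 0.278 exceeds an observed 0.25: only the first axis stands
  expect_equal(broken_stick(c(0.7, 0.25, 0.05)), 1L)
  expect_equal(broken_stick(c(0.65, 0.3, 0.05)), 2L)
  expect_error(broken_stick(numeric(0)), "empty")
  # independent implementation of the null proportions
  p <- 7
  expect_equal(rev(cumsum(1 / rev(seq_len(p)))) / p,
               as.numeric(vegan::bstick(p, tot.var = 1)))
})

test_that("PERMANOVA separates groups and respects distance symmetry", {
  set.seed(83)
  X <- rbind(matrix(stats::rnorm(60, 0), 10, 6),
             matrix(stats::rnorm(60, 3), 10, 6))
  g <- rep(c("a", "b"), each = 10)
  pv <- permanova(stats::dist(X), g, n_perm = 199, seed = 1)
  expect_equal(pv$p, 1 / 200)
  expect_gt(pv$R2, 0.3)
  expect_equal(pv$pairwise$p[1], pv$p)

  # jointly permuting rows+columns of D leaves F unchanged
  D <- as.matrix(stats::dist(X))
  idx <- sample(20)
  pv2 <- permanova(D[idx, idx], g[idx], n_perm = 99, seed = 1)
  expect_equal(pv2$F, pv$F)

  # a sequential covariate absorbs its share before the grouping
  site <- rep(c("s1", "s2"), 10)
  pv3 <- permanova(stats::dist(X), g, covariate = site, n_perm = 99, seed = 1)
  expect_gt(pv3$R2, 0.3)

  expect_warning(permanova(stats::dist(X), c(rep("a", 10), rep("b", 9), "c"),
                           n_perm = 99), "single member")
})

test_that("jackknifed CVA yields sane accuracy and kappa", {
  set.seed(84)
  X <- rbind(matrix(stats::rnorm(100, 0), 20, 5),
             matrix(stats::rnorm(100, 4), 20, 5))
  g <- rep(c("a", "b"), each = 20)
  cv <- cva_jackknife(X, g)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$kappa, 1)

  # closed-form kappa of a hand confusion matrix
  expect_equal(cohens_kappa(matrix(c(8, 3, 2, 7), 2, 2)), 0.5)
  expect_equal(100 * (8 + 7) / 20, 75)

  # shuffled labels: kappa near zero
  set.seed(85)
  cv0 <- cva_jackknife(X, sample(g))
  expect_lt(abs(cv0$kappa), 0.35)
})

test_that("the genome-dose gradient is fitted, tested and rotated correctly", {
  set.seed(86)
  ef <- e_genome_fraction(rep(c("EE", "TT", "ET", "EET", "ETT"), each = 8))
  # scores an exact linear function of the dose: R2 = 1
  S <- cbind(2 * ef + 1, -ef + 0.3)
  fit <- fit_genome_gradient(S, ef, n_perm = 199, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$p_perm, 1 / 200)

  # direction points toward increasing E fraction
  proj <- fit$scores %*% fit$direction
  expect_gt(stats::cor(proj, ef), 0.99)

  # gradient along axis 1 only: no rotation, scores unchanged
  S2 <- cbind(ef, stats::rnorm(40, 0, 1e-8))
  fit2 <- fit_genome_gradient(S2, ef, n_perm = 99, seed = 1)
  rot2 <- rotate_to_gradient(fit2)
  expect_lt(abs(rot2$angle), 1e-3)
  expect_equal(rot2$rotated_scores[, 1], S2[, 1], tolerance = 1e-4,
               ignore_attr = TRUE)

  # rotation is an isometry
  S3 <- matrix(stats::rnorm(80), 40, 2)
  fit3 <- fit_genome_gradient(S3, ef, n_perm = 99, seed = 1)
  rot3 <- rotate_to_gradient(fit3, groups = rep(c("EE", "TT", "ET", "EET",
                                                  "ETT"), each = 8),
                             n_perm = 99, seed = 1)
  expect_equal(stats::dist(rot3$rotated_scores), stats::dist(S3),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(fit_genome_gradient(S, rep(0.5, 40)), "constant")

  # recovery: biotype means on the rotated first axis are monotone in dose
  tm <- simulate_trait_matrix(reps = c(EE = 12, TT = 12, ET = 12, EET = 12,
                                       ETT = 12),
                              gradient_effect = 5, n_features = 8,
                              noise_sd = 0.8, seed = 87)
  ord <- pca_ordination(tm$X)
  fit4 <- fit_genome_gradient(ord, tm$meta$e_fraction, n_perm = 199, seed = 2)
  rot4 <- rotate_to_gradient(fit4, groups = tm$meta$biotype, n_perm = 199,
                             seed = 2)
  m <- rot4$anova$group_means
  ord_ef <- order(e_genome_fraction(names(m)))
  expect_true(all(diff(m[ord_ef]) > 0) || all(diff(m[ord_ef]) < 0))
  expect_lt(rot4$anova$p, 0.05)
})
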