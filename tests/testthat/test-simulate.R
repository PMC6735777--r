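test_that("simulation is reproducible and validates its configuration", {
  cfg <- sim_config(n_genes = 50, reps = c(EE = 2, TT = 2, ET = 2),
                    tissues = "liver", seed = 3)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$alleles$counts_E, b$alleles$counts_E)
  expect_identical(a$truth, b$truth)

  expect_error(sim_config(mixture = c(conserved = 0.5, cis_only = 0.4)),
               "sum to 1")
  expect_error(sim_config(dispersion = 0), "positive")
  expect_error(sim_config(kappa = 2), "kappa")
})

test_that("architecture constraints hold in the simulated truth", {
  cfg <- sim_config(n_genes = 500, reps = c(EE = 2, TT = 2), tissues = "liver",
                    mixture = c(conserved = 0.2, cis_only = 0.2,
                                trans_only = 0.2, enhancing = 0.2,
                                compensating = 0.2), seed = 4)
  tr <- simulate_dataset(cfg)$truth
  expect_true(all(tr$trans[tr$architecture == "cis_only"] == 0))
  expect_true(all(tr$cis[tr$architecture == "cis_only"] != 0))
  expect_true(all(tr$cis[tr$architecture == "trans_only"] == 0))
  expect_true(all(tr$cis[tr$architecture == "conserved"] == 0 &
                  tr$trans[tr$architecture == "conserved"] == 0))
  with_et <- tr$architecture %in% c("enhancing", "compensating")
  expect_true(all((tr$cis * tr$trans)[tr$architecture == "enhancing"] > 0))
  expect_true(all((tr$cis * tr$trans)[tr$architecture == "compensating"] < 0))
})

test_that("simulated counts match the NB moments of the model", {
  # one gene, many replicate samples of the same biotype
  cfg <- sim_config(n_genes = 3, reps = c(EE = 5000), tissues = "liver",
                    mixture = c(conserved = 1), beta_mean = log2(50),
                    beta_sd = 0, dispersion = 0.2, libsize_sd = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  y <- sim$counts$counts[1, ]
  mu <- 2 * 50  # two copies at per-copy mean 50
  expect_lt(abs(mean(y) - mu) / mu, 0.05)
  expect_lt(abs(stats::var(y) / (mu + 0.2 * mu^2) - 1), 0.15)
})

test_that("trans cross-talk reproduces the cis/trans allelic expectations", {
  # kappa = 1, cis-only: dose-adjusted hybrid ratio = 2^c = parental ratio
  em <- expected_allele_means(5, cis = 1.2, trans = 0, biotype = "ET",
                              kappa = 1)
  expect_equal(unname(em["E"] / em["T"]), 2^1.2)
  # kappa = 1, trans-only: hybrid alleles balanced despite parental 2^t
  em2 <- expected_allele_means(5, cis = 0, trans = 1.7, biotype = "ET",
                               kappa = 1)
  expect_equal(unname(em2["E"] / em2["T"]), 1)
  pe <- expected_allele_means(5, 0, 1.7, "EE", kappa = 1)
  pt <- expected_allele_means(5, 0, 1.7, "TT", kappa = 1)
  expect_equal(unname(pe["E"] / pt["T"]), 2^1.7)
  # kappa = 0, trans-only: autonomous regulation mimics cis
  em3 <- expected_allele_means(5, cis = 0, trans = 1.7, biotype = "ET",
                               kappa = 0)
  expect_equal(unname(em3["E"] / em3["T"]), 2^1.7)

  # Monte-Carlo mean of the simulated dose-adjusted ratio matches 2^t
  # within 3 SE under kappa = 0
  cfg <- sim_config(n_genes = 2, reps = c(ET = 10000), tissues = "liver",
                    mixture = c(trans_only = 1),
                    t_dist = list(dist = "lognormal", meanlog = log(1.5),
                                  sdlog = 1e-6),
                    beta_mean = log2(200), beta_sd = 0, dispersion = 0.05,
                    libsize_sd = 0, kappa = 0, snp_observable_fraction = 1,
                    seed = 11)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth[1, ]
  rE <- mean(sim$alleles$counts_E[1, ])
  rT <- mean(sim$alleles$counts_T[1, ])
  target <- 2^tr$trans
  se <- stats::sd(sim$alleles$counts_E[1, ] / pmax(sim$alleles$counts_T[1, ], 1)) /
    sqrt(10000)
  expect_lt(abs(rE / rT - target), 3 * se + 0.02 * target)
})

test_that("in-silico hybrids are multinomial thinnings at the dose ratio", {
  set.seed(5)
  pe <- stats::rpois(50, 100); pt <- stats::rpois(50, 100)
  names(pe) <- names(pt) <- paste0("g", 1:50)
  h <- make_insilico_hybrid(pe, pt, dose = c(1, 1), depth = 100)
  expect_equal(sum(h$counts_E), 50)  # exact thinning targets
  expect_equal(sum(h$counts_T), 50)
  h2 <- make_insilico_hybrid(pe, pt, dose = c(2, 1), depth = 300)
  expect_equal(sum(h2$counts_E), 200)
  expect_equal(sum(h2$counts_T), 100)

  # a gene empty in both parents stays empty
  pe[1] <- 0L; pt[1] <- 0L
  h3 <- make_insilico_hybrid(pe, pt, dose = c(1, 1), depth = 100)
  expect_equal(unname(h3$counts_E[1] + h3$counts_T[1]), 0)

  expect_error(make_insilico_hybrid(pe, pt, dose = c(3, 1)), "dose")
  expect_error(make_insilico_hybrid(pe, pt, depth = 10 * sum(pe)),
               "oversample")
  expect_silent(make_insilico_hybrid(pe, pt, depth = 3 * sum(pe),
                                     oversample = TRUE))

  # E-layer expectation is half the total under a 1:1 dose
  hs <- replicate(200, sum(make_insilico_hybrid(pe, pt, dose = c(1, 1),
                                                depth = 100)$counts_E))
  expect_equal(mean(hs), 50, tolerance = 0.02)
})

test_that("trait matrices order individuals along the dose gradient", {
  tm <- simulate_trait_matrix(reps = c(EE = 10, TT = 10, ET = 10),
                              gradient_effect = 5, n_features = 6,
                              noise_sd = 0.5, seed = 2)
  expect_equal(dim(tm$X), c(30L, 6L))
  proj <- tm$X %*% rep(1 / sqrt(6), 6)
  m <- tapply(proj, tm$meta$biotype, mean)
  expect_true(all(diff(m[order(e_genome_fraction(names(m)))]) > 0))
  expect_error(simulate_trait_matrix(n_features = 1), "n_features")
  expect_error(simulate_trait_matrix(reps = c(EE = 5)), "two biotypes")
})
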