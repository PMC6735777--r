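ase_fixture <- function(E_hyb, T_hyb, E_par = c(200L, 210L),
                        T_par = c(190L, 205L), hybrid = "ET") {
  nh <- length(E_hyb)
  meta <- tiny_meta(c("EE", "EE", "TT", "TT", rep(hybrid, nh)))
  gene <- "g1"
  mkrow <- function(v) matrix(as.integer(v), 1,
                              dimnames = list(gene, meta$sample_id))
  cE <- mkrow(c(E_par, 0, 0, E_hyb))
  cT <- mkrow(c(0, 0, T_par, T_hyb))
  allele_counts(cE, cT, meta)
}

test_that("coverage filter requires strict >30 in two hybrid individuals", {
  a <- ase_fixture(E_hyb = c(16L, 16L), T_hyb = c(15L, 15L))  # 31, 31
  expect_equal(nrow(ase_filter(a)$counts_E), 1L)
  b <- ase_fixture(E_hyb = c(15L, 60L), T_hyb = c(15L, 40L))  # 30, 100
  expect_equal(nrow(ase_filter(b)$counts_E), 0L)
  empty <- ase_filter(a[integer(0), ])
  expect_equal(nrow(empty$counts_E), 0L)
})

test_that("dose adjustment: per-copy-equal EET gene has raw ratio 2, adjusted 1", {
  # equal sequencing depth everywhere; EET hybrid with E at two copies
  a <- ase_fixture(E_hyb = c(200L, 200L), T_hyb = c(100L, 100L),
                   E_par = c(300L, 300L), T_par = c(300L, 300L),
                   hybrid = "EET")
  tb <- ase_table(a, "EET")
  expect_equal(tb$E_hyb / tb$T_hyb, 2)
  expect_equal(tb$adj_ratio_hyb, 1)
  expect_equal(tb$rae_percent, 100 * 2 / 3)
  expect_equal(tb$ratio_par, 1)
})

test_that("silencing is called only on exactly zero hybrid reads", {
  a <- ase_fixture(E_hyb = c(120L, 80L), T_hyb = c(0L, 0L))
  tb <- ase_table(a, "ET")
  expect_equal(as.character(detect_silencing(tb)), "T_silenced")
  b <- ase_fixture(E_hyb = c(1L, 0L), T_hyb = c(250L, 250L))
  expect_equal(as.character(detect_silencing(ase_table(b, "ET"))),
               "both_expressed")
})

test_that("silencing is rare when the generator includes no silencing", {
  cfg <- sim_config(n_genes = 800, reps = c(EE = 4, TT = 4, ET = 3),
                    tissues = "liver", seed = 51, snp_observable_fraction = 1)
  sim <- simulate_dataset(cfg)
  tb <- ase_table(ase_filter(sim$alleles), "ET")
  expect_gt(mean(detect_silencing(tb) == "both_expressed"), 0.99)
})

test_that("the compensating/enhancing direction rule follows the ratio inequalities", {
  tb <- data.frame(adj_ratio_hyb = c(8, 8, 1 / 8, 1 / 8),
                   ratio_par = c(4, 16, 1 / 4, 1 / 16),
                   E_hyb_n = c(8000L, 8000L, 1000L, 1000L),
                   T_hyb_n = c(1000L, 1000L, 8000L, 8000L),
                   E_par_n = c(4000L, 16000L, 1000L, 1000L),
                   T_par_n = c(1000L, 1000L, 4000L, 16000L),
                   E_par_eff = c(4000L, 16000L, 1000L, 1000L),
                   T_par_eff = c(1000L, 1000L, 4000L, 16000L),
                   nE = 1L, nT = 1L)
  ct <- classify_cis_trans(tb, alpha_q = 0.05)
  # hybrid ratio 8 with parental 4 below it: compensating; parental 16
  # above it: enhancing; mirrored below 1
  expect_equal(as.character(ct$category),
               c("Compensating", "Enhancing", "Compensating", "Enhancing"))
})

test_that("regulatory classes are recovered from simulated architectures", {
  cfg <- sim_config(n_genes = 1500, reps = c(EE = 4, TT = 4, ET = 2),
                    tissues = "liver", kappa = 1, seed = 52,
                    snp_observable_fraction = 1)
  sim <- simulate_dataset(cfg)
  tb <- ase_table(ase_filter(sim$alleles), "ET")
  ct <- classify_cis_trans(tb)
  tr <- sim$truth[match(ct$gene_id, sim$truth$gene_id), ]
  informative <- !ct$category %in% c("NoCisNoTrans", "NotAvailable")
  # among genes the tests could decide, cis- and trans-only architectures
  # are recovered nearly always
  expect_gt(mean(ct$category[tr$architecture == "cis_only" & informative] ==
                 "Cis"), 0.9)
  expect_gt(mean(ct$category[tr$architecture == "trans_only" & informative] ==
                 "Trans"), 0.9)
  # conserved genes essentially never drift into Cis/Trans
  expect_lt(mean(ct$category[tr$architecture == "conserved"] %in%
                 c("Cis", "Trans")), 0.05)

  # label-swap symmetry: swapping the roles of E and T everywhere keeps
  # Cis as Cis and Trans as Trans
  sw <- sim$alleles
  sw2 <- allele_counts(sw$counts_T, sw$counts_E, within_swap(sw$samples))
  tb2 <- ase_table(ase_filter(sw2), "ET")
  ct2 <- classify_cis_trans(tb2)
  m <- match(ct$gene_id, ct2$gene_id)
  agree <- table(ct$category, ct2$category[m])
  expect_gt(agree["Cis", "Cis"] / sum(agree["Cis", ]), 0.9)
  expect_gt(agree["Trans", "Trans"] / sum(agree["Trans", ]), 0.9)
})

test_that("hybrid-on-parent regression tracks the regulatory mode", {
  cfg <- sim_config(n_genes = 1200, reps = c(EE = 4, TT = 4, ET = 2),
                    tissues = "liver", kappa = 1,
                    mixture = c(cis_only = 0.5, trans_only = 0.5), seed = 53,
                    snp_observable_fraction = 1)
  sim <- simulate_dataset(cfg)
  tb <- ase_table(ase_filter(sim$alleles), "ET")
  tr <- sim$truth[match(tb$gene_id, sim$truth$gene_id), ]
  cis <- regress_hybrid_on_parent(tb[tr$architecture == "cis_only", ])
  expect_lt(abs(cis$slope_corrected - 1), 3 * cis$se)
  expect_gt(cis$r2, 0.7)
  trn <- regress_hybrid_on_parent(tb[tr$architecture == "trans_only", ])
  expect_lt(abs(trn$slope), 0.15)
  expect_error(regress_hybrid_on_parent(tb[1:5, ]), ">= 10 genes")
})

test_that("the slope-by-inheritance interaction test detects slope splits", {
  set.seed(54)
  n <- 200
  mk <- function(slope, cat) {
    x <- stats::rnorm(n, 0, 1)
    ey <- 400 * exp(slope * x)  # hybrid ratio responds with the given slope
    data.frame(gene_id = sprintf("%s_%d", cat, 1:n),
               E_hyb_n = as.integer(stats::rpois(n, ey)),
               T_hyb_n = 400L, nE = 1L, nT = 1L,
               ratio_par = exp(x))
  }
  tbl <- rbind(mk(1.0, "up"), mk(0.3, "dn"))
  calls <- data.frame(gene_id = tbl$gene_id,
                      group = rep(c("dominance_up", "dominance_down"),
                                  each = n))
  res <- regress_with_inheritance_interaction(tbl, calls)
  expect_lt(res$p_lrt, 0.01)
  expect_lt(abs(res$slopes[["dominance_up"]] - 1), 0.1)
  expect_lt(abs(res$slopes[["dominance_down"]] - 0.3), 0.1)

  # a single usable category is an error, the small one warns
  calls2 <- calls; calls2$group[calls2$group == "dominance_down"][-(1:3)] <-
    "dominance_up"
  expect_warning(expect_error(
    regress_with_inheritance_interaction(tbl, calls2), ">= 2"), "< 5 genes")
})

test_that("parental divergence is larger in cis-regulated genes when simulated so", {
  set.seed(55)
  mk <- function(cat, shift, n = 80) {
    data.frame(gene_id = sprintf("%s%d", cat, 1:n),
               log2fc_par = stats::rnorm(n, 0, 0.7) +
                 shift * sample(c(-1, 1), n, TRUE),
               category = factor(cat, levels = c("Cis", "Trans", "Enhancing",
                                                 "Compensating",
                                                 "NoCisNoTrans",
                                                 "NotAvailable")))
  }
  tbl <- rbind(mk("Cis", 2), mk("Trans", 0), mk("Compensating", 0))
  res <- divergence_by_category(tbl)
  cis_rows <- res$cat1 == "Cis" | res$cat2 == "Cis"
  expect_true(all(res$p[cis_rows] < 0.001))
  # null pair stays non-significant most of the time; here just check it
  # is the largest p
  expect_equal(which.max(res$p), which(!cis_rows))
  expect_error(divergence_by_category(tbl[tbl$category == "Cis", ]),
               ">= 2 categories")
})
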