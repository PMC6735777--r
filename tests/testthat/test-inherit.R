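# direct decision-table cases: q-values and normalized means chosen by hand
call_one <- function(q_par, q_he, q_ht, mE, mT, mH) {
  classify_inheritance("g", q_par, q_he, q_ht, mE, mT, mH)
}

test_that("the decision table assigns the canonical patterns", {
  # parents differ, hybrid differs from both and sits between: additive I
  c1 <- call_one(0.001, 0.01, 0.01, mE = 10, mT = 40, mH = 22)
  expect_equal(as.character(c1$category), "I")
  expect_equal(as.character(c1$group), "additive")
  # mirrored parental direction: XII
  c2 <- call_one(0.001, 0.01, 0.01, mE = 40, mT = 10, mH = 22)
  expect_equal(as.character(c2$category), "XII")

  # dominance toward T (hybrid = T, != E), T higher: up dominance (II),
  # intermediate fold change marks it additive-like
  c3 <- call_one(0.001, 0.01, 0.8, mE = 10, mT = 40, mH = 30)
  expect_equal(as.character(c3$category), "II")
  expect_equal(as.character(c3$group), "dominance_up")
  expect_equal(as.character(c3$dominant_parent), "T")
  expect_true(c3$additive_like)
  # same pattern with the hybrid at the matched parent: not additive-like
  c4 <- call_one(0.001, 0.01, 0.8, mE = 10, mT = 40, mH = 41)
  expect_equal(as.character(c4$category), "II")
  expect_false(c4$additive_like)
  # dominance toward the lower parent: down dominance
  c5 <- call_one(0.001, 0.8, 0.01, mE = 10, mT = 40, mH = 11)
  expect_equal(as.character(c5$category), "IX")
  expect_equal(as.character(c5$dominant_parent), "E")

  # transgressive above both parents, parents not different
  c6 <- call_one(0.9, 0.01, 0.01, mE = 20, mT = 21, mH = 60)
  expect_equal(as.character(c6$category), "VI")
  expect_equal(as.character(c6$group), "transgressive_up")
  # below both with parents different
  c7 <- call_one(0.01, 0.01, 0.01, mE = 20, mT = 40, mH = 2)
  expect_equal(as.character(c7$category), "III")

  # no significant comparison: NoChange
  c8 <- call_one(0.5, 0.5, 0.5, 10, 12, 11)
  expect_equal(as.character(c8$category), "NoChange")
  # a single significant comparison: Ambiguous
  c9 <- call_one(0.5, 0.01, 0.5, 10, 12, 11)
  expect_equal(as.character(c9$category), "Ambiguous")

  expect_error(call_one(NA, 0.5, 0.5, 1, 2, 3), "missing")
})

test_that("swapping parental labels maps the categories symmetrically", {
  set.seed(41)
  n <- 400
  qp <- stats::runif(n); qe <- stats::runif(n); qt <- stats::runif(n)
  mE <- stats::rlnorm(n, 3); mT <- stats::rlnorm(n, 3); mH <- stats::rlnorm(n, 3)
  a <- classify_inheritance(paste0("g", 1:n), qp, qe, qt, mE, mT, mH)
  b <- classify_inheritance(paste0("g", 1:n), qp, qt, qe, mT, mE, mH)
  swap <- c(I = "XII", XII = "I", II = "IV", IV = "II", IX = "XI", XI = "IX",
            III = "X", X = "III", V = "VIII", VIII = "V", VI = "VI",
            VII = "VII", NoChange = "NoChange", Ambiguous = "Ambiguous")
  expect_identical(unname(swap[as.character(a$category)]),
                   as.character(b$category))
  expect_identical(as.character(a$group), as.character(b$group))
  # every gene receives exactly one category
  expect_equal(sum(table(a$category)), n)
})

test_that("transition matrices tabulate category co-assignment", {
  calls <- classify_inheritance(paste0("g", 1:3),
                                c(0.001, 0.001, 0.9),
                                c(0.01, 0.01, 0.01),
                                c(0.01, 0.8, 0.01),
                                c(10, 10, 20), c(40, 40, 21),
                                c(22, 30, 60))
  tm <- transition_matrix(calls, calls)
  expect_equal(sum(diag(tm)), 3)
  expect_equal(sum(tm), 3)

  calls_b <- calls
  calls_b$category[2] <- "IX"
  tm2 <- transition_matrix(calls, calls_b)
  expect_equal(tm2["II", "IX"], 1L)
  expect_equal(sum(diag(tm2)), 2)

  calls_c <- calls; calls_c$gene_id <- paste0("x", 1:3)
  expect_error(transition_matrix(calls, calls_c), "share no genes")
})

test_that("the matrix permutation test tracks true association", {
  set.seed(42)
  M1 <- matrix(stats::rpois(144, 8), 12, 12)
  mt <- mantel_test(M1, M1, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200)
  # affine transforms leave r untouched
  mt2 <- mantel_test(M1, 2 * M1 + 7, n_perm = 199, seed = 1)
  expect_equal(mt2$r, 1)

  expect_error(mantel_test(M1, matrix(1, 12, 12), n_perm = 99), "constant")
  expect_error(mantel_test(M1, M1[1:4, 1:4]), "identical shape")

  # independent-noise null: p approximately uniform over replicates
  set.seed(43)
  ps <- replicate(120, {
    M2 <- matrix(stats::rpois(144, 8), 12, 12)
    mantel_test(M1, M2, n_perm = 99)$p
  })
  fr <- mean(ps <= 0.05)
  expect_gt(fr, 0.05 - 3 * sqrt(0.05 * 0.95 / 120) - 0.001)
  expect_lt(fr, 0.05 + 3 * sqrt(0.05 * 0.95 / 120) + 0.001)
})

test_that("additivity depletion is detected against the in-silico null", {
  mk <- function(n_add, n_dom, n_domlike) {
    n <- n_add + n_dom
    cat <- c(rep("I", n_add), rep("II", n_dom))
    data.frame(gene_id = paste0("g", seq_len(n)), biotype = "ET",
               category = factor(cat, levels = levels(classify_inheritance(
                 "g", 0.5, 0.5, 0.5, 1, 2, 3)$category)),
               group = inheritance_group(cat),
               dominant_parent = "T",
               additive_like = c(rep(FALSE, n_add),
                                 rep(c(TRUE, FALSE),
                                     c(n_domlike, n_dom - n_domlike))),
               stringsAsFactors = FALSE)
  }
  same <- compare_additivity_to_null(mk(100, 200, 100), mk(100, 200, 100))
  expect_equal(same$ratio, 1)
  expect_gt(same$p, 0.99)

  # five-fold depleted additivity in the real set at n = 3000
  real <- mk(60, 2940, 1500); insilico <- mk(300, 2700, 2600)
  cmp <- compare_additivity_to_null(real, insilico)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$ratio, 4)
  # oracle: plain chi-square on the same 2x2 table
  oracle <- stats::chisq.test(rbind(c(60, 2940), c(300, 2700)),
                              correct = FALSE)$p.value
  expect_equal(cmp$p, oracle)
  expect_gt(cmp$additive_like_dominance[["insilico"]], 0.92)
})
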