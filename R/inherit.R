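#' Category numerals of the twelve expression-inheritance classes
#'
#' The classes group as: additive `{I, XII}`, dominance-up `{II, IV}`,
#' dominance-down `{IX, XI}`, transgressive-down `{III, VII, X}` and
#' transgressive-up `{V, VI, VIII}`. Within each group the numeral is
#' fixed by the parental direction: `E < T` takes the lower numeral of a
#' pair, `E > T` the higher; for the transgressive triples the middle
#' numeral (`VII`, `VI`) is used when the parents do not differ
#' significantly. This convention is localized here.
#' @return Named list mapping group x parental-direction to numeral.
#' @export
inheritance_numerals <- function() {
  list(additive           = c(lt = "I",   gt = "XII"),
       dominance_up       = c(lt = "II",  gt = "IV"),
       dominance_down     = c(lt = "IX",  gt = "XI"),
       transgressive_down = c(lt = "III", eq = "VII", gt = "X"),
       transgressive_up   = c(lt = "V",   eq = "VI",  gt = "VIII"))
}

.CATEGORY_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                      "IX", "X", "XI", "XII", "NoChange", "Ambiguous")

#' Group of an inheritance category
#' @param category Character vector of category numerals.
#' @return Factor of groups (`additive`, `dominance_up`, `dominance_down`,
#'   `transgressive_up`, `transgressive_down`, `none`).
#' @export
inheritance_group <- function(category) {
  num <- inheritance_numerals()
  map <- stats::setNames(rep(names(num), lengths(num)), unlist(num))
  g <- unname(map[as.character(category)])
  g[is.na(g)] <- "none"
  factor(g, levels = c(names(num), "none"))
}

#' Classify genes into expression-inheritance categories
#'
#' Decision table over the three pairwise tests (parents E vs T, hybrid vs
#' E, hybrid vs T) at BH-adjusted `q < alpha_q`, and the normalized group
#' means:
#' \itemize{
#'  \item no test significant: `NoChange`;
#'  \item hybrid significantly beyond both parental means (both hybrid
#'    tests significant): transgressive up/down;
#'  \item parents different, hybrid different from both and strictly
#'    between them: additive (`I`/`XII`);
#'  \item parents different, hybrid matching exactly one parent
#'    (non-significant) and differing from the other: expression-level
#'    dominance toward the matched parent, direction up if the matched
#'    parent is the higher-expressed one; `additive_like = TRUE` when the
#'    hybrid mean still lies strictly between the parental means;
#'  \item anything else (e.g. a single significant comparison): `Ambiguous`.
#' }
#'
#' @param gene_id Character vector.
#' @param q_par,q_he,q_ht Adjusted q-values of the parent-vs-parent,
#'   hybrid-vs-E and hybrid-vs-T tests (same length/order as `gene_id`).
#' @param mean_E,mean_T,mean_H Normalized group mean expression.
#' @param biotype Hybrid biotype label the calls refer to.
#' @param alpha_q Significance threshold on q.
#' @return data.frame of class calls: `gene_id`, `biotype`, `category`,
#'   `group`, `dominant_parent`, `additive_like`.
#' @export
classify_inheritance <- function(gene_id, q_par, q_he, q_ht,
                                 mean_E, mean_T, mean_H,
                                 biotype = "ET", alpha_q = 0.05) {
  n <- length(gene_id)
  stopifnot(length(q_par) == n, length(q_he) == n, length(q_ht) == n,
            length(mean_E) == n, length(mean_T) == n, length(mean_H) == n)
  if (anyNA(c(q_par, q_he, q_ht)))
    stop("missing test results; all three pairwise tests are required")
  num <- inheritance_numerals()
  sig_p <- q_par < alpha_q
  sig_e <- q_he < alpha_q
  sig_t <- q_ht < alpha_q
  dir3 <- ifelse(mean_E < mean_T, "lt", ifelse(mean_E > mean_T, "gt", "eq"))
  dir_sig <- ifelse(sig_p, dir3, "eq")  # parental direction when testable
  between <- (mean_H > pmin(mean_E, mean_T)) & (mean_H < pmax(mean_E, mean_T))
  above <- mean_H > pmax(mean_E, mean_T)
  below <- mean_H < pmin(mean_E, mean_T)

  category <- rep("Ambiguous", n)
  dominant <- rep("none", n)
  add_like <- rep(FALSE, n)

  none <- !sig_p & !sig_e & !sig_t
  category[none] <- "NoChange"

  trans_up <- sig_e & sig_t & above
  category[trans_up] <- num$transgressive_up[dir_sig[trans_up]]
  trans_dn <- sig_e & sig_t & below
  category[trans_dn] <- num$transgressive_down[dir_sig[trans_dn]]

  addv <- sig_p & sig_e & sig_t & between
  category[addv] <- num$additive[dir3[addv]]

  # dominance: parents differ, hybrid matches exactly one parent
  dom_e <- sig_p & !sig_e & sig_t & dir3 != "eq"  # hybrid matches E
  dom_t <- sig_p & sig_e & !sig_t & dir3 != "eq"  # hybrid matches T
  up_e <- dom_e & (mean_E > mean_T)   # matched parent higher-expressed
  dn_e <- dom_e & (mean_E < mean_T)
  up_t <- dom_t & (mean_T > mean_E)
  dn_t <- dom_t & (mean_T < mean_E)
  category[up_e] <- num$dominance_up[dir3[up_e]]
  category[dn_e] <- num$dominance_down[dir3[dn_e]]
  category[up_t] <- num$dominance_up[dir3[up_t]]
  category[dn_t] <- num$dominance_down[dir3[dn_t]]
  dominant[dom_e] <- "E"
  dominant[dom_t] <- "T"
  add_like[(dom_e | dom_t) & between] <- TRUE

  data.frame(gene_id = gene_id, biotype = biotype,
             category = factor(category, levels = .CATEGORY_LEVELS),
             group = inheritance_group(category),
             dominant_parent = factor(dominant, levels = c("E", "T", "none")),
             additive_like = add_like, stringsAsFactors = FALSE)
}

#' Inheritance calls for a hybrid biotype from a count table
#'
#' Convenience wrapper running the three pairwise NB contrasts
#' (EE vs TT, hybrid vs EE, hybrid vs TT) on a jointly normalized table
#' and feeding [classify_inheritance()].
#'
#' @param x A [gene_counts] containing EE, TT and the hybrid biotype's
#'   samples (already expression-filtered).
#' @param hybrid Hybrid biotype label.
#' @param alpha_q Significance threshold.
#' @param sf Optional size factors for the full table.
#' @return The call data.frame of [classify_inheritance()].
#' @export
inheritance_calls <- function(x, hybrid = "ET", alpha_q = 0.05, sf = NULL) {
  stopifnot(inherits(x, "gene_counts"))
  b <- x$samples$biotype
  if (!all(c("EE", "TT", hybrid) %in% b))
    stop("table must contain EE, TT and ", hybrid, " samples")
  if (is.null(sf)) sf <- size_factors(x)
  sub <- function(which) {
    j <- b %in% which
    x[, j]
  }
  run <- function(groups) {
    j <- b %in% unlist(groups)
    nb_contrast(x[, j], groups, sf = sf[j])
  }
  t_par <- run(list("EE", "TT"))
  t_he <- run(list("EE", hybrid))
  t_ht <- run(list("TT", hybrid))
  nm <- normalized_counts(x, sf)
  mE <- rowMeans(nm[, b == "EE", drop = FALSE])
  mT <- rowMeans(nm[, b == "TT", drop = FALSE])
  mH <- rowMeans(nm[, b == hybrid, drop = FALSE])
  classify_inheritance(rownames(x$counts), t_par$q, t_he$q, t_ht$q,
                       mE, mT, mH, biotype = hybrid, alpha_q = alpha_q)
}

#' Category transition matrix between two biotypes
#'
#' Entry (i, j) counts genes assigned to category i in the first call set
#' and j in the second, over the twelve numbered categories (genes that
#' are `NoChange`/`Ambiguous` in either set are not tabulated).
#'
#' @param calls_A,calls_B Call data.frames from [classify_inheritance()]
#'   over a shared gene universe.
#' @return 12 x 12 integer matrix.
#' @export
transition_matrix <- function(calls_A, calls_B) {
  shared <- intersect(calls_A$gene_id, calls_B$gene_id)
  if (!length(shared)) stop("call sets share no genes")
  a <- calls_A[match(shared, calls_A$gene_id), ]
  b <- calls_B[match(shared, calls_B$gene_id), ]
  lev <- .CATEGORY_LEVELS[1:12]
  tab <- table(factor(a$category, levels = lev),
               factor(b$category, levels = lev))
  m <- matrix(as.integer(tab), 12, 12, dimnames = dimnames(tab))
  m
}

#' Mantel-type permutation test for matrix association
#'
#' Pearson correlation of the off-diagonal entries of two same-shaped
#' square matrices; significance by jointly permuting the row and column
#' labels of the second matrix, with
#' `p = (1 + #\{r_perm >= r\}) / (n_perm + 1)`.
#'
#' @param M1,M2 Square numeric matrices of identical shape.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(M1, M2, n_perm = 9999, seed = NULL) {
  if (!is.matrix(M1) || !is.matrix(M2) || !identical(dim(M1), dim(M2)) ||
      nrow(M1) != ncol(M1))
    stop("M1 and M2 must be square matrices of identical shape")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(M1)
  offd <- !diag(k)
  v1 <- M1[offd]
  if (stats::sd(v1) == 0 || stats::sd(M2[offd]) == 0)
    stop("constant matrix: correlation undefined")
  r_obs <- stats::cor(v1, M2[offd])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(k)
    rp <- stats::cor(v1, M2[idx, idx][offd])
    if (!is.na(rp) && rp >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (n_perm + 1))
}

#' Compare the additive fraction between real and in-silico call sets
#'
#' 2x2 test (additive vs non-additive, real vs in-silico) over genes with
#' an assigned numbered category; chi-square with Fisher's exact fallback
#' when an expected cell drops below 5. Also reports the ratio of additive
#' proportions (in-silico over real) and, for each set, the additive-like
#' fraction among expression-level-dominance calls.
#'
#' @param real_calls,insilico_calls Call data.frames.
#' @return List: `p`, `test`, `prop_additive` (named pair), `ratio`,
#'   `additive_like_dominance` (named pair).
#' @export
compare_additivity_to_null <- function(real_calls, insilico_calls) {
  cls <- function(calls) {
    assigned <- calls$group != "none"
    addv <- calls$group == "additive"
    dom <- calls$group %in% c("dominance_up", "dominance_down")
    c(add = sum(addv), nonadd = sum(assigned & !addv),
      domlike = sum(dom & calls$additive_like), dom = sum(dom))
  }
  a <- cls(real_calls); b <- cls(insilico_calls)
  tab <- rbind(real = c(a["add"], a["nonadd"]),
               insilico = c(b["add"], b["nonadd"]))
  colnames(tab) <- c("additive", "non_additive")
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expct < 5)) {
    ht <- stats::fisher.test(tab); test <- "fisher"
  } else {
    ht <- stats::chisq.test(tab, correct = FALSE); test <- "chisq"
  }
  pa <- a["add"] / (a["add"] + a["nonadd"])
  pb <- b["add"] / (b["add"] + b["nonadd"])
  list(p = ht$p.value, test = test, table = tab,
       prop_additive = c(real = unname(pa), insilico = unname(pb)),
       ratio = unname(pb / pa),
       additive_like_dominance = c(real = unname(a["domlike"] / a["dom"]),
                                   insilico = unname(b["domlike"] / b["dom"])))
}
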