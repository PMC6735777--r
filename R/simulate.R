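#' Simulation configuration
#'
#' Parameters of the generative model for parental/hybrid allele-specific
#' counts. Each gene carries a baseline log2 per-copy expression `beta`, a
#' cis divergence `c` and a trans divergence `t` (both log2), a NB
#' dispersion, and a regulatory architecture. The defaults reflect the
#' study conditions: sample numbers per biotype and tissue as sequenced
#' (4 EE, 4 TT, 2 ET, 2 EET, 4 ETT females, liver and oocyte pools), an
#' architecture mixture of 50% conserved, 20% cis-only, 20% trans-only and
#' 10% compensating genes, gene dispersion 0.1, divergence magnitudes with
#' log2 SD 1.5, median allele-specific coverage around 100 reads per
#' sample, and full trans cross-talk (`kappa = 1`).
#'
#' @param n_genes Number of genes.
#' @param reps Named integer vector: samples per biotype (per tissue).
#' @param tissues Character vector of tissues to simulate. Gene-level
#'   parameters are shared across tissues; counts are drawn independently.
#' @param mixture Named proportions over architectures
#'   `conserved`, `cis_only`, `trans_only`, `enhancing`, `compensating`;
#'   must sum to 1.
#' @param beta_mean,beta_sd Normal distribution of the baseline log2
#'   per-copy expression.
#' @param c_dist,t_dist Magnitude distributions of the cis and trans
#'   divergences (log2) for genes whose architecture includes the
#'   component: either `list(dist = "lognormal", meanlog =, sdlog =)`
#'   (default: median magnitude 1.5) or `list(dist = "normal", sd =)`
#'   (magnitude `|N(0, sd)|`); signs are random subject to the
#'   architecture constraints.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   either a single value or a vector of length `n_genes`.
#' @param libsize_sd SD of the log-normal library size factors.
#' @param kappa Trans cross-talk in \[0,1\]: 1 = fully shared trans
#'   environment mixed in proportion to genomic dose, 0 = each genome
#'   regulated autonomously by its own trans factors.
#' @param snp_observable_fraction Fraction of genes carrying diagnostic
#'   SNPs, i.e. appearing in the allele-resolved table.
#' @param seed Integer master seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 15000,
                       reps = c(EE = 4, TT = 4, ET = 2, EET = 2, ETT = 4),
                       tissues = c("oocyte", "liver"),
                       mixture = c(conserved = 0.5, cis_only = 0.2,
                                   trans_only = 0.2, enhancing = 0,
                                   compensating = 0.1),
                       beta_mean = log2(50), beta_sd = 1.5,
                       c_dist = list(dist = "lognormal",
                                     meanlog = log(1.5), sdlog = 0.4),
                       t_dist = list(dist = "lognormal",
                                     meanlog = log(1.5), sdlog = 0.4),
                       dispersion = 0.1,
                       libsize_sd = 0.15,
                       kappa = 1,
                       snp_observable_fraction = 0.3,
                       seed = 1L) {
  archs <- c("conserved", "cis_only", "trans_only", "enhancing", "compensating")
  if (is.null(names(mixture)) || !all(names(mixture) %in% archs))
    stop("mixture must be named with architectures: ", paste(archs, collapse = ", "))
  mix <- stats::setNames(numeric(length(archs)), archs)
  mix[names(mixture)] <- mixture
  if (abs(sum(mix) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (any(mix < 0)) stop("mixture proportions must be non-negative")
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0,1]")
  if (snp_observable_fraction < 0 || snp_observable_fraction > 1)
    stop("snp_observable_fraction must lie in [0,1]")
  bad <- setdiff(names(reps), biotype_labels())
  if (length(bad)) stop("unknown biotype in reps: ", paste(bad, collapse = ", "))
  for (d in list(c_dist, t_dist))
    if (!is.list(d) || !d$dist %in% c("lognormal", "normal"))
      stop("divergence distributions must be lognormal or normal")
  structure(list(n_genes = as.integer(n_genes), reps = reps, tissues = tissues,
                 mixture = mix, beta_mean = beta_mean, beta_sd = beta_sd,
                 c_dist = c_dist, t_dist = t_dist, dispersion = dispersion,
                 libsize_sd = libsize_sd, kappa = kappa,
                 snp_observable_fraction = snp_observable_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Trans exposures of the two alleles for a biotype with copies (nE, nT).
# theta_mix = nE/(nE+nT) is the dose-weighted mixed trans environment;
# kappa interpolates between full cross-talk (kappa=1, both alleles see the
# mixture) and autonomy (kappa=0, each genome sees only its own factors:
# the E allele a full E trans environment, the T allele none of it).
.trans_exposure <- function(nE, nT, kappa) {
  theta_mix <- nE / (nE + nT)
  c(E = kappa * theta_mix + (1 - kappa), T = kappa * theta_mix)
}

#' Expected per-copy allele means of the generative model
#'
#' Deterministic part of the model, exposed so tests and power analyses
#' can compare Monte-Carlo output to closed-form expectations. The
#' per-copy mean of the E allele is `s * 2^(beta + c + theta_E * t)` and
#' of the T allele `s * 2^(beta + theta_T * t)`, with `theta` the trans
#' exposures for the biotype's genome doses under cross-talk `kappa`.
#'
#' @param beta,cis,trans Gene parameters (log2).
#' @param biotype Biotype label.
#' @param kappa Trans cross-talk in \[0,1\].
#' @param size_factor Library size factor `s`.
#' @return Named vector `c(E=, T=)` of per-copy means (0 for absent genomes).
#' @export
expected_allele_means <- function(beta, cis, trans, biotype, kappa = 1,
                                  size_factor = 1) {
  cp <- biotype_copies(biotype)
  th <- .trans_exposure(cp[["E"]], cp[["T"]], kappa)
  lamE <- if (cp[["E"]] > 0L) size_factor * 2^(beta + cis + th[["E"]] * trans) else 0
  lamT <- if (cp[["T"]] > 0L) size_factor * 2^(beta + th[["T"]] * trans) else 0
  c(E = lamE, T = lamT)
}

.draw_divergence <- function(arch, c_dist, t_dist) {
  # returns c(cis, trans) honouring the architecture sign constraints
  mag <- function(d) {
    x <- 0
    while (x == 0)
      x <- if (d$dist == "lognormal") stats::rlnorm(1, d$meanlog, d$sdlog)
           else abs(stats::rnorm(1, 0, d$sd))
    x
  }
  sgn <- function() sample(c(-1, 1), 1)
  switch(arch,
    conserved    = c(0, 0),
    cis_only     = c(sgn() * mag(c_dist), 0),
    trans_only   = c(0, sgn() * mag(t_dist)),
    enhancing    = { s <- sgn(); c(s * mag(c_dist), s * mag(t_dist)) },
    compensating = { s <- sgn(); c(s * mag(c_dist), -s * mag(t_dist)) })
}

#' Simulate an allele-resolved expression dataset with known truth
#'
#' Draws negative-binomial allele counts for all configured biotypes and
#' tissues under the cis/trans generative model (see
#' [expected_allele_means()]). Expected counts are `nE * lambda_E` and
#' `nT * lambda_T` (genome copies times per-copy mean); the variance
#' follows `mu + alpha mu^2`. Only a `snp_observable_fraction` of genes
#' appears in the allele-resolved table; all genes appear in the total
#' count table.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `alleles` ([allele_counts], SNP-observable
#'   genes), `counts` ([gene_counts], all genes), `truth` (data.frame of
#'   per-gene parameters) and `size_factors` (per sample).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  arch <- sample(names(cfg$mixture), n, replace = TRUE, prob = cfg$mixture)
  beta <- stats::rnorm(n, cfg$beta_mean, cfg$beta_sd)
  ct <- t(vapply(arch, .draw_divergence, numeric(2),
                 c_dist = cfg$c_dist, t_dist = cfg$t_dist))
  disp <- rep_len(cfg$dispersion, n)
  observable <- stats::runif(n) < cfg$snp_observable_fraction

  reps <- cfg$reps[cfg$reps > 0]
  meta <- do.call(rbind, lapply(cfg$tissues, function(ts) {
    do.call(rbind, lapply(names(reps), function(b) {
      data.frame(sample_id = sprintf("%s_%s_%d", b, ts, seq_len(reps[[b]])),
                 individual_id = sprintf("%s_%d", b, seq_len(reps[[b]])),
                 biotype = b, tissue = ts, stringsAsFactors = FALSE)
    }))
  }))
  meta <- make_sample_meta(meta)
  m <- nrow(meta)
  sf <- exp(stats::rnorm(m, 0, cfg$libsize_sd))
  names(sf) <- meta$sample_id

  cE <- matrix(0L, n, m, dimnames = list(gene_ids, meta$sample_id))
  cT <- cE
  size <- 1 / disp  # NB size parameter
  # the gene's total is NB (extrinsic noise shared by both alleles of a
  # sample); the allelic split given the total is binomial with the
  # expected allelic fraction, i.e. read-level sampling from one library
  for (j in seq_len(m)) {
    cp <- biotype_copies(meta$biotype[j])
    th <- .trans_exposure(cp[["E"]], cp[["T"]], cfg$kappa)
    muE <- if (cp[["E"]] > 0L)
      cp[["E"]] * sf[j] * 2^(beta + ct[, 1] + th[["E"]] * ct[, 2]) else
      numeric(n)
    muT <- if (cp[["T"]] > 0L)
      cp[["T"]] * sf[j] * 2^(beta + th[["T"]] * ct[, 2]) else numeric(n)
    tot <- stats::rnbinom(n, mu = muE + muT, size = size)
    if (cp[["E"]] > 0L && cp[["T"]] > 0L) {
      cE[, j] <- stats::rbinom(n, tot, muE / (muE + muT))
      cT[, j] <- tot - cE[, j]
    } else if (cp[["E"]] > 0L) cE[, j] <- tot else cT[, j] <- tot
  }

  truth <- data.frame(gene_id = gene_ids, architecture = arch, beta = beta,
                      cis = ct[, 1], trans = ct[, 2], dispersion = disp,
                      snp_observable = observable, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(alleles = allele_counts(cE[observable, , drop = FALSE],
                               cT[observable, , drop = FALSE], meta),
       counts = gene_counts(cE + cT, meta),
       truth = truth,
       size_factors = sf)
}

#' Build one in-silico hybrid sample by count-level read mixing
#'
#' Emulates the construction of artificial additive hybrids by mixing
#' sequencing reads from one parent of each species at the genomic dose
#' ratio: each parental count vector is multinomially thinned to
#' `depth * d / (dE + dT)` total reads, and the thinned E-parent reads
#' become the hybrid's E-allele layer (likewise for T).
#'
#' @param sample_E,sample_T Per-gene count vectors of the two parents over
#'   identical gene ids.
#' @param dose Integer pair `(dE, dT)`; one of (1,1), (2,1), (1,2).
#' @param depth Total read target; defaults to the mean parental depth.
#' @param oversample Permit a per-layer target exceeding the parent's
#'   available reads (sampling is multinomial, i.e. with replacement at
#'   read level); if `FALSE` (default) such a request is an error.
#' @return List `counts_E`, `counts_T` of integer per-gene vectors.
#' @export
make_insilico_hybrid <- function(sample_E, sample_T, dose = c(1, 1),
                                 depth = NULL, oversample = FALSE) {
  if (length(sample_E) != length(sample_T))
    stop("parental vectors must cover identical gene ids")
  if (!is.null(names(sample_E)) && !is.null(names(sample_T)) &&
      !identical(names(sample_E), names(sample_T)))
    stop("parental vectors must cover identical gene ids")
  ok <- list(c(1, 1), c(2, 1), c(1, 2))
  if (!any(vapply(ok, function(d) all(dose == d), logical(1))))
    stop("dose must be one of (1,1), (2,1), (1,2)")
  if (is.null(depth)) depth <- round((sum(sample_E) + sum(sample_T)) / 2)
  tE <- round(depth * dose[1] / sum(dose))
  tT <- depth - tE
  thin <- function(v, target, lab) {
    if (target == 0) return(integer(length(v)))
    if (sum(v) == 0) stop("parent ", lab, " has no reads to sample")
    if (target > sum(v) && !oversample)
      stop("requested depth exceeds available ", lab,
           "-parent reads; set oversample=TRUE to sample with replacement")
    drop(stats::rmultinom(1, target, prob = v))
  }
  out <- list(counts_E = thin(sample_E, tE, "E"), counts_T = thin(sample_T, tT, "T"))
  names(out$counts_E) <- names(sample_E)
  names(out$counts_T) <- names(sample_E)
  out
}

#' Build a cohort of in-silico hybrids from parental samples
#'
#' For each artificial hybrid one EE and one TT sample are drawn at random
#' from the parental columns of `parents` and mixed with
#' [make_insilico_hybrid()] at the dose of the requested biotype.
#'
#' @param parents A [gene_counts] (or [allele_counts]) containing EE and
#'   TT samples.
#' @param biotype Hybrid biotype to emulate (`ET`, `EET` or `ETT`).
#' @param n Number of hybrid samples.
#' @param depth Per-hybrid total depth; default mean parental column sum.
#' @param tissue Tissue label for the generated metadata.
#' @param seed Optional seed.
#' @return An [allele_counts] with `n` hybrid samples.
#' @export
insilico_hybrid_set <- function(parents, biotype = "ET", n = 2, depth = NULL,
                                tissue = "liver", seed = NULL) {
  if (inherits(parents, "allele_counts")) parents <- allele_totals(parents)
  stopifnot(inherits(parents, "gene_counts"))
  if (!is.null(seed)) set.seed(seed)
  cp <- biotype_copies(biotype)
  if (cp[["E"]] == 0L || cp[["T"]] == 0L) stop("biotype must be a hybrid")
  ee <- which(parents$samples$biotype == "EE")
  tt <- which(parents$samples$biotype == "TT")
  if (!length(ee) || !length(tt)) stop("parents must contain EE and TT samples")
  if (is.null(depth)) depth <- round(mean(colSums(parents$counts)))
  gE <- gT <- matrix(0L, nrow(parents$counts), n,
                     dimnames = list(rownames(parents$counts),
                                     sprintf("sim%s_%s_%d", biotype, tissue,
                                             seq_len(n))))
  for (k in seq_len(n)) {
    pe <- parents$counts[, sample(ee, 1)]
    pt <- parents$counts[, sample(tt, 1)]
    h <- make_insilico_hybrid(pe, pt, dose = c(cp[["E"]], cp[["T"]]),
                              depth = depth, oversample = TRUE)
    gE[, k] <- h$counts_E
    gT[, k] <- h$counts_T
  }
  meta <- data.frame(sample_id = colnames(gE),
                     individual_id = colnames(gE),
                     biotype = biotype, tissue = tissue,
                     stringsAsFactors = FALSE)
  allele_counts(gE, gT, meta)
}

#' Simulate a multivariate trait matrix ordered along the E-genome dose
#'
#' Each individual's feature vector is
#' `gradient_effect * e_fraction * v + offset(biotype) + noise`, with `v`
#' a fixed unit direction (equal loading on every feature) and Gaussian
#' noise. Per-biotype offsets can emulate a systematic bias of hybrids
#' toward one parental species that is not explained by dose.
#'
#' @param reps Named integer vector of individuals per biotype. The
#'   default mirrors the morphometric sampling of the study populations
#'   (24 EE, 38 TT, 95 ET, 17 EET, 17 ETT females).
#' @param gradient_effect Scalar strength of the dose gradient.
#' @param n_features Number of trait features (>= 2).
#' @param noise_sd Gaussian noise SD per feature.
#' @param offsets Optional named list/vector of per-biotype scalar offsets
#'   applied along the same direction `v`.
#' @param seed Optional seed.
#' @return List `X` (individuals x features matrix), `meta` (data.frame
#'   with `individual_id`, `biotype`, `e_fraction`).
#' @export
simulate_trait_matrix <- function(reps = c(EE = 24, TT = 38, ET = 95,
                                           EET = 17, ETT = 17),
                                  gradient_effect = 1, n_features = 20,
                                  noise_sd = 1, offsets = NULL, seed = NULL) {
  if (n_features < 2) stop("n_features must be >= 2")
  if (length(reps) < 2) stop("need at least two biotypes")
  if (!is.null(seed)) set.seed(seed)
  bio <- rep(names(reps), reps)
  n <- length(bio)
  ef <- e_genome_fraction(bio)
  v <- rep(1, n_features) / sqrt(n_features)
  off <- rep(0, n)
  if (!is.null(offsets)) {
    offsets <- unlist(offsets)
    off <- ifelse(bio %in% names(offsets), offsets[bio], 0)
  }
  X <- outer(gradient_effect * ef + off, v) +
    matrix(stats::rnorm(n * n_features, 0, noise_sd), n, n_features)
  rownames(X) <- sprintf("ind_%s_%d", bio, stats::ave(seq_len(n), bio,
                                                      FUN = seq_along))
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  list(X = X,
       meta = data.frame(individual_id = rownames(X), biotype = bio,
                         e_fraction = ef, stringsAsFactors = FALSE))
}
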