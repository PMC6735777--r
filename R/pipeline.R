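#' Default pipeline configuration
#'
#' Returns the default run configuration as a nested list; fields mirror
#' the stage parameters. Any subset can be overridden by the `config`
#' argument of [run_pipeline()] (or a YAML file with the same structure).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "allodose_run",
    seed = 1L,
    alpha_q = 0.05,
    n_perm_ordination = 9999L,
    n_perm_skewness = 1000L,
    stages = list(simulate = TRUE, dge = TRUE, inherit = TRUE,
                  asereg = TRUE, homodyn = TRUE, ordin = TRUE),
    simulate = list(n_genes = 2000L,
                    reps = c(EE = 4, TT = 4, ET = 2, EET = 2, ETT = 4),
                    tissues = c("oocyte", "liver"),
                    kappa = 1, dispersion = 0.1,
                    snp_observable_fraction = 0.3),
    dge = list(min_total = 100),
    asereg = list(min_cov = 30, min_individuals = 2),
    ordin = list(reps = c(EE = 24, TT = 38, ET = 95, EET = 17, ETT = 17),
                 gradient_effect = 1, n_features = 20, noise_sd = 1)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.stage_path <- function(dir, name) file.path(dir, name)

.require_input <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' is missing required input: ", basename(path))
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, differential expression (three factor
#' contrasts per tissue), inheritance classification per hybrid biotype,
#' cis/trans regulatory calls, homoeolog modulation summaries (with the
#' cross-tissue correlation when two tissues are present) and the
#' trait-matrix ordination with dose-gradient fit. Stage outputs are TSV
#' files under `out_dir`; a JSON manifest records seeds, parameters and
#' MD5 hashes of every written file. Stage failure writes a failure
#' marker into the manifest and aborts, preserving partial outputs.
#'
#' @param config Named list overriding [default_config()], or the path of
#'   a YAML file with the same structure.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  cfg$simulate$reps <- unlist(cfg$simulate$reps)
  cfg$ordin$reps <- unlist(cfg$ordin$reps)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "allodose",
                   version = as.character(utils::packageVersion("allodose")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = cfg$seed, parameters = cfg, stages = list(),
                   files = list(), status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  fail <- function(stage, err) {
    manifest$status <<- paste0("failed:", stage)
    manifest$error <<- conditionMessage(err)
    write_manifest()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }
  note_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    tryCatch(fun(), error = function(e) fail(name, e))
    manifest$stages[[name]] <<- "ok"
  }
  p <- function(...) file.path(cfg$out_dir, ...)

  run_stage("simulate", function() {
    sc <- sim_config(n_genes = cfg$simulate$n_genes, reps = cfg$simulate$reps,
                     tissues = cfg$simulate$tissues,
                     kappa = cfg$simulate$kappa,
                     dispersion = cfg$simulate$dispersion,
                     snp_observable_fraction = cfg$simulate$snp_observable_fraction,
                     seed = cfg$seed)
    sim <- simulate_dataset(sc)
    write_counts(sim$counts, p("counts.tsv"))
    write_counts(gene_counts(sim$alleles$counts_E, sim$alleles$samples),
                 p("alleles_E.tsv"))
    write_counts(gene_counts(sim$alleles$counts_T, sim$alleles$samples),
                 p("alleles_T.tsv"))
    write_metadata(sim$counts$samples, p("meta.tsv"))
    utils::write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (f in c("counts.tsv", "alleles_E.tsv", "alleles_T.tsv", "meta.tsv",
                "truth.tsv")) note_file(p(f))
  })

  load_counts <- function(stage) {
    read_counts(.require_input(p("counts.tsv"), stage),
                .require_input(p("meta.tsv"), stage))
  }
  load_alleles <- function(stage) {
    read_allele_counts(.require_input(p("alleles_E.tsv"), stage),
                       .require_input(p("alleles_T.tsv"), stage),
                       .require_input(p("meta.tsv"), stage))
  }

  groupings <- list(species = list("EE", "TT"),
                    reproduction = list(c("EE", "TT"), c("ET", "EET", "ETT")),
                    ploidy = list(c("EE", "TT", "ET"), c("EET", "ETT")))

  run_stage("dge", function() {
    x <- load_counts("dge")
    for (ts in unique(x$samples$tissue)) {
      xt <- filter_low_expression(x[, x$samples$tissue == ts],
                                  cfg$dge$min_total)
      sf <- size_factors(xt)
      for (gn in names(groupings)) {
        present <- unlist(groupings[[gn]])
        if (!all(present %in% xt$samples$biotype)) next
        j <- xt$samples$biotype %in% present
        res <- nb_contrast(xt[, j], groupings[[gn]], sf = sf[j])
        fn <- p(sprintf("deg_%s_%s.tsv", gn, ts))
        utils::write.table(res, fn, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note_file(fn)
      }
    }
  })

  run_stage("inherit", function() {
    x <- load_counts("inherit")
    for (ts in unique(x$samples$tissue)) {
      xt <- filter_low_expression(x[, x$samples$tissue == ts],
                                  cfg$dge$min_total)
      hybs <- intersect(c("ET", "EET", "ETT"), xt$samples$biotype)
      calls <- lapply(hybs, function(h)
        inheritance_calls(xt[, xt$samples$biotype %in% c("EE", "TT", h)],
                          hybrid = h, alpha_q = cfg$alpha_q))
      all <- do.call(rbind, calls)
      all$tissue <- ts
      fn <- p(sprintf("inheritance_%s.tsv", ts))
      utils::write.table(all, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_file(fn)
      summ <- table(all$biotype, all$category)
      fn2 <- p(sprintf("inheritance_summary_%s.tsv", ts))
      utils::write.table(as.data.frame.matrix(summ), fn2, sep = "\t",
                         quote = FALSE, col.names = NA)
      note_file(fn2)
    }
  })

  run_stage("asereg", function() {
    a <- load_alleles("asereg")
    for (ts in unique(a$samples$tissue)) {
      at <- a[, a$samples$tissue == ts]
      hybs <- intersect(c("ET", "EET", "ETT"), at$samples$biotype)
      calls <- lapply(hybs, function(h)
        regulatory_calls(at, hybrid = h, alpha_q = cfg$alpha_q,
                         min_cov = cfg$asereg$min_cov,
                         min_individuals = cfg$asereg$min_individuals))
      all <- do.call(rbind, calls)
      all$tissue <- ts
      fn <- p(sprintf("regulatory_%s.tsv", ts))
      utils::write.table(all, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_file(fn)
      summ <- do.call(rbind, lapply(calls, function(d) table(d$category)))
      rownames(summ) <- hybs
      fn2 <- p(sprintf("regulatory_summary_%s.tsv", ts))
      utils::write.table(summ, fn2, sep = "\t", quote = FALSE,
                         col.names = NA)
      note_file(fn2)
    }
  })

  run_stage("homodyn", function() {
    a <- load_alleles("homodyn")
    tissues <- unique(a$samples$tissue)
    per_tissue <- list()
    summ <- list()
    for (ts in tissues) {
      at <- a[, a$samples$tissue == ts]
      hybs <- intersect(c("ET", "EET", "ETT"), at$samples$biotype)
      rr <- do.call(rbind, lapply(hybs, function(h) {
        f <- ase_filter(at[, at$samples$biotype %in% c("EE", "TT", h)],
                        cfg$asereg$min_cov, cfg$asereg$min_individuals)
        if (!nrow(f$counts_E)) return(NULL)
        r <- modulation_ratios(ase_table(f, h))
        r$tissue <- ts
        for (ax in c("log2_Ehyb_over_E", "log2_Thyb_over_T")) {
          v <- r[[ax]]
          summ[[length(summ) + 1L]] <<- data.frame(
            biotype = h, tissue = ts, axis = ax, n = length(v),
            skewness = skewness(v), mad = stats::mad(v),
            stringsAsFactors = FALSE)
        }
        r
      }))
      per_tissue[[ts]] <- rr
      fn <- p(sprintf("modulation_%s.tsv", ts))
      utils::write.table(rr, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_file(fn)
    }
    fn <- p("modulation_summary.tsv")
    utils::write.table(do.call(rbind, summ), fn, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note_file(fn)
    if (length(tissues) == 2) {
      a1 <- per_tissue[[tissues[1]]]; a2 <- per_tissue[[tissues[2]]]
      ct <- do.call(rbind, lapply(intersect(a1$biotype, a2$biotype),
        function(h) {
          cc <- cross_tissue_correlation(a1[a1$biotype == h, ],
                                         a2[a2$biotype == h, ])
          cc$biotype <- h
          cc
        }))
      fn <- p("cross_tissue.tsv")
      utils::write.table(ct, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note_file(fn)
    }
  })

  run_stage("ordin", function() {
    tm <- simulate_trait_matrix(reps = cfg$ordin$reps,
                                gradient_effect = cfg$ordin$gradient_effect,
                                n_features = cfg$ordin$n_features,
                                noise_sd = cfg$ordin$noise_sd,
                                seed = cfg$seed)
    ord <- pca_ordination(tm$X)
    fit <- fit_genome_gradient(ord, tm$meta$e_fraction, axes = c(1, 2),
                               n_perm = cfg$n_perm_ordination,
                               seed = cfg$seed)
    rot <- rotate_to_gradient(fit, groups = tm$meta$biotype,
                              n_perm = cfg$n_perm_ordination,
                              seed = cfg$seed)
    pv <- permanova(stats::dist(tm$X), tm$meta$biotype, n_perm = 999,
                    seed = cfg$seed)
    sc <- data.frame(individual_id = tm$meta$individual_id,
                     biotype = tm$meta$biotype, ord$scores[, 1:2],
                     rot1 = rot$rotated_scores[, 1],
                     rot2 = rot$rotated_scores[, 2])
    fn <- p("ordination_scores.tsv")
    utils::write.table(sc, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    note_file(fn)
    rep <- list(significant_axes = ord$significant_axes,
                proportion_explained = ord$proportion_explained[1:2],
                gradient = list(r2 = fit$r2, p = fit$p_perm,
                                direction = as.numeric(fit$direction),
                                angle = rot$angle),
                rotated_axis_anova = list(F = rot$anova$F, p = rot$anova$p),
                permanova = list(F = pv$F, R2 = pv$R2, p = pv$p))
    fn <- p("ordination_report.json")
    jsonlite::write_json(rep, fn, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    note_file(fn)
  })

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest()
  invisible(manifest)
}
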