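# allodose

Expression inheritance, homoeolog regulation and genomic dose gradients
in diploid and triploid interspecific hybrids.

## The problem

When two diverged genomes meet in a hybrid — and when one of them is
then duplicated in a triploid — every gene must be transcribed under a
mixture of the parents' regulatory machineries. `allodose` is an R
toolkit for the questions this raises in systems of co-occurring
parental species (EE, TT), diploid hybrids (ET) and triploid hybrids
(EET, ETT), such as clonal fish complexes:

* **Inheritance.** Per gene and hybrid biotype: is expression additive
  (between both parents), dominant (matching one parent), or
  transgressive (beyond both)? Genes are placed into the twelve
  classical inheritance categories with explicit `NoChange`/`Ambiguous`
  handling, and real hybrids are compared against *in-silico additive
  hybrids* built by mixing parental reads 50:50 (or 2:1 / 1:2) — the
  null in which every dominance call is a statistical artefact.
* **Cis/trans regulation.** With species-diagnostic SNPs, each gene's
  allelic ratio in the hybrid is compared to the parental divergence,
  dose-adjusted for triploids: a preserved ratio indicates cis
  divergence, an equalized ratio trans divergence, and combined
  patterns are split into enhancing and compensating. A tunable
  cross-talk parameter κ in the bundled simulator spans the two poles —
  fully shared trans environment (κ = 1) versus autonomous subgenomes
  (κ = 0).
* **Dose asymmetry.** Per-copy log2 ratios of hybrid allele to parental
  expression (`Ehyb/E`, `Thyb/T`) quantify how strongly each subgenome's
  trans factors modulate the other's alleles; skewness, MAD,
  Fligner–Killeen and permutation tests detect the triploid asymmetry in
  which the homoeolog contributed as a haploid set is modulated more
  than the duplicated one.
* **Phenotype gradients.** Procrustes-aligned morphometrics, habitat
  and expression matrices are ordinated (PCA/PCoA, broken-stick axis
  selection, PERMANOVA, jackknifed CVA), the E-genome fraction
  (EE = 100%, EET = 66.6%, ET = 50%, ETT = 33.3%, TT = 0%) is fitted
  into the ordination plane with a permutation test, and the biplot is
  rotated onto the fitted dose gradient.

The model at the package's core: per gene, allele means follow
`lambda_E = s·2^(beta + c + theta_E·t)` and `lambda_T = s·2^(beta + theta_T·t)`
with cis divergence `c`, trans divergence `t`, and trans exposures
`theta_E = kappa·theta_mix + (1 − kappa)`, `theta_T = kappa·theta_mix`,
`theta_mix = nE/(nE + nT)` the dose-weighted trans environment. Counts
are negative binomial in each gene's total with a binomial allelic
split within a sample. All classifiers are validated against this
generative truth.

## Worked example

```r
library(allodose)

cfg <- sim_config(n_genes = 2000, reps = c(EE = 4, TT = 4, EET = 4),
                  tissues = "liver", kappa = 1, seed = 42,
                  snp_observable_fraction = 1)
sim <- simulate_dataset(cfg)

# inheritance categories of the EET triploid
x <- filter_low_expression(sim$counts)
calls <- inheritance_calls(x, hybrid = "EET")
table(calls$group)
#>           additive       dominance_up     dominance_down transgressive_down
#>                  0                139                107                  0
#>   transgressive_up               none
#>                  0               1741

# cis/trans regulatory divergence calls
tb  <- ase_table(ase_filter(sim$alleles), "EET")
reg <- classify_cis_trans(tb)
table(reg$category)
#>          Cis        Trans    Enhancing Compensating NoCisNoTrans NotAvailable
#>          294          210            5          117         1213            0

# dose asymmetry: the haploid-dose T homoeolog is modulated more
rat <- modulation_ratios(tb)
fk  <- fligner_killeen(rat$log2_Ehyb_over_E, rat$log2_Thyb_over_T)
sprintf("MAD Ehyb/E = %.3f, MAD Thyb/T = %.3f, Fligner-Killeen p = %.3g",
        fk$mad[["x"]], fk$mad[["y"]], fk$p)
#> "MAD Ehyb/E = 0.409, MAD Thyb/T = 0.506, Fligner-Killeen p = 4.26e-26"

# a trait matrix ordered along the E-genome dose gradient
tm  <- simulate_trait_matrix(gradient_effect = 2, noise_sd = 1, seed = 42)
ord <- pca_ordination(tm$X)
fit_genome_gradient(ord, tm$meta$e_fraction, axes = c(1, 2),
                    n_perm = 999, seed = 42)
#> <gradient fit on axes 1,2: R2 = 0.181, p = 0.001>
```

Reading the output: under full cross-talk (κ = 1) a 2:1 genome dose
pulls hybrid expression toward the E parent, so truly divergent genes
surface as expression-level dominance rather than additivity; among
genes with decidable allelic patterns, cis-preserved ratios (`Cis`),
equalized ratios (`Trans`) and over-compensated ratios (`Compensating`)
are separated; the larger MAD of `Thyb/T` shows the haploid-dose T
homoeolog answering two thirds of the trans divergence while each
duplicated E copy answers one third; and the trait ordination carries a
significant dose gradient (R² = 0.18 at its default effect size).

A full multi-stage run (simulation → differential expression →
inheritance → regulation → modulation → ordination, with a manifest of
seeds and output hashes) is one call:

```r
run_pipeline(list(out_dir = "my_run", seed = 1))
```

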