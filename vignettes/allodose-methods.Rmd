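---
title: "Methods: homoeolog regulation and dose gradients in hybrid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog regulation and dose gradients in hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodose)
```

## The biological setting

`allodose` analyses gene expression in a system of two parental fish
species and their clonal hybrids: the diploid parents EE and TT, the
diploid hybrid ET, and the triploid hybrids EET and ETT. Every analysis
revolves around two quantities derived from the genome composition: the
integer *genomic dose* of each parental subgenome (2:0, 0:2, 1:1, 2:1,
1:2) and the *E-genome fraction* `copies_E / (copies_E + copies_T)`
(1, 0, 1/2, 2/3, 1/3), which orders biotypes along a dose gradient.
Reproduction mode (sexual vs. clonal) and ploidy are functions of the
biotype and are always derived, never stored, so metadata cannot
contradict itself.

The package asks, for hybrids of each dose: do genes inherit parental
expression additively, dominantly or transgressively; is allele-specific
expression governed by cis- or trans-acting divergence; how strongly does
each subgenome's trans machinery modulate the other subgenome's alleles;
and how far do multivariate phenotypes follow the dose gradient.

## The generative model

`simulate_dataset()` is a first-class module, not a test fixture: it
defines the ground truth against which every classifier in the package is
validated. Per gene it draws

* a baseline log2 per-copy expression `beta ~ N(log2 50, 1.5)`, giving a
  median per-copy mean of 50 reads (about 100 reads of allele-specific
  coverage per diploid sample, the order of magnitude at which
  ASE analyses typically operate);
* a regulatory architecture from a mixture (default 50% conserved, 20%
  cis-only, 20% trans-only, 10% compensating; enhancing is available but
  defaults to 0 because it is empirically rare);
* cis (`c`) and trans (`t`) divergences in log2. Magnitudes default to
  lognormal(meanlog = log 1.5, sdlog = 0.4) — genes labelled divergent
  carry a clearly nonzero effect, as a near-zero "divergence" is
  semantically conserved — with random signs subject to the architecture
  constraints (`c t > 0` enhancing, `c t < 0` compensating). A
  `normal` option (`|N(0, sd)|`) is used where a normal fold-change
  distribution is the stated benchmark condition;
* a NB dispersion `alpha` (default 0.1, variance `mu + alpha mu^2`), the
  magnitude typical of outbred bulk RNA-seq.

Sample numbers default to the sequencing design of the study system
(4 EE, 4 TT, 2 ET, 2 EET, 4 ETT females; liver and oocyte), with
log-normal library size factors (sd 0.15).

**Trans exposure.** The allele means follow
`lambda_E = s 2^(beta + c + theta_E t)` and
`lambda_T = s 2^(beta + theta_T t)` with trans exposures
`theta_E = kappa theta_mix + (1 - kappa)`, `theta_T = kappa theta_mix`,
`theta_mix = nE / (nE + nT)`. The cross-talk parameter `kappa`
interpolates between the two poles of homoeolog regulation: at
`kappa = 1` both alleles share a dose-weighted trans environment, so the
dose-adjusted hybrid allelic ratio is `2^c` (the classic shared-trans
expectation); at `kappa = 0` each subgenome answers only its own factors
and the hybrid ratio equals the full parental ratio `2^(c + t)` —
autonomous regulation that masquerades as cis. The dose weighting of
`theta_mix` is what produces the triploid asymmetry analysed by the
`homodyn` functions: in an EET cell the haploid T allele is displaced by
`(2/3) t` while each duplicated E allele moves only `(1/3) t`.

**Counting noise.** A gene's total count in a sample is NB; the split
between the two alleles given that total is binomial with the expected
allelic fraction. This mirrors how allele-specific reads arise — both
alleles are sequenced from one library, so extrinsic expression noise is
shared within a sample and the within-sample allelic fraction is
binomial given coverage. Biological noise between individuals remains NB.
The generator does not model sequencing error, mapping bias, tissue-
specific regulatory divergence (tissues share the gene truth and differ
only in sampling noise), allele silencing, or SNP-calling errors; passing
tests therefore demonstrate correctness of the statistical machinery
under this model, not robustness to those artefacts in real data.

**In-silico hybrids.** `make_insilico_hybrid()` mixes two parental count
vectors at the dose ratio by multinomial thinning to
`depth * d / (dE + dT)` reads per layer. Mixing at count level is exact
for every downstream statistic because per-gene counts are the
sufficient statistics of read-level mixing. Artificial triploids default
to the same total depth as diploids (the depth-matching question is
configurable via `depth`).

## Differential expression

Genes with cumulated counts not strictly above 100 are removed.
Normalization is median-of-ratios against the geometric-mean
pseudo-reference; `per_condition` mode evaluates every sample against
each biotype-by-tissue reference and takes the per-sample maximum, a
conservative sharing rule, then rescales to geometric mean 1.

`nb_contrast()` fits per gene a NB log-link model with a group indicator
and log size-factor offset. The dispersion is estimated by **Cox–Reid
adjusted profile likelihood** and the Wald statistic is referred to a
t distribution with `n - 2` df. With 2–4 replicates per group, plain
per-gene ML dispersion is biased low and the normal-reference Wald test
rejects a true null about 13% of the time at nominal 5%; the CR
adjustment plus t reference restores the nominal level (measured 4.5%
on 2,000 null genes) while keeping power above 0.9 for |log2FC| = 2 at
six replicates. Plain ML (`disp = "ml"`) and the likelihood-ratio test
(`test = "lrt"`) remain available.

`anova_type2()` tests each of the three design factors (species status,
ploidy, reproduction) by a likelihood-ratio chi-square against the model
with that factor removed while all others are retained (type-II
marginality, main effects). Because every triploid is clonal and every
parental individual sexual, `reproduction` adds no rank beyond
`species_status`; such terms are reported as `aliased` rather than
silently dropped.

## Inheritance categories

`classify_inheritance()` maps the three pairwise tests (EE vs TT,
hybrid vs EE, hybrid vs TT; BH-corrected q at 0.05) and the normalized
means onto the twelve inheritance categories. The grouping into
additive {I, XII}, dominance-up {II, IV}, dominance-down {IX, XI},
transgressive-down {III, VII, X} and transgressive-up {V, VI, VIII} is
fixed; the numeral within a group encodes the parental direction
(`E < T` takes the lower numeral; the middle transgressive numerals are
used when parents do not differ). That convention lives in one table
(`inheritance_numerals()`) and swapping the parental labels maps
I↔XII, II↔IV, IX↔XI, III↔X, V↔VIII exactly. "Intermediate" always means
strictly between the parental means; ties are not intermediate, so a
hybrid exactly at a parental mean is never additive-like. Genes with no
significant pair are `NoChange`; any unlisted pattern (e.g. a single
significant comparison) is `Ambiguous`.

The additive-like flag among dominance calls is the package's main
statistical-artefact control: hybrids built as exact 50:50 parental
mixtures are additive by construction, so any dominance call on them is
a power artefact, and nearly all such calls show the hybrid mean
strictly between the parental means.

`mantel_test()` correlates the off-diagonal entries of two category
transition matrices and permutes row and column labels jointly; raw
transition counts (not distances) are used, an interpretation choice
made because the co-assignment counts are the natural association
structure between biotypes' category assignments.

## Cis/trans classification

For each gene of one hybrid biotype `ase_table()` pools normalized
counts into: hybrid allelic sums, parental sums, the relative allelic
expression (`rae_percent`), the dose-adjusted hybrid ratio
`(E_hyb/nE)/(T_hyb/nT)` and the parental per-copy ratio. Zeros receive
a Haldane 0.5 correction and are flagged. Three two-sided proportion
tests (chi-square with continuity correction), each BH-corrected across
genes within its own family, then decide:

| pattern | call |
|---|---|
| parental divergence (T_A) and hybrid imbalance (T_C), hybrid = parents (T_B ns) | Cis |
| parental divergence (T_A) and hybrid ≠ parents (T_B), hybrid balanced (T_C ns) | Trans |
| T_B and T_C both significant, parental ratio beyond the hybrid ratio | Enhancing |
| T_B and T_C both significant, parental ratio short of the hybrid ratio | Compensating |
| anything else | NoCisNoTrans |

Genes without diagnostic SNPs or failing the coverage filter (allelic
coverage strictly above 30 in at least two hybrid individuals) are
`NotAvailable`. T_B's null proportion re-weights the parental per-copy
means by the hybrid dose (`p0 = nE e / (nE e + nT t)`), implemented as a
two-sample test so parental sampling uncertainty is retained.

**Effective counts.** Reads pooled across biological replicates are not
binomial: replicate-level NB dispersion inflates the variance of a
pooled count by the design effect `1 + alpha mu`. The parental side of
T_A/T_B is therefore deflated by a per-gene common factor
`1 + alpha_hat hm(mu_E, mu_T)` (harmonic mean; `alpha_hat` estimated by
a weighted least-squares fit of `var = mu + alpha mu^2` pooled across
genes), which preserves the allelic proportion while matching the
variance of the parental log ratio. Without it the conserved genes'
false-assignment rate into Cis/Trans is an order of magnitude above the
nominal FDR; with it, it stays below. Raw pooling is available
(`use_effective = FALSE`). The hybrid side needs no deflation because
the within-sample allelic split is binomial given the total. A
consequence worth stating plainly: the parental-side information is
capped near `k / alpha` effective reads regardless of coverage, so
trans components below roughly one log2 unit are undetectable at four
parental replicates, and compensating genes whose trans component falls
under that limit are assigned — correctly, given the data — to Cis.
Recovery of the compensating class is therefore bounded near 75–80%
even though cis- and trans-only recovery among decidable genes exceeds
95%.

`regress_hybrid_on_parent()` fits the NB regression of hybrid E-counts
with offset `log(T_hyb nE / nT)` on the parental log ratio; slope 1 is
the pure-cis expectation. Because the predictor is itself estimated
from finitely many parental replicates, the naive slope is attenuated
by the reliability ratio; the function reports the dilution-corrected
slope alongside the naive one.

## Homoeolog modulation

`modulation_ratios()` computes per-copy log2 ratios of hybrid allele to
parental expression; dose adjustment makes a per-copy-conserved EET
allele read 0 rather than +1. Distributions along the two axes are
summarized by skewness (moment form `g1 = m3 / m2^{3/2}`; the adjusted
Fisher–Pearson variant is switchable) and MAD (reported with the
standard 1.4826 consistency constant). Dispersion differences use the
Fligner–Killeen test; skewness differences use a permutation test that
re-divides the pooled values into pseudo-samples of the original sizes
(true permutation without replacement by default, bootstrap behind a
flag) with smoothed p `(1 + hits) / (n_perm + 1)`.

## Ordination

Landmark configurations are aligned by generalized Procrustes analysis —
centering, unit centroid size, iterative proper rotation (reflections
excluded so alignment is order-invariant) onto the evolving consensus to
tolerance 1e-8. PCA is a centered covariance eigen-decomposition; PCoA is
the Gower double-centering, with negative eigenvalues reported and
excluded from proportions. Axis significance uses the broken-stick null
`b_k = (1/p) sum_{i>=k} 1/i` with strict inequality and contiguity from
axis 1. PERMANOVA (through `vegan::adonis2`) provides the grouping
pseudo-F with optional sequential covariate and pairwise follow-ups.
`cva_jackknife()` reduces high-dimensional inputs by PCA to 95%
variance (capped to keep the pooled covariance nonsingular) before
leave-one-out linear discriminant classification. The body-arching
correction of morphometric data is expressed as an axis mask chosen by
the user (e.g. fitting on PC2/PC3), never hard-coded.

`fit_genome_gradient()` regresses the E-genome fraction on the selected
significant axes, reports the normalized direction (pointing toward
increasing E fraction), the squared multiple correlation, and a
permutation p over `(1 + hits)/(1 + n_perm)` with 9,999 permutations by
default; the exhaustive search over pairs of significant axes maximizing
R² is the package's interpretation of "the strongest correspondence".
`rotate_to_gradient()` turns the biplot by `-atan2(d_y, d_x)` so rotated
axis 1 is the gradient (an isometry), then runs a one-way permutational
ANOVA of biotype on that axis.

## Determinism, problem sizes and error handling

Every stochastic routine takes a seed; `run_pipeline()` records seeds,
parameters and output MD5s in a JSON manifest, and reruns with the same
configuration are hash-identical. Degenerate inputs error early and by
name: constant matrices in the Mantel test, collinear shapes in GPA,
all-zero reference genes in normalization, constant E-fractions in the
gradient fit, single-member PERMANOVA groups (dropped with a warning).

The test suite exercises the same pipelines at reduced sizes chosen to
keep the default run fast while leaving Monte-Carlo tolerances
meaningful: 2,000–6,000 genes for the recovery and calibration suites,
200 replicates for type-I checks (binomial 3-sigma bands), and the
full-size benchmark (15,000 genes) lives in `scripts/acceptance.R`.

## Known limitations

* The proportion-test classifier inherits the pooled-read design of its
  field; the effective-count correction restores calibration but cannot
  recover information that four parental replicates do not carry.
* The simulator's tissues share one regulatory truth; cross-tissue
  correlations of modulation ratios are therefore upper bounds relative
  to real tissue-specific trans divergence.
* `per_condition`/`maximum` normalization approximates the conservative
  behaviour of legacy per-condition sharing; it is not a reimplementation
  of any specific package's internals.
* GO-term enrichment, read mapping, transcriptome assembly and
  pileup-level allele counting are out of scope; the package starts from
  count tables and VCF calls.
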