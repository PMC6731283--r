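---
title: "Decomposing genetic associations: model, scores, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genetic associations: model, scores, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degas)
library(data.table)
```

## The problem

A biobank-scale GWAS campaign produces, for each of thousands of phenotypes,
one association statistic per genotyped variant. Individually these tables
are phenotype-centric; jointly they encode pleiotropy — the sharing of
genetic signal across traits. `degas` organizes the whole collection as a
single phenotype-by-variant matrix of Wald Z-scores and asks what low-rank
latent structure explains it. Each latent component is a direction in both
the phenome and the genome at once: a weighted set of traits co-varying with
a weighted set of variants. The package implements the matrix assembly, the
truncated singular value decomposition (TSVD), the scoring system that makes
components interpretable, a regulatory-domain region-enrichment kernel for
biological annotation of components, and a synthetic-data generator that
makes every stage testable without access-controlled cohort data.

## From summary statistics to the matrix `W`

An association record carries an effect estimate (`BETA` for quantitative
traits, log odds ratio for binary traits), its standard error, and a
p-value. The entry of `W` for phenotype `i` and variant `j` is the Wald
Z-score `estimate/se`. Only confident associations enter the matrix:

* p-value below `0.001`;
* standard error below `0.08` (quantitative) or `0.2` (binary).

Phenotypes require at least 100 cases (binary) or 100 non-missing
measurements (quantitative). Variants must pass QC — missingness below 1%,
minor-allele frequency above 0.01%, Hardy–Weinberg disequilibrium p above
1e-7, membership in the LD-pruned set (consumed as a precomputed flag) —
and lie outside the MHC region (chr6:25477797–36448354, GRCh37), whose
extreme LD would otherwise dominate components. Three datasets are defined
by consequence class: `all` variants, `coding` (missense through
protein-truncating), and `ptv` only (stop gain, frameshift, splice
acceptor/donor).

Cells with no surviving association are zero. This zero-fill is a declared
convention: the selection step leaves most pairs unobserved, a Z near zero
is the natural neutral value for "no confident association", and it
preserves sparsity. Mean-filling was rejected because row means are
dominated by the observed (significant) entries and would leak signal into
unobserved cells. Phenotypes or variants with *no* surviving association are
dropped from the axes entirely, which is why consequence-restricted
matrices have fewer phenotypes.

Finally each phenotype row is standardized to zero mean and unit variance,
so that every phenotype contributes comparable mass regardless of how many
significant associations it has. Variance uses the population convention
(division by `M`); rows that are constant after filtering have no direction
and are dropped with a warning rather than imputed. Duplicate
(phenotype, variant) records are an error, not a silent overwrite —
summary-statistic inputs should be unambiguous.

## The decomposition

`truncated_svd()` computes the leading `K` triplets of `W = U S V'`.
Rather than an iterative Lanczos solver, the implementation uses the exact
symmetric eigendecomposition of the Gram matrix on the smaller axis
(`W W'` when phenotypes are fewer) and recovers the other side as
`V = W' U S^{-1}`. At the scales this method targets, the smaller axis is
the phenome (hundreds to a few thousand rows), where a dense symmetric
eigensolve is fast, deterministic, and accurate to machine precision; the
test suite checks it against R's dense `svd()` to 1e-8 and against the
Eckart–Young optimum. Requests for components beyond the numerical rank
are an error rather than a silently padded result.

Singular vectors are only defined up to sign. For reproducible tables and
plots, each component's sign is fixed so that the largest-magnitude entry
of its phenotype singular vector is positive, with the flip mirrored in
`V`; the product `U S V'` is untouched. Components with (near-)tied
singular values are only comparable at the subspace level, which is how the
recovery tests treat them.

**Choosing `K`.** The scree comparison uses a null expectation for
per-component variance explained, computed from the full rank of `W`.
The default reference is `1/Rank(W)^2`; the natural uniform-null value
`1/Rank(W)` is also available (`model = "uniform"`). The two differ by a
factor of `Rank(W)` and the squared form is far more permissive; both are
exposed rather than silently picking one, and the default follows the
squared form as the method's stated rule. With either reference,
`select_component_count()` caps the answer at `k_max = 100`, the
conventional operating point chosen for computational economy.

## The scoring system

All interpretation flows from two complementary normalizations of the same
factorization:

* **Factor scores** `F_p = U S`, `F_v = V S` are principal-component
  coordinates; column `k` has norm `s_k`.
* **Contribution scores** square the singular vectors: `u_{ik}^2` is the
  share of component `k` carried by phenotype `i` (columns sum to 1 by
  orthonormality). They answer "what drives this component?".
* **Squared cosine scores** square the factor scores and normalize within
  an entity: `f_{ik}^2 / sum_k f_{ik}^2` (rows sum to 1). They answer
  "which components matter for this trait?".

The two mappings need not invert each other — a phenotype's top component
by squared cosine can itself be driven chiefly by a different phenotype —
and the test suite asserts this on a constructed counterexample, because
treating the scores as inverses is the most tempting misuse.

**Gene aggregation.** Gene contribution scores sum variant contributions
over a *partition* of the variant axis: variants with identical multi-gene
annotation sets form an intersection group (keyed e.g. `GENE_A,GENE_B`),
and each unannotated non-coding variant is its own singleton group. The
partition is what keeps columns summing to one; assigning a shared variant
to every one of its genes would double-count its mass. An entity with all
factor scores zero has no defined squared-cosine row; such rows are dropped
and recorded rather than propagated as NaN.

Squared-cosine denominators run over the `K` computed components — the
truncated basis is the only one that exists after TSVD — so the scores are
relative to that basis and grow mechanically less concentrated as `K`
increases. Rankings break ties lexicographically by identifier so reports
are deterministic. For stacked-bar displays, segments below 0.5%
(phenotypes) or 0.05% (genes) of a component's mass are aggregated as
"others"; both thresholds are arguments.

**Biplots.** `biplot_frame()` emits phenotype points (`F_p`), variant
points (`F_v`), and arrows (`U` rows, drawn on sub-axes) for selected
phenotypes. The contract is that the inner product of a variant point with
a phenotype arrow is the projection of that pair's association onto the
displayed components: aligned means positive, opposed means negative,
orthogonal or zero-length means none.

## Region enrichment and specificity

To characterize a component biologically, its top 5,000 variants by
contribution score (the default; smaller synthetic runs use fewer) are
exported as single-base BED intervals and tested against an ontology via a
self-contained binomial regulatory-domain kernel. Each gene's regulatory
domain is a strand-oriented basal window (5 kb upstream, 1 kb downstream
of the TSS) extended up to 1 Mb in each direction but stopping at the
nearest neighboring basal domain, clipped to the chromosome. For a term,
`pi` is the genome fraction covered by the union of its genes' domains;
the observed region hits are tested against `Binomial(n, pi)` with an
upper-tail p-value, and fold enrichment is `hits/(n*pi)`. The kernel is
checked against exact tail sums to 1e-12. Two significance modes mirror
reporting practice: a Bonferroni-style table threshold `p < 5e-6`, and a
stricter display filter `p < 5e-7` with fold ≥ 2.

Ontology input is a flat two-column (term, gene) table; hierarchical
propagation and obsolete-term removal are assumed done upstream. The
extension parameters are exposed rather than hard-coded because curated
domain variants of the rule exist; the defaults are the standard
basal-plus-extension settings.

**Specificity.** To ask whether components capture distinct biology, each
component's top five terms by fold are expanded to their gene-set unions
and compared pairwise with the Jaccard index; the profile reports the
median across the first `k` components as `k` grows. Identical components
give 1, disjoint biology gives 0. Components with no enriched term are
skipped and logged.

## What the generator emulates — and what it does not

`simulate_latent_model()` draws orthonormal `U0`, `V0`, plants
`W0 = U0 diag(S0) V0'` with `S0 = s_profile * sqrt(M)`, adds i.i.d.
Gaussian noise (`noise_sd`, in Z-score units, default 0.1), and converts
entries back into association records (SE uniform below the value-filter
cap for the phenotype's kind, estimate `z*se`, p from the two-sided normal
tail). The `sqrt(M)` scaling keeps per-entry signal magnitude — and hence
signal-to-noise against per-entry noise — independent of the variant
count, so `s_profile = c(10, 5, 1)` means the same thing at any matrix
size. The default study condition used throughout the tests is
`N = 200, M = 500, k0 = 3, s_profile = c(10, 5, 1), noise_sd = 0.1`:
large enough for spectral gaps to be meaningful, small enough that the
whole suite runs in seconds-to-minutes.

The significance-based selection of real pipelines is emulated by masking
a `(1 - sparsity)` fraction of entries at random rather than by simulating
genotypes and running GWAS — the package's scope begins at summary
statistics. Consequently, when the pipeline's own value filter is applied
to synthetic records it genuinely filters on the simulated p-values, and
planted-structure recovery is assessed on the matrix built from all
emitted records (the mask *is* the selection). Noise is Gaussian because
that is the simplest model under which TSVD behavior is analyzable;
heavy-tailed effects, LD correlation between variants, case-control
imbalance, and winner's-curse selection are all real-data features the
generator does not model. Passing tests therefore demonstrate correctness
of the algebra and the planted-recovery behavior, not robustness to those
real-data pathologies.

`simulate_annotations()` plants disjoint blocks that each violate exactly
one QC rule, so every filter's removal count is known exactly; coding
variants are placed within 500 bp of their host gene's TSS (inside the
basal domain) so that enrichment can recover planted gene sets, and genes
are kept off chromosome 6 so domains never straddle the MHC exclusion.
`simulate_ontology()` draws background terms from the non-planted gene
pool when a term is planted; this keeps the planted signal identifiable
instead of letting background terms absorb the same host genes by chance.
Recovered-versus-planted components are matched greedily by absolute
cosine of variant singular vectors, in component order.

## Numerical choices and degenerate inputs

* Row standardization tolerance: rows with population variance below 1e-12
  are treated as constant and dropped.
* Orthonormality, normalization, and reconstruction identities are held to
  1e-8 in tests; the implementation typically achieves 1e-13.
* `p = 0` never occurs in generated data: normal-tail p-values are floored
  at the smallest positive double.
* Zero-coverage terms with nonzero hits are an error (inconsistent
  coordinates); zero-coverage terms with zero hits report fold 0, p 1.
* Empty ontologies yield empty results with a warning, not an error.
* All ranking ties (drivers, top variants, top terms) break
  lexicographically; all stochastic steps take explicit seeds.

## Reproducibility

Every pipeline run serializes its resolved configuration to
`config.json`, and every output table is stamped with the package version
and a hash of the scientific parameters (paths excluded, so the same
analysis in a different directory stamps identically). Two runs with the
same configuration and seed produce byte-identical tables; the test suite
asserts this end to end.

```{r example, eval = FALSE}
sim <- simulate_latent_model(seed = 1)
ann <- simulate_annotations(n_variants = 500, seed = 1)
z <- standardize_phenotype_rows(build_zscore_matrix(sim$associations))
d <- truncated_svd(z, 10)
head(variance_explained(d))
recovery_score(d, sim$truth)
```

## Known limitations

* The Gram-matrix TSVD is quadratic in the smaller axis; beyond roughly
  10^4 phenotypes an iterative solver would be preferable.
* The enrichment kernel implements the binomial region test only, not the
  companion gene-based hypergeometric test, and treats regions as
  single-base variant positions rather than LD blocks.
* Squared-cosine scores depend on the truncated basis (`K`); comparing
  them across runs requires equal `K`.
* The generator's independence assumptions (no LD, independent noise)
  make recovery easier than on real cohort data; planted-recovery results
  are upper bounds on real-data performance.
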