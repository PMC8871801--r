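---
title: "Mining co-significant SNP sets from voxelwise GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining co-significant SNP sets from voxelwise GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-marker GWAS asks, one SNP at a time, whether a variant is associated
with a phenotype. In imaging genetics the phenotype is not one number but a
brain map — here, a gray-matter-density value per voxel — and the scientific
object of interest is often not one SNP but a *set* of SNPs whose effects
co-occur across a region. `snpfim` casts that question as frequent itemset
mining: after a voxelwise GWAS, each voxel is a market-basket *transaction*
and each SNP significant at that voxel is an *item* in it. A set of SNPs
that is jointly significant across many voxels of, say, the hippocampus is a
frequent itemset, and the conditional co-occurrence of its members is an
association rule with a confidence.

The pipeline is: simulate or load data → per-(SNP, voxel) regression →
threshold into transactions → mine with FP-Growth or Eclat → derive rules →
assess which anatomical regions a SNP activates. Every stage is a package
function; the `analysis/` scripts in the repository are thin narrative
drivers over them.

## Voxelwise GWAS

For SNP $j$ and voxel $v$ the model is ordinary least squares

$$ y_v = \beta_0 + \beta_g \, g_j + X\gamma + \varepsilon, $$

with $g_j$ the 0/1/2 minor-allele dosage and $X$ covariates (age, education,
genotype principal components, ... — consumed as columns, never computed).
The entry of the p-value matrix is the two-sided p-value of $\beta_g$'s
t-statistic on $n - (\text{covariates} + 2)$ degrees of freedom. Two-sided
is the convention of the standard GWAS tools; dosage (additive) coding is
assumed.

Rather than fitting SNPs × voxels separate models, `run_vgwas()` residualizes
genotypes and phenotypes once against $[1, X]$ and then computes all
correlations in a single cross-product (the Frisch–Waugh–Lovell theorem
makes this exactly equivalent for $\beta_g$'s t-test). A 1784 × 49,900
problem is a few matrix products. Monomorphic SNPs carry no evidence and get
p = 1 with a warning; rank-deficient covariates are an error, not a silent
drop.

One subtlety worth knowing when reading results: all voxels share the same
subjects, so the per-voxel tests for a given SNP are strongly dependent.
A SNP that is by chance correlated with a strong multi-SNP signal in the
sample will be nominally significant at *many* of the signal's voxels at
once. This is faithful to real voxelwise GWAS, and it is why the synthetic
studies occasionally promote a non-planted SNP into the frequent set — the
mining layer is honest about what the association layer hands it.

Genotype QC is the usual Hardy–Weinberg equilibrium filter
(`hwe_filter()`, keep iff $p_{HW} \ge 10^{-6}$), implemented as the
1-df chi-square of observed genotype counts against the expectation from the
sample allele frequency. The chi-square (rather than the exact) test is
adequate at cohort-scale n and is documented as swappable.

## Transactions, support, thresholds

`build_transactions()` applies the indicator $p \le \alpha$ (inclusive — the
boundary counts, and the choice is pinned in tests to avoid `<`/`≤` drift)
with $\alpha = 0.05$ by default. Deliberately, **no multiple-testing
correction** is applied before transactionalization: recurrence across
thousands of voxels is itself the filter, and correcting first would empty
the baskets. Voxels with no significant SNP are kept as empty transactions
so that support rates always have the full ROI voxel count as denominator.

Support of an itemset is the number of transactions containing all of its
items; the support rate divides by `td_num`. The mining threshold $s$ is a
*rate*. Internally it is converted once to the minimal integer count $c$
with $c/\text{td\_num} \ge s$ under the same double-precision predicate used
everywhere else; every keep/drop decision then compares integer counts, so a
boundary case like $s = 0.6$ on 5 transactions is decided identically in
mining, support tables and tests.

## FP-Growth, Eclat, and the oracle

`fp_growth()` is the tree miner: items are sorted by descending support
(ties by identifier — the published pseudocode leaves ties open, and
determinism requires *some* rule), transactions are inserted into a prefix
tree whose per-item pointer chains let the algorithm assemble the
conditional pattern base of each item, build the conditional tree, and
recurse; trees that collapse to a single path are expanded by direct subset
enumeration. `eclat()` is the vertical miner: each item carries its
transaction-id set, and an extension's support is the size of the
intersection of tid-sets within an equivalence class. `apriori_oracle()` is
the deliberately naive level-wise miner kept as ground truth: the test suite
asserts all three return identical (itemset, support) collections on
hundreds of randomized databases, and an even more naive full-power-set
enumerator sits in the test helpers as a second, independent route.

Recursion depth is bounded by the number of frequent items on a path; at the
problem sizes this package targets (hundreds of frequent items, transactions
of tens of items) plain R recursion is nowhere near the interpreter's limit.
Very deep pattern spaces (thousands of co-frequent items) would need an
explicit stack; that is a known limitation, not a correctness issue.

Output ordering is fixed — (k, descending support rate, lexicographic
items) — so "top 5" tables are reproducible. Diffset-style Eclat
optimizations are omitted on purpose; plain intersection is what the
algorithm statement describes and is fast at this scale.

## Association rules

For a rule $A \to B$, $\text{confidence} = \text{support}(A \cup B) /
\text{support}(A)$ — the support of transactions containing *both* sides
over the antecedent's support (the standard semantics; the published
fraction pairs, e.g. $0.74/0.82 = 0.90$, confirm this reading).
`generate_rules()` recomputes every support on the transaction database
rather than trusting the mining output, emits all $(k-1) \to 1$ rules by
default (the full power set of antecedents is available behind
`policy = "all"` but is exponential), and *flags* rules below the confidence
threshold (default 0.8, the conventional "relatively high" cut) instead of
dropping them: the display column shows `--`, exactly how weak links are
reported in practice. Display rounding is half-up to 2 decimals and is
strictly a formatting concern — internal values are never rounded.
`rule_chain()` walks the prefix chain of an ordered itemset, the natural way
to read how a k-item set grew.

## ROI activation

`activated_rois()` implements the top-fraction criterion: within an ROI,
rank voxels by the SNP's per-voxel association strength, keep the top
`ceiling(top_frac * n)` (ceiling so tiny ROIs keep at least one voxel), and
declare the ROI activated iff all kept voxels are significant. The ranking
score is $-\log_{10}(p)$. This is a deliberate design surface: the criterion
is sometimes phrased as ranking voxels "by heritability", without a defined
per-voxel estimator; association strength is the only per-voxel,
per-SNP quantity this pipeline possesses, and with it the criterion is
monotone in both $\alpha$ and (for this ranking) `top_frac`. Ties break by
voxel identifier; the `<=`/`<` comparator is configurable with `<=` the
default, consistent with the transaction indicator.

## The synthetic-data generator

There is no public imaging-genetics cohort bundled here; the generator
stands in for one. It emulates exactly the features downstream stages
consume:

- **Genotypes** i.i.d. per SNP in Hardy–Weinberg proportions at chosen MAFs
  (default 0.3, the middle of the common-variant range). No linkage
  disequilibrium — LD-aware simulation is out of scope, so equivalence with
  LD-pruned real panels should not be assumed.
- **Effect blocks**: a set of SNPs × a set of voxels with an additive per-
  allele effect `beta`. Default `beta = 1.0` in residual-SD units with
  `noise_sd = 1` at n = 500: each planted (SNP, voxel) cell then has
  essentially unit power at $\alpha = 0.05$ even with the other block SNPs
  acting as extra noise, which is the regime where recovery *should* be
  expected of a correct implementation. No published effect-size scale
  exists for this design, so `beta` is an explicit free parameter.
- **Phenotypes**: block signal + covariate term + Gaussian noise. No spatial
  smoothness across voxels — passing tests say nothing about cluster-extent
  statistics on smooth maps.
- **Shortcut p-value matrices**: null cells Uniform(0,1), planted cells
  Uniform(0, $\alpha$). The mining layer only sees the thresholded
  indicator, so the simplest guaranteed-sub-threshold shape is the right
  one; a noncentral shape would add realism the consumer cannot observe.

One global seed is expanded into per-stage substreams (a fixed hash of the
stage name), so enlarging the voxel grid leaves the genotype draws
untouched — a property the tests assert. Every generator is bit-reproducible
under a fixed seed, and the RNG state of the caller is restored afterwards.

## Problem sizes and numerical choices

The bundled analysis uses 600 subjects × 100 SNPs × 1,183 voxels in four
regions (left/right hippocampus at the familiar ~280/~300-voxel scale, plus
two controls), with two overlapping 5-SNP blocks; the property suites use
databases up to 15 items × 60 transactions for three-way miner equivalence
(100 of them), 10,000 null pairs for p-value uniformity, and 20 replicates
of a 500-subject planted-recovery study. These sizes were chosen so each
claim is tested at a scale where its failure mode could actually appear
(e.g. miner disagreement needs deep, messy pattern spaces, not toy
baskets).

Numerical corner cases, and what the package does:

- p exactly at $\alpha$: included (indicator is $\le$).
- support rate exactly at $s$: included; decided on integer counts as above.
- Perfect fits ($|r| = 1$): p underflows to 0 rather than NaN.
- Monomorphic SNPs / constant phenotype columns: p = 1 (warning for SNPs).
- Adding a covariate orthogonal to genotype and phenotype leaves the
  estimate and residual sum of squares exactly unchanged but lowers the
  error degrees of freedom by one, so p moves by O(1/n); the test asserts
  near-invariance at n = 1000 rather than exact equality, which ordinary
  least squares does not provide.
- Empty antecedent support: rule undefined, rejected with an error.

## Known limitations

No MRI preprocessing, no NIfTI I/O (voxels are abstract columns plus an
external ROI map), no LD or epistasis analysis, no closed/maximal itemset
mining, no statistical significance testing of rules (confidence is a
descriptive conditional frequency, not a test), and no correction for the
strong dependence between voxel-level tests when interpreting support rates.
The package mines and reports patterns; causal or even associational claims
about individual SNPs still require the usual genetic follow-up.
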