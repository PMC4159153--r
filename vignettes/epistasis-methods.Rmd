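---
title: "Methods: pairwise epistasis discovery for quantitative traits"
author: "EpistasisScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise epistasis discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`EpistasisScan` implements a complete discovery workflow for pairwise
SNP–SNP interactions on a quantitative trait: quality control, polygenic
residualization (the GRAMMAR strategy), an exhaustive bit-packed pairwise
interaction scan with Bonferroni threshold derivation and local-interaction
classification, conditional/forward-selection model building with variance
accounting, and regulatory-enrichment statistics. This vignette records the
statistical model behind each stage, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does and
does not emulate, and the design decisions that were genuinely open.

# The analysis trait: GRAMMAR residuals

All association and interaction tests run against *environmental
residuals* of a polygenic mixed model rather than the raw trait. The model
is

$$ y = X\beta + g + e,\qquad g \sim N(0, \sigma_g^2 K),\qquad
   e \sim N(0, \sigma_e^2 I), $$

where $y$ is the rank-inverse-normal transformed trait
($\Phi^{-1}((r-0.5)/n)$ on ranks, ties averaged), $X$ contains the
covariates (sex, age, BMI, creatinine, treatment flag, centre) plus the
first 10 principal components of the kinship matrix, and $K$ is the
genomic relationship matrix: centred dosages scaled by
$\sqrt{2p(1-p)}$ per SNP, averaged over polymorphic markers
(Astle–Balding style; missing calls contribute zero after centring). The
PCs are eigenvectors of $K$ itself, not a separate SNP PCA, because both
objects derive from the same similarity matrix.

REML estimation is one-dimensional: after a single eigendecomposition
$K = U\Lambda U'$, the restricted likelihood is profiled over the total
variance and maximised over $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ by
Brent search on $[0, 1-10^{-6}]$ with tolerance $10^{-8}$; both interval
edges are checked explicitly because boundary optima ($h^2 = 0$) are
common. Fixed effects are GLS at the optimum and the residuals are

$$ \mathrm{pgresidualY} \;=\; y - X\hat\beta - \mathrm{BLUP}(g)
   \;=\; \hat\sigma_e^2 \hat V^{-1}(y - X\hat\beta). $$

Two degenerate cases are handled deliberately. If $K$ is the identity (or
omitted) every eigenvalue is 1 and the likelihood is flat in $h^2$; the
fit then short-circuits to ordinary least squares with $h^2 = 0$, which is
also the correct limiting semantics for the residuals. If the design is
rank-deficient the fit refuses rather than silently dropping columns.

The GRAMMAR strategy is known to be somewhat conservative for additive
single-SNP tests, increasingly so with strong structure and high
heritability. No deflation correction is applied here — the residuals are
used as-is, and the marginal scan's score test is exactly the OLS score
test when $\hat V \propto I$.

# Quality control

Per-SNP: fail if MAF $< 0.02$ (computed on called genotypes; a
monomorphic SNP has MAF 0 and fails, it is not an error), call rate
$< 0.95$, or Hardy–Weinberg $P < 10^{-10}$. The HWE test is a 1-df
chi-square of observed vs HWE-expected genotype counts without continuity
correction; at a $10^{-10}$ threshold the difference from the exact test
is immaterial, and the chi-square is auditable by hand. The exact
conditional test is available behind `hweExact = TRUE`.

Per-sample: fail on call rate $< 0.97$; on *unacceptably high*
heterozygosity, read as upper-tail only — one-sided z P-values of the
per-sample heterozygosity proportion, Benjamini–Hochberg controlled at
FDR 0.01; on age $< 18$, BMI $> 50$, or creatinine beyond 3 SD of the
cohort mean. Samples with missing covariates are recorded as
`unevaluable` and excluded.

Kinship-PC outliers: samples beyond `sdMult` SD on any of the first three
PC scores fail; after removal the PCs are recomputed once and the rule
re-applied. The multiplier has no published value; the default 6 is
conventional and conservative. QC is one pass in the order listed, not
iterated to convergence; on clean data the SNP and sample masks commute,
which the test suite checks.

# The pairwise scan

## Bit-plane engine

Each SNP is encoded as four bit planes over samples — genotype classes
0/1/2 and a called mask — packed into 64-bit words. For any pair, the
9-cell two-locus contingency table over pairwise-complete samples comes
from ANDing class planes and popcounting; per-cell trait sums and sums of
squares come from iterating set bits of the same AND words. Encoding is
lossless (`decodeBitwise(encodeBitwise(x))` restores the matrix) and the
plane popcounts equal the genotype counts by construction.

## Screening statistic

From the 9-cell summaries the screen computes

$$ F = \frac{(SS_{\text{cells}} - SS_{\text{main}})/df_{\text{int}}}
            {SS_{\text{within}}/(n - c)}, $$

where $SS_{\text{cells}}$ is the between-cell sum of squares,
$SS_{\text{main}}$ the explained sum of squares of the best two-locus
main-effect model (intercept + additive + dominance per locus, five
parameters, fitted to the cell means with cell-count weights),
$c$ the number of non-empty cells and
$df_{\text{int}} = c - \mathrm{rank}(\text{main design})$. The weighted
5×5 normal equations are solved by Gauss–Jordan elimination with full
pivoting; the pivot tolerance ($10^{-10}$ relative to the largest
diagonal) determines the rank, so empty or collinear cells reduce
$df_{\text{int}}$ instead of corrupting the statistic. Pairs whose
interaction degrees of freedom collapse to zero are skipped and counted.

Because a factor model is fully determined by its cell summaries, this
screening F equals the individual-level interaction F *exactly* whenever
screen and verification see the same samples — the suite asserts equality
to $10^{-10}$ on complete data and $|\Delta\log_{10}P| < 0.3$ under
missingness. The scan nevertheless verifies every emitted pair with an
exact factor-coded least-squares partial F test, and reports that
verification P as $P_{\text{int}}$; the screening P is retained for
audit. Full-model verification is mandated regardless of the screen's
quality, since screening statistics in this family are approximate and
treat pairs independently.

## Thresholds and categories

With $m$ scanned SNPs and $k$ marginal SNPs (single-SNP $P <$ 5e−08), the
Bonferroni thresholds are $0.05/(m(m-1)/2)$ for the full scan and
$0.05/((m-1)k)$ for pairs involving a marginal SNP ($k=0$ leaves the
latter undefined and flagged absent). Raw values drive comparisons;
reporting rounds to two significant figures. Local interactions are
same-chromosome pairs within 1 Mb — read *inclusively* at exactly
1 000 000 bp — with $P_{\text{int}} < 10^{-5}$, a conventional
permutation-derived level. Distances are reported in kb rounded half-up
to one decimal (half-up, not banker's rounding, to match how such tables
are conventionally printed). LD between pair members is composite
dosage $r^2$ (squared Pearson correlation of 0/1/2 dosages), which is
phase-free and matches array practice; missing genotypes are handled by
pairwise-complete deletion, mirroring the contingency construction. Pairs
are emitted with the lexicographically smaller SNP id first so output is
independent of input order.

# Model building

Conditional tests hold accepted terms in the model as fixed effects:
marginal SNPs enter the background *additive-only* (matching how a lead
SNP is conventionally conditioned on), pairs enter with full 9-cell
coding minus aliased columns. A marginal candidate is tested by a 1-df
partial F; a pair candidate by the interaction partial F over its own
main effects plus the background. Statistical independence is declared at
conditional $P < 0.05$, with no multiplicity correction inside the
selection loop — the selection rule is the quoted greedy procedure, not a
corrected one. Conditioning a term on itself (or any collinear
background) yields an absent P with reason `collinear`. Ties in the
minimum conditional P are broken by genomic order, which also makes the
path invariant to candidate input order.

Variance explained is defined on the residual-trait scale as
$\mathrm{Var}(X_{\text{terms}}\hat\beta)/\mathrm{Var}(y) \times 100$,
refitting the polygenic model (or OLS when no kinship is supplied) with
the terms as fixed effects and accumulating along the path; the exact
estimator behind published variance-explained columns is generally
unstated, so this definition is documented and used consistently,
including in the recovery tests. Replication of a discovery pair in a
second cohort is SNP-identity based: it requires both SNPs genotyped
there and $P_{\text{int}} < 0.05$ strictly; otherwise the record is NA.
The alternative effect-size-reduction criterion used by meta-analyses is
noted but not implemented.

# Regulatory enrichment

Enhancer enrichment uses the exact upper-tail binomial: with $n$ tagged
SNPs and background overlap frequency $f$ estimated from *all genotyped
QC-passed SNPs* (the array defines the genomic background, not the whole
genome), $\mathrm{expected} = nf$, $\mathrm{fold} =$ observed/expected
(reported to one decimal), $P = P(X \ge \text{obs})$. LD-expansion of the
tagged set (r² > 0.8 proxies) would require external reference
haplotypes, so the core statistic is self-contained and proxies are out
of scope. SNP-in-interval queries use half-open BED semantics through
IRanges.

Region binning is greedy left-to-right: open a region at the first
unassigned SNP, absorb all SNPs within 25 kb of that first SNP, close,
repeat; the span is $[\text{first}, \text{first}+25\,000)$. The exact
region-forming rule behind published region counts is not fully
specified; this greedy reading is one consistent choice and is asserted
only against itself. Chromatin interactions are counted for a region if
either anchor overlaps the ±100 kb window around the region midpoint,
each interaction at most once per region; the empirical rank of a focal
region is the fraction of regions with *strictly more* interactions.

# The synthetic-data generator

LD is produced by left-neighbour copying on a latent-uniform scale: each
haplotype carries a latent uniform refreshed at site $j$ with probability
$1-\exp(-\Delta\text{bp}/\text{ldDecayBp})$ (always at a chromosome
change), and the allele is (latent < $p_j$). This preserves each site's
drawn frequency exactly, gives monotone distance decay through one
auditable parameter, and is a stand-in — it is not a claim about any real
cohort's LD structure, and it produces no recombination hotspots,
demography or allele-frequency spectrum realism. Genotypes are sums of
two panel haplotypes; sib-pair families share parental haplotypes, and
the generator records the *realized* IBD count per pair (0/1/2) so tests
can compare estimated relatedness to its realized expectation rather
than the 0.25 pedigree average. Missingness is injected uniformly *after*
phenotype simulation so QC has work to do.

Phenotypes decompose as marginal (additive + dominance) effects, 3×3
epistatic lookups, covariate terms, a polygenic background and N(0,
σ<sub>e</sub>²) noise. The polygenic background is realised as a sum of
small random additive effects across the genotyped markers with total
variance $\sigma_g^2 = h^2_{\text{poly}}/(1-h^2_{\text{poly}})\sigma_e^2$
— distributionally equivalent to an abstract $N(0,\sigma_g^2 K)$ draw
given the genotypes, and necessary for REML recovery to be well-posed
(the estimated kinship must carry the planted signal). Epistatic effect
matrices can be centred against HWE genotype frequencies
(`centeredEpistasisMatrix`) so the planted interaction variance has a
closed form and marginal content is exactly zero; the XOR-like matrix
(corners and centre +1, edges −1) has zero marginal content at allele
frequency 0.5 and unit interaction variance. `plantedAdditiveEffect`
sizes an additive effect to a target variance fraction in closed form.
One master seed drives every stage through derived sub-seeds; identical
seeds give bit-identical cohorts and there is no hidden global RNG state
(the generator restores `.Random.seed`).

What passing tests on these cohorts do **not** show: robustness to
genotyping batch effects, platform-specific missingness patterns,
population admixture beyond simple frequency shifts, or real LD
architecture. They do show that every statistic computes what its formula
says, at the sample sizes stated below.

# Problem sizes and numerical tolerances

The validation suite uses cohorts of 2 000–9 000 samples and 40–1 000
SNPs: screening-vs-exact agreement on 1 000 random pairs with 5%
missingness at n = 2 000; interaction-test type-I error over 2 000 null
replicates at n = 2 000; planted XOR-pair recovery over 50 seeded scans
(n = 4 000, 500 SNPs, ~1.5% interaction variance); forward-selection
recovery of a 3-marginal + 1-pair model over 100 replicates at n = 6 000;
REML h² recovery at n = 4 000 with 1 000 markers; variance-explained
recovery of a 4.5% SNP at n = 9 000. These sizes were chosen so each
property is measured with comfortable Monte-Carlo margin while the whole
suite stays desk-scale. Key tolerances: screening equals the exact test
to $10^{-10}$ on complete data; REML convergence $10^{-8}$; rank
decisions at $10^{-10}$ relative pivot tolerance.

# Module-to-interface map

The analysis stages are exposed as plain R functions plus the
`runPipeline()` driver (QC → residualization → scans → selection →
enrichment, each stage writing a TSV artifact and the log recording the
thresholds actually used, including the derived Bonferroni values).
Position columns in outputs are 1-based; BED/BEDPE intervals are 0-based
half-open; conversions are centralised in the IO helpers. PLINK
bed/bim/fam is read and written directly (standard 2-bit SNP-major
dialect, A1 treated as the counted alternate allele by default and
flaggable) since no suitable reader is available among the package's
dependencies. Sex-stratified scanning is a configuration flag of the same
pipeline, not separate code.

# Known limitations

- The screening and verification tests assume a quantitative trait;
  binary traits and X-chromosome models are out of scope.
- Composite LD r² is reported; EM haplotype-frequency r² is not the
  default (phase-free arrays rarely warrant it).
- Variance explained under GLS refitting is not guaranteed monotone along
  a path in pathological designs; the reported cumulative column is
  clamped to monotone and agrees with OLS accounting on identity
  kinship.
- The enrichment background is the genotyping array, so enrichment
  conclusions inherit the array's ascertainment.
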