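---
title: "Expected and observed genomic relationships in line crosses"
author: "crossgrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected and observed genomic relationships in line crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgrm)
```

## The problem

Composite populations — advanced intercross lines, synthetic lines,
selection experiments — are founded by a handful of individuals drawn from
two or more genetically distinct lines.  Pedigree relationship matrices that
treat these founders as unrelated and non-inbred mis-scale the genetic
variance of the intercross: loci fixed for alternative alleles in the
founder lines contribute no variance in the F1 but start segregating in the
F2 (the *segregation variance*), and no pedigree can know how much of that
there is.  When all founders are genotyped, their line allele frequencies
determine the expected genomic relationship of every descendant, and the
genetic variance can be defined on a meaningful scale: the variance among
unrelated, non-inbred individuals of an idealized infinitely large F2.

`crossgrm` builds this machinery for autosomes and for the X chromosome
(where males are hemizygous and the approach to allele-frequency equilibrium
is oscillatory rather than immediate).

## Model

For marker $i$ let $p_{i\ell}$ be the counted-allele frequency in founder
line $\ell$, and let $\bar p_i = \sum_\ell w_\ell\, p_{i\ell}$ be the
composite frequency under line contributions $w$ (uniform by default: the
frequency the intercross approaches when lines contribute equally).  All
relationships are scaled by the expected heterozygosity

$$S = 2 \sum_i \bar p_i (1 - \bar p_i).$$

**Observed founder matrix.**  Gene counts are centered at $2\bar p_i$
(autosomes; X females) or $\bar p_i$ (hemizygous X males) into $Z_0$, and
$G_0 = Z_0 Z_0^\top / S$.  This is the familiar frequency-centered genomic
relationship matrix, except that centering uses the composite frequency
$\bar p$, not the current-sample frequency — so $G_0$ expresses
relationships relative to the idealized F2, and founder self-relationships
well above one simply record their elevated homozygosity relative to that
reference.

**Gamete moments.**  A gamete drawn at random from line $\ell$ has expected
squared centered value (its *self-relationship*)

$$d_\ell = \frac{1}{S}\sum_i \big[p_{i\ell}(1-p_{i\ell}) +
(p_{i\ell}-\bar p_i)^2\big],$$

and two gametes from lines $\ell$ and $m$ have expected cross-product

$$r_{\ell m} = \frac{1}{S}\sum_i (p_{i\ell}-\bar p_i)(p_{im}-\bar p_i).$$

For two lines with uniform weights, $d_A + d_B = 1$ and
$r_{AA} = r_{BB} = -r_{AB}$ hold identically; more generally
$\sum_\ell w_\ell\, r_{\ell m} = 0$ for every $m$.  These identities are
asserted in the test suite over random frequency draws.

**Expected founder matrix.**  Autosomal entries follow from summing gamete
moments over the 2×2 gametes of a pair: self $2d_\ell + 2r_{\ell\ell}$,
same-line pair $4r_{\ell\ell}$, between-line pair $4r_{\ell m}$.  On the X
the eight sex/line cases are tabulated: male self $d_\ell$, female self
$2d_\ell + 2r_{\ell\ell}$, male–male $r_{\ell m}$, female–female
$4r_{\ell\ell}$ (same line) or $r_{\ell\ell} + r_{mm} + 2r_{\ell m}$
(different lines), male–female $2r_{\ell m}$.

One subtlety deserves a note.  The tabulated between-line female–female
form, $r_{\ell\ell} + r_{mm} + 2r_{\ell m}$, is the value for two
individuals each carrying one gamete from each line; for two purebred
females the binomial-sampling average would instead be $4 r_{\ell m}$.  In
the founder designs this method targets (all founders of a line of one sex,
as in a males-of-line-A × females-of-line-B cross) the case never occurs,
and no result in this package depends on it.  We keep the tabulated form;
the Monte-Carlo cross-validation tests use founder layouts in which the
case does not arise, mirroring the designs the method is used for.

**Extension through the pedigree.**  The expected matrix
$\tilde A$ for the full pedigree follows by a modified tabular method in
topological order.  With $s_{\mathrm{sire}}, s_{\mathrm{dam}}$ the expected
self-relationships of the gametes an individual receives:

* autosomes: $g_{kk} = s_{\mathrm{sire}} + s_{\mathrm{dam}} +
  \tfrac12 g_{\mathrm{sire,dam}}$ and
  $g_{k_1 k_2} = \tfrac12 (g_{\mathrm{sire_1},k_2} +
  g_{\mathrm{dam_1},k_2})$;
* X, females: $g_{kk} = s_{\mathrm{sire}} + s_{\mathrm{dam}} +
  g_{\mathrm{sire,dam}}$ and $g_{k_1 k_2} = g_{\mathrm{sire_1},k_2} +
  \tfrac12 g_{\mathrm{dam_1},k_2}$ (a sire transmits his whole X);
* X, males: $g_{kk} = s_{\mathrm{dam}}$ and
  $g_{k_1 k_2} = \tfrac12 g_{\mathrm{dam_1},k_2}$.

The $s$-terms are computed as $s = \sum_\ell f_\ell\, d_\ell$, where $f$ is
the *line composition* of the transmitted gamete: founders transmit their
line with certainty; autosomal compositions average the parents; on the X a
male passes on his maternal composition unchanged while a female averages
her sire's X and her dam's transmitted X.  This rule is exact by linearity
of per-locus expectations, reproduces the stated F1 and F2 values
($s = d_\ell$ for a line-$\ell$ founder's gamete, $s = \tfrac12(d_A + d_B)
= \tfrac12$ from the F2 on in a balanced two-line cross), and extends to
any number of generations, lines and weights.  On the X it makes
$s$ oscillate over early generations — male compositions approach the
$(1/3, 2/3)$ asymptote of a males-of-A × females-of-B cross with halving,
sign-alternating deviations — which is exactly the oscillatory
equilibration that X-linked allele frequencies show when the founding sexes
come from different lines.

**Conditional extension for observed seeds.**  When the recursion is seeded
with the *observed* founder matrix the propagated object is the expectation
of the realized GRM conditional on the founder genotypes, and the
$s$-terms must be conditional too: a founder's realized value is the mean
squared centered value of the alleles it actually carries (its single X
allele, for a hemizygous male), and the same ½-averaging recursion
propagates these values ([founder_gamete_self()], [gamete_self_path()],
wrapped by [conditional_extension()]).  Using the unconditional moment-based
$s$-terms here would bias every diagonal, which the gene-drop oracle
detects immediately; under line-wise Hardy–Weinberg resampling the realized
values average back to $d_\ell$, recovering the unconditional recursion.

**Infinite-F2 reference and segregation variance.**  An F2 individual
carries two line-A gametes, one of each, or two line-B gametes with
probabilities $(\tfrac14, \tfrac12, \tfrac14)$.  Averaging the resulting
self-relationships gives $d_A + d_B = 1$; averaging the nine pairwise
combinations gives $r_{AA} + r_{BB} + 2r_{AB} = 0$.  The reference
population is therefore unrelated and non-inbred by construction, and the
proportion of the F2 genetic variance that is segregation variance is
$-2 r_{AB}$ — from 0 (identical lines) to 1 (lines fixed for opposite
alleles).

**Combining with observed genotypes.**  Observed founder relationships
deviate from their expectation (e.g., excess heterozygosity relative to
within-line Hardy–Weinberg).  The single-step combination

$$H^{-1} = \tilde A^{-1} +
\begin{bmatrix} G_0^{-1} - E(G_0)^{-1} & 0 \\ 0 & 0 \end{bmatrix}$$

corrects the founder block.  $G_0$ is often singular — with in-sample
composite-frequency centering the columns of $Z_0$ sum to zero, so an
$f$-founder matrix has rank at most $f-1$ even before any duplicated
genotypes — and is therefore blended first:
$G_0^{BLD} = \alpha G_0 + (1-\alpha) E(G_0)$ with $\alpha = 0.98$ by
default.  Note that blending cannot rescue *fully* inbred opposite lines:
there $d_\ell = r_{\ell\ell}$, the expected matrix itself has rank equal to
the number of lines, and the combined inverse does not exist; the pipeline
either raises a named error (default) or records the singularity and skips
the H stage (`on_singular_h = "skip"`).

Variance components estimated with related founders are rescaled by

$$D_k = \frac{\sum_i g_0(i,i)}{f} - \frac{\sum_i \sum_j g_0(i,j)}{f^2},$$

the mean founder self-relationship minus the mean of all $f^2$ founder
block elements, computed from the blended block by default.

## The gene-drop oracle

`gene_drop_grm()` transmits founder alleles through the pedigree locus by
locus (unlinked loci, exactly as the expectations assume) and averages the
realized relationship matrices.  Two founder sources back two different
oracles: `"hwe"` redraws founder genotypes from the line frequencies each
replicate and must average to $\tilde A$; `"observed"` keeps the genotypes
fixed and must average to the conditional extension.  Replicates use
seed-plus-index streams so any subset is reproducible.

Calibration matters when comparing a 200 × 200 mean matrix elementwise:
every element shares each replicate's draws, so Monte-Carlo errors carry a
strongly correlated common component (dominated by the founder resampling),
and the whole matrix can sit a marginal standard error high or low by
chance.  The test suite therefore checks (a) the marginal three-SE
agreement rate, (b) the common mode against its own standard error computed
from per-replicate grand means (`rep_means` in the result), and (c) a
Bonferroni-level cap on the largest common-mode-centered deviation.  A
small systematic error — a wrong coefficient, a biased $s$-term — moves all
three; pure Monte-Carlo noise does not.

## The fixture generator

`make_fixture()` creates the study conditions tests run under: $L$ founder
lines with line-specific frequency spectra (fully inbred lines fixed for
opposite alleles, uniform or beta spectra, or supplied matrices), founder
genotypes drawn in line-specific Hardy–Weinberg proportions with single X
alleles for males, and intercross pedigrees.  Defaults mirror a small
selection-experiment design: four males of one line crossed to four females
of the other, litters of eight with alternating sexes, six intercross
generations with rotational full-sib inter-mating — roughly 200 individuals.
Templates: `"trio"` (minimal), `"f2"`, `"ail"` (full-sib or random
inter-mating; one family carried forward), and `"tree"`, a non-inbred
crossing design in which mates never share an ancestor, used to isolate the
generation profile of self-relationships from inbreeding (autosomal means
are exactly 1 from the F2 on; X means show the pure oscillation).

What the generator does *not* emulate: linkage (loci are unlinked here and
in the expectations — both sides of every oracle comparison share this
assumption, so the tests validate the relationship algebra, not robustness
to LD), selection, litter-size standardization, genotyping error, and
missing data beyond the reader's line-mean imputation option.  Passing
tests show the implementation computes the model's quantities correctly;
they do not show the model captures everything about a real intercross.

## Numerical choices

* Sums over markers use R's long-double accumulators (`sum`, `rowSums`,
  `tcrossprod`), which keeps the two-line identities at or below
  $10^{-12}$ relative error for the marker counts in scope (up to
  $10^6$).
* Positive semi-definiteness is asserted with a relative eigenvalue
  tolerance of $10^{-8}$; the numerical rank uses the same relative
  threshold (none is stated for the original analyses).
* Inversions use a symmetric (Cholesky) factorization after explicit
  symmetrization, guarded by an exact condition-number threshold of
  $10^{12}$; a singular observed matrix produces an error naming blending
  as the remedy.
* The tabular recursions process individuals one at a time in topological
  order; relationships between two individuals entering in the same
  generation are resolved by the earlier-processed one already being in the
  matrix.  The apparently asymmetric X rule for females is applied to the
  new individual's row and mirrored, which keeps the matrix symmetric to
  machine precision.
* Unknown parents are allowed only for founders; half-known parent pairs,
  selfing, unknown sex and duplicate ids are rejected rather than guessed.
  Generation labels are informational — every recursion uses topological
  order.
* Monomorphic-across-founders markers are dropped at load time with a
  logged count: with $\bar p_i \in \{0, 1\}$ they contribute nothing to
  any sum, so results are unchanged and the polymorphic marker counts
  become explicit.
* The counted allele is the first-listed allele per marker.  Relationship
  matrices are invariant to that choice (re-encoding maps $c \to
  \mathrm{ploidy} - c$ and the centering frequency to $1 - \bar p$);
  reported frequencies are not, which is why the convention is documented.

## Problem sizes

The shipped tests run the oracle comparisons on a two-line,
150-marker (110 autosomal, 40 X), six-generation advanced-intercross
fixture of about 200 individuals with 2000 gene-drop replicates per
scenario, and the analytic identities on fifty random frequency draws per
criterion — sizes at which the whole suite completes in about a minute on a
single core while holding Monte-Carlo standard errors small enough for the
three-SE checks to bite.

## Limitations

* No REML or mixed-model solving: the package produces the relationship
  matrices (and $H^{-1}$ in solver-ready triplet form) that an external
  mixed-model package consumes, plus the $D_k$ factor to rescale the
  resulting variance components.
* No within-line identity-by-descent estimation: founder genotypes are
  treated as the complete allele inventory of the composite population.
* No linkage: expectations and simulator both assume unlinked loci.
* A sparse closed-form inverse of $\tilde A$ is not provided; inversion is
  numeric, which bounds practical pedigree sizes to what a dense symmetric
  factorization can handle.
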