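# crossgrm

Genomic relationship matrices for pedigreed intercross populations founded
by a small number of genotyped individuals from two or more lines — for
autosomes and for the X chromosome with hemizygous males.

## The problem

Advanced intercross lines, synthetic lines and selection experiments are
founded by a handful of animals from genetically distinct lines.  Treating
those founders as unrelated mis-scales every downstream genetic analysis,
because loci fixed for alternative alleles in the founder lines contribute
*segregation variance* from the F2 generation on — variance that pedigree
relationships cannot see.  When the founders are genotyped, their line
allele frequencies determine the expected genomic relationship of every
descendant, putting the genetic variance on the scale of an idealized,
unrelated, non-inbred F2 population.

`crossgrm` is for quantitative geneticists analyzing such populations: it
produces the observed founder relationship matrix, its analytic
expectation, the pedigree-propagated expectation for all descendants, and a
solver-ready combined inverse for mixed models.

## The method in brief

With line frequencies `p[l,i]` and composite frequency
`pbar[i] = sum_l w[l] p[l,i]` (uniform line weights by default), scaled by
`S = 2 * sum_i pbar[i](1 - pbar[i])`:

* **Observed founder matrix** `G0 = Z0 Z0' / S`, where `Z0` holds gene
  counts centered at `2*pbar` (autosomes, X females) or `pbar` (X males).
* **Gamete moments** `d[l] = (1/S) sum_i [p(1-p) + (p - pbar)^2]` and
  `r[l,m] = (1/S) sum_i (p[l]-pbar)(p[m]-pbar)` give the **expected founder
  matrix** `E(G0)` (autosomal self `2d + 2r`, same-line `4r[l,l]`,
  between-line `4r[l,m]`; eight tabulated sex/line cases on the X).
* A **modified tabular method** extends `E(G0)` (or `G0`) through the
  pedigree into the expected relationship matrix `Ã`, with gamete
  self-relationship terms that follow each individual's expected line
  composition — on the X these oscillate toward equilibrium across early
  generations.
* For two lines, the proportion of genetic variance that is segregation
  variance is `-2 r[A,B]`; the F2 reference population has mean
  self-relationship exactly 1 and mean pairwise relationship exactly 0.
* **Single-step combination**: `H^-1 = Ã^-1 + [G0^-1 - E(G0)^-1]` on the
  founder block, with blending `0.98 G0 + 0.02 E(G0)` to restore
  invertibility, and the `Dk` factor (mean founder self-relationship minus
  mean founder-block element) to rescale estimated variance components.
* A **gene-drop simulator** (observed or Hardy–Weinberg-resampled founder
  alleles) serves as a Monte-Carlo oracle for all of the above, and a
  **fixture generator** builds synthetic founder lines and intercross
  pedigrees for testing without any external data.

## Worked example

```r
library(crossgrm)

# two founder lines, 4 males of line A x 4 females of line B, six
# intercross generations, ~200 individuals
fix <- make_fixture(freq_model = "beta", beta_shape = c(0.4, 0.4),
                    markers = c(autosomal = 200, x = 40),
                    template = "ail", generations = 6, seed = 42)
ped   <- fix$pedigree
g     <- fix$genotypes
freqs <- line_frequencies(g)

mom <- gametic_moments(freqs, "autosomal")
mom
#> <gametic_moments> partition=autosomal, 200 markers, S=69.4609
#> d: A=0.496963, B=0.503037
#> r:
#>           A         B
#> A  0.207007 -0.207007
#> B -0.207007  0.207007

f2_reference_summary(mom)$segregation_proportion
#> [1] 0.4140137
```

`d_A + d_B = 1` and `r_AA = -r_AB` are the two-line identities; about 41%
of the F2 genetic variance of this fixture is segregation variance
(`-2 r_AB`).

```r
g0 <- observed_grm(g, freqs, "autosomal")
g0
#> <cross_grm> 8 x 8, partition=autosomal, kind=observed
#>         Am1     Am2     Am3     Am4     Bf1     Bf2
#> Am1  1.3076  0.6544  0.6166  0.7443 -0.7277 -0.8069
#> Am2  0.6544  1.3400  0.6112  0.7102 -0.8915 -0.8411
#> ...
grm_rank(g0)
#> [1] 7
```

Founder self-relationships sit well above 1 (homozygosity relative to the
F2 reference); between-line relationships are strongly negative.  With
in-sample composite-frequency centering the columns of `Z0` sum to zero,
so the 8-founder matrix has rank 7 and needs blending before inversion.

```r
e0     <- expected_founder_grm(ped, mom)
atilde <- extend_autosomal(ped, e0, mom)
mean(diag(atilde)[fix$pedigree$generation == 2])
#> [1] 1.146135   # F2 mean self-relationship: 1 + inbreeding from F1 full-sib mating

h <- build_h_inverse(atilde, blend_grm(g0, e0, 0.98), e0)
dk_correction(blend_grm(g0, e0, 0.98))
#> [1] 1.343096   # multiply estimated genetic variances by this factor
```

`h$hinv` is the pedigree-sized combined inverse, founders first, ready for
mixed-model software that accepts user-defined inverse covariance
structures (`write_grm_triplet()` emits the conventional lower-triangle
triplet text).  The same pipeline runs for the X chromosome via
`extend_x()`, and end to end from files via `run_pipeline()` or the CLI:

```sh
Rscript inst/cli/crossgrm.R run --pedigree ped.csv --genotypes geno.csv --out results/
```

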