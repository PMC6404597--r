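# Modified tabular method: propagates expected founder relationships through
# the pedigree.  The gamete self-relationship an individual transmits is the
# line-composition-weighted average of the per-line gamete moments d, exact
# by linearity of per-locus expectations.

#' Expected self-relationship of transmitted gametes
#'
#' For every individual, `s = sum(f * d)` where `f` is the line composition
#' of the gamete the individual transmits ([line_composition()]) and `d` the
#' per-line gamete self-relationship moments.  In a balanced two-line cross
#' the autosomal `s` is `d[l]` for a founder of line `l` and exactly 0.5 for
#' every individual from the F1 onward (so every F2 gamete has `s = 0.5`).
#'
#' @param lc output of [line_composition()].
#' @param moments a `gametic_moments`.
#' @return named numeric vector of `s` per individual, for the moments'
#'   partition.
#' @export
gamete_self <- function(lc, moments) {
  part <- moments$partition
  f <- lc[[if (part == "x") "x" else "autosomal"]]
  if (!all(colnames(f) %in% names(moments$d)))
    stop("line_mismatch_between_composition_and_moments")
  as.numeric(f %*% moments$d[colnames(f)])
}

#' Gamete self-relationships of founders from their observed genotypes
#'
#' Conditional counterpart of the moment-based values: for each founder, the
#' realized expected self-relationship of a transmitted gamete, `(1/S) *
#' sum_i mean((a - pbar_i)^2)` over the founder's carried alleles `a` at
#' locus i (a hemizygous male's single X allele enters alone).  Under
#' line-wise Hardy-Weinberg resampling these average to the line moments
#' `d`.
#'
#' @param g a [founder_geno()].
#' @param freqs a `line_freqs`.
#' @param partition `"autosomal"` or `"x"`.
#' @return named numeric vector over founders.
#' @export
founder_gamete_self <- function(g, freqs, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  sel <- g$partition == partition
  if (!any(sel)) stop("no_markers_in_partition: ", partition)
  cnt <- g$counts[, sel, drop = FALSE]
  pbar <- freqs[[partition]]$pbar
  S <- 2 * sum(pbar * (1 - pbar))
  if (S <= 0) stop("zero_heterozygosity_scale")
  n <- nrow(cnt)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (partition == "x" && g$sex[i] == "M") {
      out[i] <- sum((cnt[i, ] - pbar)^2) / S
    } else {
      # mean squared centered allele over the two carried alleles:
      # c=2 -> (1-pbar)^2; c=1 -> ((1-pbar)^2 + pbar^2)/2; c=0 -> pbar^2
      c2 <- cnt[i, ] == 2; c1 <- cnt[i, ] == 1
      v <- pbar^2
      v[c2] <- (1 - pbar[c2])^2
      v[c1] <- ((1 - pbar[c1])^2 + pbar[c1]^2) / 2
      out[i] <- sum(v) / S
    }
  }
  stats::setNames(out, rownames(cnt))
}

#' Propagate gamete self-relationships through the pedigree
#'
#' Linear recursion on transmitted gametes: autosomal `s_k` of a non-founder
#' is `(s_sire + s_dam)/2`; on the X a male transmits his maternal gamete
#' (`s_k = s_dam`) and a female averages her sire's X and her dam's
#' transmitted X (`s_k = (s_sire + s_dam)/2`).  With founder values equal to
#' the line moments `d` this reproduces the line-composition rule exactly;
#' with founder values from [founder_gamete_self()] it yields the
#' conditional terms used when seeding the tabular method with an observed
#' founder matrix.
#'
#' @param ped a `cross_pedigree`.
#' @param founder_s named vector of founder gamete self-relationships.
#' @param partition `"autosomal"` or `"x"`.
#' @return named numeric vector of `s` for every individual in pedigree
#'   order.
#' @export
gamete_self_path <- function(ped, founder_s, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  stopifnot(inherits(ped, "cross_pedigree"))
  fid <- founder_ids(ped)
  if (!all(fid %in% names(founder_s)))
    stop("founder_s_missing_ids")
  ids <- ped$id
  sire_i <- match(ped$sire, ids)
  dam_i  <- match(ped$dam, ids)
  s <- numeric(nrow(ped))
  for (k in seq_len(nrow(ped))) {
    if (is.na(sire_i[k])) {
      s[k] <- founder_s[[ids[k]]]
    } else if (partition == "autosomal") {
      s[k] <- 0.5 * (s[sire_i[k]] + s[dam_i[k]])
    } else {
      s[k] <- if (ped$sex[k] == "M") s[dam_i[k]]
              else 0.5 * (s[sire_i[k]] + s[dam_i[k]])
    }
  }
  stats::setNames(s, ids)
}

.check_seed <- function(ped, seed) {
  fid <- founder_ids(ped)
  if (!identical(rownames(seed), fid) || !identical(colnames(seed), fid))
    stop("seed_label_mismatch: seed must cover founders in pedigree order")
}

#' Extend founder relationships through the pedigree (autosomes)
#'
#' The modified tabular method for autosomes.  Founders keep their seed
#' relationships; each non-founder `k` gets diagonal
#' `s_sire + s_dam + g(sire,dam)/2` (the self-relationships of the two
#' parental gametes plus half the parents' relationship) and off-diagonals
#' `(g(sire,k2) + g(dam,k2))/2` against every previously processed
#' individual.  Seeded with the expected founder matrix this yields the
#' expected genomic relationship matrix; seeded with an observed matrix it
#' yields the conditional expectation given observed founder genotypes.
#'
#' @param ped a `cross_pedigree`.
#' @param seed founder `cross_grm` (expected, observed or blended), ordered
#'   as `founder_ids(ped)`.
#' @param moments autosomal `gametic_moments`.
#' @param lc output of [line_composition()] (computed if `NULL`).
#' @param s optional per-individual gamete self-relationships in pedigree
#'   order (e.g. from [gamete_self_path()] with observed founder values when
#'   seeding with an observed matrix); default: the moment-based
#'   line-composition values.
#' @return pedigree-sized `cross_grm` of kind `"expected-pedigree"`, rows in
#'   pedigree (topological) order.
#' @export
extend_autosomal <- function(ped, seed, moments, lc = NULL, s = NULL) {
  stopifnot(inherits(ped, "cross_pedigree"))
  if (moments$partition != "autosomal")
    stop("moments_partition_mismatch: need autosomal moments")
  .check_seed(ped, seed)
  if (is.null(s)) {
    if (is.null(lc)) lc <- line_composition(ped)
    s <- gamete_self(lc, moments)
  }
  n <- nrow(ped)
  ids <- ped$id
  sire_i <- match(ped$sire, ids)
  dam_i  <- match(ped$dam, ids)
  g <- matrix(0, n, n, dimnames = list(ids, ids))
  f_idx <- match(founder_ids(ped), ids)
  g[f_idx, f_idx] <- unclass(seed)
  for (k in seq_len(n)) {
    si <- sire_i[k]; di <- dam_i[k]
    if (is.na(si)) next  # founder: seeded above
    prev <- seq_len(k - 1)
    if (length(prev) > 0) {
      row <- 0.5 * (g[si, prev] + g[di, prev])
      g[k, prev] <- row
      g[prev, k] <- row
    }
    g[k, k] <- s[si] + s[di] + 0.5 * g[si, di]
  }
  .new_grm(g, "autosomal", "expected-pedigree")
}

#' Extend founder relationships through the pedigree (X chromosome)
#'
#' The X-chromosomal tabular recursion with hemizygous males.  Females:
#' diagonal `s_sire + s_dam + g(sire,dam)` and off-diagonal
#' `g(sire,k2) + g(dam,k2)/2` (the sire transmits his whole X, the dam one of
#' two).  Males: diagonal `s_dam` (the self-relationship of the maternal
#' gamete) and off-diagonal `g(dam,k2)/2`.  The `s` terms follow male and
#' female line compositions, so they fluctuate over early generations and
#' converge to the classical value 0.5 only when line frequencies are equal.
#'
#' @inheritParams extend_autosomal
#' @param moments X-partition `gametic_moments`.
#' @return pedigree-sized `cross_grm` of kind `"expected-pedigree"`.
#' @export
extend_x <- function(ped, seed, moments, lc = NULL, s = NULL) {
  stopifnot(inherits(ped, "cross_pedigree"))
  if (moments$partition != "x")
    stop("moments_partition_mismatch: need X moments")
  .check_seed(ped, seed)
  if (is.null(s)) {
    if (is.null(lc)) lc <- line_composition(ped)
    s <- gamete_self(lc, moments)  # uses X-context composition
  }
  n <- nrow(ped)
  ids <- ped$id
  sire_i <- match(ped$sire, ids)
  dam_i  <- match(ped$dam, ids)
  g <- matrix(0, n, n, dimnames = list(ids, ids))
  f_idx <- match(founder_ids(ped), ids)
  g[f_idx, f_idx] <- unclass(seed)
  for (k in seq_len(n)) {
    si <- sire_i[k]; di <- dam_i[k]
    if (is.na(si)) next
    prev <- seq_len(k - 1)
    if (ped$sex[k] == "F") {
      if (length(prev) > 0) {
        row <- g[si, prev] + 0.5 * g[di, prev]
        g[k, prev] <- row
        g[prev, k] <- row
      }
      g[k, k] <- s[si] + s[di] + g[si, di]
    } else {
      if (length(prev) > 0) {
        row <- 0.5 * g[di, prev]
        g[k, prev] <- row
        g[prev, k] <- row
      }
      g[k, k] <- s[di]
    }
  }
  .new_grm(g, "x", "expected-pedigree")
}

#' Conditional tabular extension seeded with the observed founder matrix
#'
#' Extends the observed (or blended) founder relationships through the
#' pedigree, using gamete self-relationship terms computed from the actual
#' founder genotypes ([founder_gamete_self()] propagated by
#' [gamete_self_path()]).  The result is the expectation of the realized
#' genomic relationship matrix conditional on the founder genotypes, i.e.
#' the analytic counterpart of a gene-drop average with fixed founders.
#'
#' @param ped a `cross_pedigree`.
#' @param g a [founder_geno()].
#' @param freqs a `line_freqs`.
#' @param partition `"autosomal"` or `"x"`.
#' @param seed founder `cross_grm` to propagate; default the observed matrix.
#' @return pedigree-sized `cross_grm`.
#' @export
conditional_extension <- function(ped, g, freqs,
                                  partition = c("autosomal", "x"),
                                  seed = NULL) {
  partition <- match.arg(partition)
  if (is.null(seed)) seed <- observed_grm(g, freqs, partition)
  mom <- gametic_moments(freqs, partition)
  s <- gamete_self_path(ped, founder_gamete_self(g, freqs, partition),
                        partition)
  if (partition == "x") extend_x(ped, seed, mom, s = s)
  else extend_autosomal(ped, seed, mom, s = s)
}

#' Reference summary for an infinitely large F2 population
#'
#' For a two-line cross with uniform weights: the mean self-relationship of
#' an F2 individual (`d[A] + d[B]`, equal to 1), the HWE-weighted nine-case
#' mean pairwise covariance between two F2 individuals (0), and the
#' proportion of additive genetic variance that is segregation variance,
#' `-2 * r[A,B]`.
#'
#' @param moments a two-line `gametic_moments` with uniform weights.
#' @return list with `mean_self`, `mean_pairwise`, `segregation_proportion`.
#' @export
f2_reference_summary <- function(moments) {
  stopifnot(inherits(moments, "gametic_moments"))
  if (length(moments$d) != 2)
    stop("f2_summary_requires_two_lines")
  if (max(abs(moments$weights - 0.5)) > 1e-12)
    stop("f2_summary_requires_uniform_weights")
  d <- moments$d; r <- moments$r
  A <- 1; B <- 2
  mean_self <- 0.25 * (2 * d[[A]] + 2 * r[A, A]) +
               0.25 * (2 * d[[B]] + 2 * r[B, B]) +
               0.50 * (d[[A]] + d[[B]] + 2 * r[A, B])
  # nine ordered gamete-combination cases with weights (1,2,1)/4 x (1,2,1)/4;
  # each case sums r over the four gamete pairs, e.g. AA x AB = 2r_AA + 2r_AB
  mean_pairwise <-
    (1 / 16) * 4 * r[A, A] +
    (2 / 16) * (2 * r[A, A] + 2 * r[A, B]) +
    (1 / 16) * 4 * r[A, B] +
    (2 / 16) * (2 * r[A, A] + 2 * r[A, B]) +
    (4 / 16) * (r[A, A] + r[B, B] + 2 * r[A, B]) +
    (2 / 16) * (2 * r[B, B] + 2 * r[A, B]) +
    (1 / 16) * 4 * r[A, B] +
    (2 / 16) * (2 * r[A, B] + 2 * r[B, B]) +
    (1 / 16) * 4 * r[B, B]
  list(mean_self = as.numeric(mean_self),
       mean_pairwise = as.numeric(mean_pairwise),
       segregation_proportion = as.numeric(-2 * r[A, B]))
}
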