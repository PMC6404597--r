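# Expected founder relationships E(G0) under line-specific Hardy-Weinberg
# sampling of founder alleles.  Autosomal: self 2d_l + 2r_ll, same-line pair
# 4r_ll, between-line pair 4r_lm.  X: eight cases depending on the sexes and
# lines of the pair (a male carries a single X gamete).

#' Expected founder relationship matrix E(G0)
#'
#' Builds the founder block of expected genomic relationships from the
#' gamete moments, for autosomes or the X chromosome.  Autosomal entries:
#' diagonal `2*d[l] + 2*r[l,l]`, off-diagonal `4*r[l,m]` (same or different
#' lines).  X entries distinguish the eight sex/line cases: male self
#' `d[l]`; female self `2*d[l] + 2*r[l,l]`; male-male `r[l,m]`; female-female
#' same line `4*r[l,l]`, different lines `r[l,l] + r[m,m] + 2*r[l,m]`;
#' male-female `2*r[l,m]`.
#'
#' @param ped a `cross_pedigree` (supplies founder ids, sexes and lines).
#' @param moments a `gametic_moments` for the requested partition.
#' @return a `cross_grm` of kind `"expected-founder"`, rows/columns ordered
#'   as `founder_ids(ped)`.
#' @export
expected_founder_grm <- function(ped, moments) {
  stopifnot(inherits(ped, "cross_pedigree"),
            inherits(moments, "gametic_moments"))
  fid <- founder_ids(ped)
  sex <- ped$sex[match(fid, ped$id)]
  line <- ped$line[match(fid, ped$id)]
  if (!all(line %in% names(moments$d)))
    stop("founder_line_missing_from_moments")
  d <- moments$d; r <- moments$r
  part <- moments$partition
  n <- length(fid)
  e <- matrix(0, n, n, dimnames = list(fid, fid))
  for (i in seq_len(n)) {
    li <- line[i]
    for (j in seq_len(i)) {
      lj <- line[j]
      val <- if (part == "autosomal") {
        if (i == j) 2 * d[[li]] + 2 * r[li, li] else 4 * r[li, lj]
      } else {
        if (i == j) {
          if (sex[i] == "M") d[[li]] else 2 * d[[li]] + 2 * r[li, li]
        } else if (sex[i] == "M" && sex[j] == "M") {
          r[li, lj]
        } else if (sex[i] == "F" && sex[j] == "F") {
          if (li == lj) 4 * r[li, li]
          else r[li, li] + r[lj, lj] + 2 * r[li, lj]
        } else {
          2 * r[li, lj]
        }
      }
      e[i, j] <- e[j, i] <- val
    }
  }
  .new_grm(e, part, "expected-founder")
}
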