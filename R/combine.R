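# Single-step combination of the pedigree expectation with observed founder
# genotypes, and the founder-relatedness variance correction.

.safe_inverse <- function(m, label, condition_threshold = 1e12) {
  m <- unclass(m)
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap > condition_threshold)
    stop(sprintf(
      "singular_matrix: %s has condition number %.3g (threshold %.3g); %s",
      label, kap, condition_threshold,
      "consider blending the observed matrix with its expectation"))
  inv <- chol2inv(chol((m + t(m)) / 2))
  dimnames(inv) <- dimnames(m)
  inv
}

#' Combined inverse relationship matrix H^-1
#'
#' `H^-1 = Atilde^-1 + B` where `B` is zero except on the founder block,
#' which holds `solve(G0) - solve(E(G0))` for the (typically blended)
#' observed founder matrix `G0`.  When the observed matrix equals its
#' expectation the correction vanishes and `H^-1 = Atilde^-1`.
#'
#' @param atilde pedigree-sized `cross_grm` (the expectation-seeded tabular
#'   extension).
#' @param g0 founder-sized observed or blended `cross_grm`.
#' @param e0 founder-sized expected `cross_grm` (the founder block of
#'   `atilde`).
#' @param condition_threshold condition-number guard for all three
#'   inversions, default `1e12`.
#' @return list of class `combined_inverse`: `hinv` (pedigree-sized
#'   symmetric matrix, founders first), `order` (ids), `founder_ids`,
#'   `provenance` (kinds and alpha when available).
#' @export
build_h_inverse <- function(atilde, g0, e0, condition_threshold = 1e12) {
  fid <- rownames(g0)
  if (!identical(fid, rownames(e0)))
    stop("grm_label_mismatch: observed and expected founder matrices differ")
  if (!all(fid %in% rownames(atilde)))
    stop("grm_label_mismatch: founder ids missing from pedigree matrix")
  ids <- rownames(atilde)
  # founder-first ordering
  ord <- c(match(fid, ids), setdiff(seq_along(ids), match(fid, ids)))
  a_sorted <- unclass(atilde)[ord, ord]
  a_inv <- .safe_inverse(a_sorted, "Atilde", condition_threshold)
  g_inv <- .safe_inverse(g0, "observed founder matrix", condition_threshold)
  e_inv <- .safe_inverse(e0, "expected founder matrix", condition_threshold)
  hinv <- a_inv
  f_idx <- seq_along(fid)
  hinv[f_idx, f_idx] <- hinv[f_idx, f_idx] + (g_inv - e_inv)
  structure(list(hinv = hinv, order = ids[ord], founder_ids = fid,
                 provenance = list(atilde_kind = grm_kind(atilde),
                                   g0_kind = grm_kind(g0),
                                   e0_kind = grm_kind(e0))),
            class = "combined_inverse")
}

#' @export
print.combined_inverse <- function(x, ...) {
  cat(sprintf("<combined_inverse> %d x %d (%d founders first)\n",
              nrow(x$hinv), ncol(x$hinv), length(x$founder_ids)))
  invisible(x)
}

#' Founder-relatedness correction factor for variance components
#'
#' `Dk = mean(diag(g0)) - mean(g0)`: the mean founder self-relationship
#' minus the mean over all f^2 elements of the founder block.  Genetic
#' variance components estimated with related founders are multiplied by
#' `Dk` to express them on the scale of unrelated base individuals.
#'
#' @param founder_block square founder relationship matrix (f >= 2).
#' @return scalar.
#' @export
dk_correction <- function(founder_block) {
  m <- unclass(founder_block)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 2) stop("dk_requires_at_least_two_founders")
  mean(diag(m)) - mean(m)
}
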