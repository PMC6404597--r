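# Observed genomic relationships among founders: VanRaden-style ZZ'/S with
# the composite (intercross equilibrium) frequency pbar used for centering
# and scaling, and hemizygous-male coding on the X.

.new_grm <- function(mat, partition, kind) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  structure(mat, partition = partition, kind = kind,
            class = c("cross_grm", "matrix", "array"))
}

#' @export
print.cross_grm <- function(x, ...) {
  cat(sprintf("<cross_grm> %d x %d, partition=%s, kind=%s\n", nrow(x),
              ncol(x), attr(x, "partition"), attr(x, "kind")))
  k <- min(6L, nrow(x))
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("...\n")
  invisible(x)
}

#' Kind and partition tags of a relationship matrix
#' @param m a `cross_grm`.
#' @return character scalar.
#' @export
grm_kind <- function(m) attr(m, "kind")

#' @rdname grm_kind
#' @export
grm_partition <- function(m) attr(m, "partition")

#' Centered genotype matrix Z0
#'
#' Gene counts minus their centering constant: `2*pbar` for autosomal loci
#' and for females on the X, `pbar` for hemizygous males on the X.
#'
#' @param g a [founder_geno()].
#' @param freqs a `line_freqs`.
#' @param partition `"autosomal"` or `"x"`.
#' @return founders-by-markers numeric matrix.
#' @export
centered_genotypes <- function(g, freqs, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  sel <- g$partition == partition
  if (!any(sel)) stop("no_markers_in_partition: ", partition)
  cnt <- g$counts[, sel, drop = FALSE]
  pbar <- freqs[[partition]]$pbar
  if (length(pbar) != ncol(cnt)) stop("frequency_marker_mismatch")
  center <- matrix(2 * pbar, nrow(cnt), ncol(cnt), byrow = TRUE)
  if (partition == "x")
    center[g$sex == "M", ] <- matrix(pbar, sum(g$sex == "M"), ncol(cnt),
                                     byrow = TRUE)
  cnt - center
}

#' Observed genomic founder relationship matrix G0
#'
#' `G0 = Z0 %*% t(Z0) / S` where `Z0` is the centered genotype matrix and
#' `S = 2 * sum(pbar * (1 - pbar))` over the partition's markers.
#'
#' @inheritParams centered_genotypes
#' @return a `cross_grm` of kind `"observed"`.
#' @export
observed_grm <- function(g, freqs, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  z <- centered_genotypes(g, freqs, partition)
  S <- 2 * sum(freqs[[partition]]$pbar * (1 - freqs[[partition]]$pbar))
  if (S <= 0) stop("zero_heterozygosity_scale")
  .new_grm(tcrossprod(z) / S, partition, "observed")
}

#' Blend an observed matrix with its expectation
#'
#' `alpha * g0 + (1 - alpha) * e0`; restores invertibility when the observed
#' matrix is singular (e.g., rank-deficient founder sets).
#'
#' @param g0 observed `cross_grm`.
#' @param e0 expected `cross_grm` with identical labels and partition.
#' @param alpha blending weight on the observed matrix, default 0.98.
#' @return a `cross_grm` of kind `"blended"`.
#' @export
blend_grm <- function(g0, e0, alpha = 0.98) {
  if (!identical(rownames(g0), rownames(e0)))
    stop("grm_label_mismatch")
  if (!identical(attr(g0, "partition"), attr(e0, "partition")))
    stop("grm_partition_mismatch")
  if (alpha < 0 || alpha > 1) stop("alpha_out_of_range")
  .new_grm(unclass(g0) * alpha + unclass(e0) * (1 - alpha),
           attr(g0, "partition"), "blended")
}

#' Numerical rank of a symmetric relationship matrix
#'
#' Number of eigenvalues exceeding `tol` times the largest eigenvalue.
#'
#' @param m symmetric matrix.
#' @param tol relative tolerance, default `1e-8`.
#' @return integer rank.
#' @export
grm_rank <- function(m, tol = 1e-8) {
  ev <- eigen(unclass(m), symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev))
}

#' Write a relationship matrix as dense text
#'
#' Whitespace-delimited, header row of ids, 17 significant digits.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_grm_dense <- function(m, path) {
  ids <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = " "), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(m[i, ], digits = 17, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Read a dense-text relationship matrix
#' @param path file written by [write_grm_dense()].
#' @return numeric matrix with dimnames.
#' @export
read_grm_dense <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "[ \t]+")[[1]]
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]))
  m <- do.call(rbind, vals)
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a relationship matrix in lower-triangle triplet form
#'
#' Rows `id_i<TAB>id_j<TAB>value` for the lower triangle including the
#' diagonal, 17 significant digits; the format mixed-model solvers accept
#' for user-defined inverse covariance structures.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_grm_triplet <- function(m, path) {
  ids <- rownames(m)
  n <- nrow(m)
  i <- rep(seq_len(n), times = seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  lines <- sprintf("%s\t%s\t%s", ids[i], ids[j],
                   formatC(m[cbind(i, j)], digits = 17, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a lower-triangle triplet relationship matrix
#' @param path file written by [write_grm_triplet()].
#' @return symmetric numeric matrix with dimnames.
#' @export
read_grm_triplet <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("i", "j", "value"),
                          colClasses = c("character", "character", "numeric"))
  ids <- unique(c(df$i, df$j))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(match(df$i, ids), match(df$j, ids))] <- df$value
  m[cbind(match(df$j, ids), match(df$i, ids))] <- df$value
  m
}
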