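# Line allele frequencies, composite frequencies and the gamete moments d/r
# that drive every expected relationship.  All sums run over the loaded
# (polymorphic-across-founders) marker set; accumulation relies on R's
# long-double accumulators in sum()/colSums().

#' Line allele frequencies and composite frequency
#'
#' Counted-allele frequencies per founder line and partition, plus the
#' composite frequency `pbar`, the weighted average of line frequencies that
#' is expected in the intercross at equilibrium under the given line
#' contributions.  On the X chromosome males contribute one allele and
#' females two.
#'
#' @param g a [founder_geno()].
#' @param weights optional line weights (named or in line order),
#'   non-negative, summing to 1; default uniform `1/L`.
#' @return Object of class `line_freqs`: per partition a list with `p`
#'   (lines-by-markers frequency matrix) and `pbar` (composite frequency per
#'   marker); plus `weights` and `lines`.
#' @export
line_frequencies <- function(g, weights = NULL) {
  stopifnot(inherits(g, "founder_geno"))
  lines <- unique(g$line)
  L <- length(lines)
  if (is.null(weights)) weights <- rep(1 / L, L)
  if (!is.null(names(weights))) weights <- weights[lines]
  if (length(weights) != L) stop("weights_wrong_length")
  if (any(weights < 0)) stop("weights_negative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights_do_not_sum_to_one")
  weights <- stats::setNames(as.numeric(weights), lines)

  out <- list(weights = weights, lines = lines)
  for (part in c("autosomal", "x")) {
    sel <- g$partition == part
    if (!any(sel)) { out[[part]] <- NULL; next }
    cnt <- g$counts[, sel, drop = FALSE]
    ploidy <- matrix(2, nrow(cnt), ncol(cnt))
    if (part == "x") ploidy[g$sex == "M", ] <- 1
    p <- matrix(0, L, ncol(cnt), dimnames = list(lines, colnames(cnt)))
    for (li in seq_len(L)) {
      rows <- g$line == lines[li]
      if (!any(rows)) stop("line_without_founders: ", lines[li])
      p[li, ] <- colSums(cnt[rows, , drop = FALSE]) /
                 colSums(ploidy[rows, , drop = FALSE])
    }
    pbar <- as.numeric(crossprod(p, weights))
    names(pbar) <- colnames(cnt)
    out[[part]] <- list(p = p, pbar = pbar)
  }
  structure(out, class = "line_freqs")
}

#' Construct line frequencies directly from frequency matrices
#'
#' Used by the fixture generator (which knows the generating frequencies) and
#' in tests; bypasses genotype counting.
#'
#' @param p_autosomal,p_x lines-by-markers frequency matrices (either may be
#'   `NULL`); rownames are line labels.
#' @param weights line weights as in [line_frequencies()].
#' @return a `line_freqs` object.
#' @export
line_freqs_from_matrix <- function(p_autosomal = NULL, p_x = NULL,
                                   weights = NULL) {
  pm <- if (!is.null(p_autosomal)) p_autosomal else p_x
  if (is.null(pm)) stop("no_frequency_matrix_supplied")
  lines <- rownames(pm)
  if (is.null(lines)) stop("frequency_matrix_needs_line_rownames")
  L <- length(lines)
  if (is.null(weights)) weights <- rep(1 / L, L)
  if (abs(sum(weights) - 1) > 1e-12) stop("weights_do_not_sum_to_one")
  if (any(weights < 0)) stop("weights_negative")
  weights <- stats::setNames(as.numeric(weights), lines)
  out <- list(weights = weights, lines = lines)
  for (part in c("autosomal", "x")) {
    p <- if (part == "autosomal") p_autosomal else p_x
    if (is.null(p)) next
    if (any(p < 0 | p > 1)) stop("frequencies_out_of_range")
    pbar <- as.numeric(crossprod(p, weights))
    out[[part]] <- list(p = p, pbar = pbar)
  }
  structure(out, class = "line_freqs")
}

#' @export
print.line_freqs <- function(x, ...) {
  for (part in c("autosomal", "x")) {
    if (!is.null(x[[part]]))
      cat(sprintf("<line_freqs> %s: %d lines x %d markers\n", part,
                  nrow(x[[part]]$p), ncol(x[[part]]$p)))
  }
  cat("weights:", paste(sprintf("%s=%.4g", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Gamete moments d, r and the scaling factor S
#'
#' From the line and composite allele frequencies of one partition, computes
#' the heterozygosity scaling factor `S = 2 * sum(pbar * (1 - pbar))`, the
#' expected self-relationship `d[l]` of a gamete drawn from line `l`
#' (`(1/S) * sum(p_l*(1-p_l) + (p_l-pbar)^2)`) and the expected relationship
#' `r[l,m] = (1/S) * sum((p_l-pbar)*(p_m-pbar))` between gametes drawn from
#' lines `l` and `m`.  For two lines with uniform weights, `d` sums to one
#' and `r[A,A] = r[B,B] = -r[A,B]`.
#'
#' @param freqs a `line_freqs` object.
#' @param partition `"autosomal"` or `"x"`.
#' @return Object of class `gametic_moments`: list with `S`, `d` (length-L
#'   named vector), `r` (L-by-L symmetric matrix), `weights`, `partition`,
#'   `n_markers`.
#' @export
gametic_moments <- function(freqs, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  stopifnot(inherits(freqs, "line_freqs"))
  blk <- freqs[[partition]]
  if (is.null(blk)) stop("no_markers_in_partition: ", partition)
  p <- blk$p; pbar <- blk$pbar
  S <- 2 * sum(pbar * (1 - pbar))
  if (S <= 0)
    stop("zero_heterozygosity_scale: all composite frequencies are 0 or 1; ",
         "no relationship scale exists for partition ", partition)
  dev <- sweep(p, 2, pbar)            # p_l - pbar per marker
  d <- (rowSums(p * (1 - p)) + rowSums(dev^2)) / S
  r <- tcrossprod(dev) / S
  structure(list(S = S, d = d, r = r, weights = freqs$weights,
                 partition = partition, n_markers = length(pbar)),
            class = "gametic_moments")
}

#' @export
print.gametic_moments <- function(x, ...) {
  cat(sprintf("<gametic_moments> partition=%s, %d markers, S=%.6g\n",
              x$partition, x$n_markers, x$S))
  cat("d:", paste(sprintf("%s=%.6g", names(x$d), x$d), collapse = ", "), "\n")
  cat("r:\n"); print(round(x$r, 6))
  invisible(x)
}

#' Write a TSV report of moments
#'
#' Key-value rows: S, each d entry and each distinct r entry, tagged by
#' partition.
#'
#' @param moments_list named list of `gametic_moments` (names used as tags).
#' @param path output file.
#' @return invisibly, the data frame written.
#' @export
write_moments_report <- function(moments_list, path) {
  rows <- list()
  for (tag in names(moments_list)) {
    m <- moments_list[[tag]]
    rows[[length(rows) + 1]] <- data.frame(partition = tag, key = "S",
                                           value = m$S)
    for (l in names(m$d))
      rows[[length(rows) + 1]] <- data.frame(partition = tag,
                                             key = paste0("d_", l),
                                             value = m$d[[l]])
    ln <- rownames(m$r)
    for (i in seq_along(ln)) for (j in i:length(ln))
      rows[[length(rows) + 1]] <- data.frame(partition = tag,
                                             key = paste0("r_", ln[i], "_", ln[j]),
                                             value = m$r[i, j])
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
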