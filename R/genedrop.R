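# Monte-Carlo oracle: founder alleles (observed or freshly sampled from the
# line frequencies) are dropped through the pedigree locus by locus, and the
# realized relationship matrices are averaged over replicates.  Loci are
# unlinked, exactly as the analytic expectations assume.

# Founder gametes for one replicate: list with `a1`, `a2` (founders x loci
# 0/1 allele matrices; males on X carry only `a1`, `a2` is NA there).
.founder_gametes_observed <- function(g, partition) {
  sel <- g$partition == partition
  cnt <- g$counts[, sel, drop = FALSE]
  if (any(abs(cnt - round(cnt)) > 0))
    stop("genedrop_requires_integer_counts (no imputed genotypes)")
  n <- nrow(cnt); m <- ncol(cnt)
  a1 <- matrix(0, n, m, dimnames = dimnames(cnt))
  a2 <- a1
  # phase is irrelevant for uniform transmission: het -> (1, 0)
  a1[cnt >= 1] <- 1
  a2[cnt == 2] <- 1
  if (partition == "x") {
    male <- g$sex == "M"
    a2[male, ] <- NA_real_
    a1[male, ] <- cnt[male, ]
  }
  list(a1 = a1, a2 = a2)
}

.founder_gametes_hwe <- function(g, freqs, partition) {
  sel <- g$partition == partition
  m <- sum(sel)
  lines <- freqs$lines
  p <- freqs[[partition]]$p
  n <- nrow(g$counts)
  a1 <- matrix(0, n, m, dimnames = list(rownames(g$counts),
                                        colnames(g$counts)[sel]))
  a2 <- a1
  for (i in seq_len(n)) {
    pi <- p[g$line[i], ]
    a1[i, ] <- as.numeric(stats::runif(m) < pi)
    if (partition == "x" && g$sex[i] == "M") a2[i, ] <- NA_real_
    else a2[i, ] <- as.numeric(stats::runif(m) < pi)
  }
  list(a1 = a1, a2 = a2)
}

#' One gene-drop replicate
#'
#' Transmits founder alleles through the pedigree once.  Autosomes: each
#' non-founder receives one allele from each parent, picked uniformly from
#' that parent's two per locus.  X: daughters receive the sire's single X
#' allele plus one of the dam's two; sons receive one of the dam's two only.
#'
#' @param ped a `cross_pedigree`.
#' @param g a [founder_geno()].
#' @param partition `"autosomal"` or `"x"`.
#' @param founder_source `"observed"` (founders keep their genotypes) or
#'   `"hwe"` (founder alleles freshly sampled from line frequencies, which
#'   requires `freqs`).
#' @param freqs a `line_freqs`, needed when `founder_source = "hwe"`.
#' @return individuals-by-loci gene-count matrix (X males in 0/1).
#' @export
drop_once <- function(ped, g, partition = c("autosomal", "x"),
                      founder_source = c("observed", "hwe"), freqs = NULL) {
  partition <- match.arg(partition)
  founder_source <- match.arg(founder_source)
  fg <- if (founder_source == "observed") .founder_gametes_observed(g, partition)
        else .founder_gametes_hwe(g, freqs, partition)
  counts <- .drop_through(ped, fg, partition)
  counts
}

# core transmission; fg holds founder gametes; returns gene counts
.drop_through <- function(ped, fg, partition) {
  ids <- ped$id
  n <- length(ids)
  m <- ncol(fg$a1)
  sire_i <- match(ped$sire, ids)
  dam_i  <- match(ped$dam, ids)
  f_row <- match(ids, rownames(fg$a1))
  a1 <- matrix(NA_real_, n, m, dimnames = list(ids, colnames(fg$a1)))
  a2 <- a1
  for (k in seq_len(n)) {
    si <- sire_i[k]; di <- dam_i[k]
    if (is.na(si)) {
      a1[k, ] <- fg$a1[f_row[k], ]
      a2[k, ] <- fg$a2[f_row[k], ]
      next
    }
    if (partition == "autosomal") {
      pick_s <- (stats::runif(m) < 0.5) + 0
      pick_d <- (stats::runif(m) < 0.5) + 0
      a1[k, ] <- pick_s * a1[si, ] + (1 - pick_s) * a2[si, ]
      a2[k, ] <- pick_d * a1[di, ] + (1 - pick_d) * a2[di, ]
    } else {
      # dam's gamete: one of her two X alleles (dams always carry two)
      pick_d <- (stats::runif(m) < 0.5) + 0
      dam_gam <- pick_d * a1[di, ] + (1 - pick_d) * a2[di, ]
      if (ped$sex[k] == "F") {
        a1[k, ] <- a1[si, ]      # sire's single X
        a2[k, ] <- dam_gam
      } else {
        a1[k, ] <- dam_gam
        a2[k, ] <- NA_real_
      }
    }
  }
  a2[is.na(a2)] <- 0
  a1 + a2
}

#' Gene-drop estimate of the expected relationship matrix
#'
#' Replicates the gene-drop, computes each replicate's realized relationship
#' matrix (counts centered by `2*pbar`, or `pbar` for X males, scaled by the
#' partition's `S`) and returns the elementwise mean and Monte-Carlo
#' standard error.  Replicates use independent seed-derived streams
#' (`seed + replicate`), so any subset is reproducible.
#'
#' @inheritParams drop_once
#' @param freqs a `line_freqs` (always required: supplies centering).
#' @param replicates number of gene-drop replicates, default 2000.
#' @param seed integer base seed.
#' @param loci optional marker-id subset for speed.
#' @return list of class `genedrop_result`: `mean`, `se` (matrices),
#'   `rep_means` (per-replicate grand matrix means, used to assess the
#'   strongly correlated "common mode" of Monte-Carlo error), `replicates`,
#'   `partition`, `founder_source`.
#' @export
gene_drop_grm <- function(ped, g, freqs, partition = c("autosomal", "x"),
                          replicates = 2000, seed = 1,
                          founder_source = c("observed", "hwe"),
                          loci = NULL) {
  partition <- match.arg(partition)
  founder_source <- match.arg(founder_source)
  stopifnot(replicates >= 1)
  sel <- g$partition == partition
  pbar <- freqs[[partition]]$pbar
  keep <- rep(TRUE, sum(sel))
  if (!is.null(loci)) {
    keep <- colnames(g$counts)[sel] %in% loci
    if (!any(keep)) stop("loci_subset_empty")
  }
  pbar <- pbar[keep]
  S <- 2 * sum(pbar * (1 - pbar))
  if (S <= 0) stop("zero_heterozygosity_scale")
  ids <- ped$id
  n <- length(ids)
  male <- ped$sex == "M"
  center <- matrix(2 * pbar, n, length(pbar), byrow = TRUE)
  if (partition == "x")
    center[male, ] <- matrix(pbar, sum(male), length(pbar), byrow = TRUE)

  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  acc2 <- acc
  rep_means <- numeric(replicates)  # per-replicate grand matrix mean
  fg_obs <- if (founder_source == "observed")
    .founder_gametes_observed(g, partition) else NULL
  if (!is.null(fg_obs) && !all(keep)) {
    fg_obs$a1 <- fg_obs$a1[, keep, drop = FALSE]
    fg_obs$a2 <- fg_obs$a2[, keep, drop = FALSE]
  }
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i)
    if (founder_source == "observed") {
      fg <- fg_obs
    } else {
      fg <- .founder_gametes_hwe(g, freqs, partition)
      if (!all(keep)) {
        fg$a1 <- fg$a1[, keep, drop = FALSE]
        fg$a2 <- fg$a2[, keep, drop = FALSE]
      }
    }
    cnt <- .drop_through(ped, fg, partition)
    z <- cnt - center
    grm <- tcrossprod(z) / S
    acc <- acc + grm
    acc2 <- acc2 + grm * grm
    rep_means[rep_i] <- mean(grm)
  }
  mean_m <- acc / replicates
  var_m <- pmax(acc2 / replicates - mean_m^2, 0)
  se_m <- if (replicates > 1) sqrt(var_m / (replicates - 1)) else var_m * NA
  structure(list(mean = mean_m, se = se_m, rep_means = rep_means,
                 replicates = replicates,
                 partition = partition, founder_source = founder_source),
            class = "genedrop_result")
}

#' @export
print.genedrop_result <- function(x, ...) {
  cat(sprintf("<genedrop_result> %d x %d, partition=%s, source=%s, %d replicates\n",
              nrow(x$mean), ncol(x$mean), x$partition, x$founder_source,
              x$replicates))
  invisible(x)
}

#' Empirical line-origin fractions by gene-drop
#'
#' Drops line labels (rather than alleles) through the pedigree: line-A
#' alleles are coded 1, all others 0, one line at a time.  Returns the mean
#' fraction of each individual's transmitted-gamete alleles originating from
#' each line, with Monte-Carlo standard errors; the empirical counterpart of
#' [line_composition()].
#'
#' @param ped a `cross_pedigree`.
#' @param partition `"autosomal"` or `"x"`.
#' @param replicates number of replicates.
#' @param seed integer base seed.
#' @param loci number of independent pseudo-loci per replicate (more loci
#'   sharpen the per-replicate fraction), default 20.
#' @return list with `mean` and `se`, individuals-by-lines matrices.
#' @export
line_origin_by_genedrop <- function(ped, partition = c("autosomal", "x"),
                                    replicates = 500, seed = 1, loci = 20) {
  partition <- match.arg(partition)
  lines <- line_labels(ped)
  fid <- founder_ids(ped)
  sex <- ped$sex[match(fid, ped$id)]
  line <- ped$line[match(fid, ped$id)]
  n <- nrow(ped)
  mean_acc <- matrix(0, n, length(lines), dimnames = list(ped$id, lines))
  se_acc <- mean_acc
  for (li in seq_along(lines)) {
    # founders of line li carry allele 1 everywhere, others 0
    a1 <- matrix(as.numeric(line == lines[li]), length(fid), loci,
                 dimnames = list(fid, paste0("L", seq_len(loci))))
    a2 <- a1
    if (partition == "x") a2[sex == "M", ] <- NA_real_
    fg <- list(a1 = a1, a2 = a2)
    ploidy <- rep(2, n)
    if (partition == "x") ploidy[ped$sex == "M"] <- 1
    acc <- matrix(0, n, replicates)
    for (rep_i in seq_len(replicates)) {
      set.seed(seed + rep_i)
      cnt <- .drop_through(ped, fg, partition)
      acc[, rep_i] <- rowMeans(cnt) / ploidy
    }
    mean_acc[, li] <- rowMeans(acc)
    se_acc[, li] <- apply(acc, 1, stats::sd) / sqrt(replicates)
  }
  list(mean = mean_acc, se = se_acc)
}
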