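# Founder genotypes are stored as gene counts of the "counted" allele: the
# allele listed first for each marker.  Autosomal counts are 0/1/2; X counts
# are 0/1/2 for females and 0/1 for males (hemizygous).  Chromosome labels
# "X" mark non-pseudoautosomal X loci; "XY"/"PAR" are treated as autosomal.

X_LABELS <- c("X", "x", "23", "chrX")
PAR_LABELS <- c("XY", "PAR", "xy", "par")

.partition_of <- function(chrom) {
  ifelse(chrom %in% X_LABELS, "x", "autosomal")
}

#' Founder genotype container
#'
#' @param counts founders-by-markers integer matrix of gene counts of the
#'   counted allele (rownames = founder ids, colnames = marker ids).
#' @param chrom character vector of chromosome labels per marker.
#' @param sex founder sexes ("M"/"F") aligned with `rownames(counts)`.
#' @param line founder line labels aligned with `rownames(counts)`.
#' @param alleles optional 2-column character matrix (counted, alternative).
#' @return Object of class `founder_geno` with fields `counts`, `chrom`,
#'   `partition` ("autosomal"/"x" per marker), `sex`, `line`, `alleles`.
#' @export
founder_geno <- function(counts, chrom, sex, line, alleles = NULL) {
  stopifnot(is.matrix(counts), length(chrom) == ncol(counts),
            length(sex) == nrow(counts), length(line) == nrow(counts))
  partition <- .partition_of(chrom)
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("genotype_missing_values")
  is_x <- partition == "x"
  if (any(is_x)) {
    male_x <- counts[sex == "M", is_x, drop = FALSE]
    if (any(male_x > 1))
      stop("male_x_diploid_count: male X gene counts must be 0 or 1")
  }
  if (any(counts > 2 | counts < 0)) stop("genotype_count_out_of_range")
  structure(list(counts = counts, chrom = chrom, partition = partition,
                 sex = sex, line = line, alleles = alleles),
            class = "founder_geno")
}

#' @export
print.founder_geno <- function(x, ...) {
  cat(sprintf("<founder_geno> %d founders x %d markers (%d autosomal, %d X)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$partition == "autosomal"), sum(x$partition == "x")))
  invisible(x)
}

#' Marker ids of a partition
#' @param g a `founder_geno`.
#' @param partition `"autosomal"` or `"x"`.
#' @return character vector of marker ids.
#' @export
partition_markers <- function(g, partition = c("autosomal", "x")) {
  partition <- match.arg(partition)
  colnames(g$counts)[g$partition == partition]
}

# Parse one diploid call like "A/a", "A A", "Aa"; returns the two alleles.
.split_call <- function(call) {
  call <- trimws(call)
  if (grepl("[/| ]", call)) strsplit(call, "[/| ]+")[[1]]
  else if (nchar(call) == 2) c(substr(call, 1, 1), substr(call, 2, 2))
  else c(call, call)  # single letter: hemizygous or shorthand homozygote
}

.is_missing_allele <- function(a) a %in% c("0", ".", "N", "-", "NA", "")

#' Read founder genotypes
#'
#' Reads founder marker genotypes from a marker-major CSV
#' (`marker,chrom,allele1,allele2,<founder ids...>` with calls like `A/a`) or
#' a PLINK-style text `.ped`/`.map` pair, encodes gene counts of the counted
#' allele (the first-listed allele per marker), collapses male X diploid
#' calls (`A/A` becomes count 1), and drops markers monomorphic across all
#' founders (they carry no relationship information).
#'
#' @param path CSV path, or `.ped` path when `format = "ped_map"`.
#' @param ped a `cross_pedigree`; founders must all be present in the file.
#' @param format `"csv"` or `"ped_map"`.
#' @param map_path `.map` path (defaults to `path` with extension swapped).
#' @param male_het_x `"error"` (default) or `"drop"`: what to do with a
#'   heterozygous male X call.
#' @param missing `"error"` (default) or `"line-freq"`: missing calls are
#'   either rejected or replaced by the founder's line mean count.
#' @return a [founder_geno()].
#' @export
read_founder_genotypes <- function(path, ped, format = c("csv", "ped_map"),
                                   map_path = NULL,
                                   male_het_x = c("error", "drop"),
                                   missing = c("error", "line-freq")) {
  format <- match.arg(format)
  male_het_x <- match.arg(male_het_x)
  missing <- match.arg(missing)
  stopifnot(inherits(ped, "cross_pedigree"))
  if (format == "csv") {
    parsed <- .read_geno_csv(path)
  } else {
    if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
    parsed <- .read_ped_map(path, map_path)
  }
  fid <- founder_ids(ped)
  absent <- setdiff(fid, rownames(parsed$calls))
  if (length(absent) > 0)
    stop("founder_missing_from_genotypes: ", paste(absent, collapse = ", "))
  calls <- parsed$calls[fid, , drop = FALSE]
  chrom <- parsed$chrom
  alleles <- parsed$alleles
  sex <- ped$sex[match(fid, ped$id)]
  line <- ped$line[match(fid, ped$id)]

  m <- ncol(calls)
  counts <- matrix(NA_real_, nrow(calls), m,
                   dimnames = dimnames(calls))
  partition <- .partition_of(chrom)
  drop_marker <- logical(m)
  for (j in seq_len(m)) {
    counted <- alleles[j, 1]
    for (i in seq_len(nrow(calls))) {
      ab <- .split_call(calls[i, j])
      if (any(.is_missing_allele(ab))) next  # handled below
      if (partition[j] == "x" && sex[i] == "M") {
        u <- unique(ab)
        if (length(u) > 1) {
          if (male_het_x == "drop") { drop_marker[j] <- TRUE; next }
          stop(sprintf("male_het_x_call: founder %s heterozygous at X locus %s",
                       rownames(calls)[i], colnames(calls)[j]))
        }
        counts[i, j] <- as.numeric(u == counted)
      } else {
        counts[i, j] <- sum(ab == counted)
      }
    }
  }
  na_idx <- which(is.na(counts) & !matrix(drop_marker, nrow(calls), m, byrow = TRUE))
  if (length(na_idx) > 0) {
    if (missing == "error") {
      j <- ((na_idx[1] - 1) %/% nrow(counts)) + 1
      i <- ((na_idx[1] - 1) %% nrow(counts)) + 1
      stop(sprintf("genotype_missing: founder %s at marker %s",
                   rownames(counts)[i], colnames(counts)[j]))
    }
    for (j in which(!drop_marker)) {
      nas <- which(is.na(counts[, j]))
      for (i in nas) {
        same <- which(line == line[i])
        mu <- mean(counts[same, j], na.rm = TRUE)
        if (is.nan(mu)) stop(sprintf(
          "genotype_missing: line %s entirely missing at marker %s",
          line[i], colnames(counts)[j]))
        counts[i, j] <- mu
      }
    }
  }

  # drop loci monomorphic across ALL founders: zero contribution when the
  # composite frequency is 0 or 1
  ploidy <- matrix(2, nrow(counts), m)
  ploidy[sex == "M", partition == "x"] <- 1
  tot <- colSums(counts, na.rm = TRUE)
  mono <- tot == 0 | tot == colSums(ploidy)
  drop_marker <- drop_marker | mono
  if (any(mono))
    message(sprintf("dropping %d marker(s) monomorphic across all founders",
                    sum(mono)))
  keep <- !drop_marker
  founder_geno(counts[, keep, drop = FALSE], chrom[keep], sex, line,
               alleles = alleles[keep, , drop = FALSE])
}

.read_geno_csv <- function(path) {
  if (!file.exists(path)) stop("genotype_file_not_found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  req <- c("marker", "chrom", "allele1", "allele2")
  if (!all(req %in% names(df)))
    stop("genotype_csv_missing_columns: need marker,chrom,allele1,allele2,<ids>")
  ids <- setdiff(names(df), req)
  calls <- t(as.matrix(df[, ids, drop = FALSE]))
  colnames(calls) <- df$marker
  rownames(calls) <- ids
  list(calls = calls, chrom = df$chrom,
       alleles = cbind(df$allele1, df$allele2))
}

# PLINK text .ped (FID IID PAT MAT SEX PHENO a1 a2 a1 a2 ...) + .map
# (chrom, marker, cM, bp); counted allele = first allele seen in the map has
# no standard slot, so the counted allele is the first allele observed per
# marker scanning individuals in file order.
.read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("genotype_file_not_found: ", ped_path)
  if (!file.exists(map_path)) stop("genotype_file_not_found: ", map_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4) stop("map_file_malformed: expected 4 columns")
  chrom <- map[[1]]; markers <- map[[2]]
  pedtab <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  m <- length(markers)
  if (ncol(pedtab) != 6 + 2 * m)
    stop("ped_file_malformed: expected ", 6 + 2 * m, " columns, got ",
         ncol(pedtab))
  ids <- pedtab[[2]]
  a1 <- as.matrix(pedtab[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(pedtab[, 6 + 2 * seq_len(m), drop = FALSE])
  calls <- matrix(paste(a1, a2, sep = "/"), nrow(pedtab), m,
                  dimnames = list(ids, markers))
  alleles <- t(vapply(seq_len(m), function(j) {
    obs <- c(rbind(a1[, j], a2[, j]))
    obs <- obs[!.is_missing_allele(obs)]
    u <- unique(obs)
    if (length(u) == 0) c("0", "0") else c(u[1], if (length(u) > 1) u[2] else u[1])
  }, character(2)))
  list(calls = calls, chrom = chrom, alleles = alleles)
}

#' Classify markers by segregation pattern
#'
#' Per partition, counts markers that are polymorphic across all founders
#' jointly, polymorphic within each founder line, and line-specific (fixed
#' for alternative alleles in two lines: frequency 1 in one and 0 in
#' another).
#'
#' @param g a [founder_geno()].
#' @return list with one element per partition, each a list with
#'   `all_founders`, `within_line` (named vector) and `line_specific` counts.
#' @export
classify_markers <- function(g) {
  stopifnot(inherits(g, "founder_geno"))
  lines <- unique(g$line)
  if (length(lines) < 2) stop("classification_needs_two_lines")
  out <- list()
  for (part in c("autosomal", "x")) {
    sel <- g$partition == part
    if (!any(sel)) {
      out[[part]] <- list(all_founders = 0L,
                          within_line = stats::setNames(integer(length(lines)), lines),
                          line_specific = 0L)
      next
    }
    cnt <- g$counts[, sel, drop = FALSE]
    ploidy <- matrix(2, nrow(cnt), ncol(cnt))
    if (part == "x") ploidy[g$sex == "M", ] <- 1
    tot <- colSums(cnt); tot_pl <- colSums(ploidy)
    poly_all <- tot > 0 & tot < tot_pl
    within <- stats::setNames(integer(length(lines)), lines)
    pfreq <- matrix(0, length(lines), ncol(cnt))
    for (li in seq_along(lines)) {
      rows <- g$line == lines[li]
      t_l <- colSums(cnt[rows, , drop = FALSE])
      p_l <- colSums(ploidy[rows, , drop = FALSE])
      within[li] <- sum(t_l > 0 & t_l < p_l)
      pfreq[li, ] <- t_l / p_l
    }
    fixed1 <- pfreq == 1; fixed0 <- pfreq == 0
    line_specific <- sum(vapply(seq_len(ncol(cnt)), function(j) {
      any(fixed1[, j]) && any(fixed0[, j])
    }, logical(1)))
    out[[part]] <- list(all_founders = sum(poly_all),
                        within_line = within,
                        line_specific = as.integer(line_specific))
  }
  out
}
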