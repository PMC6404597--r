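# Deterministic generator of synthetic founder lines and intercross
# pedigrees.  Founder genotypes are drawn in line-specific Hardy-Weinberg
# proportions from line allele-frequency spectra; males carry single X
# alleles.  Pedigree templates: a minimal trio, an F2 cross, and an
# advanced-intercross line (F1 from line crosses, then full-sib or random
# inter-mating of crossbreds).

#' Generate a synthetic intercross fixture
#'
#' Returns a self-consistent pedigree, founder genotypes and the generating
#' line frequencies (so tests can separate sampling error from code error).
#' Defaults emulate a two-line cross founded by four males of one line and
#' four females of the other, the design of small selection experiments.
#'
#' @param lines character vector of line labels (default `c("A", "B")`).
#' @param founders named list per line: `c(M = males, F = females)`.
#'   Default: 4 males of the first line, 4 females of the second.
#' @param markers `c(autosomal = ..., x = ...)` marker counts.
#' @param freq_model `"fixed-opposite"` (line 1 fixed for the counted
#'   allele, line 2 for the alternative), `"uniform"`, `"beta"` or
#'   `"supplied"`.
#' @param beta_shape length-2 shape parameters for `freq_model = "beta"`.
#' @param p_autosomal,p_x supplied lines-by-markers frequency matrices when
#'   `freq_model = "supplied"`.
#' @param template `"trio"`, `"f2"` or `"ail"`.
#' @param generations intercross generations for `"ail"` (F1 counts as 1),
#'   default 6.
#' @param litter_size offspring per breeding pair, default 8.
#' @param mating `"full-sib"` (rotational within-family pairing) or
#'   `"random"` for generations after the F1.
#' @param pairs_per_gen breeding pairs kept per generation (default: number
#'   of founder cross pairs).
#' @param seed integer seed; identical spec + seed reproduce the fixture
#'   bitwise.
#' @return list with `pedigree` (a `cross_pedigree`), `genotypes` (a
#'   [founder_geno()]) and `freqs_true` (a `line_freqs` built from the
#'   generating frequencies).
#' @export
make_fixture <- function(lines = c("A", "B"),
                         founders = NULL,
                         markers = c(autosomal = 100, x = 20),
                         freq_model = c("fixed-opposite", "uniform", "beta",
                                        "supplied"),
                         beta_shape = c(0.5, 0.5),
                         p_autosomal = NULL, p_x = NULL,
                         template = c("ail", "f2", "trio", "tree"),
                         generations = 6, litter_size = 8,
                         mating = c("full-sib", "random"),
                         pairs_per_gen = NULL,
                         seed = 1) {
  freq_model <- match.arg(freq_model)
  template <- match.arg(template)
  mating <- match.arg(mating)
  L <- length(lines)
  if (L < 2) stop("fixture_needs_two_lines")
  if (is.null(founders)) {
    founders <- stats::setNames(rep(list(c(M = 0, F = 0)), L), lines)
    founders[[1]]["M"] <- 4
    founders[[2]]["F"] <- 4
  }
  set.seed(seed)

  n_a <- as.integer(markers[["autosomal"]])
  n_x <- if ("x" %in% names(markers)) as.integer(markers[["x"]]) else 0L
  freq <- .fixture_frequencies(lines, n_a, n_x, freq_model, beta_shape,
                               p_autosomal, p_x)
  ped <- .fixture_pedigree(lines, founders, template, generations,
                           litter_size, mating, pairs_per_gen)
  geno <- .fixture_genotypes(ped, freq, n_a, n_x)
  freqs_true <- line_freqs_from_matrix(p_autosomal = freq$autosomal,
                                       p_x = freq$x)
  list(pedigree = ped, genotypes = geno, freqs_true = freqs_true)
}

.fixture_frequencies <- function(lines, n_a, n_x, model, beta_shape,
                                 p_autosomal, p_x) {
  L <- length(lines)
  gen_block <- function(m) {
    if (m == 0) return(NULL)
    p <- switch(model,
      "fixed-opposite" = rbind(rep(1, m),
                               matrix(0, L - 1, m)),
      "uniform" = matrix(stats::runif(L * m), L, m),
      "beta" = matrix(stats::rbeta(L * m, beta_shape[1], beta_shape[2]), L, m),
      "supplied" = NULL)
    p
  }
  a <- if (model == "supplied") p_autosomal else gen_block(n_a)
  x <- if (model == "supplied") p_x else gen_block(n_x)
  if (!is.null(a)) {
    rownames(a) <- lines
    colnames(a) <- paste0("am", seq_len(ncol(a)))
  }
  if (!is.null(x)) {
    rownames(x) <- lines
    colnames(x) <- paste0("xm", seq_len(ncol(x)))
  }
  list(autosomal = a, x = x)
}

.fixture_pedigree <- function(lines, founders, template, generations,
                              litter_size, mating, pairs_per_gen) {
  rows <- list()
  add <- function(id, sire, dam, sex, line, gen) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, line = line,
      generation = gen, stringsAsFactors = FALSE)
  }
  f_m <- list(); f_f <- list()
  for (ln in lines) {
    nm <- founders[[ln]][["M"]]; nf <- founders[[ln]][["F"]]
    ids_m <- if (nm > 0) paste0(ln, "m", seq_len(nm)) else character(0)
    ids_f <- if (nf > 0) paste0(ln, "f", seq_len(nf)) else character(0)
    for (id in ids_m) add(id, "0", "0", "M", ln, 0)
    for (id in ids_f) add(id, "0", "0", "F", ln, 0)
    f_m[[ln]] <- ids_m; f_f[[ln]] <- ids_f
  }
  all_m <- unlist(f_m); all_f <- unlist(f_f)
  if (length(all_m) == 0 || length(all_f) == 0)
    stop("fixture_impossible_template: need founder males and females")

  if (template == "trio") {
    add("C1", all_m[1], all_f[1], "F", NA, 1)
    return(pedigree(do.call(rbind, rows)))
  }

  if (template == "tree") {
    # non-inbred crossing design: mates never share an ancestor.  Founder
    # pairs are line-1 males x line-2 females; each generation halves the
    # number of disjoint lineages, so `generations` g needs 2^(g-1) pairs.
    npairs <- 2^(generations - 1)
    rows <- list()
    ln_m <- lines[1]; ln_f <- lines[2]
    sires <- paste0(ln_m, "m", seq_len(npairs))
    dams <- paste0(ln_f, "f", seq_len(npairs))
    for (id in sires) add(id, "0", "0", "M", ln_m, 0)
    for (id in dams) add(id, "0", "0", "F", ln_f, 0)
    cur_m <- sires; cur_f <- dams
    counter <- 0
    for (gen in seq_len(generations)) {
      k <- length(cur_m)
      new_m <- character(0); new_f <- character(0)
      if (gen == 1) {
        for (i in seq_len(k)) {
          counter <- counter + 1
          m_id <- sprintf("T%d_%dM", gen, counter)
          f_id <- sprintf("T%d_%dF", gen, counter)
          add(m_id, cur_m[i], cur_f[i], "M", NA, gen)
          add(f_id, cur_m[i], cur_f[i], "F", NA, gen)
          new_m <- c(new_m, m_id); new_f <- c(new_f, f_id)
        }
      } else {
        for (i in seq_len(k %/% 2)) {
          counter <- counter + 1
          m_id <- sprintf("T%d_%dM", gen, counter)
          f_id <- sprintf("T%d_%dF", gen, counter)
          sire <- cur_m[2 * i - 1]; dam <- cur_f[2 * i]
          add(m_id, sire, dam, "M", NA, gen)
          add(f_id, sire, dam, "F", NA, gen)
          new_m <- c(new_m, m_id); new_f <- c(new_f, f_id)
        }
      }
      cur_m <- new_m; cur_f <- new_f
    }
    return(pedigree(do.call(rbind, rows)))
  }

  # cross pairs: pair founder males with founder females from other lines
  pair_m <- character(0); pair_f <- character(0)
  fm <- all_m; ff <- all_f
  line_of <- function(id) sub("[mf][0-9]+$", "", id)
  while (length(fm) > 0 && length(ff) > 0) {
    m1 <- fm[1]
    j <- which(line_of(ff) != line_of(m1))
    if (length(j) == 0) break
    pair_m <- c(pair_m, m1); pair_f <- c(pair_f, ff[j[1]])
    fm <- fm[-1]; ff <- ff[-j[1]]
  }
  if (length(pair_m) == 0)
    stop("fixture_impossible_template: no between-line founder pair")
  if (is.null(pairs_per_gen)) pairs_per_gen <- length(pair_m)
  if (template == "f2") generations <- 2

  # family = index of the founder pair a lineage descends from
  prev <- data.frame(id = character(0), sex = character(0),
                     family = integer(0), stringsAsFactors = FALSE)
  counter <- 0
  for (gen in seq_len(generations)) {
    if (gen == 1) {
      pairs <- data.frame(sire = pair_m, dam = pair_f,
                          family = seq_along(pair_m))
    } else {
      pairs <- .form_pairs(prev, mating, pairs_per_gen)
      if (nrow(pairs) == 0)
        stop("fixture_impossible_template: no breeding pairs in generation ",
             gen)
    }
    cur <- list()
    for (pi in seq_len(nrow(pairs))) {
      for (o in seq_len(litter_size)) {
        counter <- counter + 1
        id <- sprintf("G%d_%d", gen, counter)
        sex <- if (o %% 2 == 1) "M" else "F"
        add(id, pairs$sire[pi], pairs$dam[pi], sex, NA, gen)
        cur[[length(cur) + 1]] <- data.frame(
          id = id, sex = sex, family = pairs$family[pi],
          stringsAsFactors = FALSE)
      }
    }
    prev <- do.call(rbind, cur)
  }
  pedigree(do.call(rbind, rows))
}

# pair males and females of the previous generation; full-sib pairing keeps
# families separate with a rotational offset, random pairing shuffles pools
.form_pairs <- function(prev, mating, pairs_per_gen) {
  males <- prev[prev$sex == "M", , drop = FALSE]
  females <- prev[prev$sex == "F", , drop = FALSE]
  out <- list()
  if (mating == "full-sib") {
    for (fam in unique(prev$family)) {
      fm <- males[males$family == fam, , drop = FALSE]
      fl <- females[females$family == fam, , drop = FALSE]
      k <- min(nrow(fm), nrow(fl))
      if (k == 0) next
      rot <- c(seq_len(k)[-1], 1)  # rotate partners within the family
      for (i in seq_len(k))
        out[[length(out) + 1]] <- data.frame(sire = fm$id[i],
                                             dam = fl$id[rot[i]],
                                             family = fam)
    }
  } else {
    k <- min(nrow(males), nrow(females))
    ord_m <- sample(nrow(males))[seq_len(k)]
    ord_f <- sample(nrow(females))[seq_len(k)]
    for (i in seq_len(k))
      out[[length(out) + 1]] <- data.frame(sire = males$id[ord_m[i]],
                                           dam = females$id[ord_f[i]],
                                           family = males$family[ord_m[i]])
  }
  if (length(out) == 0)
    return(data.frame(sire = character(0), dam = character(0),
                      family = integer(0)))
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  utils::head(pairs, pairs_per_gen)
}

.fixture_genotypes <- function(ped, freq, n_a, n_x) {
  fid <- founder_ids(ped)
  sex <- ped$sex[match(fid, ped$id)]
  line <- ped$line[match(fid, ped$id)]
  m_total <- n_a + n_x
  counts <- matrix(0, length(fid), m_total,
                   dimnames = list(fid, c(colnames(freq$autosomal),
                                          colnames(freq$x))))
  chrom <- c(rep("1", n_a), rep("X", n_x))
  for (i in seq_along(fid)) {
    if (n_a > 0) {
      p <- freq$autosomal[line[i], ]
      counts[i, seq_len(n_a)] <- stats::rbinom(n_a, 2, p)
    }
    if (n_x > 0) {
      p <- freq$x[line[i], ]
      ncop <- if (sex[i] == "M") 1 else 2
      counts[i, n_a + seq_len(n_x)] <- stats::rbinom(n_x, ncop, p)
    }
  }
  alleles <- cbind(rep("A", m_total), rep("a", m_total))
  founder_geno(counts, chrom, sex, line, alleles = alleles)
}

#' Write a fixture to disk
#'
#' Emits the pedigree CSV and the genotypes in either the marker-major CSV
#' dialect or a PLINK-style text `.ped`/`.map` pair, in the formats the
#' package readers accept.
#'
#' @param fix result of [make_fixture()].
#' @param dir output directory (created if absent).
#' @param format `"csv"` or `"ped_map"`.
#' @return invisibly, named character vector of written paths.
#' @export
write_fixture <- function(fix, dir, format = c("csv", "ped_map")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- fix$pedigree
  ped_path <- file.path(dir, "pedigree.csv")
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  df$line[is.na(df$line)] <- ""
  utils::write.csv(df, ped_path, row.names = FALSE, quote = FALSE)

  g <- fix$genotypes
  call_of <- function(cnt, counted, alt, male_x) {
    if (male_x) {
      if (cnt >= 1) paste0(counted, "/", counted) else paste0(alt, "/", alt)
    } else {
      if (cnt == 2) paste0(counted, "/", counted)
      else if (cnt == 1) paste0(counted, "/", alt)
      else paste0(alt, "/", alt)
    }
  }
  n <- nrow(g$counts); m <- ncol(g$counts)
  calls <- matrix("", n, m, dimnames = dimnames(g$counts))
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      calls[i, j] <- call_of(g$counts[i, j], g$alleles[j, 1], g$alleles[j, 2],
                             g$partition[j] == "x" && g$sex[i] == "M")
    }
  }
  if (format == "csv") {
    geno_path <- file.path(dir, "genotypes.csv")
    out <- data.frame(marker = colnames(g$counts), chrom = g$chrom,
                      allele1 = g$alleles[, 1], allele2 = g$alleles[, 2],
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(t(calls)))
    utils::write.csv(out, geno_path, row.names = FALSE, quote = FALSE)
    paths <- c(pedigree = ped_path, genotypes = geno_path)
  } else {
    ped_file <- file.path(dir, "genotypes.ped")
    map_file <- file.path(dir, "genotypes.map")
    sexcode <- ifelse(g$sex == "M", "1", "2")
    lines_out <- vapply(seq_len(n), function(i) {
      paste(c("FAM", rownames(g$counts)[i], "0", "0", sexcode[i], "-9",
              gsub("/", " ", calls[i, ])), collapse = " ")
    }, character(1))
    writeLines(lines_out, ped_file)
    writeLines(sprintf("%s %s 0 %d", g$chrom, colnames(g$counts),
                       seq_len(m)), map_file)
    paths <- c(pedigree = ped_path, ped = ped_file, map = map_file)
  }
  invisible(paths)
}
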