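# Sex is stored as "M"/"F"; parents of founders as NA. Founder line labels
# are character; non-founders carry NA in `line`.

UNKNOWN_CODES <- c("0", "", "NA")

.norm_sex <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "M", "m", "male", "Male")] <- "M"
  out[x %in% c("2", "F", "f", "female", "Female")] <- "F"
  out
}

.norm_parent <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% UNKNOWN_CODES | is.na(x)] <- NA_character_
  x
}

#' Construct and validate a pedigree
#'
#' Validates parent references, sexes and founder line labels, then sorts the
#' records topologically so that every parent precedes its offspring.
#' Founders are individuals with both parents unknown; they must carry a line
#' label.  Non-founders must have both parents known (half-known parent pairs
#' are rejected) and no line label.
#'
#' @param df data frame with columns `id`, `sire`, `dam`, `sex`, `line` and
#'   optionally `generation`.  Unknown parents are encoded as `0`, `NA` or an
#'   empty string; sex as `1`/`M` (male) or `2`/`F` (female).
#' @return An object of class `cross_pedigree`: a data frame in topological
#'   order with attributes `founder_ids` (character) and `lines` (ordered
#'   unique founder line labels).
#' @export
pedigree <- function(df) {
  req <- c("id", "sire", "dam", "sex", "line")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("pedigree_missing_columns: ", paste(miss, collapse = ", "))
  ped <- data.frame(
    id   = trimws(as.character(df$id)),
    sire = .norm_parent(df$sire),
    dam  = .norm_parent(df$dam),
    sex  = .norm_sex(df$sex),
    line = {
      ln <- trimws(as.character(df$line))
      ln[ln %in% UNKNOWN_CODES | is.na(ln)] <- NA_character_
      ln
    },
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id))
    stop("pedigree_duplicate_id: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (any(is.na(ped$sex)))
    stop("pedigree_unknown_sex: ",
         paste(ped$id[is.na(ped$sex)], collapse = ", "))

  half <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(half))
    stop("pedigree_half_known_parents: ",
         paste(ped$id[half], collapse = ", "))
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(is_founder & is.na(ped$line)))
    stop("pedigree_founder_without_line: ",
         paste(ped$id[is_founder & is.na(ped$line)], collapse = ", "))
  ped$line[!is_founder] <- NA_character_

  sire_i <- match(ped$sire, ped$id)
  dam_i  <- match(ped$dam, ped$id)
  bad <- !is_founder & (is.na(sire_i) | is.na(dam_i))
  if (any(bad))
    stop("pedigree_unknown_parent_reference: ",
         paste(ped$id[bad], collapse = ", "))
  if (any(sire_i == seq_len(nrow(ped)), na.rm = TRUE) ||
      any(dam_i == seq_len(nrow(ped)), na.rm = TRUE))
    stop("pedigree_selfing_or_own_parent: an individual references itself")
  if (any(sire_i == dam_i, na.rm = TRUE))
    stop("pedigree_selfing: ",
         paste(ped$id[which(sire_i == dam_i)], collapse = ", "))
  wrong_sire <- !is.na(sire_i) & ped$sex[sire_i] != "M"
  wrong_dam  <- !is.na(dam_i) & ped$sex[dam_i] != "F"
  if (any(wrong_sire) || any(wrong_dam))
    stop("pedigree_sex_inconsistency: ",
         paste(ped$id[wrong_sire | wrong_dam], collapse = ", "))

  ord <- .topo_order(sire_i, dam_i, ped$id)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL

  # regenerate parent indices in the new order and infer generations
  sire_i <- match(ped$sire, ped$id)
  dam_i  <- match(ped$dam, ped$id)
  gen <- integer(nrow(ped))
  for (k in seq_len(nrow(ped))) {
    gen[k] <- if (is.na(sire_i[k])) 0L
              else 1L + max(gen[sire_i[k]], gen[dam_i[k]])
  }
  if (!is.null(df$generation) && !all(is.na(df$generation))) {
    supplied <- suppressWarnings(as.integer(df$generation[match(ped$id, trimws(as.character(df$id)))]))
    gen[!is.na(supplied)] <- supplied[!is.na(supplied)]
  }
  ped$generation <- gen

  founders <- ped$id[is.na(ped$sire)]
  lines <- unique(ped$line[!is.na(ped$line)])
  structure(ped,
            founder_ids = founders,
            lines = lines,
            class = c("cross_pedigree", "data.frame"))
}

# Kahn topological sort; raises a named error on cycles.
.topo_order <- function(sire_i, dam_i, ids) {
  n <- length(ids)
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(sire_i[k], dam_i[k])) {
      if (!is.na(p)) {
        indeg[k] <- indeg[k] + 1L
        children[[p]] <- c(children[[p]], k)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    k <- queue[1]; queue <- queue[-1]
    ord <- c(ord, k)
    for (ch in children[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("pedigree_cycle: ", paste(ids[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Read a pedigree from CSV
#'
#' Expected header: `id,sire,dam,sex,line[,generation]`.  Unknown parents are
#' `0` or empty; sex is coded `1`/`2` or `M`/`F`.
#'
#' @param path path to a CSV file.
#' @return A validated [pedigree()] object in topological order.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree_file_not_found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  pedigree(df)
}

#' @export
print.cross_pedigree <- function(x, ...) {
  cat(sprintf("<cross_pedigree> %d individuals (%d founders, lines: %s)\n",
              nrow(x), length(attr(x, "founder_ids")),
              paste(attr(x, "lines"), collapse = ", ")))
  utils::str(as.data.frame(utils::head(x, 6)))
  invisible(x)
}

#' Founder ids of a pedigree
#' @param ped a `cross_pedigree`.
#' @return Character vector of founder ids in pedigree order.
#' @export
founder_ids <- function(ped) attr(ped, "founder_ids")

#' Founder line labels of a pedigree
#' @param ped a `cross_pedigree`.
#' @return Character vector of line labels in first-appearance order.
#' @export
line_labels <- function(ped) attr(ped, "lines")

#' Expected line-of-origin composition of transmitted gametes
#'
#' For every individual, the probability vector over founder lines describing
#' the expected line of origin of an allele in a gamete that the individual
#' transmits.  In the autosomal context a founder of line L transmits L
#' alleles with certainty and a non-founder's gamete is an equal mixture of
#' the gametes received from its two parents.  In the X context a male
#' transmits, unchanged, the X gamete he received from his dam, while a
#' female transmits an equal mixture of her sire's X and her dam's
#' transmitted X.
#'
#' Every row sums to one; in a two-line cross the autosomal composition is
#' (1/2, 1/2) for every individual from the F1 onward, while the X
#' composition oscillates around its asymptote with halving amplitude.
#'
#' @param ped a `cross_pedigree`.
#' @return list with elements `autosomal` and `x`, each an individuals-by-lines
#'   matrix of line-origin probabilities (rows sum to 1).
#' @export
line_composition <- function(ped) {
  stopifnot(inherits(ped, "cross_pedigree"))
  lines <- line_labels(ped)
  n <- nrow(ped); L <- length(lines)
  sire_i <- match(ped$sire, ped$id)
  dam_i  <- match(ped$dam, ped$id)
  fa <- matrix(0, n, L, dimnames = list(ped$id, lines))
  fx <- fa
  for (k in seq_len(n)) {
    if (is.na(sire_i[k])) {
      fa[k, ped$line[k]] <- 1
      fx[k, ped$line[k]] <- 1
    } else {
      fa[k, ] <- 0.5 * (fa[sire_i[k], ] + fa[dam_i[k], ])
      fx[k, ] <- if (ped$sex[k] == "M") fx[dam_i[k], ]
                 else 0.5 * (fx[sire_i[k], ] + fx[dam_i[k], ])
    }
  }
  list(autosomal = fa, x = fx)
}
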