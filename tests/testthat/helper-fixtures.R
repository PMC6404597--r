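# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# two fully inbred lines fixed for opposite alleles; 4 males of line A,
# 4 females of line B (plus optionally both sexes per line)
inbred_opposite_fixture <- function(n_a = 20, n_x = 10, template = "ail",
                                    generations = 4, both_sexes = FALSE,
                                    seed = 1) {
  founders <- if (both_sexes)
    list(A = c(M = 2, F = 2), B = c(M = 2, F = 2))
  else NULL
  make_fixture(freq_model = "fixed-opposite", template = template,
               founders = founders,
               markers = c(autosomal = n_a, x = n_x),
               generations = generations, seed = seed)
}

# random two-line fixture with uniform(0,1) line frequencies
uniform_fixture <- function(seed, n_a = 50, n_x = 20, template = "ail",
                            generations = 4, litter_size = 6, ...) {
  make_fixture(freq_model = "uniform", template = template,
               markers = c(autosomal = n_a, x = n_x),
               generations = generations, litter_size = litter_size,
               seed = seed, ...)
}

# a tiny hand-built pedigree: A-male x B-female founder pair, F1 pair,
# one F2 female
tiny_cross_pedigree <- function() {
  pedigree(data.frame(
    id = c("sA", "dB", "f1m", "f1f", "f2f"),
    sire = c("0", "0", "sA", "sA", "f1m"),
    dam = c("0", "0", "dB", "dB", "f1f"),
    sex = c("M", "F", "M", "F", "F"),
    line = c("A", "B", "", "", "")
  ))
}

# founder_geno built directly from a counts matrix (autosomal unless chrom
# given)
geno_from_counts <- function(counts, sex, line, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("1", ncol(counts))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("m", seq_len(ncol(counts)))
  founder_geno(counts, chrom, sex, line,
               alleles = cbind(rep("A", ncol(counts)),
                               rep("a", ncol(counts))))
}

# strip grm class/tags, keep dim + dimnames
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(unclass(m) - t(unclass(m)))), tol)
}
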