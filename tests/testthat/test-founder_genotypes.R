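make_geno_csv <- function(dir, rows) {
  path <- file.path(dir, "geno.csv")
  writeLines(rows, path)
  path
}

two_founder_ped <- function() {
  pedigree(data.frame(id = c("fa", "fb"), sire = c("0", "0"),
                      dam = c("0", "0"), sex = c("M", "F"),
                      line = c("A", "B")))
}

test_that("CSV genotypes load with partitioning and hemizygous collapse", {
  dir <- withr::local_tempdir()
  ped <- two_founder_ped()
  path <- make_geno_csv(dir, c(
    "marker,chrom,allele1,allele2,fa,fb",
    "m1,1,A,a,A/A,a/a",
    "m2,1,A,a,A/a,A/a",
    "m3,X,A,a,A/A,A/a",   # male fa: diploid X call collapses to 1
    "m4,X,A,a,a/a,A/A"))
  g <- read_founder_genotypes(path, ped)
  expect_equal(sum(g$partition == "autosomal"), 2)
  expect_equal(sum(g$partition == "x"), 2)
  expect_equal(g$counts["fa", "m3"], 1)
  expect_equal(g$counts["fa", "m4"], 0)
  expect_equal(g$counts["fb", "m2"], 1)
})

test_that("male heterozygous X calls error by default and drop on request", {
  dir <- withr::local_tempdir()
  ped <- two_founder_ped()
  path <- make_geno_csv(dir, c(
    "marker,chrom,allele1,allele2,fa,fb",
    "m1,1,A,a,A/a,A/A",
    "m2,X,A,a,A/a,A/a"))
  expect_error(read_founder_genotypes(path, ped),
               "male_het_x_call.*fa.*m2")
  g <- read_founder_genotypes(path, ped, male_het_x = "drop")
  expect_false("m2" %in% colnames(g$counts))
})

test_that("missing genotypes error by default, impute line means on request", {
  dir <- withr::local_tempdir()
  ped <- pedigree(data.frame(id = c("a1", "a2", "b1"),
                             sire = "0", dam = "0",
                             sex = c("M", "M", "F"),
                             line = c("A", "A", "B")))
  path <- make_geno_csv(dir, c(
    "marker,chrom,allele1,allele2,a1,a2,b1",
    "m1,1,A,a,A/A,0/0,a/a",
    "m2,1,A,a,A/a,A/a,A/A"))
  expect_error(read_founder_genotypes(path, ped), "genotype_missing.*a2.*m1")
  g <- read_founder_genotypes(path, ped, missing = "line-freq")
  expect_equal(g$counts["a2", "m1"], 2)  # line-A mean count at m1
})

test_that("monomorphic-across-founders markers are dropped with a message", {
  dir <- withr::local_tempdir()
  ped <- two_founder_ped()
  path <- make_geno_csv(dir, c(
    "marker,chrom,allele1,allele2,fa,fb",
    "m1,1,A,a,A/A,A/A",    # monomorphic
    "m2,1,A,a,A/a,a/a"))
  expect_message(g <- read_founder_genotypes(path, ped), "monomorphic")
  expect_equal(colnames(g$counts), "m2")
})

test_that("missing founders are reported", {
  dir <- withr::local_tempdir()
  ped <- pedigree(data.frame(id = c("fa", "fb", "fc"), sire = "0",
                             dam = "0", sex = c("M", "F", "F"),
                             line = c("A", "B", "B")))
  path <- make_geno_csv(dir, c(
    "marker,chrom,allele1,allele2,fa,fb",
    "m1,1,A,a,A/A,a/a"))
  expect_error(read_founder_genotypes(path, ped),
               "founder_missing_from_genotypes.*fc")
})

test_that("ped/map pairs round trip against the CSV dialect", {
  fix <- uniform_fixture(11, n_a = 30, n_x = 10, template = "f2")
  dir_csv <- withr::local_tempdir()
  dir_pm <- withr::local_tempdir()
  p_csv <- write_fixture(fix, dir_csv, format = "csv")
  p_pm <- write_fixture(fix, dir_pm, format = "ped_map")
  ped <- read_pedigree(p_csv[["pedigree"]])
  g_csv <- read_founder_genotypes(p_csv[["genotypes"]], ped)
  g_pm <- read_founder_genotypes(p_pm[["ped"]], ped, format = "ped_map")
  fr_csv <- line_frequencies(g_csv)
  fr_pm <- line_frequencies(g_pm)
  # counted alleles may differ between dialects; the GRM must not
  for (part in c("autosomal", "x")) {
    expect_equal(unclass(observed_grm(g_csv, fr_csv, part)),
                 unclass(observed_grm(g_pm, fr_pm, part)),
                 tolerance = 1e-12)
  }
})

test_that("marker classification counts the three categories", {
  # two fully inbred lines, opposite alleles at 10 autosomal loci
  cnt <- rbind(matrix(2, 2, 10), matrix(0, 2, 10))
  g <- geno_from_counts(cnt, sex = c("M", "M", "F", "F"),
                        line = c("A", "A", "B", "B"))
  cls <- classify_markers(g)
  expect_equal(cls$autosomal$all_founders, 10)
  expect_equal(unname(cls$autosomal$within_line), c(0L, 0L))
  expect_equal(cls$autosomal$line_specific, 10L)

  # counts A-line {2,2}, B-line {2,1}: polymorphic across, within B only
  cnt2 <- matrix(c(2, 2, 2, 1), ncol = 1)
  g2 <- geno_from_counts(cnt2, sex = c("M", "M", "F", "F"),
                         line = c("A", "A", "B", "B"))
  cls2 <- classify_markers(g2)
  expect_equal(cls2$autosomal$all_founders, 1)
  expect_equal(cls2$autosomal$within_line[["A"]], 0L)
  expect_equal(cls2$autosomal$within_line[["B"]], 1L)
  expect_equal(cls2$autosomal$line_specific, 0L)
})

test_that("classification is invariant to founder and marker order", {
  fix <- uniform_fixture(13, n_a = 25, n_x = 10, template = "f2")
  g <- fix$genotypes
  cls <- classify_markers(g)
  perm_r <- c(3, 1, 4, 2, 5:nrow(g$counts))[seq_len(nrow(g$counts))]
  perm_c <- rev(seq_len(ncol(g$counts)))
  g2 <- founder_geno(g$counts[perm_r, perm_c], g$chrom[perm_c],
                     g$sex[perm_r], g$line[perm_r],
                     alleles = g$alleles[perm_c, ])
  expect_equal(classify_markers(g2), cls)
})

test_that("swapping the counted allele leaves relationship matrices unchanged", {
  fix <- uniform_fixture(17, n_a = 30, n_x = 12, template = "f2")
  g <- fix$genotypes
  fr <- line_frequencies(g)
  # swap at every locus: c -> ploidy - c
  cnt <- g$counts
  ploidy <- matrix(2, nrow(cnt), ncol(cnt))
  ploidy[g$sex == "M", g$partition == "x"] <- 1
  g_swap <- founder_geno(ploidy - cnt, g$chrom, g$sex, g$line,
                         alleles = g$alleles[, 2:1])
  fr_swap <- line_frequencies(g_swap)
  for (part in c("autosomal", "x")) {
    expect_equal(unclass(observed_grm(g_swap, fr_swap, part)),
                 unclass(observed_grm(g, fr, part)), tolerance = 1e-12)
    m1 <- gametic_moments(fr, part)
    m2 <- gametic_moments(fr_swap, part)
    expect_equal(m2$d, m1$d, tolerance = 1e-12)
    expect_equal(m2$r, m1$r, tolerance = 1e-12)
  }
})
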