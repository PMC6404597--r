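test_that("a minimal pedigree validates and sorts topologically", {
  df <- data.frame(id = c("c", "m", "f"),
                   sire = c("m", "0", "0"),
                   dam = c("f", "0", "0"),
                   sex = c("2", "1", "2"),
                   line = c("", "A", "B"))
  ped <- pedigree(df)
  expect_s3_class(ped, "cross_pedigree")
  expect_equal(length(founder_ids(ped)), 2)
  expect_equal(ped$id[3], "c")  # child last after sorting
  expect_equal(ped$generation, c(0L, 0L, 1L))

  # order independence: already-sorted input gives the same object
  ped2 <- pedigree(df[c(2, 3, 1), ])
  expect_equal(as.data.frame(ped), as.data.frame(ped2))
})

test_that("pedigree validation raises distinct named errors", {
  base <- data.frame(id = c("m", "f", "c"),
                     sire = c("0", "0", "m"),
                     dam = c("0", "0", "f"),
                     sex = c("M", "F", "F"),
                     line = c("A", "B", ""))
  expect_s3_class(pedigree(base), "cross_pedigree")

  bad <- base; bad$sire[3] <- "f"; bad$dam[3] <- "m"
  expect_error(pedigree(bad), "sex_inconsistency")

  bad <- base; bad$sire[3] <- "ghost"
  expect_error(pedigree(bad), "unknown_parent")

  bad <- base; bad$line[1] <- ""
  expect_error(pedigree(bad), "founder_without_line")

  bad <- rbind(base, data.frame(id = "c", sire = "m", dam = "f",
                                sex = "M", line = ""))
  expect_error(pedigree(bad), "duplicate_id")

  bad <- base; bad$dam[3] <- "0"
  expect_error(pedigree(bad), "half_known")

  bad <- base; bad$sex[3] <- "?"
  expect_error(pedigree(bad), "unknown_sex")

  # cycle: two individuals each other's ancestors
  cyc <- data.frame(id = c("m", "f", "x", "y"),
                    sire = c("0", "0", "m", "x"),
                    dam = c("0", "0", "y", "f"),
                    sex = c("M", "F", "M", "F"),
                    line = c("A", "B", "", ""))
  expect_error(pedigree(cyc), "cycle")
})

test_that("pedigree CSV round trips through read_pedigree", {
  fix <- uniform_fixture(3, template = "ail", generations = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fix, dir)
  ped <- read_pedigree(paths[["pedigree"]])
  expect_equal(as.data.frame(ped), as.data.frame(fix$pedigree))
})

test_that("line composition follows the gamete transmission rules", {
  ped <- tiny_cross_pedigree()
  lc <- line_composition(ped)
  # founders: indicators in both contexts
  expect_equal(lc$autosomal["sA", ], c(A = 1, B = 0))
  expect_equal(lc$x["sA", ], c(A = 1, B = 0))
  # F1: equal autosomal mixture
  expect_equal(lc$autosomal["f1f", ], c(A = 0.5, B = 0.5))
  # F1 male X comes from the dam's line
  expect_equal(lc$x["f1m", ], c(A = 0, B = 1))
  # F2 female X: half sire's X (0,1) + half dam's mixture (0.5,0.5)
  expect_equal(lc$x["f2f", ], c(A = 0.25, B = 0.75))
})

test_that("line composition rows sum to one and autosomal mixture is stable", {
  fix <- uniform_fixture(5, template = "ail", generations = 6,
                         litter_size = 4)
  ped <- fix$pedigree
  lc <- line_composition(ped)
  expect_equal(unname(rowSums(lc$autosomal)), rep(1, nrow(ped)))
  expect_equal(unname(rowSums(lc$x)), rep(1, nrow(ped)))
  # autosomal composition is exactly (1/2, 1/2) from F1 onward
  non_f <- ped$generation > 0
  expect_equal(unname(lc$autosomal[non_f, 1]),
               rep(0.5, sum(non_f)))
})

test_that("X composition oscillates toward its asymptote with shrinking amplitude", {
  fix <- uniform_fixture(6, template = "ail", generations = 7,
                         litter_size = 4)
  ped <- fix$pedigree
  lc <- line_composition(ped)
  # one male per generation: line-1 fraction of the X
  gens <- 1:7
  frac <- vapply(gens, function(g) {
    mean(lc$x[ped$generation == g & ped$sex == "M", 1])
  }, numeric(1))
  # asymptote of an A-male x B-female cross: male-line weight 1/3
  dev <- frac - 1 / 3
  expect_true(all(abs(diff(abs(dev))) > 0))        # amplitude changes
  expect_true(all(abs(dev[-1]) < abs(dev[-length(dev)])))  # shrinking
  expect_true(all(sign(dev[-1]) == -sign(dev[-length(dev)])))  # alternating
})

test_that("line composition matches empirical gene-drop line origins", {
  fix <- uniform_fixture(7, template = "ail", generations = 3,
                         litter_size = 4)
  ped <- fix$pedigree
  lc <- line_composition(ped)
  for (part in c("autosomal", "x")) {
    emp <- line_origin_by_genedrop(ped, part, replicates = 400, seed = 2,
                                   loci = 20)
    dev <- abs(emp$mean - lc[[part]])
    tol <- 3 * emp$se + 1e-12
    expect_true(all(dev <= tol),
                info = sprintf("partition %s: max excess %.3g", part,
                               max(dev - tol)))
  }
})
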