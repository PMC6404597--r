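test_that("gamete self-relationships follow the line-composition rule", {
  fix <- uniform_fixture(41, template = "ail", generations = 4)
  ped <- fix$pedigree
  fr <- fix$freqs_true
  lc <- line_composition(ped)
  mom <- gametic_moments(fr, "autosomal")
  s <- gamete_self(lc, mom)
  fid <- founder_ids(ped)
  # founders: s = d of their line
  expect_equal(s[match(fid, ped$id)],
               unname(mom$d[ped$line[match(fid, ped$id)]]))
  # two-line uniform cross: s = 0.5 for everyone from F1 onward
  expect_equal(unname(s[ped$generation >= 1]),
               rep(0.5, sum(ped$generation >= 1)), tolerance = 1e-12)
  # recursion with founder d-values reproduces the composition rule
  fs <- stats::setNames(mom$d[ped$line[match(fid, ped$id)]], fid)
  expect_equal(unname(gamete_self_path(ped, fs, "autosomal")), unname(s),
               tolerance = 1e-14)
})

test_that("autosomal extension reproduces the F1/F2 closed forms", {
  ped <- tiny_cross_pedigree()
  set.seed(6)
  p <- matrix(runif(2 * 40), 2, 40, dimnames = list(c("A", "B"), NULL))
  colnames(p) <- paste0("m", 1:40)
  fr <- line_freqs_from_matrix(p_autosomal = p)
  mom <- gametic_moments(fr, "autosomal")
  e0 <- expected_founder_grm(ped, mom)
  ext <- extend_autosomal(ped, e0, mom)
  a <- unclass(ext)
  dA <- mom$d[["A"]]; dB <- mom$d[["B"]]; rAB <- mom$r["A", "B"]
  # F1 self-relationship
  expect_equal(a["f1m", "f1m"], dA + dB + 2 * rAB, tolerance = 1e-12)
  # F2 self = 1 + g(sire,dam)/2 (and the gamete terms sum to 1)
  expect_equal(a["f2f", "f2f"], 1 + 0.5 * a["f1m", "f1f"],
               tolerance = 1e-12)
  # F1 to founder: average of the founder pair's relationships
  expect_equal(a["f1m", "sA"],
               0.5 * (a["sA", "sA"] + a["dB", "sA"]), tolerance = 1e-12)
  # founder block is the seed, bitwise
  fid <- founder_ids(ped)
  expect_identical(a[fid, fid], unclass(e0)[fid, fid])
})

test_that("inbred-opposite cross zeroes the F1 self-relationships", {
  fix <- inbred_opposite_fixture(generations = 2)
  ped <- fix$pedigree
  fr <- line_frequencies(fix$genotypes)
  ma <- gametic_moments(fr, "autosomal")
  mx <- gametic_moments(fr, "x")
  exta <- extend_autosomal(ped, expected_founder_grm(ped, ma), ma)
  extx <- extend_x(ped, expected_founder_grm(ped, mx), mx)
  f1 <- ped$id[ped$generation == 1]
  f1f <- f1[ped$sex[match(f1, ped$id)] == "F"]
  f1m <- f1[ped$sex[match(f1, ped$id)] == "M"]
  expect_equal(unname(diag(unclass(exta))[f1]), rep(0, length(f1)))
  expect_equal(unname(diag(unclass(extx))[f1f]), rep(0, length(f1f)))
  # F1 male X self is the dam's gamete self-relationship d_B = 0.5
  expect_equal(unname(diag(unclass(extx))[f1m]), rep(0.5, length(f1m)))
})

test_that("equal line frequencies give the classical X rule s = 0.5 always", {
  set.seed(12)
  p <- matrix(runif(30), 1, 30)[c(1, 1), ]  # identical rows
  rownames(p) <- c("A", "B"); colnames(p) <- paste0("x", 1:30)
  fr <- line_freqs_from_matrix(p_x = p)
  mom <- gametic_moments(fr, "x")
  fix <- uniform_fixture(43, template = "ail", generations = 6,
                         litter_size = 4)
  ped <- fix$pedigree
  s <- gamete_self(line_composition(ped), mom)
  expect_equal(unname(s), rep(0.5, nrow(ped)), tolerance = 1e-12)
})

test_that("the extension is symmetric and keeps its seed bitwise", {
  fix <- uniform_fixture(47, template = "ail", generations = 5,
                         litter_size = 4)
  ped <- fix$pedigree
  fr <- line_frequencies(fix$genotypes)
  fid <- founder_ids(ped)
  for (part in c("autosomal", "x")) {
    mom <- gametic_moments(fr, part)
    e0 <- expected_founder_grm(ped, mom)
    ext <- if (part == "x") extend_x(ped, e0, mom)
           else extend_autosomal(ped, e0, mom)
    expect_symmetric(ext)
    expect_identical(unclass(ext)[fid, fid], unclass(e0)[fid, fid])
    # seeding with the observed matrix also keeps the founder block
    g0 <- observed_grm(fix$genotypes, fr, part)
    cext <- conditional_extension(ped, fix$genotypes, fr, part)
    expect_identical(unclass(cext)[fid, fid], unclass(g0)[fid, fid])
    expect_symmetric(cext)
  }
})

test_that("non-inbred descendants have diagonal s_sire + s_dam, exactly 1 from F2", {
  fix <- uniform_fixture(53, template = "tree", generations = 5)
  ped <- fix$pedigree
  fr <- fix$freqs_true
  mom <- gametic_moments(fr, "autosomal")
  ext <- extend_autosomal(ped, expected_founder_grm(ped, mom), mom)
  d <- diag(unclass(ext))
  expect_equal(unname(d[ped$generation >= 2]),
               rep(1, sum(ped$generation >= 2)), tolerance = 1e-12)
})

test_that("X diagonal generation means oscillate with decreasing amplitude", {
  fix <- uniform_fixture(59, template = "tree", generations = 6, n_x = 40)
  ped <- fix$pedigree
  fr <- fix$freqs_true
  mom <- gametic_moments(fr, "x")
  ext <- extend_x(ped, expected_founder_grm(ped, mom), mom)
  dx <- diag(unclass(ext))
  male_means <- vapply(1:6, function(g) {
    mean(dx[ped$generation == g & ped$sex == "M"])
  }, numeric(1))
  # male diagonal equals the dam-gamete s, whose asymptote is
  # (d_A + 2 d_B) / 3 for an A-male x B-female cross
  lim <- (mom$d[["A"]] + 2 * mom$d[["B"]]) / 3
  dev <- male_means - lim
  expect_true(all(abs(dev[-1]) < abs(dev[-length(dev)])))
  expect_true(all(sign(dev[-1]) == -sign(dev[-length(dev)])))
})

test_that("the infinite-F2 reference summary matches its closed forms", {
  set.seed(3)
  for (i in 1:25) {
    p <- matrix(runif(2 * 30), 2, 30, dimnames = list(c("A", "B"), NULL))
    colnames(p) <- paste0("m", 1:30)
    fr <- line_freqs_from_matrix(p_autosomal = p)
    mom <- gametic_moments(fr, "autosomal")
    f2 <- f2_reference_summary(mom)
    expect_equal(f2$mean_self, 1, tolerance = 1e-12)
    expect_equal(f2$mean_pairwise, 0, tolerance = 1e-12)
    expect_equal(f2$segregation_proportion, -2 * mom$r["A", "B"],
                 tolerance = 1e-14)
  }
  # fully inbred opposite lines: all genetic variance is segregation
  fix <- inbred_opposite_fixture()
  frio <- line_frequencies(fix$genotypes)
  expect_equal(
    f2_reference_summary(gametic_moments(frio, "autosomal"))$segregation_proportion,
    1)
  # not defined beyond two lines
  p3 <- matrix(runif(3 * 10), 3, 10,
               dimnames = list(c("A", "B", "C"), paste0("m", 1:10)))
  fr3 <- line_freqs_from_matrix(p_autosomal = p3)
  expect_error(f2_reference_summary(gametic_moments(fr3, "autosomal")),
               "two_lines")
})
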