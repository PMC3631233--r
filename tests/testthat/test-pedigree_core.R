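# pedigree/map I/O, validation, trimming, allele frequencies, map function

test_that("read_pedfile maps fields, phenotype codes, and allele pairs", {
  f <- withr::local_tempfile(lines = c(
    "F1 A 0 0 1 2 A G",
    "F1 B 0 0 2 1 A A",
    "F1 C A B 1 0 G G",
    "F2 D 0 0 1 -9 0 0"))
  peds <- suppressMessages(read_pedfile(f))
  expect_named(peds, c("F1", "F2"))
  p <- peds$F1
  expect_true(is.na(p$members$father[1]))
  expect_equal(p$members$sex[1], 1L)
  expect_equal(p$members$aff, c(2L, 1L, 0L))           # 2/1/0 codes
  al <- attr(peds, "marker_alleles")
  expect_equal(al$a1, "A"); expect_equal(al$a2, "G")
  expect_equal(unname(p$geno[, "m1"]), c(1L, 0L, 2L))  # {A,G},{A,A},{G,G}
  expect_equal(peds$F2$members$aff, 0L)                 # -9 -> uncertain
  expect_false(peds$F2$members$sampled)                 # all-missing calls
})

test_that("malformed PED lines and half-specified parents are rejected", {
  bad1 <- withr::local_tempfile(lines = c("F1 A 0 0 1 2 A G",
                                          "F1 B 0 0 2 1 A"))
  expect_error(suppressMessages(read_pedfile(bad1)), "column count")
  bad2 <- withr::local_tempfile(lines = "F1 C A 0 1 2 A G")
  expect_error(suppressMessages(read_pedfile(bad2)), "half-specified")
})

test_that("pedigree validation catches cycles, loops, and sex conflicts", {
  expect_error(quick_ped("X", c("a", "b"), c("b", "a"), c("b", "a"),
                         c(1, 2), c(1, 1)))
  # first-cousin marriage = loop
  expect_error(quick_ped("L",
    c("gf", "gm", "p1", "p2", "s1", "s2", "k"),
    c("", "", "gf", "gf", "", "", "p1"),
    c("", "", "gm", "gm", "", "", "p2"),
    c(1, 2, 1, 2, 1, 2, 1), rep(1, 7)), "loop")
  expect_error(quick_ped("S", c("a", "b", "c"), c("", "", "a"),
                         c("", "", "b"), c(2, 2, 1), c(1, 1, 1)),
               "sex inconsistent")
})

test_that("map reading orders by cM, flags missing distance, rejects dups", {
  f <- withr::local_tempfile(lines = c(
    "1 mA 0.0 1000", "1 mB 0.5 2000", "1 mC 1.0 3000", "2 mD NA 500"))
  map <- suppressMessages(read_mapfile(f))
  expect_equal(map$marker[1:3], c("mA", "mB", "mC"))
  expect_equal(diff(map$cm[1:3]), c(0.5, 0.5))
  expect_true(map$missing_cm[map$marker == "mD"])
  dupf <- withr::local_tempfile(lines = c("1 mA 0.0 1000", "1 mA 0.5 2000"))
  expect_error(suppressMessages(read_mapfile(dupf)), "duplicate")
  # cM order disagreeing with bp order warns and cM wins
  oo <- withr::local_tempfile(lines = c("1 mA 2.0 1000", "1 mB 1.0 2000"))
  expect_warning(mm <- suppressMessages(read_mapfile(oo)), "re-sorted")
  expect_equal(mm$marker, c("mB", "mA"))
})

test_that("PED/MAP round-trip is identity on a synthetic cohort", {
  coh <- suppressMessages(generate_cohort(
    cohort_spec(n_families = 4, markers_per_chrom = 5, seed = 11)))
  pd <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_pedfile(coh$peds, pd, coh$map)
  write_mapfile(coh$map, mp)
  back <- suppressMessages(read_pedfile(pd, map = suppressMessages(
    read_mapfile(mp))))
  expect_equal(names(back), names(coh$peds))
  for (fid in names(back)) {
    expect_equal(back[[fid]]$members$id, coh$peds[[fid]]$members$id)
    expect_equal(back[[fid]]$members$aff, coh$peds[[fid]]$members$aff)
    expect_equal(unname(back[[fid]]$geno), unname(coh$peds[[fid]]$geno))
  }
  # and writing the round-tripped cohort reproduces identical bytes
  pd2 <- withr::local_tempfile()
  mp2 <- suppressMessages(read_mapfile(mp))
  write_pedfile(back, pd2, mp2)
  expect_identical(readLines(pd), readLines(pd2))
})

test_that("trim_pedigree removes uninformative leaves only", {
  g <- matrix(c(1L, 0L, 1L, NA), ncol = 1,
              dimnames = list(c("fa", "mo", "c1", "c2"), "m1"))
  p <- quick_ped("T", c("fa", "mo", "c1", "c2"),
                 c("", "", "fa", "fa"), c("", "", "mo", "mo"),
                 c(1, 2, 1, 1), c(2, 1, 2, 1), g)
  tr <- trim_pedigree(p)
  expect_setequal(tr$members$id, c("fa", "mo", "c1"))
  expect_equal(ped_bits(p) - ped_bits(tr), 2L)
  # all informative -> identity
  p2 <- quick_ped("T2", c("fa", "mo", "c1"), c("", "", "fa"),
                  c("", "", "mo"), c(1, 2, 1), c(2, 1, 2),
                  matrix(c(1L, 0L, 1L), ncol = 1,
                         dimnames = list(c("fa", "mo", "c1"), "m1")))
  expect_equal(trim_pedigree(p2)$members$id, p2$members$id)
  # unsampled grandparents retained: they are parents
  p3 <- quick_ped("T3", c("gf", "gm", "fa", "mo", "c1"),
                  c("", "", "gf", "", "fa"), c("", "", "gm", "", "mo"),
                  c(1, 2, 1, 2, 1), c(1, 1, 2, 1, 2),
                  matrix(c(NA, NA, 1L, 0L, 1L), ncol = 1,
                         dimnames = list(c("gf", "gm", "fa", "mo", "c1"),
                                         "m1")))
  expect_true(all(c("gf", "gm") %in% trim_pedigree(p3)$members$id))
})

test_that("trimming never changes the two-point LOD", {
  set.seed(42)
  dm <- disease_model(0.001, c(0, 0.8, 0.8))
  for (k in 1:6) {
    p <- random_fixture_ped(paste0("R", k), n_children = sample(2:4, 1),
                            three_gen = k %% 2 == 0, miss_rate = 0.3)
    tr <- trim_pedigree(p)
    if (nrow(tr$members) == nrow(p$members)) next
    l1 <- twopoint_lod(p, "m1", 0.4, dm)$lod
    l2 <- twopoint_lod(tr, "m1", 0.4, dm)$lod
    expect_equal(l1, l2, tolerance = 1e-12)
  }
})

test_that("allele frequencies: counting, founder classes, missing flags", {
  g <- matrix(c(0L, 1L, 2L, 1L, NA), ncol = 1,
              dimnames = list(paste0("f", 1:5), "m1"))
  p <- quick_ped("A", paste0("f", 1:5), rep("", 5), rep("", 5),
                 c(1, 2, 1, 2, 1), c(1, 1, 1, 1, 2), g)
  map <- markermap("1", "m1", 0, 1000)
  fr <- estimate_allele_freqs(list(p), map, "founders")
  expect_equal(fr$freq2, 0.5)  # {AA, AB, BB, AB} among typed founders
  # unaffected_founders excludes the affected founder (who is untyped anyway)
  g2 <- g; g2[5] <- 2L
  p2 <- quick_ped("A2", paste0("f", 1:5), rep("", 5), rep("", 5),
                  c(1, 2, 1, 2, 1), c(1, 1, 1, 1, 2), g2)
  fr2 <- estimate_allele_freqs(list(p2), map, "unaffected_founders")
  expect_equal(fr2$freq2, 0.5)
  fr3 <- estimate_allele_freqs(list(p2), map, "founders")
  expect_equal(fr3$freq2, 6 / 10)
  # all-missing marker flagged
  g3 <- g; g3[] <- NA_integer_
  p3 <- quick_ped("A3", paste0("f", 1:5), rep("", 5), rep("", 5),
                  c(1, 2, 1, 2, 1), c(1, 1, 1, 1, 1), g3,
                  sampled = rep(TRUE, 5))
  fr4 <- estimate_allele_freqs(list(p3), map, "founders")
  expect_true(is.na(fr4$freq2))
  expect_equal(fr4$freq_nobs, 0L)
})

test_that("gene-dropped cohort recovers generator allele frequencies", {
  coh <- suppressMessages(generate_cohort(
    cohort_spec(n_families = 40, markers_per_chrom = 15, seed = 7,
                founder_unsampled_rate = 0)))
  fr <- estimate_allele_freqs(coh$peds, coh$map, "founders")
  n2 <- fr$freq_nobs
  bound <- 3 * sqrt(coh$map$freq2 * (1 - coh$map$freq2) / (2 * n2))
  ok <- abs(fr$freq2 - coh$map$freq2) < bound
  expect_gte(mean(ok), 0.95)
})

test_that("Haldane map function and inverse", {
  expect_equal(cm_to_theta(0), 0)
  expect_equal(cm_to_theta(50), (1 - exp(-1)) / 2, tolerance = 1e-12)
  expect_lt(abs(cm_to_theta(5000) - 0.5), 1e-12)
  expect_error(cm_to_theta(-1), "nonnegative")
  d <- c(0.1, 1, 10, 80)
  expect_equal(theta_to_cm(cm_to_theta(d)), d, tolerance = 1e-9)
  # kosambi variant monotone and below haldane cap
  expect_lt(cm_to_theta(10, "kosambi"), 0.5)
})
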