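# QC cascade, Mendelian scan, HWE exact test, inbreeding F, map thinning

test_that("mendelian_error_scan classifies PPC and PC violations", {
  map <- markermap("1", "m1", 0, 1000)
  # parents AA x AA, child AB -> one PPC error
  p1 <- nuclear_ped("E1", 1, c(1, 1, 2), c(0, 0, 1))
  e1 <- mendelian_error_scan(list(p1), map)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$kind, "PPC")
  # single typed parent AA, child BB -> one PC error
  p2 <- nuclear_ped("E2", 1, c(1, 1, 2), c(0, NA, 2))
  e2 <- mendelian_error_scan(list(p2), map)
  expect_equal(e2$kind, "PC")
  # AB x AB mating can produce anything
  for (gc in 0:2) {
    p3 <- nuclear_ped("E3", 1, c(1, 1, 2), c(1, 1, gc))
    expect_equal(nrow(mendelian_error_scan(list(p3), map)), 0L)
  }
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  # full enumeration over heterozygote counts, independent implementation
  brute_hwe <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    na <- 2 * nAA + nAB; nb <- 2 * nBB + nAB
    if (na == 0 || nb == 0) return(1)
    hets <- seq(nb %% 2, min(na, nb), by = 2)
    pr <- vapply(hets, function(h) {
      exp(lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
            lfactorial((nb - h) / 2) + h * log(2) + lfactorial(na) +
            lfactorial(nb) - lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[match(nAB, hets)] * (1 + 1e-9)])
  }
  expect_equal(hwe_exact_test(3, 0, 3), 20 / 924, tolerance = 1e-10)
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  p <- hwe_exact_test(25, 50, 25)
  expect_gte(p, exp(lfactorial(100) - 2 * lfactorial(25) - lfactorial(50) +
                      50 * log(2) + 2 * lfactorial(100) - lfactorial(200)))
  set.seed(5)
  for (k in 1:40) {
    n <- sample(1:50, 1)
    nAB <- sample(0:n, 1); rest <- n - nAB
    nAA <- sample(0:rest, 1); nBB <- rest - nAA
    expect_equal(hwe_exact_test(nAA, nAB, nBB), brute_hwe(nAA, nAB, nBB),
                 tolerance = 1e-12)
  }
})

test_that("inbreeding F: closed-form cases and null calibration", {
  # fully heterozygous at MAF 0.5: F = (0 - N/2)/(N - N/2) = -1
  expect_equal(inbreeding_coefficient(rep(1L, 50), rep(0.5, 50)), -1)
  # fully homozygous: F = 1
  expect_equal(inbreeding_coefficient(rep(0L, 50), rep(0.3, 50)), 1)
  expect_warning(f <- inbreeding_coefficient(NA_integer_, 0.3), "informative")
  expect_true(is.na(f))
  # HWE draws: cohort mean approx 0
  set.seed(9)
  q <- runif(300, 0.1, 0.5)
  fs <- replicate(200, {
    g <- rbinom(300, 2, q)
    inbreeding_coefficient(g, q)
  })
  expect_lt(abs(mean(fs)), 3 * sd(fs) / sqrt(200))
})

test_that("snp_filter_cascade removes exactly the planted defects", {
  fx <- qc_fixture()
  batches <- do.call(rbind, lapply(fx$peds, function(p)
    data.frame(family = p$family_id, id = p$members$id[p$members$sampled],
               batch = if (as.integer(sub("F", "", p$family_id)) %% 2)
                 "b1" else "b2")))
  rep <- snp_filter_cascade(fx$peds, fx$map, qc_thresholds(),
                            batches = batches)
  expect_equal(unname(rep$filter_counts),
               c(5L, 0L, 3L, 4L, 2L, 2L, 0L, 0L))
  expect_equal(nrow(rep$map), 100L - 16L)
  # removed markers are exactly the planted ones, attributed first-hit;
  # for duplicated bp the tie-break (call rate, then position) may keep the
  # planted marker and drop its left neighbour, so membership is by pair
  led <- fx$ledger
  for (ty in c("low_call", "mendel", "low_maf", "hwe")) {
    want <- switch(ty, low_call = "call_rate", mendel = "mendel",
                   low_maf = "maf", hwe = "hwe")
    expect_true(all(rep$removed[unique(led$marker[led$type == ty])] == want))
  }
  dup_removed <- names(rep$removed)[rep$removed == "identical_bp"]
  for (mk in unique(led$marker[led$type == "dup_bp"])) {
    j <- match(mk, fx$map$marker)
    pair <- fx$map$marker[fx$map$chrom == fx$map$chrom[j] &
                            fx$map$bp == fx$map$bp[j]]
    expect_equal(sum(dup_removed %in% pair), 1L)
  }
  expect_equal(length(setdiff(names(rep$removed),
                              c(led$marker, dup_removed))), 0L)
})

test_that("cascade masks whole families at surviving Mendel-error markers", {
  # plant a single Mendel error (one family) so the marker survives the
  # family-fraction filter but the family is masked
  coh <- suppressMessages(generate_cohort(cohort_spec(
    n_families = 30, markers_per_chrom = 10, seed = 33,
    founder_unsampled_rate = 0)))
  fx <- plant_defects(coh, n_mendel = 1, mendel_n_families = 1, seed = 5)
  rep <- snp_filter_cascade(fx$peds, fx$map, qc_thresholds())
  mk <- fx$ledger$marker[1]; fam <- fx$ledger$family[1]
  expect_true(mk %in% rep$map$marker)  # 1/30 families < 4%
  expect_true(any(rep$masked$family == fam & rep$masked$marker == mk))
  masked_peds <- apply_mask(fx$peds, rep$masked)
  expect_true(all(is.na(masked_peds[[fam]]$geno[, mk])))
  other <- setdiff(names(fx$peds), rep$masked$family)[1]
  expect_false(all(is.na(masked_peds[[other]]$geno[, mk])))
})

test_that("identical genetic position at 2 dp keeps the first by bp", {
  peds <- drop_two_marker_cohort(25, freq2 = 0.4, seed = 14)
  map <- markermap(c("1", "1"), c("mA", "mB"), cm = c(12.344, 12.339),
                   bp = c(500, 400))
  rep <- snp_filter_cascade(peds, map, qc_thresholds())
  # both round to 12.34; mB has the lower bp and sorts first by cM anyway
  expect_equal(unname(rep$filter_counts[["identical_cm_2dp"]]), 1L)
  expect_equal(rep$map$marker, "mB")
})

test_that("cascade is deterministic and loses few clean markers", {
  coh <- suppressMessages(generate_cohort(cohort_spec(
    n_families = 25, markers_per_chrom = 30, maf_mean = 0.35, maf_sd = 0.05,
    seed = 55, founder_unsampled_rate = 0)))
  r1 <- snp_filter_cascade(coh$peds, coh$map, qc_thresholds(),
                           batches = coh$batches)
  r2 <- snp_filter_cascade(coh$peds, coh$map, qc_thresholds(),
                           batches = coh$batches)
  expect_identical(r1$filter_counts, r2$filter_counts)
  expect_identical(r1$removed, r2$removed)
  expect_identical(r1$masked, r2$masked)
  # clean gene-dropped data with MAF >= 0.2: < 2% lost to MAF/HWE
  lost <- sum(r1$filter_counts[c("maf", "hwe")])
  expect_lt(lost / nrow(coh$map), 0.02 + 3 * sqrt(0.02 / nrow(coh$map)))
})

test_that("select_multipoint_markers walks greedily with MAF preference", {
  map <- markermap("1", paste0("t", 1:10), cm = seq(0, 0.9, by = 0.1),
                   bp = 1:10 * 100)
  map$freq2 <- c(0.1, 0.3, 0.2, 0.4, 0.25, 0.45, 0.2, 0.35, 0.15, 0.42)
  th <- select_multipoint_markers(map, 0.3)
  expect_equal(nrow(th), 4L)  # windows [0,.3) [.3,.6) [.6,.9) [.9,1.2)
  expect_equal(th$marker, c("t2", "t6", "t8", "t10"))  # max MAF per window
  expect_error(select_multipoint_markers(map, 0), "target_spacing")
  # ties broken by lower bp
  map2 <- suppressWarnings(
    markermap("1", c("a", "b"), cm = c(0, 0.1), bp = c(200, 100)))
  map2$freq2 <- c(0.3, 0.3)
  expect_equal(select_multipoint_markers(map2, 1)$marker, "b")
  # spacing exceeding chromosome length -> single best marker
  th3 <- select_multipoint_markers(map, 99)
  expect_equal(th3$marker, "t6")
})

test_that("cohort_inbreeding flags planted autozygous sample", {
  coh <- suppressMessages(generate_cohort(cohort_spec(
    n_families = 20, markers_per_chrom = 40, seed = 12,
    founder_unsampled_rate = 0)))
  fr <- estimate_allele_freqs(coh$peds, coh$map, "founders")
  # force one sample fully homozygous
  p1 <- coh$peds[[1]]
  id1 <- p1$members$id[1]
  coh$peds[[1]]$geno[id1, ] <- ifelse(is.na(p1$geno[id1, ]), NA_integer_,
                                      2L * (p1$geno[id1, ] >= 1L))
  tab <- cohort_inbreeding(coh$peds, fr, f_sd_limit = 4)
  expect_true(id1 %in% tab$id[tab$flagged])
})
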