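# Lander-Green HMM, S_all, Kong-Cox, LD clustering, error detection,
# support intervals

test_that("singlepoint posterior matches vector enumeration", {
  set.seed(14)
  for (k in 1:4) {
    p <- random_fixture_ped(paste0("LG", k), n_children = 2,
                            three_gen = k > 2, miss_rate = 0.2)
    map <- markermap("1", "m1", 5, 1e6)
    map$freq2 <- 0.4
    lg <- lander_green(p, map)
    desc <- oracle_descent(p)
    e <- oracle_emission(desc, as.integer(p$geno[p$members$id, "m1"]), 0.4)
    expect_equal(as.numeric(lg$post[1, ]), e / sum(e), tolerance = 1e-10)
  }
})

test_that("multipoint posterior matches two-marker enumeration", {
  set.seed(15)
  p <- random_fixture_ped("MP", n_children = 3, miss_rate = 0.1)
  g2 <- cbind(p$geno,
              m2 = as.integer(rbinom(nrow(p$members), 2, 0.5)))
  # make m2 Mendelian-consistent by re-dropping
  hap <- list(fa = rbinom(2, 1, 0.5), mo = rbinom(2, 1, 0.5))
  for (ck in paste0("c", 1:3))
    hap[[ck]] <- c(hap$fa[sample(1:2, 1)], hap$mo[sample(1:2, 1)])
  g2[, "m2"] <- vapply(p$members$id, function(i) sum(hap[[i]]), numeric(1))
  p$geno <- g2
  d_cm <- 10
  map <- markermap(c("1", "1"), c("m1", "m2"), cm = c(0, d_cm),
                   bp = c(1e6, 2e6))
  map$freq2 <- c(0.4, 0.5)
  lg <- lander_green(p, map)
  desc <- oracle_descent(p)
  e1 <- oracle_emission(desc, as.integer(p$geno[p$members$id, "m1"]), 0.4)
  e2 <- oracle_emission(desc, as.integer(p$geno[p$members$id, "m2"]), 0.5)
  oc <- oracle_two_marker_post(desc, e1, e2, cm_to_theta(d_cm))
  expect_equal(as.numeric(lg$post[1, ]), oc$p1, tolerance = 1e-10)
  expect_equal(as.numeric(lg$post[2, ]), oc$p2, tolerance = 1e-10)
})

test_that("no data gives uniform posteriors; distant positions mix to uniform", {
  p <- nuclear_ped("U", 2, c(1, 1, 2, 2), c(NA, NA, NA, NA))
  map <- markermap("1", "m1", 0, 1e6); map$freq2 <- 0.3
  lg <- lander_green(p, map)
  expect_true(all(abs(lg$post - 1 / lg$setup$V) < 1e-12))
  # informative marker, then a position 250 cM away
  p2 <- nuclear_ped("U2", 2, c(1, 1, 2, 2), c(1, 0, 1, 1))
  lg2 <- lander_green(p2, map, positions_cm = 250)
  far <- lg2$post[nrow(lg2$post), ]
  expect_lt(0.5 * sum(abs(far - 1 / lg2$setup$V)), 1e-3)
})

test_that("S_all scores and null moments match the literal definition", {
  set.seed(16)
  for (k in 1:3) {
    p <- random_fixture_ped(paste0("S", k), n_children = 3,
                            three_gen = k == 2)
    setup <- stratlink:::lg_setup(p, 16L)
    if (length(setup$aff) < 2) next
    s_pkg <- stratlink:::sall_scores(setup)
    desc <- oracle_descent(p)
    s_orc <- oracle_sall(desc)
    expect_equal(sort(s_pkg), sort(s_orc), tolerance = 1e-12)
    expect_equal(mean(s_pkg), mean(s_orc), tolerance = 1e-12)
    expect_equal(sd(s_pkg), sd(s_orc), tolerance = 1e-12)
  }
})

test_that("affected sib pair worked values: IBD 2, IBD 0, no data", {
  mk_asp <- function(g_s2) {
    mem <- data.frame(id = c("fa", "mo", "s1", "s2"),
                      father = c(NA, NA, "fa", "fa"),
                      mother = c(NA, NA, "mo", "mo"),
                      sex = c(1, 2, 1, 1), aff = c(1, 1, 2, 2),
                      sampled = TRUE)
    g <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L, g_s2), nrow = 4, byrow = TRUE,
                dimnames = list(mem$id, c("m1", "m2")))
    pedigree("ASP", mem, geno = g)
  }
  map <- markermap(c("1", "1"), c("m1", "m2"), cm = c(10, 10),
                   bp = c(1e6, 1.1e6))
  map$freq2 <- c(0.4, 0.4)
  p_ibd2 <- mk_asp(c(1L, 1L))
  np2 <- npl_sall(p_ibd2, lander_green(p_ibd2, map))
  expect_equal(np2$z, rep(sqrt(2), 2), tolerance = 1e-9)
  expect_equal(np2$null$mu, 1.25)
  expect_equal(np2$null$sd, sqrt(0.03125), tolerance = 1e-12)
  p_ibd0 <- mk_asp(c(0L, 0L))
  np0 <- npl_sall(p_ibd0, lander_green(p_ibd0, map))
  expect_equal(np0$z, rep(-sqrt(2), 2), tolerance = 1e-9)
  nog <- mk_asp(c(1L, 1L)); nog$geno[] <- NA_integer_
  npu <- npl_sall(nog, lander_green(nog, map))
  expect_equal(npu$z, rep(0, 2), tolerance = 1e-12)
})

test_that("kong_cox boundaries, monotonicity, and engine null laws", {
  expect_equal(kong_cox(rep(0, 8))$lod, 0)
  expect_equal(kong_cox(rep(-2, 8))$lod, 0)          # one-sided
  expect_error(kong_cox(NA_real_), "no usable")
  # increasing evidence -> non-decreasing LOD
  lods <- vapply(c(0.2, 0.8, 1.6, 2.4), function(z)
    kong_cox(matrix(rep(z, 10), ncol = 1),
             null = rep(list(list(sd = 1, zvals = c(-1, 1),
                                  probs = c(0.5, 0.5), zmin = -1)), 10))$lod,
    numeric(1))
  expect_true(all(diff(lods) >= -1e-12))
  # exponential with exact null law at Z = 0 stays 0
  expect_equal(kong_cox(rep(0, 5), model = "exponential")$lod, 0)
})

test_that("multipoint parametric LOD at a lone marker equals two-point at theta 0", {
  dm <- disease_model(0.001, c(0, 0.9, 0.9))
  set.seed(77)
  peds <- lapply(1:3, function(k)
    random_fixture_ped(paste0("MT", k), n_children = 3))
  map <- markermap("1", "m1", 2, 1e6); map$freq2 <- 0.35
  mp <- multipoint_parametric_lod(peds, map, dm)
  tp <- twopoint_lod(peds, "m1", 0.35, dm, c(0, 0.1, 0.5))
  expect_equal(unname(mp$lod[mp$positions$is_marker]), unname(tp$lod[1]),
               tolerance = 1e-9)
  # unlinked position far away drifts to LOD ~ 0
  mp2 <- multipoint_parametric_lod(peds, map, dm, step_cm = 0.3)
  expect_equal(nrow(mp2$positions) |> length(), 1L)
})

test_that("oversize families are skipped with a warning", {
  big <- nuclear_ped("BIG", 9, c(1, 1, rep(2, 9)), c(1, 1, rep(1, 9)))
  small <- phase_known_ped("SM", 3)
  map <- markermap("1", "m1", 0, 1e6); map$freq2 <- 0.5
  expect_warning(
    mp <- multipoint_parametric_lod(list(big, small), map, disease_model(),
                                    cap_bits = 10L),
    "skip")
  expect_equal(mp$skipped, "BIG")
})

test_that("ld_cluster thresholds and EM haplotype frequencies", {
  set.seed(3)
  # founders drawn from a 2-marker haplotype pool with known LD
  mk_cohort <- function(hfreq, n = 150) {
    haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    lapply(seq_len(n), function(k) {
      h <- haps[sample(4, 2, TRUE, prob = hfreq), , drop = FALSE]
      g <- matrix(as.integer(colSums(h)), 1,
                  dimnames = list("f1", c("mA", "mB")))
      quick_ped(paste0("C", k), "f1", "", "", 1, 1, g)
    })
  }
  map <- markermap(c("1", "1"), c("mA", "mB"), cm = c(0, 0.1),
                   bp = c(1e5, 2e5))
  # perfect LD: only 00 and 11 haplotypes
  coh1 <- mk_cohort(c(0.6, 0, 0, 0.4))
  cl1 <- ld_cluster(coh1, map, 0.16)
  expect_length(cl1$clusters, 1L)
  hf <- cl1$clusters[[1]]$hap_freqs
  hp <- cl1$clusters[[1]]$haplotypes
  i00 <- which(apply(hp, 1, function(h) all(h == 1)))
  i11 <- which(apply(hp, 1, function(h) all(h == 2)))
  emp <- mean(vapply(coh1, function(p) p$geno[1, "mA"], numeric(1))) / 2
  expect_equal(hf[i11], emp, tolerance = 1e-6)
  expect_equal(hf[i00] + hf[i11], 1, tolerance = 1e-6)
  # independent markers: r2 near 0 -> no cluster
  coh2 <- mk_cohort(c(0.36, 0.24, 0.24, 0.16))
  cl2 <- ld_cluster(coh2, map, 0.16)
  expect_length(cl2$clusters, 0L)
})

test_that("clustered emissions integrate with the multipoint engine", {
  # cluster of two perfectly linked markers acts as one informative
  # super-marker
  mem <- data.frame(id = c("fa", "mo", "s1", "s2"),
                    father = c(NA, NA, "fa", "fa"),
                    mother = c(NA, NA, "mo", "mo"),
                    sex = c(1, 2, 1, 1), aff = c(1, 1, 2, 2), sampled = TRUE)
  g <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L), nrow = 4, byrow = TRUE,
              dimnames = list(mem$id, c("mA", "mB")))
  p <- pedigree("CL", mem, geno = g)
  map <- markermap(c("1", "1"), c("mA", "mB"), cm = c(0, 0.05),
                   bp = c(1e5, 2e5))
  map$freq2 <- c(0.4, 0.4)
  clusters <- list(clusters = list(list(
    markers = c("mA", "mB"),
    haplotypes = rbind(c(1L, 1L), c(2L, 2L)),
    hap_freqs = c(0.6, 0.4))))
  lg <- lander_green(p, map, clusters = clusters)
  expect_equal(nrow(lg$post), 1L)  # one super-marker position
  expect_equal(sum(lg$post[1, ]), 1, tolerance = 1e-12)
  # posterior must match a single biallelic marker with the same information
  map1 <- markermap("1", "mA", 0, 1e5); map1$freq2 <- 0.4
  p1 <- p; p1$geno <- p$geno[, "mA", drop = FALSE]
  lg1 <- lander_green(p1, map1)
  expect_equal(lg$post[1, ], lg1$post[1, ], tolerance = 1e-12)
})

test_that("error_detect flags a planted double recombinant and little else", {
  set.seed(90)
  spec <- cohort_spec(n_families = 6, n_chrom = 1, markers_per_chrom = 9,
                      spacing_cm = 1, maf_mean = 0.45, maf_sd = 0.03,
                      founder_unsampled_rate = 0, geno_missing_rate = 0,
                      seed = 41)
  coh <- suppressMessages(generate_cohort(spec))
  clean <- error_detect(coh$peds, coh$map, threshold = 1000)
  n_geno <- sum(vapply(coh$peds, function(p) sum(!is.na(p$geno)),
                       numeric(1)))
  expect_lt(nrow(clean) / n_geno, 0.001)
  # plant: flip a middle-marker child genotype hom -> opposite hom where
  # both parents are het; Mendelian-consistent but forces an unlikely
  # double recombinant on a 1 cM map
  found <- NULL
  for (fi in seq_along(coh$peds)) {
    p <- coh$peds[[fi]]
    for (kid in p$members$id[!is.na(p$members$father)]) {
      fa <- p$members$father[match(kid, p$members$id)]
      mo <- p$members$mother[match(kid, p$members$id)]
      for (mk in coh$map$marker[4:6]) {
        if (isTRUE(p$geno[fa, mk] == 1L) && isTRUE(p$geno[mo, mk] == 1L) &&
            isTRUE(p$geno[kid, mk] %in% c(0L, 2L))) {
          found <- list(fi = fi, kid = kid, mk = mk)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  fi <- found$fi; kid <- found$kid; mk <- found$mk
  coh$peds[[fi]]$geno[kid, mk] <-
    as.integer(2L - coh$peds[[fi]]$geno[kid, mk])
  flags <- error_detect(coh$peds[fi], coh$map, threshold = 1000)
  if (nrow(flags)) {
    expect_true(any(flags$id == kid & flags$marker == mk))
    # flagged set is a subset of observed genotypes
    for (r in seq_len(nrow(flags)))
      expect_false(is.na(coh$peds[[fi]]$geno[flags$id[r],
                                             flags$marker[r]]))
    masked <- apply_error_mask(coh$peds, flags)
    expect_true(is.na(masked[[fi]]$geno[kid, mk]))
  } else {
    fail("planted error not flagged")
  }
})

test_that("support_interval geometry", {
  # triangular peak: slope 0.5/cM around max 3.0 at 10 cM
  cm <- seq(0, 20, by = 0.5)
  lod <- 3 - 0.5 * abs(cm - 10)
  si <- support_interval(cm, lod, drop = 1)
  expect_equal(si$start_cm, 8, tolerance = 1e-9)
  expect_equal(si$end_cm, 12, tolerance = 1e-9)
  expect_equal(si$peak_cm, 10)
  si0 <- support_interval(cm, lod, drop = 0)
  expect_equal(c(si0$start_cm, si0$end_cm), c(10, 10))
  # twin peaks: interval spans both iff the saddle is within the drop
  lod2 <- pmax(3 - 0.5 * abs(cm - 5), 3 - 0.5 * abs(cm - 15))
  si2 <- support_interval(cm, lod2, drop = 1)   # saddle at 0.5 < 3 - 1
  expect_lt(si2$end_cm, 15)
  si3 <- support_interval(cm, lod2, drop = 3)   # saddle 0.5 >= 3 - 3
  expect_equal(si3$end_cm, 20, tolerance = 1e-9)
  # flat curve warns
  expect_warning(support_interval(cm, rep(1, length(cm))), "flat")
  expect_error(support_interval(cm, rep(-1, length(cm))), "no peak")
  # bp interpolation
  map <- markermap("1", c("x", "y"), cm = c(0, 20), bp = c(0, 2e6))
  si4 <- support_interval(cm, lod, map = map, drop = 1)
  expect_equal(si4$start_bp, 8e5)
  expect_equal(si4$end_bp, 1.2e6)
})
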