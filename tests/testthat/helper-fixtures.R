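# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive enumerations, written without reference to
# the package's peeling/HMM code paths.

# quick pedigree builder: parents vectors use "" for founders
quick_ped <- function(fid, id, father, mother, sex, aff, geno = NULL,
                      sampled = NULL) {
  if (is.null(sampled))
    sampled <- if (is.null(geno)) rep(TRUE, length(id)) else
      rowSums(!is.na(geno)) > 0
  mem <- data.frame(id = id,
                    father = ifelse(father == "", NA, father),
                    mother = ifelse(mother == "", NA, mother),
                    sex = sex, aff = aff, sampled = sampled,
                    stringsAsFactors = FALSE)
  pedigree(fid, mem, geno = geno)
}

# nuclear family: parents + nk children; genotype dosages given per member
nuclear_ped <- function(fid, nk, aff, geno_vec = NULL, marker = "m1") {
  id <- c("fa", "mo", paste0("c", seq_len(nk)))
  g <- NULL
  if (!is.null(geno_vec))
    g <- matrix(as.integer(geno_vec), ncol = 1,
                dimnames = list(id, marker))
  quick_ped(fid, id, c("", "", rep("fa", nk)), c("", "", rep("mo", nk)),
            c(1, 2, rep(1, nk)), aff, g)
}

# phase-known fixture: grandparents fix the doubly-heterozygous parent's
# phase; nk affected children each carry the linked marker allele
phase_known_ped <- function(fid, nk) {
  id <- c("gf", "gm", "fa", "mo", paste0("c", seq_len(nk)))
  g <- matrix(c(2L, 0L, 1L, 0L, rep(1L, nk)), ncol = 1,
              dimnames = list(id, "m1"))
  quick_ped(fid, id, c("", "", "gf", "", rep("fa", nk)),
            c("", "", "gm", "", rep("mo", nk)),
            c(1, 2, 1, 2, rep(1, nk)), c(2, 1, 2, 1, rep(2, nk)), g)
}

# random loop-free pedigree of <= n_max members with random genotypes at one
# marker; returns NULL if the draw is degenerate
random_fixture_ped <- function(fid, n_children = 2, three_gen = FALSE,
                               freq2 = 0.4, miss_rate = 0.15) {
  if (three_gen) {
    id <- c("gf", "gm", "fa", "mo", paste0("c", seq_len(n_children)))
    father <- c("", "", "gf", "", rep("fa", n_children))
    mother <- c("", "", "gm", "", rep("mo", n_children))
    sex <- c(1, 2, 1, 2, sample(1:2, n_children, TRUE))
  } else {
    id <- c("fa", "mo", paste0("c", seq_len(n_children)))
    father <- c("", "", rep("fa", n_children))
    mother <- c("", "", rep("mo", n_children))
    sex <- c(1, 2, sample(1:2, n_children, TRUE))
  }
  n <- length(id)
  aff <- sample(c(0L, 1L, 2L), n, TRUE, prob = c(0.15, 0.45, 0.4))
  if (sum(aff == 2L) < 1L) aff[sample(n, 2)] <- 2L
  # gene-drop a marker so genotypes are Mendelian-consistent
  hap <- vector("list", n)
  for (i in seq_len(n)) {
    if (father[i] == "") {
      hap[[i]] <- rbinom(2, 1, freq2)
    } else {
      fi <- match(father[i], id); mi <- match(mother[i], id)
      hap[[i]] <- c(hap[[fi]][sample(1:2, 1)], hap[[mi]][sample(1:2, 1)])
    }
  }
  g <- vapply(hap, sum, numeric(1))
  g[runif(n) < miss_rate] <- NA
  gm <- matrix(as.integer(g), ncol = 1, dimnames = list(id, "m1"))
  quick_ped(fid, id, father, mother, sex, aff, gm)
}

# ---- oracle 1: two-locus likelihood by enumeration over phased states ----
# state s in 1..16 encodes (paternal hap, maternal hap); hap 1..4 = (disease
# allele, marker allele)
oracle_two_locus_loglik <- function(p, marker, freq2, dm, theta) {
  hapd <- c(1, 1, 2, 2); hapm <- c(1, 2, 1, 2)
  m <- p$members; n <- nrow(m)
  gobs <- if (is.null(marker)) rep(NA, n) else as.integer(p$geno[m$id, marker])
  q <- dm$disease_freq
  pd <- c(1 - q, q); pm <- c(1 - freq2, freq2)
  s16 <- 1:16; hp <- ((s16 - 1) %% 4) + 1; hm <- ((s16 - 1) %/% 4) + 1
  prior16 <- pd[hapd[hp]] * pm[hapm[hp]] * pd[hapd[hm]] * pm[hapm[hm]]
  pen16 <- function(aff) if (aff == 2)
    dm$penetrances[(hapd[hp] == 2) + (hapd[hm] == 2) + 1] else rep(1, 16)
  allowed <- lapply(seq_len(n), function(i) {
    ok <- rep(TRUE, 16)
    if (!is.na(gobs[i]))
      ok <- ok & ((hapm[hp] == 2) + (hapm[hm] == 2)) == gobs[i]
    if (m$aff[i] == 2) ok <- ok & pen16(2) > 0
    s16[ok]
  })
  # direct sum over all joint assignments (vectorized over grid rows)
  tg1 <- function(s, gam) {
    hps <- ((s - 1) %% 4) + 1; hms <- ((s - 1) %/% 4) + 1
    pr <- 0
    if (gam == hps) pr <- pr + (1 - theta) / 2
    if (gam == hms) pr <- pr + (1 - theta) / 2
    if (gam == 2 * (hapd[hps] - 1) + hapm[hms]) pr <- pr + theta / 2
    if (gam == 2 * (hapd[hms] - 1) + hapm[hps]) pr <- pr + theta / 2
    pr
  }
  TT <- array(0, c(16, 16, 16))  # [s_child, s_father, s_mother]
  for (sf in 1:16) for (smo in 1:16) for (sc in 1:16)
    TT[sc, sf, smo] <- tg1(sf, ((sc - 1) %% 4) + 1) *
      tg1(smo, ((sc - 1) %/% 4) + 1)
  grid <- as.matrix(do.call(expand.grid, allowed))
  pr <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    w <- pen16(m$aff[i])
    if (is.na(m$father[i])) {
      pr <- pr * prior16[grid[, i]] * w[grid[, i]]
    } else {
      fi <- match(m$father[i], m$id); mi <- match(m$mother[i], m$id)
      pr <- pr * TT[cbind(grid[, i], grid[, fi], grid[, mi])] * w[grid[, i]]
    }
  }
  log(sum(pr))
}

# size of the oracle enumeration for a fixture (used to keep it tractable)
oracle_grid_size <- function(p, marker, dm) {
  gobs <- as.integer(p$geno[p$members$id, marker])
  hapd <- c(1, 1, 2, 2); hapm <- c(1, 2, 1, 2)
  hp <- ((1:16 - 1) %% 4) + 1; hm <- ((1:16 - 1) %/% 4) + 1
  prod(vapply(seq_len(nrow(p$members)), function(i) {
    ok <- rep(TRUE, 16)
    if (!is.na(gobs[i]))
      ok <- ok & ((hapm[hp] == 2) + (hapm[hm] == 2)) == gobs[i]
    if (p$members$aff[i] == 2)
      ok <- ok & dm$penetrances[(hapd[hp] == 2) + (hapd[hm] == 2) + 1] > 0
    sum(ok)
  }, numeric(1)))
}

# ---- oracle 2: inheritance-vector machinery by naive enumeration ----
# descent graph per vector computed independently (plain loops); emission by
# summing over all founder-allele assignments
oracle_descent <- function(p) {
  m <- p$members; n <- nrow(m)
  fo <- which(is.na(m$father)); nf <- which(!is.na(m$father))
  depth <- function(i) if (is.na(m$father[i])) 0 else
    1 + max(depth(match(m$father[i], m$id)), depth(match(m$mother[i], m$id)))
  nf <- nf[order(vapply(nf, depth, numeric(1)))]
  B <- 2L * length(nf)
  V <- 2^B
  pat <- mat <- matrix(0L, V, n)
  for (k in seq_along(fo)) { pat[, fo[k]] <- 2L * k - 1L; mat[, fo[k]] <- 2L * k }
  for (v in seq_len(V)) {
    bits <- as.integer(intToBits(v - 1L))[1:B]
    for (j in seq_along(nf)) {
      i <- nf[j]
      fi <- match(m$father[i], m$id); mi <- match(m$mother[i], m$id)
      pat[v, i] <- if (bits[2 * j - 1] == 0L) pat[v, fi] else mat[v, fi]
      mat[v, i] <- if (bits[2 * j] == 0L) pat[v, mi] else mat[v, mi]
    }
  }
  list(pat = pat, mat = mat, B = B, V = V, n_nodes = 2L * length(fo),
       ids = m$id, aff = which(m$aff == 2L))
}

oracle_emission <- function(desc, dosages, freq2) {
  typed <- which(!is.na(dosages))
  out <- numeric(desc$V)
  nn <- desc$n_nodes
  for (v in seq_len(desc$V)) {
    tot <- 0
    for (mask in 0:(2^nn - 1)) {
      x <- as.integer(intToBits(mask))[1:nn]
      pr <- prod(ifelse(x == 1L, freq2, 1 - freq2))
      ok <- TRUE
      for (i in typed) {
        d <- x[desc$pat[v, i]] + x[desc$mat[v, i]]
        if (d != dosages[i]) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + pr
    }
    out[v] <- tot
  }
  out
}

# S_all by literal definition
oracle_sall <- function(desc) {
  aff <- desc$aff; a <- length(aff)
  s <- numeric(desc$V)
  for (v in seq_len(desc$V)) {
    tot <- 0
    for (mask in 0:(2^a - 1)) {
      take <- as.integer(intToBits(mask))[1:a]
      lab <- ifelse(take == 1L, desc$mat[v, aff], desc$pat[v, aff])
      tot <- tot + prod(factorial(table(lab)))
    }
    s[v] <- tot / 2^a
  }
  s
}

# two-marker multipoint posterior by direct summation over vector pairs
oracle_two_marker_post <- function(desc, e1, e2, theta) {
  V <- desc$V; B <- desc$B
  trans <- matrix(0, V, V)
  for (v1 in seq_len(V)) for (v2 in seq_len(V)) {
    nflip <- sum(as.integer(intToBits(bitwXor(v1 - 1L, v2 - 1L)))[1:B])
    trans[v1, v2] <- theta^nflip * (1 - theta)^(B - nflip)
  }
  joint <- outer(e1, e2) * trans / V
  list(p1 = rowSums(joint) / sum(joint), p2 = colSums(joint) / sum(joint))
}

# ---- oracle 3: single-locus genotype posterior by 3^n enumeration ----
# (for the conditional sampler; affecteds-only contract: unaffected factor 1)
oracle_genotype_posterior <- function(p, dm) {
  m <- p$members; n <- nrow(m)
  q <- dm$disease_freq; f <- dm$penetrances
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  # transmission P(child g | father g, mother g), g = 0/1/2 copies
  tr1 <- function(g) switch(g + 1L, c(1, 0), c(0.5, 0.5), c(0, 1))
  trans <- array(0, c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) {
    pf <- tr1(gf); pm <- tr1(gm)
    for (af in 0:1) for (am in 0:1)
      trans[gf + 1, gm + 1, af + am + 1] <-
        trans[gf + 1, gm + 1, af + am + 1] + pf[af + 1] * pm[am + 1]
  }
  grid <- do.call(expand.grid, rep(list(0:2), n))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ]); pr <- 1
    for (i in seq_len(n)) {
      if (is.na(m$father[i])) pr <- pr * hw[g[i] + 1]
      else pr <- pr * trans[g[match(m$father[i], m$id)] + 1,
                            g[match(m$mother[i], m$id)] + 1, g[i] + 1]
      if (m$aff[i] == 2L) pr <- pr * f[g[i] + 1]
    }
    w[r] <- pr
  }
  w <- w / sum(w)
  marg <- matrix(0, n, 3, dimnames = list(m$id, 0:2))
  for (gv in 0:2) for (i in seq_len(n))
    marg[i, gv + 1] <- sum(w[grid[, i] == gv])
  marg
}

# 30 small null families (no disease locus): gene-dropped genotypes at one
# marker, 2-3 affected children
null_npl_cohort <- function(n_fam = 30, freq2 = 0.3) {
  lapply(seq_len(n_fam), function(k) {
    nk <- sample(2:3, 1)
    hapf <- rbinom(2, 1, freq2); hapm <- rbinom(2, 1, freq2)
    kids <- vapply(seq_len(nk), function(j)
      hapf[sample(1:2, 1)] + hapm[sample(1:2, 1)], numeric(1))
    g <- c(sum(hapf), sum(hapm), kids)
    # parents sometimes untyped
    if (runif(1) < 0.3) g[sample(1:2, 1)] <- NA
    nuclear_ped(sprintf("N%03d", k), nk, c(1, 1, rep(2, nk)), g)
  })
}

# gene-drop a two-marker nuclear cohort with given parental frequencies
drop_two_marker_cohort <- function(n_fam = 25, freq2 = 0.4, seed = 1,
                                   markers = c("mA", "mB")) {
  set.seed(seed)
  lapply(seq_len(n_fam), function(k) {
    hapf <- matrix(rbinom(4, 1, freq2), 2)  # rows = haplotypes, cols = markers
    hapm <- matrix(rbinom(4, 1, freq2), 2)
    kids <- t(vapply(1:2, function(j)
      hapf[sample(1:2, 1), ] + hapm[sample(1:2, 1), ], numeric(2)))
    g <- rbind(colSums(hapf), colSums(hapm), kids)
    rownames(g) <- c("fa", "mo", "c1", "c2"); colnames(g) <- markers
    storage.mode(g) <- "integer"
    p <- nuclear_ped(paste0("F", k), 2, c(1, 1, 2, 2), NULL)
    p$geno <- g
    p
  })
}

# deterministic planted fixture shared with the acceptance test
qc_fixture <- function() {
  coh <- suppressMessages(generate_cohort(cohort_spec(
    n_families = 30, n_chrom = 2, markers_per_chrom = 50, spacing_cm = 0.31,
    maf_mean = 0.42, maf_sd = 0.05, founder_unsampled_rate = 0.1,
    geno_missing_rate = 0.002, seed = 202)))
  plant_defects(coh, n_low_call = 5, call_rate_target = 0.85,
                n_mendel = 3, mendel_n_families = 4,
                n_low_maf = 4, low_maf = 0.01,
                n_hwe = 2, n_dup_bp = 2, seed = 77)
}

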