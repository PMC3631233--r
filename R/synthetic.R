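# Synthetic multiplex-family cohorts: gene-dropped SNP genotypes, disease
# loci with stratum-specific linkage, ascertainment (>= 2 affected sampled),
# planted QC defects, and a truth ledger for tests.

#' Cohort specification
#'
#' Defaults emulate a multiplex CMI-style linkage cohort: 66 families with at
#' least two affected sampled members (affected-per-family mean ~2.8),
#' a dense SNP map (0.31 cM spacing, MAF centered on 0.42), two genotyping
#' batches, and some ungenotyped parents. Generation-mode disease parameters
#' are deliberately *not* the near-zero analysis penetrances: ascertainment
#' by resampling would never terminate under (0, 0.001, 0.001), so linked
#' families segregate a dominant allele with penetrances
#' \code{gen_penetrance} and a forced carrier founder, while analysis is
#' always run with the rare-dominant affecteds-only model.
#'
#' @param n_families Number of families.
#' @param n_chrom,markers_per_chrom,spacing_cm Map shape.
#' @param maf_mean,maf_sd Marker MAF distribution (truncated to [0.05, 0.5]).
#' @param locus Disease-locus placement \code{list(chrom=, cm=)} or
#'   \code{NULL} for null mode (no linked locus anywhere).
#' @param frac_linked Fraction of families linked to \code{locus}.
#' @param gen_penetrance Generation penetrances (0/1/2 disease alleles).
#' @param gen_disease_freq Generation disease-allele frequency.
#' @param background_rate P(affected) in unlinked families (familial
#'   clustering without linkage).
#' @param founder_unsampled_rate P(a founder is ungenotyped).
#' @param geno_missing_rate Per-genotype missingness among sampled members.
#' @param seed RNG seed (every generator call is a deterministic function of
#'   the spec).
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_families = 66, n_chrom = 2, markers_per_chrom = 50,
                        spacing_cm = 0.31, maf_mean = 0.42, maf_sd = 0.09,
                        locus = NULL, frac_linked = 1,
                        gen_penetrance = c(0.01, 0.8, 0.8),
                        gen_disease_freq = 0.01,
                        background_rate = 0.4,
                        founder_unsampled_rate = 0.25,
                        geno_missing_rate = 0.01, seed = 1L) {
  stopifnot(n_families >= 1, frac_linked >= 0, frac_linked <= 1,
            all(gen_penetrance >= 0 & gen_penetrance <= 1),
            background_rate >= 0 && background_rate <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# family structure templates; returns a members data frame
sample_structure <- function() {
  kind <- sample(c("nuclear", "three_gen"), 1L, prob = c(0.6, 0.4))
  if (kind == "nuclear") {
    nk <- sample(3:5, 1L)
    data.frame(id = c("fa", "mo", paste0("c", seq_len(nk))),
               father = c(NA, NA, rep("fa", nk)),
               mother = c(NA, NA, rep("mo", nk)),
               sex = c(1L, 2L, sample(1:2, nk, replace = TRUE)),
               stringsAsFactors = FALSE)
  } else {
    nk <- sample(2:3, 1L)
    data.frame(id = c("gf", "gm", "fa", "mo", paste0("c", seq_len(nk))),
               father = c(NA, NA, "gf", NA, rep("fa", nk)),
               mother = c(NA, NA, "gm", NA, rep("mo", nk)),
               sex = c(1L, 2L, 1L, 2L, sample(1:2, nk, replace = TRUE)),
               stringsAsFactors = FALSE)
  }
}

# gamete from two haplotype rows given positions in cM (Haldane, no
# interference); returns one haplotype row
recombine <- function(h1, h2, cm) {
  k <- length(cm)
  cur <- sample(1:2, 1L)
  src <- integer(k)
  src[1] <- cur
  if (k > 1L) {
    sw <- stats::runif(k - 1L) < cm_to_theta(diff(cm))
    for (j in 2:k) { if (sw[j - 1L]) cur <- 3L - cur; src[j] <- cur }
  }
  ifelse(src == 1L, h1, h2)
}

#' Generate a synthetic cohort
#'
#' Samples family structures, assigns disease genotypes at the spec's locus
#' (linked families carry a dominant allele entering through a founder),
#' draws phenotypes (generation penetrances for linked families, a background
#' familial rate otherwise), resamples each family until at least two sampled
#' members are affected, and gene-drops the SNP map with Haldane
#' recombination.
#'
#' @param spec A \code{cohort_spec}.
#' @param map Optional pre-built \code{markermap} with \code{freq2} (used by
#'   the heterogeneity generator so both strata share one map).
#' @return List: \code{peds} (list of \code{linkped}), \code{map}
#'   (\code{markermap} with generator \code{freq2}), \code{truth} (per-family
#'   linked status, locus, seed, generator frequencies), \code{batches}
#'   (family/id/batch data frame).
#' @export
generate_cohort <- function(spec, map = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  if (is.null(map)) {
    M <- spec$n_chrom * spec$markers_per_chrom
    map <- markermap(
      chrom = rep(as.character(seq_len(spec$n_chrom)),
                  each = spec$markers_per_chrom),
      marker = paste0("m", seq_len(M)),
      cm = rep(spacing_grid(spec$markers_per_chrom, spec$spacing_cm),
               spec$n_chrom),
      bp = rep(round(seq(1e6, by = 25e3,
                         length.out = spec$markers_per_chrom)),
               spec$n_chrom))
    # allele 2 is the minor-or-equal allele by construction
    map$freq2 <- pmin(pmax(stats::rnorm(nrow(map), spec$maf_mean,
                                        spec$maf_sd), 0.05), 0.5)
  }
  peds <- list(); truth_rows <- list(); batch_rows <- list()
  for (fidx in seq_len(spec$n_families)) {
    fid <- sprintf("F%03d", fidx)
    linked <- !is.null(spec$locus) && stats::runif(1) < spec$frac_linked
    fam <- sample_family(spec, map, fid, linked)
    peds[[fid]] <- fam
    truth_rows[[fid]] <- data.frame(family = fid, linked = linked,
                                    stringsAsFactors = FALSE)
    batch_rows[[fid]] <- data.frame(
      family = fid, id = fam$members$id[fam$members$sampled],
      batch = if (fidx %% 2L == 0L) "b2" else "b1",
      stringsAsFactors = FALSE)
  }
  list(peds = peds, map = map,
       truth = list(families = do.call(rbind, truth_rows),
                    locus = spec$locus, seed = spec$seed,
                    freq2 = stats::setNames(map$freq2, map$marker)),
       batches = do.call(rbind, batch_rows))
}

spacing_grid <- function(k, spacing) seq(0, by = spacing, length.out = k)

# one ascertained family (>= 2 affected sampled members)
sample_family <- function(spec, map, fid, linked) {
  f <- spec$gen_penetrance
  for (attempt in seq_len(10000L)) {
    mem <- sample_structure()
    n <- nrow(mem)
    fo <- which(is.na(mem$father))
    # haplotypes: list over individuals, each 2 x (M + 1) with the disease
    # locus spliced into its chromosome at spec$locus (last column = disease)
    pos <- map$cm; chrom <- map$chrom
    hap <- vector("list", n)
    for (k in seq_along(fo)) {
      h <- matrix(stats::rbinom(2L * nrow(map), 1L,
                                rep(map$freq2, each = 2L)), nrow = 2L)
      d <- stats::rbinom(2L, 1L, spec$gen_disease_freq)
      if (linked && k == 1L) d[1] <- 1L  # carrier founder seeds the family
      hap[[fo[k]]] <- list(mk = h, d = d)
    }
    ord <- order(vapply(seq_len(n), function(i) ped_depth(mem, i), numeric(1)))
    for (i in ord) {
      if (!is.na(mem$father[i])) {
        fi <- match(mem$father[i], mem$id); mi <- match(mem$mother[i], mem$id)
        hap[[i]] <- list(mk = matrix(0L, 2L, nrow(map)), d = c(0L, 0L))
        for (s in 1:2) {
          par <- if (s == 1L) hap[[fi]] else hap[[mi]]
          gam <- drop_gamete(par, map, spec$locus)
          hap[[i]]$mk[s, ] <- gam$mk
          hap[[i]]$d[s] <- gam$d
        }
      }
    }
    ncop <- vapply(hap, function(h) sum(h$d), numeric(1))
    p_aff <- if (linked) f[ncop + 1L] else spec$background_rate
    aff <- ifelse(stats::runif(n) < p_aff, AFF_AFFECTED, AFF_UNAFFECTED)
    sampled <- rep(TRUE, n)
    sampled[is.na(mem$father)] <-
      stats::runif(length(fo)) >= spec$founder_unsampled_rate
    if (sum(aff == AFF_AFFECTED & sampled) < 2L) next
    geno <- t(vapply(hap, function(h) colSums(h$mk), numeric(nrow(map))))
    rownames(geno) <- mem$id; colnames(geno) <- map$marker
    geno[!sampled, ] <- NA_integer_
    miss <- matrix(stats::runif(length(geno)) < spec$geno_missing_rate,
                   nrow(geno))
    geno[miss] <- NA_integer_
    mem$aff <- aff
    mem$sampled <- sampled & rowSums(!is.na(geno)) > 0
    return(pedigree(fid, mem, geno = geno))
  }
  stop("family ", fid, ": could not satisfy >= 2 affected sampled members; ",
       "increase generation penetrances or background rate")
}

ped_depth <- function(mem, i) {
  if (is.na(mem$father[i])) return(0)
  1 + max(ped_depth(mem, match(mem$father[i], mem$id)),
          ped_depth(mem, match(mem$mother[i], mem$id)))
}

# one gamete with the disease locus riding along its chromosome
drop_gamete <- function(par, map, locus) {
  if (is.null(locus)) {
    mk <- numeric(nrow(map))
    for (ch in unique(map$chrom)) {
      j <- which(map$chrom == ch)
      mk[j] <- recombine(par$mk[1, j], par$mk[2, j], map$cm[j])
    }
    return(list(mk = mk, d = par$d[sample(1:2, 1L)]))
  }
  mk <- numeric(nrow(map)); d <- NA_integer_
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    if (as.character(locus$chrom) == ch) {
      cmv <- c(map$cm[j], locus$cm)
      ordv <- order(cmv)
      h1 <- c(par$mk[1, j], par$d[1])[ordv]
      h2 <- c(par$mk[2, j], par$d[2])[ordv]
      gam <- recombine(h1, h2, cmv[ordv])
      back <- order(ordv)
      full <- gam[back]
      mk[j] <- full[seq_along(j)]
      d <- full[length(j) + 1L]
    } else {
      mk[j] <- recombine(par$mk[1, j], par$mk[2, j], map$cm[j])
    }
  }
  list(mk = mk, d = d)
}

#' Plant QC defects into a clean cohort
#'
#' Injects, on disjoint marker sets: low-call-rate markers, Mendelian-error
#' trios (parents set to homozygous reference, child to heterozygous),
#' HWE-violating markers (all founders heterozygous, descendants re-dropped),
#' low-MAF markers (column re-dropped at the given frequency), and
#' duplicated physical positions. Returns the defective cohort plus a ledger
#' enumerating every planted defect.
#'
#' @param cohort Output of \code{\link{generate_cohort}}.
#' @param n_low_call,call_rate_target Low-call-rate markers and their target
#'   rate.
#' @param n_mendel,mendel_n_families Mendel-heavy markers; families planted
#'   per marker.
#' @param n_low_maf,low_maf Rare-allele markers and their frequency.
#' @param n_hwe HWE-violating markers.
#' @param n_dup_bp Markers whose bp duplicates the preceding marker.
#' @param seed RNG seed.
#' @return List: \code{peds}, \code{map}, \code{ledger} (data frame type /
#'   marker / family).
#' @export
plant_defects <- function(cohort, n_low_call = 0, call_rate_target = 0.9,
                          n_mendel = 0, mendel_n_families = 3,
                          n_low_maf = 0, low_maf = 0.01,
                          n_hwe = 0, n_dup_bp = 0, seed = 99L) {
  set.seed(seed)
  peds <- cohort$peds; map <- cohort$map
  need <- n_low_call + n_mendel + n_low_maf + n_hwe + n_dup_bp
  if (need > nrow(map) - n_dup_bp)
    stop("defect quota exceeds marker count")
  # never plant on the first marker of a chromosome (dup-bp needs a left
  # neighbour on the same chromosome)
  eligible <- which(!duplicated(map$chrom))
  pool <- sample(setdiff(seq_len(nrow(map)), eligible), need)
  grab <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  lc <- grab(n_low_call); me <- grab(n_mendel); lm <- grab(n_low_maf)
  hw <- grab(n_hwe); db <- grab(n_dup_bp)
  ledger <- list()
  note <- function(type, marker, family = NA_character_)
    ledger[[length(ledger) + 1L]] <<- data.frame(type = type, marker = marker,
                                                 family = family,
                                                 stringsAsFactors = FALSE)
  for (j in lc) {
    mk <- map$marker[j]
    # mask exactly enough observed calls to land on the target rate
    obs <- do.call(rbind, lapply(names(peds), function(f) {
      p <- peds[[f]]
      ids <- p$members$id[p$members$sampled]
      ok <- ids[!is.na(p$geno[ids, mk])]
      if (length(ok)) data.frame(family = f, id = ok) else NULL
    }))
    n_entries <- sum(vapply(peds, function(p) sum(p$members$sampled),
                            numeric(1)))
    n_mask <- nrow(obs) - round(call_rate_target * n_entries)
    if (n_mask > 0) {
      pick <- obs[sample(nrow(obs), min(n_mask, nrow(obs))), , drop = FALSE]
      for (r in seq_len(nrow(pick)))
        peds[[pick$family[r]]]$geno[pick$id[r], mk] <- NA_integer_
    }
    note("low_call", mk)
  }
  for (j in me) {
    mk <- map$marker[j]
    cands <- Filter(function(f) {
      p <- peds[[f]]; m <- p$members
      any(!is.na(m$father) & !is.na(p$geno[m$id, mk]) &
            !is.na(p$geno[ifelse(is.na(m$father), m$id, m$father), mk]) &
            !is.na(p$geno[ifelse(is.na(m$mother), m$id, m$mother), mk]))
    }, names(peds))
    pick <- utils::head(sample(cands), mendel_n_families)
    for (f in pick) {
      p <- peds[[f]]; m <- p$members
      kid <- which(!is.na(m$father) & !is.na(p$geno[m$id, mk]))[1]
      peds[[f]]$geno[m$father[kid], mk] <- 0L
      peds[[f]]$geno[m$mother[kid], mk] <- 0L
      peds[[f]]$geno[m$id[kid], mk] <- 1L
      note("mendel", mk, f)
    }
  }
  for (j in lm) {
    mk <- map$marker[j]
    peds <- regen_marker(peds, mk, low_maf)
    map$freq2[j] <- low_maf
    note("low_maf", mk)
  }
  for (j in hw) {
    mk <- map$marker[j]
    peds <- lapply(peds, function(p) {
      fo <- is.na(p$members$father)
      # all founders heterozygous, children re-dropped consistently
      hap <- lapply(seq_len(nrow(p$members)), function(i)
        if (fo[i]) sample(c(0L, 1L)) else c(NA_integer_, NA_integer_))
      ordv <- order(vapply(seq_len(nrow(p$members)),
                           function(i) ped_depth(p$members, i), numeric(1)))
      for (i in ordv) if (!fo[i]) {
        fi <- match(p$members$father[i], p$members$id)
        mi <- match(p$members$mother[i], p$members$id)
        hap[[i]] <- c(hap[[fi]][sample(1:2, 1L)], hap[[mi]][sample(1:2, 1L)])
      }
      newg <- vapply(hap, sum, integer(1))
      keep_na <- is.na(p$geno[, mk])
      p$geno[, mk] <- ifelse(keep_na, NA_integer_, newg)
      p
    })
    note("hwe", mk)
  }
  for (j in db) {
    left <- max(which(map$chrom == map$chrom[j] & seq_len(nrow(map)) < j))
    map$bp[j] <- map$bp[left]
    note("dup_bp", map$marker[j])
  }
  list(peds = peds, map = map,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(type = character(0), marker = character(0),
                    family = character(0)))
}

# re-drop one marker column at a new founder frequency (pedigree-consistent)
regen_marker <- function(peds, mk, freq) {
  lapply(peds, function(p) {
    n <- nrow(p$members)
    fo <- is.na(p$members$father)
    hap <- lapply(seq_len(n), function(i)
      if (fo[i]) stats::rbinom(2L, 1L, freq) else c(NA_integer_, NA_integer_))
    ordv <- order(vapply(seq_len(n), function(i) ped_depth(p$members, i),
                         numeric(1)))
    for (i in ordv) if (!fo[i]) {
      fi <- match(p$members$father[i], p$members$id)
      mi <- match(p$members$mother[i], p$members$id)
      hap[[i]] <- c(hap[[fi]][sample(1:2, 1L)], hap[[mi]][sample(1:2, 1L)])
    }
    newg <- vapply(hap, sum, integer(1))
    p$geno[, mk] <- ifelse(is.na(p$geno[, mk]), NA_integer_, newg)
    p
  })
}

#' Qualifying clinical conditions for stratification
#' @return Character vector of the default connective-tissue-disorder
#'   related conditions.
#' @export
ctd_conditions <- function() c(
  "hypermobility", "kyphosis", "aneurysm", "mitral_valve_prolapse",
  "pectus_excavatum", "scoliosis", "orthostatic_hypotension",
  "supraventricular_tachycardia", "heart_valve_disease", "heart_murmur")

#' Generate a two-stratum heterogeneity cohort
#'
#' Families in stratum A (default 34, emulating CTD-positive) and stratum B
#' (default 32, CTD-negative) are generated with independent linkage
#' configurations: each stratum is linked at its own locus or unlinked. The
#' clinical-flag table marks stratum-A families with 1-2 qualifying
#' conditions, so \code{\link{stratify}} reproduces the A/B split.
#'
#' @param n_a,n_b Stratum sizes.
#' @param locus_a,locus_b Disease locus per stratum (\code{list(chrom, cm)}
#'   or \code{NULL} for unlinked).
#' @param spec Base \code{cohort_spec} (families/locus fields are overridden
#'   per stratum).
#' @param seed RNG seed.
#' @return List: \code{peds}, \code{map}, \code{flags} (wide condition
#'   table), \code{truth}, \code{batches}.
#' @export
generate_heterogeneity_cohort <- function(n_a = 34, n_b = 32,
                                          locus_a = NULL,
                                          locus_b = list(chrom = "1", cm = 7),
                                          spec = cohort_spec(), seed = 1L) {
  spec_a <- spec; spec_a$n_families <- n_a; spec_a$locus <- locus_a
  spec_a$seed <- seed
  spec_b <- spec; spec_b$n_families <- n_b; spec_b$locus <- locus_b
  spec_b$seed <- seed + 1000003L
  a <- generate_cohort(spec_a)
  b <- generate_cohort(spec_b, map = a$map)
  b$peds <- stats::setNames(lapply(b$peds, function(p) {
    p$family_id <- sub("^F", "G", p$family_id); p
  }), sub("^F", "G", names(b$peds)))
  b$truth$families$family <- sub("^F", "G", b$truth$families$family)
  b$batches$family <- sub("^F", "G", b$batches$family)
  peds <- c(a$peds, b$peds)
  set.seed(seed + 7L)
  conds <- ctd_conditions()
  flags <- as.data.frame(matrix(FALSE, length(peds), length(conds),
                                dimnames = list(NULL, conds)))
  flags <- cbind(data.frame(family = names(peds),
                            stringsAsFactors = FALSE), flags)
  for (i in seq_len(n_a))
    flags[i, sample(conds, sample(1:2, 1L))] <- TRUE
  truth <- rbind(cbind(a$truth$families, stratum = "positive",
                       stringsAsFactors = FALSE),
                 cbind(b$truth$families, stratum = "negative",
                       stringsAsFactors = FALSE))
  list(peds = peds, map = a$map, flags = flags,
       truth = list(families = truth, locus_a = locus_a, locus_b = locus_b,
                    seed = seed, freq2 = a$truth$freq2),
       batches = rbind(a$batches, b$batches))
}
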