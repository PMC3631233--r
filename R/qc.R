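# Marker/sample quality control: Mendelian scan, HWE exact test, the SNP
# filter cascade, inbreeding F, and multipoint map thinning.

#' QC thresholds
#'
#' Defaults follow the standard SNP-array family-QC cascade: call rate >= 98%,
#' Mendelian errors in > 4% of scoreable families, MAF >= 0.05 and HWE exact
#' p >= 0.001 in unaffected founders, plus map-position filters and an
#' inbreeding-F outlier limit of 4 SD.
#'
#' @param min_call_rate,mendel_family_frac,min_maf,hwe_alpha Numeric rates in
#'   [0,1].
#' @param drop_identical_bp,drop_missing_cm,drop_identical_cm_2dp Logical
#'   map-position filters.
#' @param f_sd_limit Inbreeding-F outlier limit in SD units.
#' @return A \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, mendel_family_frac = 0.04,
                          min_maf = 0.05, hwe_alpha = 0.001,
                          drop_identical_bp = TRUE, drop_missing_cm = TRUE,
                          drop_identical_cm_2dp = TRUE, f_sd_limit = 4) {
  rates <- c(min_call_rate, mendel_family_frac, min_maf, hwe_alpha)
  if (any(rates < 0 | rates > 1)) stop("QC rates must be in [0,1]")
  structure(list(min_call_rate = min_call_rate,
                 mendel_family_frac = mendel_family_frac,
                 min_maf = min_maf, hwe_alpha = hwe_alpha,
                 drop_identical_bp = drop_identical_bp,
                 drop_missing_cm = drop_missing_cm,
                 drop_identical_cm_2dp = drop_identical_cm_2dp,
                 f_sd_limit = f_sd_limit), class = "qc_thresholds")
}

#' Mendelian inconsistency scan
#'
#' Parent-parent-child (both parents genotyped): child dosage outside the
#' feasible transmission range. Parent-child (exactly one parent genotyped):
#' opposite homozygotes. Returns every violation.
#'
#' @param peds List of \code{linkped}.
#' @param map \code{markermap} (defines the marker set scanned).
#' @return Data frame: family, marker, child, kind ("PPC"/"PC").
#' @export
mendelian_error_scan <- function(peds, map) {
  out <- list()
  for (p in peds) {
    m <- p$members
    g <- p$geno[, map$marker, drop = FALSE]
    for (i in which(!is.na(m$father))) {
      gc <- g[m$id[i], ]
      gf <- g[m$father[i], ]; gm <- g[m$mother[i], ]
      both <- !is.na(gc) & !is.na(gf) & !is.na(gm)
      ppc <- both & (gc < (gf == 2L) + (gm == 2L) |
                     gc > (gf >= 1L) + (gm >= 1L))
      one_f <- !is.na(gc) & !is.na(gf) & is.na(gm)
      one_m <- !is.na(gc) & is.na(gf) & !is.na(gm)
      pc <- (one_f & ((gf == 0L & gc == 2L) | (gf == 2L & gc == 0L))) |
            (one_m & ((gm == 0L & gc == 2L) | (gm == 2L & gc == 0L)))
      hit <- which(ppc | pc)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          family = p$family_id, marker = map$marker[hit], child = m$id[i],
          kind = ifelse(ppc[hit], "PPC", "PC"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), marker = character(0),
                      child = character(0), kind = character(0)))
  do.call(rbind, out)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional exact test: given the allele counts, the p-value is the sum of
#' probabilities of all heterozygote counts whose probability does not exceed
#' the observed one.
#'
#' @param nAA,nAB,nBB Genotype counts (nonnegative).
#' @return Exact p-value; 1 for monomorphic markers.
#' @export
hwe_exact_test <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("counts must be nonnegative")
  n <- nAA + nAB + nBB
  if (n == 0) stop("hwe_exact_test: no observations")
  nb <- nAB + 2L * nBB  # minor-side allele count bookkeeping not required
  na <- nAB + 2L * nAA
  if (na == 0L || nb == 0L) return(1)
  hets <- seq(nb %% 2L, min(na, nb), by = 2L)
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial((nb - hets) / 2) + hets * log(2) +
    lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Method-of-moments inbreeding coefficient
#'
#' F = (O_hom - E_hom) / (N - E_hom) over non-missing markers, with expected
#' homozygosity from founder allele frequencies.
#'
#' @param geno Integer dosage vector over markers (NA = missing).
#' @param freq2 Matching allele-2 frequency vector.
#' @return F, or NA (with a warning) when no informative marker is available.
#' @export
inbreeding_coefficient <- function(geno, freq2) {
  ok <- !is.na(geno) & !is.na(freq2) & freq2 > 0 & freq2 < 1
  if (!any(ok)) { warning("no informative markers for F"); return(NA_real_) }
  g <- geno[ok]; q <- freq2[ok]
  N <- length(g)
  e_hom <- sum(1 - 2 * q * (1 - q))
  o_hom <- sum(g != 1L)
  (o_hom - e_hom) / (N - e_hom)
}

#' Cohort inbreeding screen
#'
#' Computes F per sampled individual and flags |F - mean| > f_sd_limit * SD.
#'
#' @param peds List of \code{linkped}.
#' @param map \code{markermap} with \code{freq2}.
#' @param f_sd_limit SD-unit outlier limit (default 4).
#' @return Data frame: family, id, f, flagged.
#' @export
cohort_inbreeding <- function(peds, map, f_sd_limit = 4) {
  rows <- list()
  for (p in peds) {
    for (id in p$members$id[p$members$sampled]) {
      f <- suppressWarnings(
        inbreeding_coefficient(p$geno[id, map$marker], map$freq2))
      rows[[length(rows) + 1L]] <- data.frame(family = p$family_id, id = id,
                                              f = f)
    }
  }
  tab <- do.call(rbind, rows)
  mu <- mean(tab$f, na.rm = TRUE); sdv <- stats::sd(tab$f, na.rm = TRUE)
  tab$flagged <- !is.na(tab$f) & sdv > 0 & abs(tab$f - mu) > f_sd_limit * sdv
  tab
}

#' SNP filter cascade
#'
#' Applies, in order: call rate, cross-batch presence, Mendelian family
#' fraction, MAF (unaffected founders), HWE exact test (unaffected founders),
#' identical physical position, missing genetic distance, identical genetic
#' position at two decimal places (keep first by bp). Each removed marker is
#' attributed to the first filter that removes it. Additionally every
#' (family, marker) with a Mendelian inconsistency among surviving markers is
#' masked: the whole family's genotypes at that marker are set missing via
#' the returned ledger.
#'
#' @param peds List of \code{linkped}.
#' @param map \code{markermap}.
#' @param thresholds A \code{qc_thresholds}.
#' @param batches Optional data frame (family, id, batch); enables the
#'   cross-batch filter.
#' @return A \code{qc_report}: \code{map} (surviving markers with unaffected-
#'   founder \code{freq2}), \code{filter_counts}, \code{removed},
#'   \code{masked}, \code{sample_flags}, \code{n_input}.
#' @export
snp_filter_cascade <- function(peds, map, thresholds = qc_thresholds(),
                               batches = NULL) {
  if (!inherits(thresholds, "qc_thresholds"))
    stop("thresholds must be a qc_thresholds object")
  filt_names <- c("call_rate", "cross_batch", "mendel", "maf", "hwe",
                  "identical_bp", "missing_cm", "identical_cm_2dp")
  removed <- character(0)
  gall <- do.call(rbind, lapply(peds, function(p)
    p$geno[p$members$id[p$members$sampled], map$marker, drop = FALSE]))
  call_rate <- colMeans(!is.na(gall))

  take <- function(markers, filter) {
    markers <- setdiff(markers, names(removed))
    if (length(markers))
      removed <<- c(removed, stats::setNames(rep(filter, length(markers)),
                                             markers))
    invisible(NULL)
  }

  take(map$marker[call_rate < thresholds$min_call_rate], "call_rate")

  if (!is.null(batches) && length(unique(batches$batch)) > 1L) {
    key <- paste(rep(vapply(peds, `[[`, character(1), "family_id"),
                     times = vapply(peds, function(p) sum(p$members$sampled),
                                    integer(1))), rownames(gall))
    bkey <- paste(batches$family, batches$id)
    bat <- batches$batch[match(key, bkey)]
    if (anyNA(bat)) stop("batch labels missing for some sampled individuals")
    present <- vapply(split(seq_len(nrow(gall)), bat), function(rows)
      colSums(!is.na(gall[rows, , drop = FALSE])) > 0L,
      logical(nrow(map)))
    take(map$marker[!apply(present, 1, all)], "cross_batch")
  }

  errs <- mendelian_error_scan(peds, map)
  scoreable <- Reduce(`+`, lapply(peds, function(p) {
    m <- p$members
    kid <- which(!is.na(m$father))
    if (!length(kid)) return(rep(0L, nrow(map)))
    gc <- !is.na(p$geno[m$id[kid], map$marker, drop = FALSE])
    gp <- !is.na(p$geno[m$father[kid], map$marker, drop = FALSE]) |
          !is.na(p$geno[m$mother[kid], map$marker, drop = FALSE])
    as.integer(colSums(gc & gp) > 0L)
  }))
  names(scoreable) <- map$marker
  err_fams <- tapply(errs$family, errs$marker,
                     function(x) length(unique(x)))
  frac <- rep(0, nrow(map)); names(frac) <- map$marker
  frac[names(err_fams)] <- err_fams / pmax(scoreable[names(err_fams)], 1)
  take(map$marker[frac > thresholds$mendel_family_frac], "mendel")

  fr <- estimate_allele_freqs(peds, map, who = "unaffected_founders")
  maf <- pmin(fr$freq2, 1 - fr$freq2)
  take(map$marker[is.na(maf) | maf < thresholds$min_maf], "maf")

  hwe_p <- vapply(seq_len(nrow(map)), function(j) {
    g <- unlist(lapply(peds, function(p) {
      sel <- is.na(p$members$father) & p$members$aff != AFF_AFFECTED
      p$geno[p$members$id[sel], map$marker[j]]
    }))
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  take(map$marker[hwe_p < thresholds$hwe_alpha], "hwe")

  if (thresholds$drop_identical_bp) {
    grp <- split(seq_len(nrow(map)), paste(map$chrom, map$bp))
    drop_bp <- unlist(lapply(grp, function(idx) {
      if (length(idx) < 2L) return(integer(0))
      # keep highest call rate, then lowest bp (row order is bp-stable)
      keep <- idx[order(-call_rate[idx], idx)][1]
      setdiff(idx, keep)
    }))
    take(map$marker[drop_bp], "identical_bp")
  }
  if (thresholds$drop_missing_cm)
    take(map$marker[map$missing_cm], "missing_cm")
  if (thresholds$drop_identical_cm_2dp) {
    alive <- setdiff(map$marker, names(removed))
    sub <- map[map$marker %in% alive, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$bp), , drop = FALSE]
    dup <- duplicated(paste(sub$chrom, round(sub$cm, 2)))
    take(sub$marker[dup], "identical_cm_2dp")
  }

  surviving <- setdiff(map$marker, names(removed))
  out_map <- fr[fr$marker %in% surviving, , drop = FALSE]
  class(out_map) <- class(map)
  masked <- errs[errs$marker %in% surviving, c("family", "marker")]
  masked <- unique(masked)
  rownames(masked) <- NULL
  counts <- stats::setNames(integer(length(filt_names)), filt_names)
  tb <- table(factor(removed, levels = filt_names))
  counts[names(tb)] <- as.integer(tb)
  flags <- cohort_inbreeding(peds, out_map, thresholds$f_sd_limit)
  structure(list(map = out_map, filter_counts = counts, removed = removed,
                 masked = masked,
                 sample_flags = flags[flags$flagged, , drop = FALSE],
                 n_input = nrow(map)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers in, %d surviving\n", x$n_input,
              nrow(x$map)))
  print(x$filter_counts)
  cat(sprintf("masked family-marker pairs: %d; flagged samples: %d\n",
              nrow(x$masked), nrow(x$sample_flags)))
  invisible(x)
}

#' Apply the masked-genotype ledger
#'
#' Sets each family's genotypes to missing at every ledgered marker.
#'
#' @param peds List of \code{linkped}.
#' @param masked Data frame (family, marker).
#' @return The cohort with masked genotypes.
#' @export
apply_mask <- function(peds, masked) {
  lapply(peds, function(p) {
    mk <- intersect(masked$marker[masked$family == p$family_id],
                    colnames(p$geno))
    if (length(mk)) p$geno[, mk] <- NA_integer_
    p
  })
}

#' Thin a map for multipoint analysis
#'
#' Greedy walk per chromosome: within consecutive windows of
#' \code{target_spacing_cm}, keep the marker with the highest MAF (ties:
#' lower bp).
#'
#' @param map \code{markermap} with \code{freq2}.
#' @param target_spacing_cm Window width in cM (> 0).
#' @return Thinned map with attributes \code{mean_spacing} and
#'   \code{mean_maf}.
#' @export
select_multipoint_markers <- function(map, target_spacing_cm = 0.3) {
  if (target_spacing_cm <= 0) stop("target_spacing_cm must be > 0")
  maf <- pmin(map$freq2, 1 - map$freq2)
  keep <- unlist(lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    cmv <- map$cm[idx]
    win <- floor((cmv - min(cmv)) / target_spacing_cm)
    unlist(lapply(split(idx, win), function(w)
      w[order(-maf[w], map$bp[w])][1]))
  }))
  out <- map[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  sp <- unlist(lapply(split(out$cm, out$chrom), diff))
  attr(out, "mean_spacing") <- if (length(sp)) mean(sp) else NA_real_
  attr(out, "mean_maf") <- mean(pmin(out$freq2, 1 - out$freq2))
  out
}
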