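# Inter-marker LD clustering (composite r^2 + EM haplotype frequencies) and
# multipoint genotyping-error detection.

#' Cluster adjacent markers in LD
#'
#' Adjacent markers on a chromosome are joined while their composite r^2
#' (squared correlation of founder dosages) meets the threshold; haplotype
#' frequencies within each cluster are estimated by EM assuming no
#' recombination within the cluster. Clusters act as super-markers in the
#' multipoint engine's emissions, which restores correct two-point/multipoint
#' behaviour when parents are missing and markers are in LD.
#'
#' @param peds List of \code{linkped} (founder genotypes are used).
#' @param map \code{markermap} for one or more chromosomes.
#' @param r2_threshold Clustering threshold (default 0.16).
#' @param max_iter,tol EM controls.
#' @return List: \code{clusters} (each with markers, haplotypes matrix of
#'   allele codes, hap_freqs), \code{r2} (adjacent-pair values).
#' @export
ld_cluster <- function(peds, map, r2_threshold = 0.16, max_iter = 500L,
                       tol = 1e-8) {
  fg <- do.call(rbind, lapply(peds, function(p)
    p$geno[p$members$id[is.na(p$members$father) & p$members$sampled],
           map$marker, drop = FALSE]))
  r2 <- rep(NA_real_, nrow(map) - 1L)
  for (j in seq_len(nrow(map) - 1L)) {
    if (map$chrom[j] != map$chrom[j + 1L]) next
    r <- suppressWarnings(stats::cor(fg[, j], fg[, j + 1L],
                                     use = "pairwise.complete.obs"))
    r2[j] <- if (is.na(r)) 0 else r^2
  }
  cl_id <- cumsum(c(TRUE, is.na(r2) | r2 < r2_threshold))
  clusters <- list()
  for (grp in split(seq_len(nrow(map)), cl_id)) {
    if (length(grp) < 2L) next
    em <- haplotype_em(fg[, grp, drop = FALSE], max_iter, tol)
    if (is.null(em)) {
      warning("haplotype EM did not converge for cluster at ",
              map$marker[grp[1]], "; markers left independent")
      next
    }
    clusters[[length(clusters) + 1L]] <-
      list(markers = map$marker[grp], haplotypes = em$haplotypes,
           hap_freqs = em$freqs)
  }
  list(clusters = clusters, r2 = r2)
}

# EM for multilocus haplotype frequencies from unphased biallelic genotypes
# (dosage coding; rows with any missing call are dropped)
haplotype_em <- function(g, max_iter = 500L, tol = 1e-8) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  L <- ncol(g)
  n <- nrow(g)
  if (!n) return(NULL)
  H <- as.matrix(expand.grid(rep(list(1:2), L)))[, L:1, drop = FALSE]
  nh <- nrow(H)
  # compatible ordered haplotype pairs per observed multilocus genotype
  dose <- function(i, j) colSums(rbind(H[i, ] == 2L, H[j, ] == 2L))
  pat_key <- apply(g, 1, paste, collapse = ",")
  upat <- unique(pat_key)
  pairs <- lapply(upat, function(key) {
    gv <- as.integer(strsplit(key, ",")[[1]])
    idx <- which(outer(1:nh, 1:nh, Vectorize(function(i, j)
      all((H[i, ] == 2L) + (H[j, ] == 2L) == gv))), arr.ind = TRUE)
    idx
  })
  wt <- as.numeric(table(pat_key)[upat])
  # init: product of marginals
  p2 <- colMeans(g) / 2
  fr <- vapply(seq_len(nh), function(i)
    prod(ifelse(H[i, ] == 2L, p2, 1 - p2)), numeric(1))
  fr <- fr / sum(fr)
  for (it in seq_len(max_iter)) {
    cnt <- numeric(nh)
    ok <- TRUE
    for (u in seq_along(upat)) {
      pp <- pairs[[u]]
      if (!nrow(pp)) { ok <- FALSE; break }
      w <- fr[pp[, 1]] * fr[pp[, 2]]
      if (sum(w) <= 0) { ok <- FALSE; break }
      w <- w / sum(w) * wt[u]
      for (r in seq_len(nrow(pp))) {
        cnt[pp[r, 1]] <- cnt[pp[r, 1]] + w[r]
        cnt[pp[r, 2]] <- cnt[pp[r, 2]] + w[r]
      }
    }
    if (!ok) return(NULL)
    new_fr <- cnt / (2 * n)
    delta <- max(abs(new_fr - fr))
    fr <- new_fr
    if (delta < tol) return(list(haplotypes = H, freqs = fr))
  }
  NULL
}

#' Detect unlikely genotypes via multipoint likelihood ratios
#'
#' A genotype is flagged when removing it multiplies the family's chromosome
#' likelihood by more than \code{threshold} (the classic signature of an
#' unlikely double recombinant).
#'
#' @param peds List of \code{linkped}.
#' @param map One chromosome's \code{markermap} with \code{freq2}.
#' @param threshold Likelihood-ratio threshold (default 1000).
#' @param cap_bits Meiosis-bit cap.
#' @return Data frame: family, id, marker, lr.
#' @export
error_detect <- function(peds, map, threshold = 1000, cap_bits = 16L) {
  out <- list()
  for (p in peds) {
    l0 <- tryCatch(lander_green(p, map, cap_bits = cap_bits)$loglik,
                   error = function(e) NA_real_)
    if (is.na(l0)) next
    for (id in p$members$id[p$members$sampled]) {
      for (mk in map$marker) {
        if (is.na(p$geno[id, mk])) next
        p2 <- p
        p2$geno[id, mk] <- NA_integer_
        l1 <- lander_green(p2, map, cap_bits = cap_bits)$loglik
        lr <- exp(l1 - l0)
        if (lr > threshold)
          out[[length(out) + 1L]] <- data.frame(
            family = p$family_id, id = id, marker = mk, lr = lr,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), id = character(0),
                      marker = character(0), lr = numeric(0)))
  do.call(rbind, out)
}

#' Mask flagged genotypes
#'
#' Sets each flagged (family, individual, marker) genotype to missing.
#'
#' @param peds List of \code{linkped}.
#' @param flags Output of \code{\link{error_detect}}.
#' @return The cohort with flagged genotypes removed.
#' @export
apply_error_mask <- function(peds, flags) {
  lapply(peds, function(p) {
    sub <- flags[flags$family == p$family_id, , drop = FALSE]
    for (r in seq_len(nrow(sub)))
      p$geno[sub$id[r], sub$marker[r]] <- NA_integer_
    p
  })
}
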