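# Whole-genome scans under the six analysis models (parametric HLOD,
# Kong-Cox linear, Kong-Cox exponential; each two-point and multipoint),
# clinical stratification, and the conditional half-split permutation test.

#' Scan configuration
#'
#' @param dm Analysis \code{disease_model} (rare-dominant affecteds-only by
#'   default).
#' @param theta_grid Two-point recombination grid (must include 0.5).
#' @param step_cm Multipoint grid step between markers.
#' @param cap_bits Meiosis-bit cap for the multipoint engine.
#' @param models Subset of
#'   \code{c("par_tp","npl_lin_tp","npl_exp_tp","par_mp","npl_lin_mp","npl_exp_mp")}.
#' @param multipoint Run the multipoint engine (needed for the *_mp models).
#' @param alpha_grid Admixture grid for HLOD.
#' @return A \code{scan_config} list.
#' @export
scan_config <- function(dm = disease_model(),
                        theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                        step_cm = 0.3, cap_bits = 16L,
                        models = c("par_tp", "npl_lin_tp", "npl_exp_tp",
                                   "par_mp", "npl_lin_mp", "npl_exp_mp"),
                        multipoint = any(grepl("_mp$", models)),
                        alpha_grid = seq(0, 1, by = 0.01)) {
  structure(list(dm = dm, theta_grid = theta_grid, step_cm = step_cm,
                 cap_bits = as.integer(cap_bits), models = models,
                 multipoint = multipoint, alpha_grid = alpha_grid),
            class = "scan_config")
}

#' Whole-cohort linkage scan
#'
#' Computes per-family statistics for every model once (two-point LOD(theta)
#' curves, multipoint LOD curves, NPL Z with exact null laws), so that any
#' family subset can be re-aggregated cheaply -- the property the conditional
#' permutation test exploits.
#'
#' @param peds List of \code{linkped} (trimmed internally).
#' @param map \code{markermap} with \code{freq2} set (founder estimates).
#' @param config A \code{scan_config}.
#' @param masked Optional masked-genotype ledger (family, marker).
#' @return A \code{linkage_scan} object; see \code{\link{aggregate_scan}}.
#' @export
linkage_scan <- function(peds, map, config = scan_config(), masked = NULL) {
  if (!is.null(masked) && nrow(masked)) peds <- apply_mask(peds, masked)
  peds <- lapply(peds, trim_pedigree)
  fams <- vapply(peds, `[[`, character(1), "family_id")
  names(peds) <- fams
  chroms <- unique(map$chrom)
  out <- list(fams = fams, config = config, chroms = chroms, by_chrom = list())
  need_par_tp <- "par_tp" %in% config$models
  need_npl_tp <- any(c("npl_lin_tp", "npl_exp_tp") %in% config$models)
  need_par_mp <- "par_mp" %in% config$models
  need_npl_mp <- any(c("npl_lin_mp", "npl_exp_mp") %in% config$models)
  need_lg <- need_npl_tp || need_par_mp || need_npl_mp
  for (ch in chroms) {
    cmap <- map[map$chrom == ch, , drop = FALSE]
    M <- nrow(cmap)
    tp_par <- if (need_par_tp)
      array(NA_real_, c(length(fams), M, length(config$theta_grid)),
            dimnames = list(fams, cmap$marker, NULL))
    tp_z <- matrix(NA_real_, length(fams), M,
                   dimnames = list(fams, cmap$marker))
    nulls <- vector("list", length(fams)); names(nulls) <- fams
    mp_par <- NULL; mp_z <- NULL; mp_pos <- NULL
    grid <- if (config$multipoint && M > 1L)
      seq(min(cmap$cm), max(cmap$cm), by = config$step_cm) else NULL
    for (fi in seq_along(fams)) {
      p <- peds[[fi]]
      if (need_par_tp) {
        for (j in seq_len(M)) {
          ll <- pedigree_likelihood_grid(p, cmap$marker[j], cmap$freq2[j],
                                         config$dm, config$theta_grid)
          tp_par[fi, j, ] <- (ll - ll[length(ll)]) / log(10)
        }
      }
      if (!need_lg) next
      setup <- tryCatch(lg_setup(p, config$cap_bits), error = function(e) e)
      if (inherits(setup, "error")) {
        warning("family ", fams[fi], " skipped on chr ", ch, ": ",
                conditionMessage(setup))
        next
      }
      emis <- lapply(seq_len(M), function(j) {
        dos <- p$geno[setup$ids, cmap$marker[j]]
        pairsets <- lapply(dos, snp_pairset)
        lg_emission(setup, pairsets, c(1 - cmap$freq2[j], cmap$freq2[j]))
      })
      zt <- NULL
      if (length(setup$aff) >= 2L) {
        s <- sall_scores(setup)
        mu <- mean(s); sd0 <- sqrt(mean((s - mu)^2))
        if (sd0 > 1e-14) {
          zt <- (s - mu) / sd0
          tab <- tapply(rep(1 / length(zt), length(zt)), round(zt, 12), sum)
          nulls[[fi]] <- list(mu = mu, sd = sd0,
                              zvals = as.numeric(names(tab)),
                              probs = as.numeric(tab), zmin = min(zt))
          if (need_npl_tp)
            tp_z[fi, ] <- vapply(emis, function(e)
              sum(e * zt) / sum(e), numeric(1))
        }
      }
      if (need_par_mp || need_npl_mp) {
        lg1 <- lg_fb(setup, emis, cmap$cm, grid, fams[fi])
        if (is.null(mp_pos)) mp_pos <- lg1$positions
        if (need_par_mp) {
          pv <- parametric_vector_lik(setup, config$dm)
          if (is.null(mp_par))
            mp_par <- matrix(NA_real_, length(fams), nrow(lg1$positions),
                             dimnames = list(fams, NULL))
          mp_par[fi, ] <- log10(as.numeric(lg1$post %*% pv)) -
            log10(mean(pv))
        }
        if (need_npl_mp && !is.null(zt))
          {
            if (is.null(mp_z))
              mp_z <- matrix(NA_real_, length(fams), nrow(lg1$positions),
                             dimnames = list(fams, NULL))
            mp_z[fi, ] <- as.numeric(lg1$post %*% zt)
          }
      }
    }
    out$by_chrom[[ch]] <- list(map = cmap, tp_par = tp_par, tp_z = tp_z,
                               nulls = nulls, mp_par = mp_par, mp_z = mp_z,
                               mp_pos = mp_pos)
  }
  class(out) <- "linkage_scan"
  out
}

#' Aggregate a scan over a family subset
#'
#' Recomputes the six model statistics from the stored per-family components
#' for an arbitrary subset of families, and reports per-chromosome and
#' genome-wide maxima.
#'
#' @param scan A \code{linkage_scan}.
#' @param families Character vector of family ids (default: all).
#' @return List: \code{tables} (per model: per-chromosome data frames of
#'   position/statistic), \code{chrom_max} (model x chromosome matrix),
#'   \code{gw_max} (named vector).
#' @export
aggregate_scan <- function(scan, families = scan$fams) {
  cfg <- scan$config
  fams <- intersect(scan$fams, families)
  if (!length(fams)) stop("aggregate_scan: empty family subset")
  models <- cfg$models
  chrom_max <- matrix(-Inf, length(models), length(scan$chroms),
                      dimnames = list(models, scan$chroms))
  tables <- stats::setNames(vector("list", length(models)), models)
  for (ch in scan$chroms) {
    bc <- scan$by_chrom[[ch]]
    zfams <- fams[!vapply(bc$nulls[fams], is.null, logical(1))]
    nulls <- bc$nulls[zfams]
    for (mod in models) {
      tab <- NULL
      if (mod == "par_tp") {
        stat <- vapply(seq_len(ncol(bc$tp_z)), function(j) {
          L <- bc$tp_par[fams, j, , drop = TRUE]
          if (is.null(dim(L))) L <- matrix(L, nrow = length(fams))
          hlod(L, cfg$alpha_grid)$max_hlod
        }, numeric(1))
        tab <- data.frame(chrom = ch, pos_cm = bc$map$cm,
                          marker = bc$map$marker, stat = stat)
      } else if (mod == "npl_lin_tp" || mod == "npl_exp_tp") {
        if (length(zfams)) {
          kc <- kong_cox(bc$tp_z[zfams, , drop = FALSE],
                         model = if (mod == "npl_lin_tp") "linear" else
                           "exponential", null = nulls)
          tab <- data.frame(chrom = ch, pos_cm = bc$map$cm,
                            marker = bc$map$marker, stat = kc$lod)
        }
      } else if (mod == "par_mp") {
        if (!is.null(bc$mp_par)) {
          L <- bc$mp_par[fams, , drop = FALSE]
          keep <- !apply(is.na(L), 1, any)
          if (any(keep)) {
            h <- hlod(L[keep, , drop = FALSE], cfg$alpha_grid)
            tab <- data.frame(chrom = ch, pos_cm = bc$mp_pos$cm,
                              stat = h$hlod, alpha = h$alpha)
          }
        }
      } else if (mod %in% c("npl_lin_mp", "npl_exp_mp")) {
        if (!is.null(bc$mp_z) && length(zfams)) {
          Zm <- bc$mp_z[zfams, , drop = FALSE]
          keep <- !apply(is.na(Zm), 1, any)
          if (any(keep)) {
            kc <- kong_cox(Zm[keep, , drop = FALSE],
                           model = if (mod == "npl_lin_mp") "linear" else
                             "exponential", null = nulls[keep])
            tab <- data.frame(chrom = ch, pos_cm = bc$mp_pos$cm,
                              stat = kc$lod)
          }
        }
      }
      if (!is.null(tab)) {
        tables[[mod]] <- rbind(tables[[mod]], tab)
        chrom_max[mod, ch] <- max(tab$stat)
      }
    }
  }
  gw_max <- apply(chrom_max, 1, max)
  list(tables = tables, chrom_max = chrom_max, gw_max = gw_max,
       families = fams)
}

#' Stratify families by clinical condition flags
#'
#' A family is positive when any qualifying condition is flagged, negative
#' otherwise. Every family must appear in the flag table.
#'
#' @param peds List of \code{linkped}.
#' @param flags Wide data frame: \code{family} column plus one logical column
#'   per condition.
#' @param conditions Qualifying conditions (default
#'   \code{\link{ctd_conditions}}).
#' @return List: \code{positive}, \code{negative} (lists of \code{linkped}),
#'   \code{labels} (named character vector).
#' @export
stratify <- function(peds, flags, conditions = ctd_conditions()) {
  fams <- vapply(peds, `[[`, character(1), "family_id")
  names(peds) <- fams
  missing_f <- setdiff(fams, flags$family)
  if (length(missing_f))
    stop("families lacking condition flags: ",
         paste(missing_f, collapse = ", "))
  use <- intersect(conditions, names(flags))
  pos_fam <- flags$family[rowSums(as.matrix(flags[, use, drop = FALSE])) > 0]
  lab <- ifelse(fams %in% pos_fam, "positive", "negative")
  names(lab) <- fams
  pos <- peds[lab == "positive"]; neg <- peds[lab == "negative"]
  message(sprintf("stratify: %d positive, %d negative families",
                  length(pos), length(neg)))
  list(positive = lapply(pos, function(p) { p$stratum <- "positive"; p }),
       negative = lapply(neg, function(p) { p$stratum <- "negative"; p }),
       labels = lab)
}

#' Stratified linkage scan
#'
#' Runs the full model battery within each stratum separately, re-estimating
#' founder allele frequencies per stratum.
#'
#' @param peds List of \code{linkped}.
#' @param flags Condition-flag table (see \code{\link{stratify}}).
#' @param map \code{markermap}.
#' @param config A \code{scan_config}.
#' @param masked Optional masked-genotype ledger.
#' @return List with per-stratum \code{scan} and \code{result}
#'   (\code{\link{aggregate_scan}} output), plus \code{labels}.
#' @export
stratified_scan <- function(peds, flags, map, config = scan_config(),
                            masked = NULL) {
  st <- stratify(peds, flags)
  out <- list(labels = st$labels)
  for (side in c("positive", "negative")) {
    sub <- st[[side]]
    if (!length(sub)) stop("stratum '", side, "' has no families")
    fr <- estimate_allele_freqs(sub, map, who = "founders")
    fr$freq2[is.na(fr$freq2)] <- map$freq2[is.na(fr$freq2)]
    sc <- linkage_scan(sub, fr, config, masked = masked)
    out[[side]] <- list(scan = sc, result = aggregate_scan(sc))
  }
  out
}

#' Conditional permutation test for stratified linkage evidence
#'
#' The null asks: is the stratified maximum larger than what an arbitrary
#' half of the families would give? Each repetition splits the cohort into
#' random halves, re-aggregates all configured models for both halves, and
#' retains per-chromosome and genome-wide maxima (2 draws per repetition).
#' Empirical p-values use the add-one estimator
#' p = (#\{draws >= observed\} + 1) / (N + 1); the raw proportion is also
#' reported.
#'
#' @param scan Cohort-level \code{linkage_scan} (all families).
#' @param observed Output of \code{\link{aggregate_scan}} on the observed
#'   stratum (its \code{chrom_max} / \code{gw_max} are the test statistics).
#' @param reps Number of half-split repetitions (default 500, i.e. 1000
#'   draws).
#' @param seed RNG seed.
#' @return A \code{perm_dist}: per model, \code{gw} (draws, observed,
#'   p_emp, p_raw) and \code{cw} (per chromosome).
#' @export
conditional_permutation <- function(scan, observed, reps = 500, seed = 1L) {
  if (reps < 50) warning("fewer than 50 repetitions: unstable p-values")
  set.seed(seed)
  fams <- scan$fams
  n <- length(fams)
  if (n %% 2L == 1L) warning("odd family count: halves of ",
                             n %/% 2L, " and ", n %/% 2L + 1L)
  models <- scan$config$models
  gw_draws <- matrix(NA_real_, 2L * reps, length(models),
                     dimnames = list(NULL, models))
  cw_draws <- array(NA_real_, c(2L * reps, length(models),
                                length(scan$chroms)),
                    dimnames = list(NULL, models, scan$chroms))
  for (r in seq_len(reps)) {
    half <- sample(fams, n %/% 2L)
    for (k in 1:2) {
      sub <- if (k == 1L) half else setdiff(fams, half)
      agg <- aggregate_scan(scan, sub)
      gw_draws[2L * r - 2L + k, ] <- agg$gw_max[models]
      cw_draws[2L * r - 2L + k, , ] <- agg$chrom_max[models, , drop = FALSE]
    }
  }
  res <- list()
  for (mod in models) {
    obs_gw <- observed$gw_max[[mod]]
    d <- gw_draws[, mod]
    gw <- list(observed = obs_gw, draws = d,
               p_emp = (sum(d >= obs_gw) + 1) / (length(d) + 1),
               p_raw = mean(d >= obs_gw))
    cw <- lapply(stats::setNames(scan$chroms, scan$chroms), function(ch) {
      oc <- observed$chrom_max[mod, ch]
      dc <- cw_draws[, mod, ch]
      list(observed = oc, p_emp = (sum(dc >= oc) + 1) / (length(dc) + 1),
           p_raw = mean(dc >= oc))
    })
    res[[mod]] <- list(gw = gw, cw = cw)
  }
  structure(list(models = res, reps = reps, n_draws = 2L * reps,
                 seed = seed), class = "perm_dist")
}

#' @export
print.perm_dist <- function(x, ...) {
  cat(sprintf("<perm_dist> %d repetitions (%d draws)\n", x$reps, x$n_draws))
  for (mod in names(x$models)) {
    g <- x$models[[mod]]$gw
    cat(sprintf("  %-11s observed GW max %6.3f  p_emp %.4g\n", mod,
                g$observed, g$p_emp))
  }
  invisible(x)
}
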