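# Exact pedigree likelihoods by variable elimination over phased genotypes.
#
# Two-point engine: each individual carries an ordered pair of two-locus
# haplotypes (paternal, maternal); a haplotype is (disease allele, marker
# allele), so the per-person state space has 4 x 4 = 16 states. Founders get
# linkage-equilibrium priors, children a transmission factor with
# recombination theta between the loci. Elimination order is the greedy
# min-degree order, which is treewidth-optimal on loop-free pedigrees.

HAP_D <- c(1L, 1L, 2L, 2L)  # disease allele of haplotype 1..4 (2 = disease)
HAP_M <- c(1L, 2L, 1L, 2L)  # marker allele of haplotype 1..4

# per-session caches: child transmission arrays by theta, peeling plans by
# pedigree structure
.stratlink_cache <- new.env(parent = emptyenv())

cached_transmission <- function(theta) {
  key <- sprintf("A_%.17g", theta)
  hit <- .stratlink_cache[[key]]
  if (is.null(hit)) {
    hit <- transmission_child(theta)
    .stratlink_cache[[key]] <- hit
  }
  hit
}

# symbolic min-degree elimination schedule over factor scopes
peel_plan <- function(var_sets, n_vars) {
  sets <- var_sets
  alive <- rep(TRUE, length(sets))
  remaining <- seq_len(n_vars)
  steps <- list()
  while (length(remaining)) {
    deg <- vapply(remaining, function(v) {
      touch <- alive & vapply(sets, function(s) v %in% s, logical(1))
      length(unique(unlist(sets[touch])))
    }, numeric(1))
    v <- remaining[which.min(deg)]
    idx <- which(alive & vapply(sets, function(s) v %in% s, logical(1)))
    vars <- sort(unique(unlist(sets[idx])))
    out <- setdiff(vars, v)
    steps[[length(steps) + 1L]] <- list(idx = idx, vars = vars, elim = v,
                                        out = out)
    alive[idx] <- FALSE
    sets[[length(sets) + 1L]] <- out
    alive <- c(alive, TRUE)
    remaining <- setdiff(remaining, v)
  }
  steps
}

cached_plan <- function(p) {
  m <- p$members
  key <- paste("plan", paste(m$id, m$father, m$mother, collapse = ";"))
  hit <- .stratlink_cache[[key]]
  if (is.null(hit)) {
    var_sets <- lapply(seq_len(nrow(m)), function(i) {
      if (is.na(m$father[i])) i else
        c(i, match(m$father[i], m$id), match(m$mother[i], m$id))
    })
    hit <- list(var_sets = var_sets, steps = peel_plan(var_sets, nrow(m)))
    .stratlink_cache[[key]] <- hit
  }
  hit
}

# numeric pass over a peeling plan; returns log-likelihood
exec_plan <- function(tables, plan, nstate) {
  vsets <- plan$var_sets
  logscale <- 0
  for (st in plan$steps) {
    vars <- st$vars
    tab <- array(1, dim = rep(nstate, length(vars)))
    for (i in st$idx)
      tab <- tab * expand_tab(tables[[i]], vsets[[i]], vars, nstate)
    pos <- match(st$elim, vars)
    k <- length(vars)
    if (k == 1L) {
      new_tab <- sum(tab)
    } else {
      perm <- c(setdiff(seq_len(k), pos), pos)
      tab <- aperm(tab, perm)
      dim(tab) <- c(nstate^(k - 1L), nstate)
      new_tab <- array(rowSums(tab), dim = rep(nstate, k - 1L))
    }
    mx <- max(new_tab)
    if (mx <= 0) return(-Inf)
    logscale <- logscale + log(mx)
    tables[[length(tables) + 1L]] <- new_tab / mx
    vsets[[length(vsets) + 1L]] <- if (k == 1L) integer(0) else
      vars[perm[-k]]
  }
  logscale
}

# gamete transmission matrix: rows = 16 parent states, cols = 4 gametes
transmission_gamete <- function(theta) {
  tm <- matrix(0, 16L, 4L)
  for (hp in 1:4) for (hm in 1:4) {
    s <- hp + 4L * (hm - 1L)
    tm[s, hp] <- tm[s, hp] + (1 - theta) / 2
    tm[s, hm] <- tm[s, hm] + (1 - theta) / 2
    r1 <- 2L * (HAP_D[hp] - 1L) + HAP_M[hm]
    r2 <- 2L * (HAP_D[hm] - 1L) + HAP_M[hp]
    tm[s, r1] <- tm[s, r1] + theta / 2
    tm[s, r2] <- tm[s, r2] + theta / 2
  }
  tm
}

# child factor A[s_child, s_father, s_mother]
transmission_child <- function(theta) {
  tm <- transmission_gamete(theta)
  A <- array(0, dim = c(16L, 16L, 16L))
  for (hp in 1:4) for (hm in 1:4) {
    sc <- hp + 4L * (hm - 1L)
    A[sc, , ] <- outer(tm[, hp], tm[, hm])
  }
  A
}

# per-person penetrance x marker-emission vector over the 16 states
state_weight <- function(aff, gobs, pen) {
  hp <- rep(1:4, times = 4); hm <- rep(1:4, each = 4)
  ncop <- (HAP_D[hp] == 2L) + (HAP_D[hm] == 2L)
  w <- if (!is.na(aff) && aff == AFF_AFFECTED) pen[ncop + 1L] else rep(1, 16)
  if (!is.na(gobs)) {
    dose <- (HAP_M[hp] == 2L) + (HAP_M[hm] == 2L)
    w <- w * (dose == gobs)
  }
  w
}

expand_tab <- function(tab, fvars, vars, nstate) {
  if (identical(fvars, vars)) return(tab)
  extra <- setdiff(vars, fvars)
  tab <- array(tab, dim = rep(nstate, length(fvars) + length(extra)))
  aperm(tab, match(vars, c(fvars, extra)))
}

# sum-product elimination; factors = list(list(vars=, tab=)); returns log-lik
eliminate_all <- function(factors, n_vars, nstate) {
  logscale <- 0
  vsets <- lapply(factors, `[[`, "vars")
  alive <- rep(TRUE, length(factors))
  remaining <- seq_len(n_vars)
  while (length(remaining)) {
    # min-degree: variable whose elimination touches the fewest distinct vars
    deg <- vapply(remaining, function(v) {
      length(unique(unlist(vsets[alive][vapply(vsets[alive],
                                               function(s) v %in% s, logical(1))])))
    }, numeric(1))
    v <- remaining[which.min(deg)]
    idx <- which(alive & vapply(vsets, function(s) v %in% s, logical(1)))
    vars <- sort(unique(unlist(vsets[idx])))
    tab <- array(1, dim = rep(nstate, length(vars)))
    for (i in idx) tab <- tab * expand_tab(factors[[i]]$tab, factors[[i]]$vars,
                                           vars, nstate)
    alive[idx] <- FALSE
    pos <- match(v, vars)
    k <- length(vars)
    if (k == 1L) {
      new_tab <- sum(tab); new_vars <- integer(0)
    } else {
      perm <- c(setdiff(seq_len(k), pos), pos)
      tab <- aperm(tab, perm)
      dim(tab) <- c(nstate^(k - 1L), nstate)
      new_tab <- array(rowSums(tab), dim = rep(nstate, k - 1L))
      new_vars <- vars[perm[-k]]
    }
    mx <- max(new_tab)
    if (mx <= 0) return(-Inf)
    logscale <- logscale + log(mx)
    factors[[length(factors) + 1L]] <- list(vars = new_vars, tab = new_tab / mx)
    vsets[[length(vsets) + 1L]] <- new_vars
    alive <- c(alive, TRUE)
    remaining <- setdiff(remaining, v)
  }
  extra <- vapply(factors[alive], function(f) {
    if (length(f$vars)) stop("elimination left a non-scalar factor")
    as.numeric(f$tab)
  }, numeric(1))
  if (any(extra <= 0)) return(-Inf)
  logscale + sum(log(extra))
}

#' Exact pedigree likelihood at one marker
#'
#' Joint log-likelihood of affection statuses and marker genotypes under a
#' two-locus (disease, marker) model with recombination fraction \code{theta},
#' computed by exact peeling over phased two-locus genotypes. Affected
#' individuals contribute the penetrance of their disease genotype; unaffected
#' and uncertain individuals contribute a factor 1 (affecteds-only contract),
#' while their marker genotypes always contribute.
#'
#' @param p A \code{linkped}.
#' @param marker Marker id (column of \code{p$geno}); \code{NULL} for the
#'   disease-locus-only likelihood.
#' @param freq2 Population frequency of marker allele 2.
#' @param dm A \code{disease_model}.
#' @param theta Recombination fraction in [0, 0.5].
#' @return Log-likelihood (natural log); \code{-Inf} for impossible data.
#' @export
pedigree_likelihood <- function(p, marker, freq2, dm, theta) {
  pedigree_likelihood_grid(p, marker, freq2, dm, theta)[1]
}

#' Pedigree likelihood on a theta grid
#'
#' Vectorized form of \code{\link{pedigree_likelihood}}: per-person factors
#' are built once and the cached peeling schedule is executed per theta.
#'
#' @inheritParams pedigree_likelihood
#' @param thetas Vector of recombination fractions.
#' @return Numeric vector of log-likelihoods.
#' @export
pedigree_likelihood_grid <- function(p, marker, freq2, dm, thetas) {
  m <- p$members
  n <- nrow(m)
  if (n > 14L)
    stop("pedigree ", p$family_id, " too large for exact peeling (", n,
         " members, bits = ", ped_bits(p), ")")
  gobs <- if (is.null(marker)) rep(NA_integer_, n) else
    as.integer(p$geno[m$id, marker])
  q <- dm$disease_freq
  prhap <- c(1 - q, q)[HAP_D] * c(1 - freq2, freq2)[HAP_M]
  prior <- as.vector(outer(prhap, prhap))  # [hp + 4*(hm-1)]
  plan <- cached_plan(p)
  w <- lapply(seq_len(n), function(i)
    state_weight(m$aff[i], gobs[i], dm$penetrances))
  is_founder <- is.na(m$father)
  vapply(thetas, function(theta) {
    A <- cached_transmission(theta)
    tables <- lapply(seq_len(n), function(i)
      if (is_founder[i]) prior * w[[i]] else A * w[[i]])
    exec_plan(tables, plan, 16L)
  }, numeric(1))
}

#' Two-point LOD curve
#'
#' LOD(theta) = log10 L(theta) - log10 L(0.5), summed over families.
#'
#' @param peds A \code{linkped} or list of them.
#' @param marker Marker id.
#' @param freq2 Frequency of marker allele 2 (scalar).
#' @param dm A \code{disease_model}.
#' @param grid Theta grid; must include 0.5.
#' @return List: \code{theta} (grid), \code{lod} (cohort LOD per theta),
#'   \code{per_family} (families x theta matrix), \code{max_lod},
#'   \code{theta_hat}.
#' @export
twopoint_lod <- function(peds, marker, freq2, dm,
                         grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (inherits(peds, "linkped")) peds <- list(peds)
  if (!any(abs(grid - 0.5) < 1e-12)) stop("theta grid must include 0.5")
  if (is.unsorted(grid, strictly = TRUE)) stop("theta grid must be increasing")
  per_fam <- t(vapply(peds, function(p) {
    ll <- pedigree_likelihood_grid(p, marker, freq2, dm, grid)
    (ll - ll[length(ll)]) / log(10)
  }, numeric(length(grid))))
  if (length(peds) == 1L) per_fam <- matrix(per_fam, nrow = 1L)
  rownames(per_fam) <- vapply(peds, `[[`, character(1), "family_id")
  colnames(per_fam) <- as.character(grid)
  lod <- colSums(per_fam)
  i <- which.max(lod)
  list(theta = grid, lod = lod, per_family = per_fam,
       max_lod = lod[[i]], theta_hat = grid[i])
}

#' Heterogeneity LOD (admixture model)
#'
#' Smith's admixture model: HLOD(theta, alpha) = sum over families of
#' log10(alpha * 10^LOD_f(theta) + 1 - alpha), maximized over alpha (and over
#' the columns of the input, typically a theta grid or map positions).
#'
#' @param per_family_lods Families x positions matrix of LOD scores.
#' @param alpha_grid Admixture-proportion grid (default step 0.01).
#' @return List: \code{hlod} and \code{alpha} per column, \code{max_hlod},
#'   \code{alpha_hat}, \code{col_hat} (index of the maximizing column).
#' @export
hlod <- function(per_family_lods, alpha_grid = seq(0, 1, by = 0.01)) {
  L <- as.matrix(per_family_lods)
  if (!nrow(L)) stop("hlod: empty family set")
  hl <- numeric(ncol(L)); ah <- numeric(ncol(L))
  for (j in seq_len(ncol(L))) {
    tenl <- 10^L[, j]
    vals <- vapply(alpha_grid, function(a) sum(log10(a * tenl + 1 - a)),
                   numeric(1))
    best <- which(vals >= max(vals) - 1e-12)[1]  # smallest alpha at the max
    hl[j] <- vals[best]  # alpha = 0 gives 0, so hlod >= 0 always
    ah[j] <- alpha_grid[best]
  }
  i <- which.max(hl)
  list(hlod = hl, alpha = ah, max_hlod = hl[i], alpha_hat = ah[i], col_hat = i)
}
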