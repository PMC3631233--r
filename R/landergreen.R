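# Lander-Green multipoint engine: exact HMM over inheritance vectors.
#
# One meiosis = one bit (0: grandpaternal allele transmitted). The chain runs
# on the full meiosis space of 2 bits per nonfounder; at the family sizes
# this package targets the full space is exact and cheap, and avoids the
# subtle transition-kernel bookkeeping of founder-phase quotient spaces.
# ped_bits() still reports the conventional founder-reduced count.

# Precompute per-pedigree descent structure: for every inheritance vector the
# founder-allele node carried paternally/maternally by each member.
lg_setup <- function(p, cap_bits = 16L) {
  m <- p$members
  n <- nrow(m)
  fo <- which(is.na(m$father))
  nf <- which(!is.na(m$father))
  B <- 2L * length(nf)
  if (B > cap_bits)
    stop("family ", p$family_id, ": ", B, " meiosis bits exceed cap ",
         cap_bits, call. = FALSE)
  # topological order of nonfounders
  depth <- rep(0L, n)
  repeat {
    nd <- ifelse(is.na(m$father), 0L,
                 pmax(depth[match(m$father, m$id)],
                      depth[match(m$mother, m$id)]) + 1L)
    if (identical(nd, depth)) break
    depth <- nd
  }
  nf <- nf[order(depth[nf])]
  V <- bitwShiftL(1L, B)
  vseq <- 0:(V - 1L)
  patnode <- matnode <- matrix(0L, V, n)
  for (k in seq_along(fo)) {
    patnode[, fo[k]] <- 2L * k - 1L
    matnode[, fo[k]] <- 2L * k
  }
  for (j in seq_along(nf)) {
    i <- nf[j]
    fi <- match(m$father[i], m$id); mi <- match(m$mother[i], m$id)
    bp <- bitwAnd(vseq, bitwShiftL(1L, 2L * j - 2L)) > 0L
    bm <- bitwAnd(vseq, bitwShiftL(1L, 2L * j - 1L)) > 0L
    patnode[, i] <- ifelse(bp, matnode[, fi], patnode[, fi])
    matnode[, i] <- ifelse(bm, matnode[, mi], patnode[, mi])
  }
  list(ped = p, n = n, B = B, V = V, n_founders = length(fo),
       n_nodes = 2L * length(fo), patnode = patnode, matnode = matnode,
       ids = m$id, aff = which(m$aff == AFF_AFFECTED))
}

# apply one inter-position transition: each bit flips independently w.p. theta
lg_mix <- function(x, theta, B) {
  if (theta <= 0 || B == 0L) return(x)
  V <- length(x)
  vseq <- 0:(V - 1L)
  for (b in 0:(B - 1L)) {
    flip <- bitwXor(vseq, bitwShiftL(1L, b)) + 1L
    x <- (1 - theta) * x + theta * x[flip]
  }
  x
}

# allowed unordered allele pairs for an observed SNP dosage (count of allele 2)
snp_pairset <- function(dosage) {
  switch(as.character(dosage),
         "0" = matrix(c(1L, 1L), 1L),
         "1" = matrix(c(1L, 2L), 1L),
         "2" = matrix(c(2L, 2L), 1L),
         NULL)
}

# P(observed genotypes | inheritance vector) for one (super-)marker, summing
# founder-allele assignments over the constraint graph. pairsets: per member,
# a matrix of allowed unordered allele pairs or NULL if untyped/missing.
# freqs: population frequency of each allele code. Memoized on the descent
# pattern of typed members, which repeats across vectors.
lg_emission <- function(setup, pairsets, freqs) {
  typed <- which(!vapply(pairsets, is.null, logical(1)))
  V <- setup$V
  if (!length(typed)) return(rep(1, V))
  simple <- length(freqs) == 2L &&
    all(vapply(pairsets[typed], nrow, integer(1)) == 1L)
  if (simple) {
    dose <- vapply(pairsets[typed], function(pr)
      sum(pr[1, ] == 2L), integer(1))
    return(lg_emission_biallelic(setup, typed, dose, freqs))
  }
  pn <- setup$patnode[, typed, drop = FALSE]
  mn <- setup$matnode[, typed, drop = FALSE]
  memo <- new.env(hash = TRUE, parent = emptyenv())
  out <- numeric(V)
  for (v in seq_len(V)) {
    key <- paste(pn[v, ], mn[v, ], collapse = " ")
    hit <- memo[[key]]
    if (!is.null(hit)) { out[v] <- hit; next }
    out[v] <- emission_one(pn[v, ], mn[v, ], pairsets[typed], freqs,
                           setup$n_nodes)
    memo[[key]] <- out[v]
  }
  out
}

# SNP fast path: enumerate founder-allele assignments over the nodes that
# reach a typed member, vectorized over all inheritance vectors
lg_emission_biallelic <- function(setup, typed, dose, freqs) {
  pn <- setup$patnode[, typed, drop = FALSE]
  mn <- setup$matnode[, typed, drop = FALSE]
  used <- sort(unique(c(pn, mn)))
  nu <- length(used)
  ridx <- integer(setup$n_nodes)
  ridx[used] <- seq_len(nu)
  pn <- matrix(ridx[pn], nrow = setup$V)
  mn <- matrix(ridx[mn], nrow = setup$V)
  out <- numeric(setup$V)
  for (mask in 0:(2^nu - 1L)) {
    x <- bitwAnd(bitwShiftR(mask, 0:(nu - 1L)), 1L)  # 0/1 = allele 1/2
    w <- prod(freqs[x + 1L])
    dv <- matrix(x[pn] + x[mn], nrow = setup$V)
    ok <- rowSums(dv == rep(dose, each = setup$V)) == length(dose)
    out[ok] <- out[ok] + w
  }
  out
}

# single-vector founder-allele-graph sum via backtracking over components
emission_one <- function(pa, ma, psets, freqs, n_nodes) {
  np <- length(pa)
  val <- integer(n_nodes)
  done <- logical(np)
  total_prob <- 1
  # union-find over nodes to get components of the constraint graph
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (j in seq_len(np)) { ra <- find(pa[j]); rb <- find(ma[j]); if (ra != rb) parent[ra] <- rb }
  roots <- vapply(seq_len(np), function(j) find(pa[j]), integer(1))
  for (r in unique(roots)) {
    comp_p <- which(roots == r)
    cnodes <- unique(c(pa[comp_p], ma[comp_p]))
    prob <- comp_sum(comp_p, pa, ma, psets, cnodes, freqs, val)
    if (prob == 0) return(0)
    total_prob <- total_prob * prob
  }
  total_prob
}

comp_sum <- function(persons, pa, ma, psets, cnodes, freqs, val) {
  rec <- function(todo, val) {
    if (!length(todo)) return(prod(freqs[val[cnodes]]))
    n_assigned <- vapply(todo, function(j)
      (val[pa[j]] > 0L) + (val[ma[j]] > 0L), numeric(1))
    j <- todo[which.max(n_assigned)]
    rest <- setdiff(todo, j)
    a <- pa[j]; b <- ma[j]
    prs <- psets[[j]]
    tot <- 0
    for (r in seq_len(nrow(prs))) {
      cand <- if (prs[r, 1] == prs[r, 2]) list(prs[r, ]) else
        list(prs[r, ], prs[r, 2:1])
      for (pq in cand) {
        if ((val[a] == 0L || val[a] == pq[1]) &&
            (val[b] == 0L || val[b] == pq[2])) {
          v2 <- val; v2[a] <- pq[1]; v2[b] <- pq[2]
          tot <- tot + rec(rest, v2)
        }
      }
    }
    tot
  }
  rec(persons, val)
}

#' Multipoint inheritance distribution (Lander-Green HMM)
#'
#' Forward-backward over inheritance vectors for one chromosome. Emissions
#' come from founder-allele-graph summation at each marker (or LD cluster
#' acting as a super-marker); transitions flip each meiosis bit independently
#' with the Haldane recombination fraction of the inter-position distance.
#'
#' @param p A \code{linkped}.
#' @param map \code{markermap} rows for one chromosome, with \code{freq2} set.
#' @param positions_cm Extra evaluation positions (cM); defaults to markers
#'   only.
#' @param cap_bits Maximum meiosis bits (2 per nonfounder); larger families
#'   raise an error that cohort drivers catch and log as a skip.
#' @param clusters Optional LD clustering from \code{\link{ld_cluster}}.
#' @param masked Optional data frame (family, marker): genotypes treated
#'   missing for this family at those markers.
#' @return An \code{lg_dist}: \code{positions} data frame (cm, marker,
#'   is_marker), \code{post} (positions x vectors posterior matrix),
#'   \code{loglik} (total chromosome log-likelihood, natural log),
#'   \code{setup}.
#' @export
lander_green <- function(p, map, positions_cm = NULL, cap_bits = 16L,
                         clusters = NULL, masked = NULL) {
  setup <- lg_setup(p, cap_bits)
  geno <- p$geno
  if (!is.null(masked)) {
    mk <- masked$marker[masked$family == p$family_id]
    if (length(mk)) geno[, intersect(colnames(geno), mk)] <- NA_integer_
  }
  units <- marker_units(map, clusters)
  emis <- vector("list", length(units))
  unit_cm <- numeric(length(units))
  for (u in seq_along(units)) {
    un <- units[[u]]
    unit_cm[u] <- un$cm
    pairsets <- lapply(seq_len(setup$n), function(i) {
      d <- geno[setup$ids[i], un$markers, drop = TRUE]
      unit_pairset(un, d)
    })
    emis[[u]] <- lg_emission(setup, pairsets, un$freqs)
  }
  out <- lg_fb(setup, emis, unit_cm, positions_cm, p$family_id)
  out$positions$marker <- NA_character_
  out$positions$marker[out$positions$is_marker] <- vapply(
    units[out$unit_at[out$positions$is_marker]], function(u) u$markers[1],
    character(1))
  out$unit_at <- NULL
  out
}

# HMM forward-backward given per-unit emissions; shared by lander_green and
# the scan driver
lg_fb <- function(setup, emis, unit_cm, positions_cm, fid) {
  extra <- setdiff(positions_cm, unit_cm)
  pos_df <- data.frame(cm = c(unit_cm, extra),
                       unit = c(seq_along(emis),
                                rep(NA_integer_, length(extra))))
  pos_df <- pos_df[order(pos_df$cm, pos_df$unit), , drop = FALSE]
  K <- nrow(pos_df); V <- setup$V
  alpha <- matrix(0, K, V); beta <- matrix(0, K, V)
  loglik <- 0
  cur <- rep(1 / V, V)
  for (k in seq_len(K)) {
    if (k > 1L)
      cur <- lg_mix(cur, cm_to_theta(pos_df$cm[k] - pos_df$cm[k - 1L]),
                    setup$B)
    if (!is.na(pos_df$unit[k])) {
      cur <- cur * emis[[pos_df$unit[k]]]
      s <- sum(cur)
      if (s <= 0) stop("family ", fid,
                       ": zero likelihood at position ", pos_df$cm[k])
      loglik <- loglik + log(s)
      cur <- cur / s
    }
    alpha[k, ] <- cur
  }
  cur <- rep(1, V)
  for (k in rev(seq_len(K))) {
    beta[k, ] <- cur
    if (!is.na(pos_df$unit[k])) {
      cur <- cur * emis[[pos_df$unit[k]]]
      cur <- cur / sum(cur)
    }
    if (k > 1L)
      cur <- lg_mix(cur, cm_to_theta(pos_df$cm[k] - pos_df$cm[k - 1L]),
                    setup$B)
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  structure(list(positions = data.frame(cm = pos_df$cm,
                                        is_marker = !is.na(pos_df$unit)),
                 unit_at = pos_df$unit,
                 post = post, loglik = loglik, setup = setup),
            class = "lg_dist")
}

# group map rows into emission units (single SNPs or LD clusters)
marker_units <- function(map, clusters) {
  if (is.null(clusters)) {
    return(lapply(seq_len(nrow(map)), function(j)
      list(markers = map$marker[j], cm = map$cm[j],
           freqs = c(1 - map$freq2[j], map$freq2[j]), haplo = NULL)))
  }
  out <- list()
  for (cl in clusters$clusters) {
    rows <- match(cl$markers, map$marker)
    out[[length(out) + 1L]] <-
      list(markers = cl$markers, cm = map$cm[rows[1]],
           freqs = cl$hap_freqs, haplo = cl$haplotypes)
  }
  solo <- setdiff(map$marker, unlist(lapply(clusters$clusters, `[[`, "markers")))
  for (mk in solo) {
    j <- match(mk, map$marker)
    out[[length(out) + 1L]] <-
      list(markers = mk, cm = map$cm[j],
           freqs = c(1 - map$freq2[j], map$freq2[j]), haplo = NULL)
  }
  out[order(vapply(out, `[[`, numeric(1), "cm"))]
}

# allowed haplotype pairs for one emission unit given observed dosages
unit_pairset <- function(un, dosages) {
  if (all(is.na(dosages))) return(NULL)
  if (is.null(un$haplo)) return(snp_pairset(dosages[1]))
  H <- nrow(un$haplo)
  prs <- NULL
  for (i in seq_len(H)) for (j in i:H) {
    dose <- (un$haplo[i, ] == 2L) + (un$haplo[j, ] == 2L)
    ok <- all(is.na(dosages) | dose == dosages)
    if (ok) prs <- rbind(prs, c(i, j))
  }
  if (is.null(prs)) matrix(integer(0), 0L, 2L) else prs
}

# Whittemore-Halpern S_all score for every inheritance vector (vectorized
# over vectors; loops only over the 2^a allele picks)
sall_scores <- function(setup) {
  aff <- setup$aff
  a <- length(aff)
  if (a < 2L) stop("S_all needs >= 2 affected members")
  pn <- setup$patnode[, aff, drop = FALSE]
  mn <- setup$matnode[, aff, drop = FALSE]
  V <- setup$V
  lfac <- factorial(0:a)
  s <- numeric(V)
  for (mask in 0:(2^a - 1L)) {
    take_m <- bitwAnd(bitwShiftR(mask, 0:(a - 1L)), 1L) == 1L
    lab <- pn
    lab[, take_m] <- mn[, take_m, drop = FALSE]
    pr <- rep(1, V)
    for (node in seq_len(setup$n_nodes))
      pr <- pr * lfac[rowSums(lab == node) + 1L]
    s <- s + pr
  }
  s / 2^a
}

#' Nonparametric linkage Z scores (S_all)
#'
#' Standardizes posterior mean allele sharing among affected members against
#' exact null moments obtained by enumeration over uniform inheritance
#' vectors: Z = (E[S_all | data] - mu0) / sigma0 per position.
#'
#' @param p A \code{linkped} with >= 2 affected members.
#' @param inheritance An \code{lg_dist} from \code{\link{lander_green}}.
#' @return List: \code{z} (per position), \code{positions}, and the family
#'   null law \code{null} = list(mu, sd, zvals, probs, zmin) of the
#'   standardized score (consumed by \code{\link{kong_cox}}).
#' @export
npl_sall <- function(p, inheritance) {
  setup <- inheritance$setup
  s <- sall_scores(setup)
  mu <- mean(s)
  sd0 <- sqrt(mean((s - mu)^2))
  if (sd0 <= 1e-14) {
    z <- rep(0, nrow(inheritance$post))
    null <- list(mu = mu, sd = 0, zvals = 0, probs = 1, zmin = 0)
  } else {
    zt <- (s - mu) / sd0
    z <- as.numeric(inheritance$post %*% zt)
    tab <- tapply(rep(1 / length(zt), length(zt)), round(zt, 12), sum)
    null <- list(mu = mu, sd = sd0,
                 zvals = as.numeric(names(tab)), probs = as.numeric(tab),
                 zmin = min(zt))
  }
  list(z = z, positions = inheritance$positions, null = null)
}

#' Kong-Cox allele-sharing LOD
#'
#' One-parameter (delta >= 0) likelihood on per-family NPL Z scores with
#' weights gamma_f (default equal, normalized so sum(gamma^2) = 1).
#' Linear model: l(delta) = sum_f log(1 + delta * gamma_f * Z_f), with delta
#' bounded so every family's smallest attainable standardized score keeps its
#' factor positive. Exponential model: exponential tilting of each family's
#' null score distribution, l(delta) = sum_f [delta*gamma_f*Z_f -
#' K_f(delta*gamma_f)] with K_f the exact cumulant generating function when
#' family null laws are supplied (Gaussian K(t) = t^2/2 otherwise).
#' LOD = max_delta l(delta) / ln 10; the one-sided boundary gives LOD = 0
#' when the score gradient at delta = 0 is nonpositive.
#'
#' @param z Numeric vector (one position) or matrix (families x positions) of
#'   per-family Z scores.
#' @param model \code{"linear"} or \code{"exponential"}.
#' @param weights Per-family weights (default equal).
#' @param null Optional list of per-family null laws as returned in
#'   \code{npl_sall()$null}.
#' @return List: \code{lod} and \code{delta} per position, plus
#'   \code{max_lod}.
#' @export
kong_cox <- function(z, model = c("linear", "exponential"), weights = NULL,
                     null = NULL) {
  model <- match.arg(model)
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
  Fn <- nrow(Z)
  if (!Fn || all(is.na(Z))) stop("kong_cox: no usable family Z scores")
  if (is.null(weights)) weights <- rep(1, Fn)
  gam <- weights / sqrt(sum(weights^2))
  zmin <- if (!is.null(null)) vapply(null, `[[`, numeric(1), "zmin") else NULL
  lods <- numeric(ncol(Z)); deltas <- numeric(ncol(Z))
  for (j in seq_len(ncol(Z))) {
    zj <- Z[, j]
    ok <- !is.na(zj)
    g <- gam[ok]; zz <- zj[ok]
    if (model == "linear") {
      lower <- if (!is.null(zmin)) zmin[ok] else pmin(zz, 0)
      neg <- g * lower < 0
      dmax <- if (any(neg)) 0.999 * min(-1 / (g[neg] * lower[neg])) else 10
      obj <- function(d) sum(log1p(d * g * zz))
    } else {
      kf <- function(t, f) {
        if (!is.null(null) && null[[f]]$sd > 0)
          log(sum(null[[f]]$probs * exp(t * null[[f]]$zvals)))
        else t^2 / 2
      }
      fok <- which(ok)
      dmax <- 10
      obj <- function(d) sum(vapply(seq_along(fok), function(i)
        d * g[i] * zz[i] - kf(d * g[i], fok[i]), numeric(1)))
    }
    if (sum(g * zz) <= 0 || dmax <= 0) { lods[j] <- 0; deltas[j] <- 0; next }
    opt <- stats::optimize(obj, c(0, dmax), maximum = TRUE, tol = 1e-8)
    cand_d <- c(0, opt$maximum, dmax)
    cand_v <- vapply(cand_d, obj, numeric(1))
    i <- which.max(cand_v)
    deltas[j] <- cand_d[i]
    lods[j] <- max(cand_v[i], 0) / log(10)
  }
  list(lod = lods, delta = deltas, max_lod = max(lods))
}

# P(affection pattern | inheritance vector): drop disease alleles through the
# vector; only affecteds constrain (affecteds-only contract).
parametric_vector_lik <- function(setup, dm) {
  aff <- setup$aff
  V <- setup$V
  if (!length(aff)) return(rep(1, V))
  q <- dm$disease_freq; f <- dm$penetrances
  pn <- setup$patnode[, aff, drop = FALSE]
  mn <- setup$matnode[, aff, drop = FALSE]
  used <- sort(unique(c(pn, mn)))
  nu <- length(used)
  ridx <- integer(setup$n_nodes)
  ridx[used] <- seq_len(nu)
  pn <- matrix(ridx[pn], nrow = V)
  mn <- matrix(ridx[mn], nrow = V)
  out <- numeric(V)
  for (mask in 0:(2^nu - 1L)) {
    x <- bitwAnd(bitwShiftR(mask, 0:(nu - 1L)), 1L)  # disease-allele count
    pr <- prod(ifelse(x == 1L, q, 1 - q))
    ncop <- matrix(x[pn] + x[mn], nrow = V)
    pen <- rep(pr, V)
    for (jj in seq_len(ncol(ncop))) pen <- pen * f[ncop[, jj] + 1L]
    out <- out + pen
  }
  out
}

#' Multipoint parametric LOD scan
#'
#' Per position x: family LOD = log10 sum_v P(v | markers) P(Phi | v) -
#' log10 sum_v 2^-B P(Phi | v), where P(Phi | v) drops disease alleles
#' through the inheritance vector under the disease model. Cohort LOD is the
#' sum over families; HLOD comes from \code{\link{hlod}}.
#'
#' @param peds List of \code{linkped} (families over the bit cap are skipped
#'   with a warning).
#' @param map One chromosome's \code{markermap} with \code{freq2}.
#' @param dm A \code{disease_model}.
#' @param step_cm Grid step between markers (default 0.3 cM).
#' @param cap_bits Meiosis-bit cap.
#' @param clusters,masked Passed to \code{\link{lander_green}}.
#' @return List: \code{positions}, \code{lod} (cohort), \code{per_family},
#'   \code{hlod}, \code{alpha}, \code{skipped} (family ids over cap).
#' @export
multipoint_parametric_lod <- function(peds, map, dm, step_cm = 0.3,
                                      cap_bits = 16L, clusters = NULL,
                                      masked = NULL) {
  if (inherits(peds, "linkped")) peds <- list(peds)
  grid <- if (nrow(map) > 1L)
    seq(min(map$cm), max(map$cm), by = step_cm) else map$cm
  per_fam <- list(); skipped <- character(0)
  positions <- NULL
  for (p in peds) {
    lg <- tryCatch(lander_green(p, map, positions_cm = grid,
                                cap_bits = cap_bits, clusters = clusters,
                                masked = masked),
                   error = function(e) e)
    if (inherits(lg, "error")) {
      warning("skipping family ", p$family_id, ": ", conditionMessage(lg))
      skipped <- c(skipped, p$family_id)
      next
    }
    pv <- parametric_vector_lik(lg$setup, dm)
    null_lik <- mean(pv)
    lodv <- log10(as.numeric(lg$post %*% pv)) - log10(null_lik)
    per_fam[[p$family_id]] <- lodv
    positions <- lg$positions
  }
  if (!length(per_fam)) stop("all families skipped (bit cap)")
  L <- do.call(rbind, per_fam)
  h <- hlod(L)
  list(positions = positions, lod = colSums(L), per_family = L,
       hlod = h$hlod, alpha = h$alpha, skipped = skipped)
}

#' 1-LOD-down support interval
#'
#' Maximal contiguous run of positions around the peak with LOD >= max - drop,
#' with boundaries refined by linear interpolation in cM and mapped to bp via
#' interpolation of the marker map.
#'
#' @param positions_cm Position grid (cM, ascending).
#' @param lod LOD per position.
#' @param map Optional \code{markermap} for the chromosome (enables bp
#'   interpolation).
#' @param drop LOD drop defining the interval (default 1).
#' @return List: \code{start_cm}, \code{end_cm}, \code{peak_cm},
#'   \code{max_lod}, and \code{start_bp}/\code{end_bp} when a map is given.
#' @export
support_interval <- function(positions_cm, lod, map = NULL, drop = 1.0) {
  if (max(lod) <= 0) stop("support_interval: no peak (max LOD <= 0)")
  if (diff(range(lod)) < 1e-12) {
    warning("flat LOD curve; support interval spans all positions")
    lo <- min(positions_cm); hi <- max(positions_cm); pk <- positions_cm[1]
  } else {
    i <- which.max(lod)
    thr <- lod[i] - drop
    l <- i; while (l > 1L && lod[l - 1L] >= thr) l <- l - 1L
    r <- i; while (r < length(lod) && lod[r + 1L] >= thr) r <- r + 1L
    lo <- if (l == 1L || drop == 0) positions_cm[l] else
      stats::approx(lod[c(l - 1L, l)], positions_cm[c(l - 1L, l)],
                    xout = thr)$y
    hi <- if (r == length(lod) || drop == 0) positions_cm[r] else
      stats::approx(lod[c(r + 1L, r)], positions_cm[c(r + 1L, r)],
                    xout = thr)$y
    pk <- positions_cm[i]
  }
  out <- list(start_cm = lo, end_cm = hi, peak_cm = pk, max_lod = max(lod))
  if (!is.null(map) && nrow(map) >= 2L) {
    out$start_bp <- stats::approx(map$cm, map$bp, xout = lo, rule = 2)$y
    out$end_bp <- stats::approx(map$cm, map$bp, xout = hi, rule = 2)$y
  }
  out
}
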