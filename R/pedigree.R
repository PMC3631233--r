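# Pedigree and marker-map data model, PED/MAP I/O, validation, map arithmetic.

SEX_MALE <- 1L
SEX_FEMALE <- 2L
SEX_UNKNOWN <- 0L
AFF_UNAFFECTED <- 1L
AFF_AFFECTED <- 2L
AFF_UNCERTAIN <- 0L

#' Construct a pedigree
#'
#' Builds a validated single-family pedigree. Genotypes are stored as counts
#' of the map's second allele (0/1/2, \code{NA} = missing), one row per
#' member, one column per marker.
#'
#' @param family_id Family identifier (coerced to character).
#' @param members Data frame with columns \code{id}, \code{father},
#'   \code{mother} (both \code{NA} for founders), \code{sex} (1 = male,
#'   2 = female, 0 = unknown), \code{aff} (2 = affected, 1 = unaffected,
#'   0 = uncertain), \code{sampled} (logical: genotyped).
#' @param geno Optional integer matrix of allele-2 dosages, rownames = member
#'   ids, colnames = marker ids.
#' @param stratum Stratum label, e.g. \code{"positive"}, \code{"negative"},
#'   or \code{NA} when unset.
#' @return An object of class \code{linkped}.
#' @export
pedigree <- function(family_id, members, geno = NULL, stratum = NA_character_) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  req <- c("id", "father", "mother", "sex", "aff", "sampled")
  if (!all(req %in% names(members)))
    stop("members must have columns: ", paste(req, collapse = ", "))
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  members$sex <- as.integer(members$sex)
  members$aff <- as.integer(members$aff)
  members$sampled <- as.logical(members$sampled)
  if (anyDuplicated(members$id))
    stop("duplicate individual ids in family ", family_id)
  p <- structure(list(family_id = as.character(family_id),
                      members = members,
                      geno = geno,
                      stratum = as.character(stratum)),
                 class = "linkped")
  validate_pedigree(p)
  if (!is.null(geno)) {
    if (is.null(rownames(geno)) || !all(rownames(geno) %in% members$id))
      stop("geno rownames must be member ids")
    storage.mode(p$geno) <- "integer"
  }
  p
}

validate_pedigree <- function(p) {
  m <- p$members
  half <- xor(is.na(m$father), is.na(m$mother))
  if (any(half))
    stop("half-specified parents for individual(s) ",
         paste(m$id[half], collapse = ", "), " in family ", p$family_id)
  for (col in c("father", "mother")) {
    ref <- m[[col]][!is.na(m[[col]])]
    missing_ref <- setdiff(ref, m$id)
    if (length(missing_ref))
      stop("family ", p$family_id, ": referenced ", col, "(s) not present: ",
           paste(unique(missing_ref), collapse = ", "))
  }
  fa_sex <- m$sex[match(m$father[!is.na(m$father)], m$id)]
  mo_sex <- m$sex[match(m$mother[!is.na(m$mother)], m$id)]
  if (any(fa_sex == SEX_FEMALE) || any(mo_sex == SEX_MALE))
    stop("family ", p$family_id, ": parent sex inconsistent with parental role")
  # acyclicity: repeatedly strip individuals whose parents are all stripped
  depth <- rep(NA_integer_, nrow(m))
  depth[is.na(m$father)] <- 0L
  for (iter in seq_len(nrow(m) + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (i in todo) {
      df <- depth[match(m$father[i], m$id)]
      dm <- depth[match(m$mother[i], m$id)]
      if (!is.na(df) && !is.na(dm)) depth[i] <- max(df, dm) + 1L
    }
    if (iter > nrow(m)) stop("family ", p$family_id, ": parent graph is cyclic")
  }
  if (has_loop(m)) stop("family ", p$family_id, ": pedigree contains a loop (not supported)")
  invisible(p)
}

# Marriage-node graph cycle check: bipartite graph of individuals and nuclear
# family nodes; a loop-free pedigree yields a forest.
has_loop <- function(m) {
  kids <- !is.na(m$father)
  if (!any(kids)) return(FALSE)
  fams <- unique(paste(m$father[kids], m$mother[kids], sep = "\r"))
  n_ind <- nrow(m)
  parent <- seq_len(n_ind + length(fams))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra == rb) return(TRUE); parent[ra] <<- rb; FALSE }
  couple <- paste(m$father, m$mother, sep = "\r")
  for (k in seq_along(fams)) {
    fam_node <- n_ind + k
    pr <- strsplit(fams[k], "\r", fixed = TRUE)[[1]]
    members <- c(match(pr[1], m$id), match(pr[2], m$id),
                 which(kids & couple == fams[k]))
    for (v in members) if (unite(v, fam_node)) return(TRUE)
  }
  FALSE
}

#' @export
print.linkped <- function(x, ...) {
  cat(sprintf("<linkped> family %s: %d members (%d founders, %d affected), bits = %d\n",
              x$family_id, nrow(x$members), sum(is.na(x$members$father)),
              sum(x$members$aff == AFF_AFFECTED), ped_bits(x)))
  invisible(x)
}

founder_ids <- function(p) p$members$id[is.na(p$members$father)]
nonfounder_ids <- function(p) p$members$id[!is.na(p$members$father)]

#' Meiosis-bit count of a pedigree
#'
#' Conventional inheritance-vector size 2 * nonfounders - founders (founder
#' phase symmetry removed).
#' @param p A \code{linkped}.
#' @return Integer bit count.
#' @export
ped_bits <- function(p) {
  nf <- sum(!is.na(p$members$father))
  f <- nrow(p$members) - nf
  max(0L, 2L * nf - f)
}

#' Read a PED file
#'
#' Whitespace-delimited PLINK/LINKAGE dialect: FID IID PAT MAT SEX PHENO
#' followed by one allele pair per marker. Phenotype codes: 1 unaffected,
#' 2 affected, 0 or -9 uncertain. Parent code \code{"0"} means founder; a
#' half-specified parent pair is an error.
#'
#' @param path PED file path.
#' @param map Optional \code{markermap}; supplies marker ids and allele
#'   labels. Without it markers are named \code{m1..mM} and allele labels are
#'   assigned per marker in sorted order of appearance.
#' @param missing_code Allele code denoting a missing call (default "0").
#' @return Named list of \code{linkped} objects, with attribute
#'   \code{marker_alleles} (data frame marker/a1/a2).
#' @export
read_pedfile <- function(path, map = NULL, missing_code = "0") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop("PED parse error: inconsistent column count at line ",
         which(ncols != ncols[1])[1], " of ", path)
  if (ncols[1] < 6L || (ncols[1] - 6L) %% 2L != 0L)
    stop("PED parse error: line 1 has ", ncols[1],
         " columns; expected 6 + 2*markers")
  n_mark <- (ncols[1] - 6L) %/% 2L
  tab <- do.call(rbind, toks)
  fid <- tab[, 1]; iid <- tab[, 2]; pat <- tab[, 3]; mat <- tab[, 4]
  sex <- suppressWarnings(as.integer(tab[, 5]))
  pheno <- tab[, 6]
  aff <- ifelse(pheno == "2", AFF_AFFECTED,
         ifelse(pheno == "1", AFF_UNAFFECTED, AFF_UNCERTAIN))
  sex[is.na(sex) | !(sex %in% c(1L, 2L))] <- SEX_UNKNOWN

  if (!is.null(map)) {
    if (nrow(map) != n_mark)
      stop("map has ", nrow(map), " markers but PED has ", n_mark)
    marker_ids <- map$marker
    a1 <- map$a1; a2 <- map$a2
  } else {
    marker_ids <- paste0("m", seq_len(n_mark))
    a1 <- a2 <- rep(NA_character_, n_mark)
  }

  al1 <- tab[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE]
  al2 <- tab[, 6L + 2L * seq_len(n_mark), drop = FALSE]
  geno_all <- matrix(NA_integer_, nrow(tab), n_mark,
                     dimnames = list(iid, marker_ids))
  for (j in seq_len(n_mark)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    miss <- x1 == missing_code | x2 == missing_code
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (is.na(a1[j])) {
      if (length(obs) > 2L)
        stop("marker ", marker_ids[j], " has >2 alleles: ",
             paste(obs, collapse = ","))
      a1[j] <- if (length(obs) >= 1L) obs[1] else "1"
      a2[j] <- if (length(obs) == 2L) obs[2] else
        if (a1[j] == "1") "2" else "1"
    } else if (length(setdiff(obs, c(a1[j], a2[j]))) > 0L) {
      stop("marker ", marker_ids[j], ": allele(s) not in map: ",
           paste(setdiff(obs, c(a1[j], a2[j])), collapse = ","))
    }
    g <- (x1 == a2[j]) + (x2 == a2[j])
    g[miss] <- NA_integer_
    geno_all[, j] <- as.integer(g)
  }

  peds <- lapply(split(seq_along(fid), factor(fid, levels = unique(fid))),
                 function(rows) {
    mem <- data.frame(id = iid[rows],
                      father = ifelse(pat[rows] == "0", NA_character_, pat[rows]),
                      mother = ifelse(mat[rows] == "0", NA_character_, mat[rows]),
                      sex = sex[rows], aff = aff[rows],
                      sampled = rowSums(!is.na(geno_all[rows, , drop = FALSE])) > 0,
                      stringsAsFactors = FALSE)
    pedigree(fid[rows[1]], mem, geno = geno_all[rows, , drop = FALSE])
  })
  message(sprintf("read_pedfile: %d families, %d individuals, %d markers",
                  length(peds), length(iid), n_mark))
  attr(peds, "marker_alleles") <- data.frame(marker = marker_ids, a1 = a1,
                                             a2 = a2, stringsAsFactors = FALSE)
  peds
}

#' Write a cohort to a PED file
#' @param peds List of \code{linkped}.
#' @param path Output path.
#' @param map \code{markermap} giving marker order and allele labels.
#' @param missing_code Missing-allele code (default "0").
#' @export
write_pedfile <- function(peds, path, map, missing_code = "0") {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in peds) {
    m <- p$members
    g <- p$geno[, map$marker, drop = FALSE]
    for (i in seq_len(nrow(m))) {
      al <- character(2L * nrow(map))
      gi <- g[m$id[i], ]
      a1s <- ifelse(is.na(gi), missing_code, ifelse(gi >= 1L, map$a2, map$a1))
      a2s <- ifelse(is.na(gi), missing_code, ifelse(gi == 2L, map$a2, map$a1))
      al[c(TRUE, FALSE)] <- a1s; al[c(FALSE, TRUE)] <- a2s
      ph <- c("0", "1", "2")[m$aff[i] + 1L]
      writeLines(paste(c(p$family_id, m$id[i],
                         ifelse(is.na(m$father[i]), "0", m$father[i]),
                         ifelse(is.na(m$mother[i]), "0", m$mother[i]),
                         m$sex[i], ph, al), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a genetic map file
#'
#' Whitespace-delimited columns: chromosome, marker id, genetic position (cM),
#' physical position (bp). An empty/NA cM field flags the marker as having no
#' genetic distance (consumed by the QC cascade). Markers are sorted by
#' (chromosome, cM); if cM order disagrees with bp order a warning is issued
#' and cM order wins.
#'
#' @param path Map file path.
#' @return A \code{markermap} data frame: chrom, marker, cm, bp, a1, a2,
#'   freq2, missing_cm.
#' @export
read_mapfile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(!(lengths(toks) %in% c(3L, 4L)))
  if (length(bad)) stop("map parse error at line ", bad[1], " of ", path)
  tab <- t(vapply(toks, function(x) c(x, rep(NA_character_, 4 - length(x))),
                  character(4)))
  cm <- suppressWarnings(as.numeric(ifelse(tab[, 3] %in% c("", "NA", "."),
                                           NA, tab[, 3])))
  map <- markermap(chrom = tab[, 1], marker = tab[, 2], cm = cm,
                   bp = as.numeric(tab[, 4]))
  message(sprintf("read_mapfile: %d markers on %d chromosome(s), %d missing cM",
                  nrow(map), length(unique(map$chrom)), sum(map$missing_cm)))
  map
}

#' Construct a marker map
#' @param chrom,marker,cm,bp Per-marker columns.
#' @param a1,a2 Allele labels (defaults "1"/"2").
#' @param freq2 Frequency of allele \code{a2} (the dosage-counted allele).
#' @return A \code{markermap} sorted by (chromosome, cM, bp).
#' @export
markermap <- function(chrom, marker, cm, bp, a1 = "1", a2 = "2",
                      freq2 = NA_real_) {
  if (anyDuplicated(marker))
    stop("duplicate marker id(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  m <- data.frame(chrom = as.character(chrom), marker = as.character(marker),
                  cm = as.numeric(cm), bp = as.numeric(bp),
                  a1 = a1, a2 = a2, freq2 = freq2,
                  missing_cm = is.na(cm), stringsAsFactors = FALSE)
  ord_bp <- order(m$chrom, m$bp)
  ord_cm <- order(m$chrom, ifelse(is.na(m$cm), Inf, m$cm), m$bp)
  if (!identical(ord_bp, ord_cm))
    warning("cM order disagrees with bp order; map re-sorted by cM")
  m <- m[ord_cm, , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("markermap", "data.frame")
  m
}

#' Write a marker map
#' @param map A \code{markermap}.
#' @param path Output path.
#' @export
write_mapfile <- function(map, path) {
  utils::write.table(
    data.frame(map$chrom, map$marker,
               ifelse(is.na(map$cm), "NA", format(map$cm, digits = 15)),
               format(map$bp, scientific = FALSE)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Disease model
#'
#' Single-locus disease model: disease allele frequency and penetrances
#' (f0, f1, f2) = P(affected | 0/1/2 copies of the disease allele). The
#' default is the rare-dominant affecteds-only model: allele frequency 0.001
#' and penetrances (0, 0.001, 0.001), under which unaffected phenotypes carry
#' essentially no information while affected individuals demand at least one
#' disease allele.
#'
#' @param disease_freq Disease allele frequency in (0, 1).
#' @param penetrances Numeric length-3 vector in [0, 1].
#' @return A \code{disease_model}.
#' @export
disease_model <- function(disease_freq = 0.001,
                          penetrances = c(0, 0.001, 0.001)) {
  if (!(disease_freq > 0 && disease_freq < 1))
    stop("disease_freq must be in (0,1)")
  if (length(penetrances) != 3L || any(penetrances < 0 | penetrances > 1))
    stop("penetrances must be 3 values in [0,1]")
  structure(list(disease_freq = disease_freq,
                 penetrances = as.numeric(penetrances)),
            class = "disease_model")
}

#' Trim a pedigree for linkage
#'
#' Iteratively removes individuals that are (a) nobody's parent, (b) not
#' genotyped, and (c) not affected. Such leaves contribute a constant factor
#' to every linkage likelihood, so LOD scores are unchanged.
#'
#' @param p A \code{linkped}.
#' @return Trimmed \code{linkped}.
#' @export
trim_pedigree <- function(p) {
  repeat {
    m <- p$members
    is_parent <- m$id %in% c(m$father, m$mother)
    drop <- !is_parent & !m$sampled & m$aff != AFF_AFFECTED
    if (!any(drop)) break
    keep <- m$id[!drop]
    p <- pedigree(p$family_id, m[!drop, , drop = FALSE],
                  geno = if (!is.null(p$geno)) p$geno[keep, , drop = FALSE],
                  stratum = p$stratum)
  }
  p
}

#' Estimate marker allele frequencies from founders
#'
#' Counting estimator over non-missing genotypes of the selected founder
#' class. Markers with zero observations are flagged (\code{freq_nobs = 0},
#' \code{freq2 = NA}).
#'
#' @param peds List of \code{linkped}.
#' @param map \code{markermap}.
#' @param who \code{"founders"} (all founders) or \code{"unaffected_founders"}
#'   (affected founders excluded; uncertain retained).
#' @return The map with \code{freq2} and \code{freq_nobs} filled in.
#' @export
estimate_allele_freqs <- function(peds, map,
                                  who = c("founders", "unaffected_founders")) {
  who <- match.arg(who)
  rows <- lapply(peds, function(p) {
    sel <- is.na(p$members$father)
    if (who == "unaffected_founders") sel <- sel & p$members$aff != AFF_AFFECTED
    if (!any(sel)) return(NULL)
    p$geno[p$members$id[sel], map$marker, drop = FALSE]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no individuals in class '", who, "' for markers: ",
                          paste(utils::head(map$marker, 5), collapse = ","))
  g <- do.call(rbind, rows)
  nobs <- colSums(!is.na(g))
  freq2 <- colSums(g, na.rm = TRUE) / (2 * nobs)
  freq2[nobs == 0] <- NA_real_
  map$freq2 <- as.numeric(freq2)
  map$freq_nobs <- as.integer(nobs)
  map
}

#' Haldane map function
#'
#' Converts genetic distance in centimorgans to a recombination fraction,
#' theta = (1 - exp(-2 d / 100)) / 2, or (Kosambi) theta = tanh(2d/100)/2.
#'
#' @param d Distance in cM (nonnegative).
#' @param map_function \code{"haldane"} (default) or \code{"kosambi"}.
#' @return Recombination fraction in [0, 0.5).
#' @export
cm_to_theta <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop("genetic distance must be nonnegative")
  switch(map_function,
         haldane = (1 - exp(-2 * d / 100)) / 2,
         kosambi = tanh(2 * d / 100) / 2)
}

#' Inverse Haldane map function
#' @param theta Recombination fraction in [0, 0.5).
#' @param map_function \code{"haldane"} or \code{"kosambi"}.
#' @return Distance in cM.
#' @export
theta_to_cm <- function(theta, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(theta < 0 | theta >= 0.5)) stop("theta must be in [0, 0.5)")
  switch(map_function,
         haldane = -50 * log(1 - 2 * theta),
         kosambi = 25 * log((1 + 2 * theta) / (1 - 2 * theta)))
}
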