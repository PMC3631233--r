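# Candidate-variant triage and family segregation classification for
# sequencing follow-up of linkage peaks.

#' Read a variant-record table
#'
#' Tab-separated columns: gene, chrom, position, variant_id, ref, alt,
#' class, study_maf, ref_maf (reference-population MAF; "NA" allowed for
#' novel variants), n_affected_carriers, same_family_novel (TRUE when a
#' novel variant's carriers are confined to one family).
#'
#' @param path File path.
#' @return Data frame of variant records.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "position", "variant_id", "ref", "alt", "class",
           "study_maf", "ref_maf", "n_affected_carriers", "same_family_novel")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(tab$position <= 0)) stop("variant positions must be positive")
  bad <- !is.na(tab$ref_maf) & (tab$ref_maf < 0 | tab$ref_maf > 0.5)
  if (any(bad | tab$study_maf < 0 | tab$study_maf > 0.5))
    stop("MAFs must lie in [0, 0.5] (minor-allele convention)")
  tab
}

#' Select variants for segregation follow-up
#'
#' Keeps records passing all three criteria: (1) reference-population MAF
#' below \code{maf_cut} (novel variants, reference MAF NA, pass vacuously);
#' (2) carried by more than one affected individual, except novel variants
#' whose carriers are confined to a single family
#' (\code{same_family_novel}); (3) reference MAF below the study MAF
#' estimated from screened affected individuals (vacuous for novel
#' variants).
#'
#' @param records Data frame as from \code{\link{read_variant_table}}.
#' @param maf_cut Reference-MAF cutoff (default 0.05).
#' @return The subset of \code{records} passing, with a \code{criteria}
#'   attribute (logical matrix).
#' @export
select_variants <- function(records, maf_cut = 0.05) {
  if (anyNA(records$study_maf))
    stop("study MAF missing for: ",
         paste(records$variant_id[is.na(records$study_maf)], collapse = ", "))
  novel <- is.na(records$ref_maf)
  c1 <- novel | records$ref_maf < maf_cut
  c2 <- records$n_affected_carriers > 1L |
    (novel & as.logical(records$same_family_novel))
  c3 <- novel | records$ref_maf < records$study_maf
  keep <- c1 & c2 & c3
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- cbind(ref_maf_rare = c1, multi_carrier = c2,
                                 enriched = c3)
  out
}

#' Read a carrier table
#'
#' Tab-separated columns: variant_id, family, id, aff (2 affected,
#' 1 unaffected, 0 uncertain), carrier (0 hom-ref, 1 het, 2 hom-alt,
#' NA unknown). Rows are sampled (sequenced) members only.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_carrier_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "family", "id", "aff", "carrier")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("carrier table missing columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Per-family segregation classification
#'
#' For one variant: \code{complete_sharing} is "yes" when every genotyped
#' affected member carries the variant; \code{reduced_penetrance} is "yes"
#' when any genotyped unaffected or uncertain member carries it, "unknown"
#' when no such member was genotyped. Counts are carriers/total per class.
#'
#' @param variant_id Variant to classify.
#' @param carriers Carrier table (see \code{\link{read_carrier_table}}).
#' @return Data frame: one row per family with counts and classifications.
#' @export
segregation_check <- function(variant_id, carriers) {
  sub <- carriers[carriers$variant_id == variant_id, , drop = FALSE]
  if (!nrow(sub)) stop("no carrier rows for variant ", variant_id)
  rows <- lapply(split(sub, sub$family), function(fam) {
    gen <- fam[!is.na(fam$carrier), , drop = FALSE]
    if (!nrow(gen)) {
      message("family ", fam$family[1], ": no genotyped members, skipped")
      return(NULL)
    }
    affc <- gen[gen$aff == 2L, , drop = FALSE]
    unc <- gen[gen$aff != 2L, , drop = FALSE]
    if (!nrow(affc)) {
      message("family ", fam$family[1], ": no genotyped affected, skipped")
      return(NULL)
    }
    data.frame(
      variant_id = variant_id, family = fam$family[1],
      complete_sharing = if (all(affc$carrier > 0L)) "yes" else "no",
      aff_carriers = sum(affc$carrier > 0L), aff_total = nrow(affc),
      reduced_penetrance = if (!nrow(unc)) "unknown" else
        if (any(unc$carrier > 0L)) "yes" else "no",
      unaff_carriers = sum(unc$carrier > 0L), unaff_total = nrow(unc),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Pooled segregation summary across families
#'
#' Mirrors the sharing / reduced-penetrance columns of a variant follow-up
#' table: counts pooled over families carrying the variant.
#'
#' @param variant_id Variant id.
#' @param carriers Carrier table.
#' @return One-row data frame with pooled counts and classifications.
#' @export
segregation_summary <- function(variant_id, carriers) {
  per_fam <- segregation_check(variant_id, carriers)
  data.frame(
    variant_id = variant_id,
    all_affecteds = if (all(per_fam$complete_sharing == "yes")) "yes" else "no",
    aff_carriers = sum(per_fam$aff_carriers),
    aff_total = sum(per_fam$aff_total),
    reduced_penetrance = if (all(per_fam$unaff_total == 0L)) "unknown" else
      if (sum(per_fam$unaff_carriers) > 0L) "yes" else "no",
    unaff_carriers = sum(per_fam$unaff_carriers),
    unaff_total = sum(per_fam$unaff_total),
    stringsAsFactors = FALSE)
}
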