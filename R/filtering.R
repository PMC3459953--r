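trace_row <- function(site_key, sample_id, stage, status, reason) {
  tibble(site_key = site_key, sample_id = sample_id, stage = stage,
         status = status, reason = reason)
}

#' Confidence filter for per-sample variant calls
#'
#' Keeps calls satisfying every per-call confidence criterion
#' (inclusive thresholds): phred quality >= \code{min_qual}, read depth
#' >= \code{min_depth}, variant allele fraction >=
#' \code{min_allele_fraction}, and - when
#' \code{require_bidirectional} - at least one alt-supporting read on
#' each strand. Only calls carrying the alt allele (het or hom-alt) are
#' evaluated; reference and missing genotypes pass through untouched
#' so later stages can still use them for carrier accounting.
#'
#' @param calls Call tibble (see [read_variant_calls()]).
#' @param thresholds A [filter_thresholds()].
#' @return List with \code{kept} (calls surviving, including
#'   non-variant calls) and \code{trace} (one row per evaluated variant
#'   call with kept/removed status and the first failing criterion).
#' @export
confident_calls <- function(calls, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  is_var <- calls$genotype %in% c("het", "hom_alt")
  ev <- calls[is_var, ]
  if (thresholds$require_bidirectional &&
      (any(is.na(ev$alt_fwd)) || any(is.na(ev$alt_rev)))) {
    stop("strand-resolved alt read counts are missing but ",
         "require_bidirectional is TRUE; supply ADF/ADR or disable the ",
         "strand rule", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(ev))
  reason[is.na(reason) & !(ev$qual >= thresholds$min_qual)] <- "quality"
  reason[is.na(reason) & !(ev$depth >= thresholds$min_depth)] <- "depth"
  reason[is.na(reason) &
           !(ev$allele_fraction >= thresholds$min_allele_fraction)] <-
    "allele_fraction"
  if (thresholds$require_bidirectional) {
    reason[is.na(reason) & !(ev$alt_fwd >= 1 & ev$alt_rev >= 1)] <-
      "unidirectional"
  }
  keep <- is.na(reason)
  trace <- trace_row(ev$site_key, ev$sample_id, "confidence",
                     ifelse(keep, "kept", "removed"),
                     ifelse(keep, "passes_confidence", reason))
  kept <- dplyr::bind_rows(calls[!is_var, ], ev[keep, ])
  list(kept = kept, trace = trace)
}

#' Pre-check for deleterious variants in known susceptibility genes
#'
#' Before database and recurrence filtering, variants are screened for
#' overtly deleterious mutations in established breast cancer genes, so
#' that known pathogenic alleles carrying dbSNP identifiers are
#' reported rather than lost to the database-removal stage.
#'
#' @param variants Annotated variant tibble.
#' @param known_gene_list Character vector of gene symbols.
#' @return Tibble of flagged variants (possibly empty).
#' @export
known_gene_precheck <- function(variants,
                                known_gene_list = default_known_genes()) {
  if (!length(known_gene_list)) {
    warning("known gene list is empty; pre-check reports nothing",
            call. = FALSE)
    return(variants[0, ])
  }
  variants[classify_overtly_deleterious(variants) &
             variants$gene %in% known_gene_list, ]
}

#' Remove database-listed variants
#'
#' Removes variants present in dbSNP unless they are also reported in
#' the public Human Gene Mutation Database - the HGMD exception retains
#' catalogued disease alleles that have acquired rs identifiers.
#'
#' @param variants Annotated variant tibble with \code{in_dbsnp} and
#'   \code{in_hgmd} flags.
#' @return List with \code{kept} and \code{trace}.
#' @export
remove_database_variants <- function(variants) {
  removed <- variants$in_dbsnp & !variants$in_hgmd
  trace <- trace_row(variants$site_key, NA_character_, "database",
                     ifelse(removed, "removed", "kept"),
                     ifelse(removed, "dbsnp_not_hgmd", "not_database_only"))
  list(kept = variants[!removed, ], trace = trace)
}

#' Remove cohort-common variants
#'
#' Removes variants detected in strictly more than
#' \code{max_cohort_carriers} of the sequenced exomes (default more
#' than 10 of 33); a variant seen in exactly the threshold number of
#' exomes is retained.
#'
#' @param variants Annotated variant tibble with
#'   \code{cohort_carrier_count}.
#' @param thresholds A [filter_thresholds()].
#' @return List with \code{kept} and \code{trace}.
#' @export
remove_cohort_common <- function(variants,
                                 thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (any(variants$cohort_carrier_count > thresholds$cohort_size)) {
    stop("cohort_carrier_count exceeds cohort_size (",
         thresholds$cohort_size, ") for ",
         variants$site_key[which(variants$cohort_carrier_count >
                                   thresholds$cohort_size)[1]],
         call. = FALSE)
  }
  removed <- variants$cohort_carrier_count > thresholds$max_cohort_carriers
  trace <- trace_row(variants$site_key, NA_character_, "cohort_common",
                     ifelse(removed, "removed", "kept"),
                     ifelse(removed, "cohort_common", "cohort_rare"))
  list(kept = variants[!removed, ], trace = trace)
}

#' Select variants with overtly deleterious consequence classes
#'
#' Keeps variants whose predicted consequence is one of the four
#' disruptive classes: nonsense (\code{stop_gained}), frameshift
#' indels, essential splice-site variants, and complex indels. Note
#' that registry-validated pathogenic missense alleles are NOT admitted
#' here - the exome cascade uses the strict four-class definition; the
#' broader rule belongs to [classify_overtly_deleterious()] used by the
#' screening counts.
#'
#' @param variants Annotated variant tibble.
#' @return Tibble of deleterious variants.
#' @export
select_deleterious <- function(variants) {
  classes <- c("stop_gained", "frameshift_coding", "essential_splice_site",
               "complex_indel")
  variants[variants$consequence %in% classes, ]
}

#' Run the full candidate-variant filtering cascade
#'
#' Applies the discovery cascade in its published order: per-call
#' confidence filtering; a pre-check for overtly deleterious variants
#' in known susceptibility genes (reported separately, before any
#' annotation-based removal); removal of dbSNP variants not in HGMD;
#' removal of cohort-common variants; and selection of deleterious
#' consequence classes. Produces the per-individual candidate lists the
#' prioritization stage consumes, plus a complete stage-by-stage trace.
#'
#' @param cohort A \code{famexome_cohort} (from [simulate_cohort()] or
#'   [assemble_cohort()]).
#' @param thresholds A [filter_thresholds()].
#' @param known_genes Gene list for the pre-check stage.
#' @return List with \code{candidates} (tibble: \code{sample_id},
#'   \code{family_id}, \code{gene}, \code{site_key},
#'   \code{consequence}), \code{precheck} (known-gene report),
#'   \code{kept_variants}, and \code{trace}.
#' @export
run_cascade <- function(cohort, thresholds = filter_thresholds(),
                        known_genes = default_known_genes()) {
  variants <- cohort$variants
  calls <- cohort$calls
  if (nrow(variants) == 0L) {
    return(list(
      candidates = tibble(sample_id = character(), family_id = character(),
                          gene = character(), site_key = character(),
                          consequence = character()),
      precheck = variants, kept_variants = variants,
      trace = trace_row(character(), character(), character(), character(),
                        character())[0, ]
    ))
  }
  conf <- confident_calls(calls, thresholds)
  confident_variant_calls <- conf$kept[conf$kept$genotype %in%
                                         c("het", "hom_alt"), ]
  seen <- variants[variants$site_key %in% confident_variant_calls$site_key, ]
  dropped_conf <- variants[!variants$site_key %in% seen$site_key, ]
  trace <- dplyr::bind_rows(
    conf$trace,
    trace_row(dropped_conf$site_key, NA_character_, "confidence",
              "removed", "no_confident_variant_call")
  )

  precheck <- known_gene_precheck(seen, known_genes)

  db <- remove_database_variants(seen)
  trace <- dplyr::bind_rows(trace, db$trace)
  cc <- remove_cohort_common(db$kept, thresholds)
  trace <- dplyr::bind_rows(trace, cc$trace)
  kept <- select_deleterious(cc$kept)
  trace <- dplyr::bind_rows(
    trace,
    trace_row(cc$kept$site_key, NA_character_, "deleterious",
              ifelse(cc$kept$site_key %in% kept$site_key, "kept", "removed"),
              ifelse(cc$kept$site_key %in% kept$site_key,
                     "deleterious_class", "non_deleterious_class"))
  )

  cand_calls <- confident_variant_calls[
    confident_variant_calls$site_key %in% kept$site_key, ]
  candidates <- dplyr::left_join(
    cand_calls[, c("sample_id", "site_key")],
    kept[, c("site_key", "gene", "consequence")],
    by = "site_key"
  )
  candidates <- dplyr::left_join(candidates, cohort$samples, by = "sample_id")
  candidates <- candidates[order(candidates$sample_id, candidates$site_key),
                           c("sample_id", "family_id", "gene", "site_key",
                             "consequence")]
  list(candidates = as_tibble(candidates), precheck = precheck,
       kept_variants = kept, trace = trace)
}
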