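#' Filtering thresholds for confident variant calls
#'
#' Container for the per-call confidence and cohort-recurrence
#' thresholds of the candidate-variant filtering cascade. Defaults are
#' the published operating point for post-GATK germline exome calls:
#' phred quality >= 30, read depth >= 10, variant allele fraction
#' >= 0.15, bidirectional strand support, and removal of variants seen
#' in more than 10 of the 33 sequenced exomes.
#'
#' @param min_qual Minimum phred-scaled call quality (inclusive).
#' @param min_depth Minimum read depth (inclusive).
#' @param min_allele_fraction Minimum variant allele fraction, alt reads
#'   over depth (inclusive).
#' @param max_cohort_carriers Variants carried by strictly more than
#'   this many sequenced individuals are removed as cohort-common.
#' @param cohort_size Number of sequenced exomes in the discovery
#'   cohort.
#' @param require_bidirectional Require at least one alt-supporting read
#'   on each strand.
#' @return A list of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_qual = 30, min_depth = 10,
                              min_allele_fraction = 0.15,
                              max_cohort_carriers = 10, cohort_size = 33,
                              require_bidirectional = TRUE) {
  stopifnot(min_qual >= 0, min_depth >= 0, min_allele_fraction >= 0,
            max_cohort_carriers >= 0, cohort_size >= 1,
            is.logical(require_bidirectional))
  if (max_cohort_carriers >= cohort_size) {
    stop("max_cohort_carriers must be smaller than cohort_size",
         call. = FALSE)
  }
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 min_allele_fraction = min_allele_fraction,
                 max_cohort_carriers = max_cohort_carriers,
                 cohort_size = cohort_size,
                 require_bidirectional = require_bidirectional),
            class = "filter_thresholds")
}

#' Default known breast-cancer gene list for the pre-check stage
#'
#' Established breast/ovarian cancer susceptibility genes examined for
#' overtly deleterious mutations before database and recurrence
#' filtering, so that known pathogenic alleles listed in dbSNP are not
#' discarded.
#'
#' @return Character vector of gene symbols.
#' @export
default_known_genes <- function() {
  c("BRCA1", "BRCA2", "TP53", "PTEN", "ATM", "CHEK2", "BRIP1", "PALB2",
    "RAD51C", "RAD51D")
}

#' Default DNA-repair gene list used for prioritization
#'
#' Genes of the homologous-recombination / Fanconi Anemia DNA repair
#' machinery; candidates in these genes receive ranking priority.
#'
#' @return Character vector of gene symbols.
#' @export
default_dna_repair_genes <- function() {
  c("FANCC", "BLM", "BRCA1", "BRCA2", "PALB2", "BRIP1", "RAD51C",
    "RAD51D", "ATM", "CHEK2", "FANCA", "FANCD2", "FANCL", "RAD51")
}

make_site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

parse_gt_alt_count <- function(gt, alt_index) {
  # number of alleles equal to alt_index in a diploid GT string; NA if missing
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(as.integer(alleles) == alt_index)
}

#' Read annotated variant calls from a multi-sample VCF
#'
#' Reads a VCF 4.x file whose FORMAT includes \code{GT}, \code{DP} and
#' strand-resolved alt read counts \code{ADF}/\code{ADR} (Number=A, one
#' count per alt allele), and whose INFO carries \code{GENE},
#' \code{CSQ} (consequence class per alt allele) and the membership
#' flags \code{DBSNP}, \code{HGMD}, \code{KPATH}. Multi-allelic records
#' are decomposed into one annotated variant per alt allele; per-sample
#' calls report the genotype with respect to that allele. Per-call
#' quality is taken from \code{GQ} when present, else from the record
#' QUAL column.
#'
#' @param vcf_path Path to the VCF file.
#' @return A list with \code{variants}: one row per (site, alt allele)
#'   with \code{site_key}, \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene}, \code{transcript_id}, \code{cdna_hgvs},
#'   \code{consequence}, \code{in_dbsnp}, \code{in_hgmd},
#'   \code{known_pathogenic}, \code{cohort_carrier_count}; and
#'   \code{calls}: one row per sample x variant with \code{sample_id},
#'   \code{site_key}, \code{genotype} (\code{hom_ref}/\code{het}/
#'   \code{hom_alt}/\code{missing}), \code{qual}, \code{depth},
#'   \code{alt_fwd}, \code{alt_rev}, \code{allele_fraction}.
#' @export
read_variant_calls <- function(vcf_path) {
  if (!file.exists(vcf_path)) {
    stop("VCF file not found: ", vcf_path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    empty_var <- tibble(site_key = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        gene = character(), transcript_id = character(),
                        cdna_hgvs = character(), consequence = character(),
                        in_dbsnp = logical(), in_hgmd = logical(),
                        known_pathogenic = logical(),
                        cohort_carrier_count = integer())
    empty_call <- tibble(sample_id = character(), site_key = character(),
                         genotype = character(), qual = double(),
                         depth = integer(), alt_fwd = integer(),
                         alt_rev = integer(), allele_fraction = double())
    return(list(variants = empty_var, calls = empty_call))
  }

  fmt <- v@gt[, "FORMAT"]
  fmt_fields <- strsplit(fmt[1], ":", fixed = TRUE)[[1]]
  for (needed in c("GT", "DP", "ADF", "ADR")) {
    if (!needed %in% fmt_fields) {
      stop("VCF FORMAT lacks mandatory field ", needed, " in ", vcf_path,
           call. = FALSE)
    }
  }
  samples <- colnames(v@gt)[-1]
  info <- vcfR::getINFO(v)
  gene <- as.character(vcfR::extract.info(v, element = "GENE"))
  transcript <- as.character(vcfR::extract.info(v, element = "TX"))
  chgvs <- as.character(vcfR::extract.info(v, element = "CHGVS"))
  csq <- as.character(vcfR::extract.info(v, element = "CSQ"))
  flag_of <- function(key) grepl(paste0("(^|;)", key, "(;|$)"), info)
  in_dbsnp <- flag_of("DBSNP")
  in_hgmd <- flag_of("HGMD")
  kpath <- flag_of("KPATH")

  gt_m <- vcfR::extract.gt(v, element = "GT")
  dp_m <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE))
  gq_m <- if ("GQ" %in% fmt_fields) {
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  } else NULL
  adf_m <- vcfR::extract.gt(v, element = "ADF")
  adr_m <- vcfR::extract.gt(v, element = "ADR")
  site_qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  var_rows <- list()
  call_rows <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    csq_i <- if (!is.na(csq[i])) strsplit(csq[i], ",", fixed = TRUE)[[1]] else
      rep("other", length(alts))
    chgvs_i <- if (!is.na(chgvs[i])) strsplit(chgvs[i], ",", fixed = TRUE)[[1]] else
      rep(NA_character_, length(alts))
    adf_i <- strsplit(adf_m[i, ], ",", fixed = TRUE)
    adr_i <- strsplit(adr_m[i, ], ",", fixed = TRUE)
    for (j in seq_along(alts)) {
      key <- make_site_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                           alts[j])
      n_alt <- vapply(gt_m[i, ], parse_gt_alt_count, integer(1),
                      alt_index = j)
      genotype <- ifelse(is.na(n_alt), "missing",
                         c("hom_ref", "het", "hom_alt")[n_alt + 1L])
      adf_j <- suppressWarnings(as.integer(vapply(adf_i, function(x) {
        if (length(x) >= j) x[j] else NA_character_
      }, character(1))))
      adr_j <- suppressWarnings(as.integer(vapply(adr_i, function(x) {
        if (length(x) >= j) x[j] else NA_character_
      }, character(1))))
      depth <- as.integer(dp_m[i, ])
      qual <- if (!is.null(gq_m)) as.numeric(gq_m[i, ]) else
        rep(site_qual[i], length(samples))
      af <- ifelse(!is.na(depth) & depth > 0, (adf_j + adr_j) / depth,
                   NA_real_)
      var_rows[[length(var_rows) + 1L]] <- tibble(
        site_key = key, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"], alt = alts[j],
        gene = gene[i], transcript_id = transcript[i],
        cdna_hgvs = chgvs_i[min(j, length(chgvs_i))],
        consequence = csq_i[min(j, length(csq_i))],
        in_dbsnp = in_dbsnp[i], in_hgmd = in_hgmd[i],
        known_pathogenic = kpath[i],
        cohort_carrier_count = sum(genotype %in% c("het", "hom_alt"))
      )
      call_rows[[length(call_rows) + 1L]] <- tibble(
        sample_id = samples, site_key = key, genotype = unname(genotype),
        qual = unname(qual), depth = unname(depth),
        alt_fwd = unname(adf_j), alt_rev = unname(adr_j),
        allele_fraction = unname(af)
      )
    }
  }
  list(variants = dplyr::bind_rows(var_rows),
       calls = dplyr::bind_rows(call_rows))
}

#' Cross-check pedigrees against a set of variant calls
#'
#' Report-only consistency validation of a loaded cohort: samples
#' present in the VCF but absent from every pedigree (orphans),
#' sequenced pedigree members absent from the VCF, and Mendelian
#' transmission impossibilities among sequenced parent-child pairs
#' (child carries an alt allele while both genotyped parents are
#' homozygous reference; child homozygous for an allele a genotyped
#' parent cannot have transmitted).
#'
#' @param pedigrees Named list of \code{pedigree} objects.
#' @param vcf_data List with \code{variants} and \code{calls} as
#'   returned by [read_variant_calls()].
#' @return A list of tibbles \code{orphan_samples},
#'   \code{missing_sequenced} and \code{mendelian}.
#' @export
validate_cohort <- function(pedigrees, vcf_data) {
  members <- dplyr::bind_rows(lapply(pedigrees, function(p) p$members))
  vcf_samples <- unique(vcf_data$calls$sample_id)
  orphans <- setdiff(vcf_samples, members$individual_id)
  seq_ids <- members$individual_id[members$is_sequenced]
  missing <- setdiff(seq_ids, vcf_samples)

  calls <- vcf_data$calls[vcf_data$calls$genotype != "missing", ]
  geno_of <- function(id, key) {
    g <- calls$genotype[calls$sample_id == id & calls$site_key == key]
    if (length(g)) g[1] else NA_character_
  }
  mend <- list()
  kids <- members[!is.na(members$father_id) &
                    members$individual_id %in% vcf_samples, ]
  for (k in seq_len(nrow(kids))) {
    child <- kids$individual_id[k]
    fa <- kids$father_id[k]
    mo <- kids$mother_id[k]
    child_keys <- unique(calls$site_key[calls$sample_id == child])
    for (key in child_keys) {
      gc <- geno_of(child, key)
      gf <- geno_of(fa, key)
      gm <- geno_of(mo, key)
      bad <- FALSE
      if (!is.na(gf) && !is.na(gm) &&
          gc %in% c("het", "hom_alt") &&
          gf == "hom_ref" && gm == "hom_ref") bad <- TRUE
      if (gc == "hom_alt" &&
          ((!is.na(gf) && gf == "hom_ref") ||
             (!is.na(gm) && gm == "hom_ref"))) bad <- TRUE
      if (gc == "hom_ref" &&
          ((!is.na(gf) && gf == "hom_alt") ||
             (!is.na(gm) && gm == "hom_alt"))) bad <- TRUE
      if (bad) {
        mend[[length(mend) + 1L]] <- tibble(
          family_id = kids$family_id[k], child = child, father = fa,
          mother = mo, site_key = key, child_genotype = gc,
          father_genotype = ifelse(is.na(gf), "untyped", gf),
          mother_genotype = ifelse(is.na(gm), "untyped", gm)
        )
      }
    }
  }
  list(
    orphan_samples = tibble(sample_id = orphans),
    missing_sequenced = tibble(individual_id = missing),
    mendelian = if (length(mend)) dplyr::bind_rows(mend) else
      tibble(family_id = character(), child = character(),
             father = character(), mother = character(),
             site_key = character(), child_genotype = character(),
             father_genotype = character(), mother_genotype = character())
  )
}

#' Assemble an analysis cohort from VCF, PED and phenotype files
#'
#' Convenience loader pairing [read_variant_calls()] with
#' [read_pedigree()] and building the sample-to-family index used by the
#' filtering cascade and prioritization.
#'
#' @param vcf_path,ped_path Paths to the VCF and PED files.
#' @param phenotype_path Optional phenotype sidecar TSV.
#' @return A list of class \code{famexome_cohort} with \code{variants},
#'   \code{calls}, \code{pedigrees}, and \code{samples} (tibble mapping
#'   \code{sample_id} to \code{family_id}).
#' @export
assemble_cohort <- function(vcf_path, ped_path, phenotype_path = NULL) {
  vcf_data <- read_variant_calls(vcf_path)
  pedigrees <- read_pedigree(ped_path, phenotype_path)
  members <- dplyr::bind_rows(lapply(pedigrees, function(p) p$members))
  samples <- tibble(sample_id = unique(vcf_data$calls$sample_id))
  samples$family_id <- members$family_id[match(samples$sample_id,
                                               members$individual_id)]
  structure(list(variants = vcf_data$variants, calls = vcf_data$calls,
                 pedigrees = pedigrees, samples = samples),
            class = "famexome_cohort")
}
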