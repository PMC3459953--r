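#' Candidate variants shared between sequenced relatives of one family
#'
#' For every unordered pair of sequenced relatives in a family, the
#' intersection of their candidate variant sites ("shared" means the
#' identical site, not merely the same gene), plus the intersection
#' across all sequenced members.
#'
#' @param candidates Candidate tibble from [run_cascade()] (any
#'   families; only rows of this pedigree's family are used).
#' @param pedigree A \code{pedigree} object with sequenced members
#'   flagged.
#' @return Tibble with \code{family_id}, \code{scope} (\code{"pair"} or
#'   \code{"all"}), \code{member_a}, \code{member_b} (\code{NA} for the
#'   all-member intersection), \code{site_key}, \code{gene}. Families
#'   with fewer than two sequenced members return an empty table with a
#'   \code{"notice"} attribute.
#' @export
pairwise_shared <- function(candidates, pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  empty <- tibble(family_id = character(), scope = character(),
                  member_a = character(), member_b = character(),
                  site_key = character(), gene = character())
  seq_ids <- sort(pedigree$members$individual_id[pedigree$members$is_sequenced])
  if (length(seq_ids) < 2L) {
    attr(empty, "notice") <- paste0("family ", pedigree$family_id,
                                    " has fewer than 2 sequenced members; skipped")
    return(empty)
  }
  cand <- candidates[candidates$sample_id %in% seq_ids, ]
  sites_of <- function(id) unique(cand$site_key[cand$sample_id == id])
  gene_of <- function(keys) cand$gene[match(keys, cand$site_key)]
  rows <- list(empty)
  pairs <- utils::combn(seq_ids, 2L, simplify = FALSE)
  for (p in pairs) {
    shared <- intersect(sites_of(p[1]), sites_of(p[2]))
    if (length(shared)) {
      rows[[length(rows) + 1L]] <- tibble(
        family_id = pedigree$family_id, scope = "pair",
        member_a = p[1], member_b = p[2], site_key = shared,
        gene = gene_of(shared)
      )
    }
  }
  all_shared <- Reduce(intersect, lapply(seq_ids, sites_of))
  if (length(all_shared)) {
    rows[[length(rows) + 1L]] <- tibble(
      family_id = pedigree$family_id, scope = "all",
      member_a = NA_character_, member_b = NA_character_,
      site_key = all_shared, gene = gene_of(all_shared)
    )
  }
  dplyr::bind_rows(rows)
}

#' Aggregate candidate variants into per-gene hits across the cohort
#'
#' Counts, for every gene with at least one candidate, the distinct
#' families and individuals hit, and how many families share the gene
#' across all their sequenced members (every sequenced member carries
#' at least one candidate in the gene). Genes hit in two or more
#' families are marked recurrent.
#'
#' @param candidates Candidate tibble from [run_cascade()].
#' @param cohort The \code{famexome_cohort} (needed for the sequenced
#'   member lists).
#' @param dna_repair_genes Genes flagged as DNA-repair for ranking
#'   priority.
#' @return Tibble with one row per gene: \code{gene},
#'   \code{n_families}, \code{families} (comma-joined ids),
#'   \code{n_individuals}, \code{n_shared_families},
#'   \code{dna_repair_flag}, \code{recurrent}.
#' @export
recurrent_genes <- function(candidates, cohort,
                            dna_repair_genes = default_dna_repair_genes()) {
  if (nrow(candidates) == 0L) {
    return(tibble(gene = character(), n_families = integer(),
                  families = character(), n_individuals = integer(),
                  n_shared_families = integer(), dna_repair_flag = logical(),
                  recurrent = logical()))
  }
  seq_by_family <- lapply(cohort$pedigrees, function(p) {
    p$members$individual_id[p$members$is_sequenced]
  })
  genes <- sort(unique(candidates$gene))
  rows <- lapply(genes, function(g) {
    hit <- candidates[candidates$gene == g, ]
    fams <- sort(unique(hit$family_id))
    shared <- vapply(fams, function(f) {
      seq_ids <- seq_by_family[[f]]
      length(seq_ids) >= 2L &&
        all(seq_ids %in% hit$sample_id[hit$family_id == f])
    }, logical(1))
    tibble(gene = g, n_families = length(fams),
           families = paste(fams, collapse = ","),
           n_individuals = length(unique(hit$sample_id)),
           n_shared_families = sum(shared),
           dna_repair_flag = g %in% dna_repair_genes,
           recurrent = length(fams) >= 2L)
  })
  dplyr::bind_rows(rows)
}

#' Rank gene hits by the prioritization policy
#'
#' Deterministic total order over gene hits. Sort key, in order:
#' number of families where the gene is shared by all sequenced members
#' (descending), number of families hit (descending), DNA-repair flag
#' (flagged first), number of individuals hit (descending), gene symbol
#' (ascending) as the final tie-break. The composite key encodes the
#' published priorities - variants shared by multiple affected
#' relatives, genes targeted in more than one family, and DNA-repair
#' involvement - as one reproducible ordering.
#'
#' @param gene_hits Tibble from [recurrent_genes()].
#' @return The same tibble ordered by priority with a \code{rank}
#'   column (1 = top candidate).
#' @export
rank_genes <- function(gene_hits) {
  if (nrow(gene_hits) == 0L) {
    gene_hits$rank <- integer(0)
    return(gene_hits)
  }
  ord <- order(-gene_hits$n_shared_families, -gene_hits$n_families,
               -gene_hits$dna_repair_flag, -gene_hits$n_individuals,
               gene_hits$gene, method = "radix")
  out <- gene_hits[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}
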