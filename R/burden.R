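#' Load a mutation-screening fixture table
#'
#' Reads a tab-separated table of qualifying variants observed in a
#' candidate-gene mutation screen, one row per carrier family or
#' control: \code{family_or_control_id}, \code{cohort} (one of
#' \code{full_screen_cases}, \code{hotspot_cases}, \code{controls}),
#' \code{gene}, \code{cdna_hgvs}, \code{consequence},
#' \code{known_pathogenic}, optional \code{note}. The packaged fixture
#' (\code{system.file("extdata", "screen_fixture.tsv", package =
#' "famexome")}) encodes the published screening observations for the
#' FANCC/BLM breast-cancer-family screen.
#'
#' @param path Path to the fixture TSV; defaults to the packaged
#'   fixture.
#' @return Tibble of screen records.
#' @export
load_screen_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "screen_fixture.tsv",
                        package = "famexome")
  }
  if (!file.exists(path)) {
    stop("screen fixture not found: ", path, call. = FALSE)
  }
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  req <- c("family_or_control_id", "cohort", "gene", "cdna_hgvs",
           "consequence", "known_pathogenic")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("screen fixture lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(x$cohort, c("full_screen_cases", "hotspot_cases",
                             "controls"))
  if (length(bad)) {
    stop("unknown cohort label(s) in fixture: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x$known_pathogenic <- as.logical(x$known_pathogenic)
  if (!"note" %in% names(x)) x$note <- NA_character_
  as_tibble(x)
}

qualifies <- function(records, rule) {
  switch(rule,
         truncating_only = records$consequence %in%
           c("stop_gained", "frameshift_coding"),
         overtly_deleterious = classify_overtly_deleterious(records),
         stop("unknown counting rule: ", rule, call. = FALSE))
}

#' Count carrier families per screening cohort
#'
#' Distinct families (or controls) carrying at least one qualifying
#' variant in a gene, per cohort and combined over case cohorts. Two
#' counting rules: \code{truncating_only} (nonsense and frameshift
#' variants) and \code{overtly_deleterious} (the four disruptive
#' classes plus registry-validated pathogenic alleles, admitting
#' functionally proven pathogenic missense).
#'
#' @param records Screen record tibble (see [load_screen_fixture()]).
#' @param gene Gene symbol.
#' @param rule \code{"truncating_only"} or \code{"overtly_deleterious"}.
#' @return Named integer vector: \code{full_screen_cases},
#'   \code{hotspot_cases}, \code{controls}, \code{combined_cases}.
#' @export
count_carrier_families <- function(records, gene,
                                   rule = c("overtly_deleterious",
                                            "truncating_only")) {
  rule <- match.arg(rule)
  hit <- records[records$gene == gene & qualifies(records, rule), ]
  if (!nrow(records[records$gene == gene, ])) {
    message("no screen records for gene ", gene)
  }
  count_in <- function(coh) {
    length(unique(hit$family_or_control_id[hit$cohort == coh]))
  }
  counts <- c(full_screen_cases = count_in("full_screen_cases"),
              hotspot_cases = count_in("hotspot_cases"),
              controls = count_in("controls"))
  c(counts, combined_cases = length(unique(
    hit$family_or_control_id[hit$cohort != "controls"])))
}

#' Exact carrier-burden comparison for a 2x2 case-control table
#'
#' One-sided Fisher exact test (hypergeometric tail; carriers enriched
#' in cases) and the cross-product odds ratio, with the
#' Haldane-Anscombe +0.5 continuity correction applied when any cell
#' of the table is zero.
#'
#' @param k1,n1 Carrier families and total families screened (cases).
#' @param k2,n2 Carrier controls and total controls.
#' @return One-row tibble: \code{carriers_cases}, \code{n_cases},
#'   \code{carriers_controls}, \code{n_controls}, \code{odds_ratio},
#'   \code{one_sided_p}.
#' @export
fisher_exact_burden <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0)
  if (n1 == 0 || n2 == 0) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  if (k1 > n1 || k2 > n2) {
    stop("carrier count exceeds cohort size", call. = FALSE)
  }
  tab <- matrix(c(k1, k2, n1 - k1, n2 - k2), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  odds_ratio <- if (any(tab == 0)) {
    ((k1 + 0.5) * (n2 - k2 + 0.5)) / ((n1 - k1 + 0.5) * (k2 + 0.5))
  } else {
    (k1 * (n2 - k2)) / ((n1 - k1) * k2)
  }
  tibble(carriers_cases = k1, n_cases = n1, carriers_controls = k2,
         n_controls = n2, odds_ratio = odds_ratio, one_sided_p = p)
}

#' Per-gene burden report for a mutation screen
#'
#' Combines carrier-family counting with the exact burden comparison
#' for each screened gene, and annotates every qualifying variant with
#' its parsed cDNA position and codon index. Cases are counted over the
#' full screen plus, for genes whose mutation-hotspot exons were
#' screened in the extension cohort, the hotspot cohort. Control
#' denominators may include external control series counted as
#' mutation-free (supplied via \code{control_totals}); external
#' population-database frequencies are deliberately not part of the
#' computation.
#'
#' @param records Screen record tibble.
#' @param genes Genes to report.
#' @param rule Counting rule (see [count_carrier_families()]).
#' @param n_full_screen,n_hotspot Case cohort sizes (families).
#' @param hotspot_genes Genes screened in the hotspot extension cohort.
#' @param control_totals Named vector of combined control denominators
#'   per gene; unnamed default used for genes not listed.
#' @return List with \code{burden} (one row per gene, see
#'   [fisher_exact_burden()]) and \code{variants} (annotated qualifying
#'   variants; codon index from [codon_of()] where the description
#'   parses to a coding position, with nomenclature notes carried
#'   through).
#' @export
screen_report <- function(records, genes = c("FANCC", "BLM"),
                          rule = "overtly_deleterious",
                          n_full_screen = 438, n_hotspot = 957,
                          hotspot_genes = "FANCC",
                          control_totals = c(FANCC = 2210, BLM = 1556)) {
  if (!nrow(records)) {
    return(list(burden = fisher_exact_burden(0, n_full_screen, 0, 464)[0, ],
                variants = records))
  }
  default_controls <- 464
  rows <- list()
  for (g in genes) {
    counts <- count_carrier_families(records, g, rule)
    n_cases <- n_full_screen + if (g %in% hotspot_genes) n_hotspot else 0
    n_ctl <- if (g %in% names(control_totals)) control_totals[[g]] else
      default_controls
    row <- fisher_exact_burden(counts[["combined_cases"]], n_cases,
                               counts[["controls"]], n_ctl)
    row <- dplyr::mutate(row, gene = g, .before = 1)
    rows[[length(rows) + 1L]] <- row
  }
  hit <- records[records$gene %in% genes & qualifies(records, rule), ]
  annotate <- function(h) {
    codons <- rep(NA_integer_, nrow(h))
    for (i in seq_len(nrow(h))) {
      parsed <- tryCatch(parse_cdna_hgvs(h$cdna_hgvs[i]),
                         error = function(e) NULL)
      if (!is.null(parsed) && !parsed$intronic) {
        codons[i] <- codon_of(parsed$start)
      }
    }
    h$codon_index <- codons
    h
  }
  list(burden = dplyr::bind_rows(rows), variants = annotate(hit))
}
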