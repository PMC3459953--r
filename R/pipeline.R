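#' Run configuration for the end-to-end pipeline
#'
#' Bundles paths, thresholds, gene lists, the penetrance model and the
#' seed for [run_pipeline()]. When \code{vcf}/\code{ped} paths are
#' \code{NULL} the pipeline simulates a cohort with
#' \code{simulation} instead.
#'
#' @param vcf,ped,phenotypes Optional input paths for a pre-existing
#'   cohort.
#' @param fixture Path to a screening fixture TSV (default: packaged).
#' @param out_dir Output directory for report TSVs.
#' @param thresholds A [filter_thresholds()].
#' @param known_genes,dna_repair_genes Gene lists.
#' @param penetrance A [penetrance_model()].
#' @param simulation A [simulation_config()] used when no VCF is given.
#' @param seed Integer seed governing all randomness.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(vcf = NULL, ped = NULL, phenotypes = NULL,
                       fixture = NULL, out_dir = tempfile("famexome_run_"),
                       thresholds = filter_thresholds(),
                       known_genes = default_known_genes(),
                       dna_repair_genes = default_dna_repair_genes(),
                       penetrance = penetrance_model(),
                       simulation = NULL, seed = 1L) {
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  simulation$seed <- as.integer(seed)
  structure(list(vcf = vcf, ped = ped, phenotypes = phenotypes,
                 fixture = fixture, out_dir = out_dir,
                 thresholds = thresholds, known_genes = known_genes,
                 dna_repair_genes = dna_repair_genes,
                 penetrance = penetrance, simulation = simulation,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML document whose top-level keys mirror the arguments of
#' [run_config()] (\code{thresholds}, \code{penetrance} and
#' \code{simulation} given as key-value maps).
#'
#' @param path Path to the YAML file.
#' @return A \code{run_config}.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("vcf", "ped", "phenotypes", "fixture", "out_dir", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(filter_thresholds, y$thresholds)
  }
  if (!is.null(y$penetrance)) {
    args$penetrance <- do.call(penetrance_model, y$penetrance)
  }
  if (!is.null(y$simulation)) {
    args$simulation <- do.call(simulation_config, y$simulation)
  }
  if (!is.null(y$known_genes)) args$known_genes <- y$known_genes
  if (!is.null(y$dna_repair_genes)) args$dna_repair_genes <- y$dna_repair_genes
  do.call(run_config, args)
}

report_header <- function(config) {
  th <- config$thresholds
  c(sprintf("# famexome %s", as.character(packageVersion("famexome"))),
    sprintf("# seed=%d", config$seed),
    sprintf(paste0("# min_qual=%g min_depth=%g min_allele_fraction=%g ",
                   "max_cohort_carriers=%g cohort_size=%g ",
                   "require_bidirectional=%s"),
            th$min_qual, th$min_depth, th$min_allele_fraction,
            th$max_cohort_carriers, th$cohort_size,
            th$require_bidirectional))
}

write_report <- function(df, path, config) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.6g", x))
  })
  writeLines(report_header(config), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

stage_log <- function(stage, t0) {
  message(sprintf("[famexome] %-10s %.2fs", stage,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full discovery pipeline
#'
#' End-to-end orchestration: obtain a cohort (simulate and emit one
#' when no VCF path is configured, otherwise load the configured
#' files), run the filtering cascade, prioritize genes across
#' families, score co-segregation of the top-ranked gene's candidate
#' sites in each carrier family, and compute the screening burden
#' report from the fixture. All randomness flows from the configured
#' seed; rerunning with the same seed reproduces every output file
#' byte for byte. Each output TSV carries a header recording tool
#' version, seed and thresholds. Progress is logged to stderr; stdout
#' is never written to.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results
#'   (\code{cohort}, \code{cascade}, \code{ranking}, \code{shared},
#'   \code{segregation}, \code{screen}) and \code{paths} of the report
#'   files.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(proc.time()["elapsed"])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$vcf)) {
    paths <- emit_cohort(config$simulation, file.path(config$out_dir,
                                                      "cohort"))
    cohort <- assemble_cohort(paths$vcf_path, paths$ped_path,
                              paths$phenotype_path)
    stage_log("simulate", t0)
  } else {
    for (p in c(config$vcf, config$ped)) {
      if (!file.exists(p)) {
        stop("input file not found: ", p, call. = FALSE)
      }
    }
    cohort <- assemble_cohort(config$vcf, config$ped, config$phenotypes)
    stage_log("load", t0)
  }

  cascade <- run_cascade(cohort, config$thresholds, config$known_genes)
  stage_log("filter", t0)

  hits <- recurrent_genes(cascade$candidates, cohort,
                          config$dna_repair_genes)
  ranking <- rank_genes(hits)
  shared <- dplyr::bind_rows(lapply(cohort$pedigrees, function(p) {
    pairwise_shared(cascade$candidates, p)
  }))
  stage_log("prioritize", t0)

  seg_rows <- list()
  if (nrow(ranking)) {
    top_gene <- ranking$gene[1]
    top_cand <- cascade$candidates[cascade$candidates$gene == top_gene, ]
    for (fam in unique(top_cand$family_id)) {
      fam_sites <- top_cand$site_key[top_cand$family_id == fam]
      site <- names(sort(table(fam_sites), decreasing = TRUE))[1]
      res <- cosegregate_family(cohort, fam, site, config$penetrance)
      if (!is.null(res)) {
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          family_id = res$family_id, gene = top_gene,
          site_key = res$site_key,
          log_bayes_factor = res$log_bayes_factor,
          bayes_factor = res$bayes_factor,
          n_genotyped_relatives = res$n_genotyped_relatives,
          proband_id = res$proband_id
        )
      }
    }
  }
  segregation <- dplyr::bind_rows(seg_rows)
  stage_log("coseg", t0)

  fixture <- load_screen_fixture(config$fixture)
  screen <- screen_report(fixture)
  stage_log("burden", t0)

  out <- list(
    candidates = cascade$candidates, trace = cascade$trace,
    precheck = cascade$precheck, gene_ranking = ranking,
    shared_variants = shared, cosegregation = segregation,
    burden = screen$burden, screen_variants = screen$variants
  )
  paths <- list()
  for (name in names(out)) {
    paths[[name]] <- write_report(out[[name]],
                                  file.path(config$out_dir,
                                            paste0(name, ".tsv")),
                                  config)
  }
  stage_log("write", t0)
  invisible(list(cohort = cohort, cascade = cascade, ranking = ranking,
                 shared = shared, segregation = segregation,
                 screen = screen, paths = paths))
}
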