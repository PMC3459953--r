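#' Two-point penetrance model for a dominant risk allele
#'
#' Carrier / non-carrier lifetime disease risks plus the population
#' frequency of the risk allele. Heterozygous and homozygous carriers
#' share one risk (dominant two-point model); optional male entries
#' allow sex-specific risks for diseases, such as breast cancer, where
#' male incidence is far lower.
#'
#' @param f_carrier Disease probability for female carriers.
#' @param f_noncarrier Disease probability for female non-carriers
#'   (the phenocopy rate).
#' @param q Population frequency of the risk allele, in (0, 0.5).
#' @param f_carrier_male,f_noncarrier_male Male risks; defaults reflect
#'   rare male disease.
#' @return A list of class \code{penetrance_model}.
#' @export
penetrance_model <- function(f_carrier = 0.30, f_noncarrier = 0.10,
                             q = 0.003, f_carrier_male = 0.06,
                             f_noncarrier_male = 0.001) {
  stopifnot(f_noncarrier >= 0, f_carrier <= 1, f_noncarrier <= f_carrier,
            f_noncarrier_male >= 0, f_carrier_male <= 1,
            f_noncarrier_male <= f_carrier_male)
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)", call. = FALSE)
  structure(list(f_carrier = f_carrier, f_noncarrier = f_noncarrier, q = q,
                 f_carrier_male = f_carrier_male,
                 f_noncarrier_male = f_noncarrier_male),
            class = "penetrance_model")
}

penetrance_of <- function(model, sex, carrier) {
  f_c <- ifelse(sex == "male", model$f_carrier_male, model$f_carrier)
  f_n <- ifelse(sex == "male", model$f_noncarrier_male, model$f_noncarrier)
  ifelse(carrier, f_c, f_n)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles the parameters of the multi-family discovery-cohort
#' simulator. Defaults mirror the study design the analysis assumes:
#' 15 high-risk families ascertained for at least four cancer cases,
#' 33 sequenced exomes (twelve families contribute two affected
#' relatives and three contribute three), a private truncating causal
#' variant in a DNA-repair gene segregating in two families under
#' moderate penetrance, rare deleterious background variants entering
#' through founders, cohort-common polymorphisms carried by well over
#' ten of the 33 exomes, mean target depth near 80x, and a small
#' fraction of true calls violating each confidence threshold.
#'
#' @param n_families Number of discovery families.
#' @param pedigree_depth Generations per pedigree.
#' @param sibship_size_mean Mean children per couple (Poisson).
#' @param marry_prob Probability a non-terminal-generation child founds
#'   a sibship with a married-in founder spouse.
#' @param min_affected Ascertainment: minimum affected members.
#' @param n_sequenced Integer vector (recycled over families) of
#'   affected relatives sequenced per family.
#' @param causal_gene Symbol of the injected causal gene.
#' @param n_causal_families Families carrying a private causal variant.
#' @param penetrance A [penetrance_model()].
#' @param phenocopy_rate Optional override of the female non-carrier
#'   disease risk used when sampling affection.
#' @param n_background_genes,background_rate Background gene count and
#'   per-family, per-gene probability that a founder carries a private
#'   rare variant in that gene.
#' @param n_common_sites,common_af_range Cohort-common polymorphic
#'   sites and the range their population allele frequency is drawn
#'   from.
#' @param depth_mean,depth_sd,qual_mean,qual_sd Read depth and call
#'   quality (phred) distributions.
#' @param het_af_beta Beta shape parameters for the heterozygous
#'   variant allele fraction.
#' @param fail_qual_rate,fail_depth_rate,fail_af_rate,fail_strand_rate
#'   Fractions of true variant calls degraded below the corresponding
#'   confidence threshold.
#' @param seed Integer seed; a fixed seed makes generator output
#'   byte-identical.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_families = 15, pedigree_depth = 3,
                              sibship_size_mean = 4, marry_prob = 0.9,
                              min_affected = 4,
                              n_sequenced = c(rep(2L, 12), rep(3L, 3)),
                              causal_gene = "FANCC",
                              n_causal_families = 2,
                              penetrance = penetrance_model(),
                              phenocopy_rate = NULL,
                              n_background_genes = 60,
                              background_rate = 0.08,
                              n_common_sites = 25,
                              common_af_range = c(0.2, 0.6),
                              depth_mean = 80, depth_sd = 25,
                              qual_mean = 60, qual_sd = 15,
                              het_af_beta = c(20, 20),
                              fail_qual_rate = 0.05,
                              fail_depth_rate = 0.05,
                              fail_af_rate = 0.05,
                              fail_strand_rate = 0.02,
                              seed = 1L) {
  probs <- c(marry_prob, background_rate, fail_qual_rate, fail_depth_rate,
             fail_af_rate, fail_strand_rate, common_af_range)
  stopifnot(all(probs >= 0), all(probs <= 1), n_families >= 1,
            pedigree_depth >= 2, sibship_size_mean > 0,
            n_causal_families <= n_families,
            inherits(penetrance, "penetrance_model"))
  if (!is.null(phenocopy_rate)) {
    stopifnot(phenocopy_rate >= 0, phenocopy_rate <= penetrance$f_carrier)
  }
  structure(list(
    n_families = as.integer(n_families),
    pedigree_depth = as.integer(pedigree_depth),
    sibship_size_mean = sibship_size_mean, marry_prob = marry_prob,
    min_affected = as.integer(min_affected),
    n_sequenced = as.integer(n_sequenced),
    causal_gene = causal_gene,
    n_causal_families = as.integer(n_causal_families),
    penetrance = penetrance, phenocopy_rate = phenocopy_rate,
    n_background_genes = as.integer(n_background_genes),
    background_rate = background_rate,
    n_common_sites = as.integer(n_common_sites),
    common_af_range = common_af_range,
    depth_mean = depth_mean, depth_sd = depth_sd,
    qual_mean = qual_mean, qual_sd = qual_sd, het_af_beta = het_af_beta,
    fail_qual_rate = fail_qual_rate, fail_depth_rate = fail_depth_rate,
    fail_af_rate = fail_af_rate, fail_strand_rate = fail_strand_rate,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

effective_model <- function(config) {
  model <- config$penetrance
  if (!is.null(config$phenocopy_rate)) {
    model$f_noncarrier <- config$phenocopy_rate
  }
  model
}

# multi-generational family structure; parents always precede children.
# Plain vectors with integer parent indices for speed in rejection loops.
simulate_pedigree_structure <- function(config, family_id) {
  cap <- 256L
  father <- mother <- integer(cap)
  sex <- character(cap)
  n <- 0L
  add <- function(fa, mo, sx) {
    n <<- n + 1L
    father[n] <<- fa; mother[n] <<- mo; sex[n] <<- sx
    n
  }
  f1 <- add(NA_integer_, NA_integer_, "male")
  f2 <- add(NA_integer_, NA_integer_, "female")
  couples <- list(c(f1, f2))
  for (gen in seq_len(config$pedigree_depth - 1L)) {
    next_couples <- list()
    for (cp in couples) {
      n_kids <- rpois(1, config$sibship_size_mean)
      if (gen == 1L) n_kids <- max(n_kids, 2L)  # founding couple reproduces
      for (k in seq_len(n_kids)) {
        sx <- if (runif(1) < 0.5) "male" else "female"
        kid <- add(cp[1], cp[2], sx)
        if (gen + 1L < config$pedigree_depth &&
            runif(1) < config$marry_prob) {
          spouse <- add(NA_integer_, NA_integer_,
                        if (sx == "male") "female" else "male")
          next_couples[[length(next_couples) + 1L]] <-
            if (sx == "male") c(kid, spouse) else c(spouse, kid)
        }
      }
    }
    couples <- next_couples
  }
  ids <- sprintf("%s_%02d", family_id, seq_len(n))
  list(family_id = family_id, ids = ids,
       father_idx = father[seq_len(n)], mother_idx = mother[seq_len(n)],
       sex = sex[seq_len(n)], n = n)
}

# Mendelian drop of a biallelic genotype (0/1/2 alt copies) over integer
# parent indices; founders draw from Hardy-Weinberg at frequency `freq`
drop_biallelic_idx <- function(father_idx, mother_idx, freq) {
  n <- length(father_idx)
  g <- integer(n)
  for (i in seq_len(n)) {
    g[i] <- if (is.na(father_idx[i])) {
      rbinom(1L, 2L, freq)
    } else {
      rbinom(1L, 1L, g[father_idx[i]] / 2) +
        rbinom(1L, 1L, g[mother_idx[i]] / 2)
    }
  }
  g
}

# gene-drop of carrier status over integer parent indices (parents first);
# homozygous draws in carrier-x-carrier matings redrawn as per the
# rare-allele model
drop_carriers_idx <- function(father_idx, mother_idx, q, forced_idx = NULL) {
  n <- length(father_idx)
  carrier <- logical(n)
  prior <- 2 * q * (1 - q)
  u <- runif(n)
  for (i in seq_len(n)) {
    if (is.na(father_idx[i])) {
      carrier[i] <- if (!is.null(forced_idx) && i == forced_idx) TRUE else
        u[i] < prior
    } else {
      fa <- carrier[father_idx[i]]
      mo <- carrier[mother_idx[i]]
      if (!fa && !mo) {
        carrier[i] <- FALSE
      } else if (xor(fa, mo)) {
        carrier[i] <- u[i] < 0.5
      } else {
        repeat {
          alt <- rbinom(1L, 1L, 0.5) + rbinom(1L, 1L, 0.5)
          if (alt < 2L) break
        }
        carrier[i] <- alt == 1L
      }
    }
  }
  carrier
}

#' Drop a rare allele through a pedigree and sample affection
#'
#' Gene dropping under the generator's model: founders are carriers
#' with probability \eqn{2q(1-q)} (the Hardy-Weinberg heterozygote
#' frequency; homozygous carriers are excluded as negligible for a rare
#' allele, and a homozygous draw in a carrier-by-carrier mating is
#' redrawn), transmission is Mendelian (each carrier parent transmits
#' the allele with probability 1/2), and affection is then sampled from
#' the penetrance given carrier status and sex, so phenocopies arise
#' through the non-carrier risk.
#'
#' @param pedigree A \code{pedigree} object (members must be ordered
#'   parents-before-children, as produced by the generator; other
#'   orders are topologically sorted first).
#' @param model A [penetrance_model()].
#' @param forced_carrier Optional id of a founder forced to carry the
#'   allele (used to inject a causal variant into a family).
#' @return Tibble with \code{individual_id}, logical \code{carrier} and
#'   logical \code{affected}.
#' @export
drop_genotypes <- function(pedigree, model, forced_carrier = NULL) {
  stopifnot(inherits(pedigree, "pedigree"),
            inherits(model, "penetrance_model"))
  m <- pedigree$members
  ids <- m$individual_id
  # topological order (parents first)
  placed <- logical(nrow(m))
  out_order <- integer(0)
  while (length(out_order) < nrow(m)) {
    ready <- !placed &
      (is.na(m$father_id) | (m$father_id %in% ids[placed])) &
      (is.na(m$mother_id) | (m$mother_id %in% ids[placed]))
    if (!any(ready)) stop("pedigree is not acyclic", call. = FALSE)
    out_order <- c(out_order, which(ready))
    placed[ready] <- TRUE
  }
  ids_ord <- ids[out_order]
  father_idx <- match(m$father_id[out_order], ids_ord)
  mother_idx <- match(m$mother_id[out_order], ids_ord)
  forced_idx <- if (is.null(forced_carrier)) NULL else
    match(forced_carrier, ids_ord)
  carrier_ord <- drop_carriers_idx(father_idx, mother_idx, model$q,
                                   forced_idx)
  carrier <- carrier_ord[match(ids, ids_ord)]
  pen <- penetrance_of(model, m$sex, carrier)
  affected <- runif(nrow(m)) < pen
  tibble(individual_id = ids, carrier = carrier, affected = affected)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  mean <- rep(mean, length.out = n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean[i], sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  round(out)
}

#' Simulate one ascertained multiplex family
#'
#' Draws pedigree structures and gene-dropped genotypes until the
#' family meets ascertainment: at least \code{min_affected} affected
#' members and at least two affected members available for sequencing.
#' For a causal family, a founding-generation founder is forced to
#' carry the family's private causal allele and at least two of the
#' sequenced members must be carriers (the cohort emulates families in
#' which the familial cluster is attributable to the injected allele).
#' Affected members receive an age at diagnosis (truncated normal on
#' [25, 80]; carriers earlier on average than phenocopies, reflecting
#' earlier onset of genetically driven disease), unaffected members a
#' censoring age. The \code{n_sequenced} earliest-diagnosed affected
#' members are flagged sequenced, ties broken by individual id, and the
#' earliest is the index case.
#'
#' @param config A [simulation_config()].
#' @param family_id Family identifier.
#' @param causal Does this family segregate the causal allele?
#' @param n_sequenced Number of affected members to sequence (2-3).
#' @return List with \code{pedigree} (affection, ages and flags filled
#'   in) and \code{genotypes} (the [drop_genotypes()] tibble).
#' @export
simulate_pedigree <- function(config, family_id = "FAM01", causal = TRUE,
                              n_sequenced = 2L) {
  stopifnot(inherits(config, "simulation_config"))
  model <- effective_model(config)
  repeat {
    st <- simulate_pedigree_structure(config, family_id)
    forced_idx <- if (causal) 1L else NULL
    carrier <- drop_carriers_idx(st$father_idx, st$mother_idx, model$q,
                                 forced_idx)
    pen <- penetrance_of(model, st$sex, carrier)
    affected <- runif(st$n) < pen
    if (sum(affected) < max(config$min_affected, 2L)) next

    age <- numeric(st$n)
    age[affected] <- rtrunc_norm(sum(affected),
                                 mean = ifelse(carrier[affected], 45, 58),
                                 sd = 10, lower = 25, upper = 80)
    age[!affected] <- round(runif(sum(!affected), 40, 75))

    aff_idx <- which(affected)
    aff_idx <- aff_idx[order(age[aff_idx], st$ids[aff_idx])]
    n_seq <- min(n_sequenced, length(aff_idx))
    seq_idx <- aff_idx[seq_len(n_seq)]
    if (causal && sum(carrier[seq_idx]) < 2L) next

    members <- tibble(
      individual_id = st$ids, family_id = family_id,
      father_id = ifelse(is.na(st$father_idx), NA_character_,
                         st$ids[st$father_idx]),
      mother_id = ifelse(is.na(st$mother_idx), NA_character_,
                         st$ids[st$mother_idx]),
      sex = st$sex,
      affection = ifelse(affected, "affected", "unaffected"),
      cancer_type = ifelse(affected, "breast", NA_character_),
      age_dx_or_censor = age,
      is_sequenced = seq_len(st$n) %in% seq_idx,
      is_index = seq_len(st$n) == seq_idx[1]
    )
    g <- tibble(individual_id = st$ids, carrier = carrier,
                affected = affected)
    return(list(pedigree = new_pedigree(members), genotypes = g,
                structure = st))
  }
}

# simulate one call per sample for a variant; genotype in 0/1/2 alt copies
simulate_calls <- function(config, site_key, genotypes_n_alt, sample_ids) {
  n <- length(sample_ids)
  depth <- pmax(1L, round(rnorm(n, config$depth_mean, config$depth_sd)))
  qual <- pmin(99, pmax(1, round(rnorm(n, config$qual_mean, config$qual_sd))))
  af_true <- ifelse(genotypes_n_alt == 0L, 0.002,
                    ifelse(genotypes_n_alt == 1L,
                           rbeta(n, config$het_af_beta[1],
                                 config$het_af_beta[2]),
                           0.98))
  is_var <- genotypes_n_alt > 0L
  # degrade a configurable fraction of true variant calls per threshold
  fq <- is_var & runif(n) < config$fail_qual_rate
  qual[fq] <- sample(5:29, sum(fq), replace = TRUE)
  fd <- is_var & runif(n) < config$fail_depth_rate
  depth[fd] <- sample(1:9, sum(fd), replace = TRUE)
  alt <- rbinom(n, depth, af_true)
  fa <- is_var & runif(n) < config$fail_af_rate
  alt[fa] <- pmax(0L, round(depth[fa] * runif(sum(fa), 0.02, 0.14)))
  alt <- pmin(alt, depth)
  alt_fwd <- rbinom(n, alt, 0.5)
  fs <- is_var & runif(n) < config$fail_strand_rate
  alt_fwd[fs] <- ifelse(runif(sum(fs)) < 0.5, 0L, alt[fs])
  tibble(
    sample_id = sample_ids, site_key = site_key,
    genotype = c("hom_ref", "het", "hom_alt")[genotypes_n_alt + 1L],
    qual = as.numeric(qual), depth = as.integer(depth),
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt - alt_fwd),
    allele_fraction = alt / depth
  )
}

#' Simulate a complete discovery cohort in memory
#'
#' Generates the full multi-family cohort the filtering and
#' prioritization stages consume: ascertained pedigrees, private causal
#' truncating variants in the configured causal gene for the causal
#' families, rare deleterious background variants entering through
#' founders and descending by Mendelian transmission, cohort-common
#' polymorphic sites (dbSNP-flagged, genotypes drawn under
#' Hardy-Weinberg), and per-call depth/quality/allele-fraction/strand
#' observations for every sequenced sample. Only variants observed in
#' at least one sequenced exome enter the call set, emulating what an
#' exome VCF of the sequenced individuals would contain.
#'
#' @param config A [simulation_config()]. The configured seed fixes all
#'   randomness.
#' @return A list of class \code{famexome_cohort} with \code{variants},
#'   \code{calls}, \code{pedigrees}, \code{samples}, \code{truth} (the
#'   injected-site table; never consumed by analysis functions) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  model <- effective_model(config)
  n_seq_vec <- rep(config$n_sequenced, length.out = config$n_families)

  fams <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    fams[[i]] <- simulate_pedigree(
      config, family_id = sprintf("FAM%02d", i),
      causal = i <= config$n_causal_families,
      n_sequenced = n_seq_vec[i]
    )
  }
  pedigrees <- lapply(fams, function(f) f$pedigree)
  names(pedigrees) <- vapply(pedigrees, function(p) p$family_id, character(1))
  members <- dplyr::bind_rows(lapply(pedigrees, function(p) p$members))
  samples <- members[members$is_sequenced, c("individual_id", "family_id")]
  names(samples)[1] <- "sample_id"
  samples <- as_tibble(samples)
  sample_ids <- samples$sample_id

  var_rows <- list()
  call_rows <- list()
  truth_rows <- list()
  csq_pool_bg <- c("missense", "synonymous", "stop_gained",
                   "frameshift_coding", "essential_splice_site", "other")
  csq_prob_bg <- c(0.45, 0.20, 0.12, 0.10, 0.05, 0.08)

  add_variant <- function(chrom, pos, ref, alt, gene, csq, cdna,
                          in_dbsnp, in_hgmd, kpath, n_alt_by_sample,
                          class, family_id = NA_character_) {
    key <- make_site_key(chrom, pos, ref, alt)
    carriers <- sample_ids[n_alt_by_sample > 0L]
    var_rows[[length(var_rows) + 1L]] <<- tibble(
      site_key = key, chrom = chrom, pos = as.integer(pos), ref = ref,
      alt = alt, gene = gene, transcript_id = NA_character_,
      cdna_hgvs = cdna, consequence = csq, in_dbsnp = in_dbsnp,
      in_hgmd = in_hgmd, known_pathogenic = kpath,
      cohort_carrier_count = length(carriers)
    )
    call_rows[[length(call_rows) + 1L]] <<-
      simulate_calls(config, key, n_alt_by_sample, sample_ids)
    n_carriers <- length(carriers)
    truth_rows[[length(truth_rows) + 1L]] <<- tibble(
      site_key = key, gene = gene, class = class, family_id = family_id,
      carriers = paste(carriers, collapse = ";"),
      n_carriers_sequenced = n_carriers
    )
  }

  # private causal truncating variants, one per causal family
  for (i in seq_len(config$n_causal_families)) {
    fam <- fams[[i]]
    fam_id <- fam$pedigree$family_id
    carrier_ids <- fam$genotypes$individual_id[fam$genotypes$carrier]
    n_alt <- as.integer(sample_ids %in% carrier_ids)
    cpos <- sample(150:1500, 1)
    truncating <- sample(c("stop_gained", "frameshift_coding"), 1)
    if (truncating == "stop_gained") {
      ref <- "C"; alt <- "T"; cdna <- sprintf("c.%dC>T", cpos)
    } else {
      ref <- "CA"; alt <- "C"; cdna <- sprintf("c.%ddelA", cpos)
    }
    add_variant(chrom = "9", pos = 37000000L + i * 211L, ref = ref,
                alt = alt, gene = config$causal_gene, csq = truncating,
                cdna = cdna, in_dbsnp = FALSE, in_hgmd = FALSE,
                kpath = FALSE, n_alt_by_sample = n_alt, class = "causal",
                family_id = fam_id)
  }

  # rare background variants: founder carriers, Mendelian descent
  for (i in seq_len(config$n_families)) {
    fam <- fams[[i]]
    ped <- fam$pedigree
    fam_id <- ped$family_id
    fam_seq <- ped$members$individual_id[ped$members$is_sequenced]
    hit_genes <- which(runif(config$n_background_genes) <
                         config$background_rate)
    st <- fam$structure
    founder_idx <- which(is.na(st$father_idx))
    for (gidx in hit_genes) {
      forced <- founder_idx[sample.int(length(founder_idx), 1)]
      # drop with q ~ 0 so only the forced founder introduces the allele
      g <- drop_carriers_idx(st$father_idx, st$mother_idx, 1e-9,
                             forced_idx = forced)
      carrier_ids <- intersect(st$ids[g], fam_seq)
      if (!length(carrier_ids)) next
      csq <- sample(csq_pool_bg, 1, prob = csq_prob_bg)
      in_db <- runif(1) < 0.30
      in_hg <- in_db && runif(1) < 0.10
      n_alt <- as.integer(sample_ids %in% carrier_ids)
      add_variant(chrom = as.character((gidx %% 22L) + 1L),
                  pos = 1000000L * gidx + i * 37L, ref = "G", alt = "A",
                  gene = sprintf("BG%03d", gidx), csq = csq,
                  cdna = NA_character_, in_dbsnp = in_db, in_hgmd = in_hg,
                  kpath = FALSE, n_alt_by_sample = n_alt,
                  class = "background", family_id = fam_id)
    }
  }

  # cohort-common polymorphisms: founders draw Hardy-Weinberg genotypes,
  # descendants inherit Mendelianly so within-family calls stay consistent
  csq_pool_cm <- c("missense", "synonymous", "stop_gained", "other")
  csq_prob_cm <- c(0.45, 0.40, 0.08, 0.07)
  for (j in seq_len(config$n_common_sites)) {
    f <- runif(1, config$common_af_range[1], config$common_af_range[2])
    n_alt <- integer(length(sample_ids))
    for (i in seq_len(config$n_families)) {
      st <- fams[[i]]$structure
      g <- drop_biallelic_idx(st$father_idx, st$mother_idx, f)
      hit <- match(st$ids, sample_ids)
      keep <- !is.na(hit)
      n_alt[hit[keep]] <- g[keep]
    }
    if (all(n_alt == 0L)) next
    add_variant(chrom = as.character((j %% 22L) + 1L),
                pos = 50000000L + j * 997L, ref = "T", alt = "C",
                gene = sprintf("CMN%02d", j),
                csq = sample(csq_pool_cm, 1, prob = csq_prob_cm),
                cdna = NA_character_, in_dbsnp = TRUE, in_hgmd = FALSE,
                kpath = FALSE, n_alt_by_sample = n_alt, class = "common")
  }

  structure(list(
    variants = dplyr::bind_rows(var_rows),
    calls = dplyr::bind_rows(call_rows),
    pedigrees = pedigrees, samples = samples,
    truth = dplyr::bind_rows(truth_rows), config = config
  ), class = "famexome_cohort")
}

chrom_order <- function(chrom) {
  suppressWarnings(n <- as.numeric(chrom))
  ifelse(is.na(n), 100 + as.numeric(factor(chrom)), n)
}

write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  ord <- order(chrom_order(v$chrom), v$pos, v$alt)
  v <- v[ord, ]
  calls <- cohort$calls
  sample_ids <- cohort$samples$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famexome_synthetic_cohort",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TX,Number=1,Type=String,Description=\"Transcript id\">",
    "##INFO=<ID=CHGVS,Number=A,Type=String,Description=\"HGVS cDNA description\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Predicted consequence class\">",
    "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"Present in dbSNP\">",
    "##INFO=<ID=HGMD,Number=0,Type=Flag,Description=\"Reported in HGMD\">",
    "##INFO=<ID=KPATH,Number=0,Type=Flag,Description=\"Registry-validated pathogenic\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=ADF,Number=A,Type=Integer,Description=\"Alt-supporting reads, forward strand\">",
    "##FORMAT=<ID=ADR,Number=A,Type=Integer,Description=\"Alt-supporting reads, reverse strand\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    key <- v$site_key[i]
    cc <- calls[calls$site_key == key, ]
    cc <- cc[match(sample_ids, cc$sample_id), ]
    info <- paste0("GENE=", v$gene[i])
    if (!is.na(v$transcript_id[i])) info <- paste0(info, ";TX=", v$transcript_id[i])
    if (!is.na(v$cdna_hgvs[i])) info <- paste0(info, ";CHGVS=", v$cdna_hgvs[i])
    info <- paste0(info, ";CSQ=", v$consequence[i])
    if (v$in_dbsnp[i]) info <- paste0(info, ";DBSNP")
    if (v$in_hgmd[i]) info <- paste0(info, ";HGMD")
    if (v$known_pathogenic[i]) info <- paste0(info, ";KPATH")
    sample_fields <- paste(gt_code[cc$genotype],
                           ifelse(is.na(cc$qual), ".", cc$qual),
                           cc$depth, cc$alt_fwd, cc$alt_rev, sep = ":")
    lines[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
                        ".", "PASS", info, "GT:GQ:DP:ADF:ADR",
                        sample_fields), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

write_truth <- function(cohort, path) {
  write.table(cohort$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Emit a synthetic discovery cohort as VCF, PED, phenotype and truth files
#'
#' Runs [simulate_cohort()] and writes its output in the formats the
#' analysis entry points read: a multi-sample VCF 4.2 (sequenced
#' individuals only; INFO GENE/CHGVS/CSQ plus DBSNP/HGMD/KPATH flags,
#' FORMAT GT:GQ:DP:ADF:ADR), a 6-column PED, a phenotype sidecar TSV
#' and a truth TSV recording every injected site (the truth file exists
#' for validation only and is never read by analysis functions).
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with \code{vcf_path}, \code{ped_path},
#'   \code{phenotype_path}, \code{truth_path}; the in-memory cohort is
#'   attached as attribute \code{"cohort"}.
#' @export
emit_cohort <- function(config = simulation_config(), out_dir = tempdir()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  paths <- list(
    vcf_path = file.path(out_dir, "cohort.vcf"),
    ped_path = file.path(out_dir, "cohort.ped"),
    phenotype_path = file.path(out_dir, "cohort_phenotypes.tsv"),
    truth_path = file.path(out_dir, "cohort_truth.tsv")
  )
  write_cohort_vcf(cohort, paths$vcf_path)
  write_pedigree(cohort$pedigrees, paths$ped_path, paths$phenotype_path)
  write_truth(cohort, paths$truth_path)
  attr(paths, "cohort") <- cohort
  paths
}

#' Simulate case/control carrier tables for a mutation screen
#'
#' Generates per-family and per-control carrier indicators for the
#' candidate-gene screening comparison, each a Bernoulli draw at the
#' configured carrier rate. Default cohort sizes follow the screening
#' design the burden analysis targets (438 case families, 464 healthy
#' controls).
#'
#' @param n_case_families,n_controls Cohort sizes.
#' @param carrier_rate_cases,carrier_rate_controls Carrier
#'   probabilities in [0, 1].
#' @param seed Integer seed.
#' @return List of tibbles \code{cases} (\code{family_id},
#'   \code{carrier}) and \code{controls} (\code{control_id},
#'   \code{carrier}).
#' @export
emit_screen_cohorts <- function(n_case_families = 438, n_controls = 464,
                                carrier_rate_cases = 0.005,
                                carrier_rate_controls = 0,
                                seed = 1L) {
  stopifnot(carrier_rate_cases >= 0, carrier_rate_cases <= 1,
            carrier_rate_controls >= 0, carrier_rate_controls <= 1)
  set.seed(seed)
  list(
    cases = tibble(
      family_id = sprintf("SCR%04d", seq_len(n_case_families)),
      carrier = runif(n_case_families) < carrier_rate_cases
    ),
    controls = tibble(
      control_id = sprintf("CTL%04d", seq_len(n_controls)),
      carrier = runif(n_controls) < carrier_rate_controls
    )
  )
}
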