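# Genotype state space: number of risk alleles, 0/1/2.
# Factors are arrays with one dimension (extent 3) per individual.

founder_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# T[child, father, mother]: Mendelian transmission for a biallelic locus
transmission_array <- function() {
  p_transmit <- c(0, 0.5, 1)  # P(transmit risk allele | genotype)
  arr <- array(0, dim = c(3, 3, 3))
  for (gf in 1:3) {
    for (gm in 1:3) {
      pf <- p_transmit[gf]
      pm <- p_transmit[gm]
      arr[1, gf, gm] <- (1 - pf) * (1 - pm)
      arr[2, gf, gm] <- pf * (1 - pm) + (1 - pf) * pm
      arr[3, gf, gm] <- pf * pm
    }
  }
  arr
}

new_factor <- function(vars, tab) list(vars = vars, tab = tab)

expand_factor_tab <- function(f, vars) {
  miss <- setdiff(vars, f$vars)
  tab <- f$tab
  if (!is.array(tab)) tab <- array(tab, dim = rep(3L, length(f$vars)))
  if (length(miss)) {
    tab <- outer(tab, array(1, dim = rep(3L, length(miss))))
  }
  cur <- c(f$vars, miss)
  aperm(array(tab, dim = rep(3L, length(vars))), match(vars, cur))
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  new_factor(vars, expand_factor_tab(f1, vars) * expand_factor_tab(f2, vars))
}

sum_out <- function(f, var) {
  i <- match(var, f$vars)
  keep <- setdiff(seq_along(f$vars), i)
  if (!length(keep)) {
    return(new_factor(character(0), sum(f$tab)))
  }
  tab <- apply(f$tab, keep, sum)
  new_factor(f$vars[keep], array(tab, dim = rep(3L, length(keep))))
}

# sum-product variable elimination with running log-scale normalization.
# Eliminating children before their parents (reverse topological order)
# keeps cliques at most parent-couple sized on loop-free pedigrees.
peel_factors <- function(factors, elim_order) {
  log_scale <- 0
  for (v in elim_order) {
    touching <- vapply(factors, function(f) v %in% f$vars, logical(1))
    joint <- Reduce(factor_product, factors[touching])
    marg <- sum_out(joint, v)
    m <- max(marg$tab)
    if (m == 0) return(-Inf)
    log_scale <- log_scale + log(m)
    marg$tab <- marg$tab / m
    factors <- c(factors[!touching], list(marg))
  }
  total <- prod(vapply(factors, function(f) sum(f$tab), numeric(1)))
  if (total <= 0) return(-Inf)
  log_scale + log(total)
}

topological_ids <- function(members) {
  ids <- members$individual_id
  placed <- logical(nrow(members))
  out <- character(0)
  while (length(out) < nrow(members)) {
    ready <- !placed &
      (is.na(members$father_id) | members$father_id %in% out) &
      (is.na(members$mother_id) | members$mother_id %in% out)
    if (!any(ready)) stop("pedigree is not acyclic", call. = FALSE)
    out <- c(out, ids[ready])
    placed[ready] <- TRUE
  }
  out
}

normalize_genotype_obs <- function(genotypes, ids) {
  obs <- setNames(rep("unknown", length(ids)), ids)
  if (is.null(genotypes) || (is.data.frame(genotypes) && !nrow(genotypes))) {
    return(obs)
  }
  if (is.data.frame(genotypes)) {
    genotypes <- setNames(genotypes$status, genotypes$individual_id)
  }
  bad_id <- setdiff(names(genotypes), ids)
  if (length(bad_id)) {
    stop("observed genotype(s) for unknown individual(s): ",
         paste(bad_id, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(genotypes, c("carrier", "noncarrier", "unknown"))
  if (length(bad_status)) {
    stop("genotype status must be carrier/noncarrier/unknown, got: ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  obs[names(genotypes)] <- genotypes
  obs
}

build_evidence <- function(member, status, model) {
  pen_c <- if (member$sex == "male") model$f_carrier_male else model$f_carrier
  pen_n <- if (member$sex == "male") model$f_noncarrier_male else
    model$f_noncarrier
  pen <- c(pen_n, pen_c, pen_c)
  phen <- switch(member$affection,
                 affected = pen,
                 unaffected = 1 - pen,
                 rep(1, 3))
  # an observed "carrier" is a heterozygote: the analysis concerns rare
  # alleles whose homozygous carriers are absent from these pedigrees
  geno <- switch(status,
                 carrier = c(0, 1, 0),
                 noncarrier = c(1, 0, 0),
                 rep(1, 3))
  phen * geno
}

#' Joint likelihood of observed genotypes and phenotypes in a pedigree
#'
#' Computes \eqn{P(\mathrm{observed\ genotypes},\ \mathrm{phenotypes})}
#' under a two-point penetrance model: founders draw genotypes from the
#' Hardy-Weinberg prior at allele frequency \eqn{q}, non-founders by
#' Mendelian transmission, and every member contributes a penetrance
#' term \eqn{P(\mathrm{phenotype} \mid \mathrm{genotype})} (affected:
#' \eqn{f(g)}; unaffected: \eqn{1-f(g)}; unknown: 1). Unobserved
#' genotypes - including untested obligate carriers - are summed out
#' exactly by recursive peeling (sum-product variable elimination on
#' the pedigree's factor graph, in log scale), so the result equals
#' exhaustive enumeration over all genotype configurations.
#'
#' Pedigrees with mating loops (inbreeding or marriage loops) are
#' detected and refused. A Mendelian impossibility among the observed
#' genotypes yields likelihood zero (\code{-Inf} in log scale) with a
#' diagnostic attribute.
#'
#' @param pedigree A \code{pedigree} object; member \code{affection}
#'   and \code{sex} supply the phenotype terms.
#' @param genotypes Observed carrier states: either a named character
#'   vector (\code{individual_id -> "carrier"/"noncarrier"/"unknown"})
#'   or a data frame with columns \code{individual_id}, \code{status}.
#'   Omitted members are unknown. An observed carrier is treated as
#'   heterozygous, the relevant state for rare risk alleles whose
#'   homozygotes are essentially absent from pedigrees.
#' @param model A [penetrance_model()].
#' @param log Return the natural-log likelihood?
#' @return The likelihood (or log-likelihood). Zero likelihood carries
#'   attribute \code{diagnostic}.
#' @export
pedigree_genotype_likelihood <- function(pedigree, genotypes = NULL,
                                         model = penetrance_model(),
                                         log = FALSE) {
  stopifnot(inherits(pedigree, "pedigree"),
            inherits(model, "penetrance_model"))
  if (has_mating_loop(pedigree)) {
    stop("pedigree ", pedigree$family_id,
         " contains a mating loop (inbreeding or marriage loop); ",
         "looped pedigrees are not supported", call. = FALSE)
  }
  m <- pedigree$members
  ids <- m$individual_id
  obs <- normalize_genotype_obs(genotypes, ids)

  trans <- transmission_array()
  factors <- list()
  for (i in seq_len(nrow(m))) {
    id <- ids[i]
    if (is.na(m$father_id[i])) {
      factors[[length(factors) + 1L]] <-
        new_factor(id, array(founder_prior(model$q), dim = 3L))
    } else {
      factors[[length(factors) + 1L]] <-
        new_factor(c(id, m$father_id[i], m$mother_id[i]), trans)
    }
    factors[[length(factors) + 1L]] <-
      new_factor(id, array(build_evidence(m[i, ], obs[id], model), dim = 3L))
  }
  ll <- peel_factors(factors, rev(topological_ids(m)))
  if (identical(ll, -Inf)) {
    out <- if (log) -Inf else 0
    attr(out, "diagnostic") <-
      "model assigns the observed genotype/phenotype data probability 0"
    return(out)
  }
  if (log) ll else exp(ll)
}

#' Retrospective-likelihood co-segregation Bayes factor
#'
#' Compares the hypothesis that an observed variant is a risk allele
#' (the \code{causal_model} penetrances) against neutrality (carrier
#' risk equal to non-carrier risk) using the retrospective likelihood
#' of genotypes given phenotypes, conditioned on the proband carrying
#' the variant - the index-case conditioning that corrects for the
#' family having been ascertained through a carrier:
#' \deqn{BF = \frac{P(\mathrm{genotypes} \mid \mathrm{phenotypes},
#'   \mathrm{proband\ carrier}; \mathrm{causal})}
#'   {P(\mathrm{genotypes} \mid \mathrm{phenotypes},
#'   \mathrm{proband\ carrier}; \mathrm{neutral})}}
#' Each conditional is computed from pedigree peeling likelihoods as
#' \eqn{P(\mathrm{geno} \wedge \mathrm{phen}) /
#' P(\mathrm{proband\ carrier} \wedge \mathrm{phen})}. BF = 1 is
#' uninformative; BF > 1 supports co-segregation with disease. The BF
#' is identically 1 when causal and neutral penetrances coincide, and
#' a pedigree containing genotype information on nobody but the
#' proband is uninformative (BF = 1).
#'
#' @param pedigree A \code{pedigree} object.
#' @param genotypes Observed carrier states (see
#'   [pedigree_genotype_likelihood()]); must include the proband as
#'   \code{"carrier"}.
#' @param causal_model A [penetrance_model()] for the risk hypothesis.
#' @param proband_id The index case the analysis conditions on.
#' @param neutral_model Optional explicit neutral model; defaults to
#'   the causal model with carrier risks set equal to non-carrier
#'   risks.
#' @param site_key Optional variant identifier carried into the result.
#' @return A list of class \code{segregation_result}:
#'   \code{family_id}, \code{site_key}, \code{log_bayes_factor}
#'   (natural log), \code{bayes_factor}, \code{n_genotyped_relatives}
#'   (observed genotypes besides the proband), \code{proband_id}, and
#'   the two models.
#' @export
cosegregation_bayes_factor <- function(pedigree, genotypes, causal_model,
                                       proband_id, neutral_model = NULL,
                                       site_key = NA_character_) {
  stopifnot(inherits(pedigree, "pedigree"),
            inherits(causal_model, "penetrance_model"))
  ids <- pedigree$members$individual_id
  obs <- normalize_genotype_obs(genotypes, ids)
  if (!proband_id %in% ids) {
    stop("proband ", proband_id, " is not a member of family ",
         pedigree$family_id, call. = FALSE)
  }
  if (!identical(obs[[proband_id]], "carrier")) {
    stop("proband ", proband_id,
         " must be an observed carrier of the variant", call. = FALSE)
  }
  if (is.null(neutral_model)) {
    neutral_model <- causal_model
    neutral_model$f_carrier <- neutral_model$f_noncarrier
    neutral_model$f_carrier_male <- neutral_model$f_noncarrier_male
  }
  proband_only <- setNames("carrier", proband_id)
  ll <- function(g, model) {
    pedigree_genotype_likelihood(pedigree, g, model, log = TRUE)
  }
  ll_num_c <- ll(obs, causal_model)
  ll_den_c <- ll(proband_only, causal_model)
  ll_num_n <- ll(obs, neutral_model)
  ll_den_n <- ll(proband_only, neutral_model)
  if (!is.finite(ll_den_c) || !is.finite(ll_den_n)) {
    stop("model assigns probability 0 to the proband being a carrier; ",
         "co-segregation Bayes factor undefined", call. = FALSE)
  }
  log_bf <- (ll_num_c - ll_den_c) - (ll_num_n - ll_den_n)
  structure(list(
    family_id = pedigree$family_id, site_key = site_key,
    log_bayes_factor = log_bf, bayes_factor = exp(log_bf),
    n_genotyped_relatives = sum(obs != "unknown") - 1L,
    proband_id = proband_id,
    causal_model = causal_model, neutral_model = neutral_model
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("<segregation_result> family ", x$family_id,
      if (!is.na(x$site_key)) paste0(" @ ", x$site_key), "\n",
      "  log BF = ", format(x$log_bayes_factor, digits = 4),
      "  (BF = ", format(x$bayes_factor, digits = 4), "), ",
      x$n_genotyped_relatives, " genotyped relatives, proband ",
      x$proband_id, "\n", sep = "")
  invisible(x)
}

#' Co-segregation analysis of a candidate site within one family
#'
#' Pipeline helper: collects the observed carrier states of the
#' sequenced members at a candidate site from the cohort's calls
#' (het/hom-alt = carrier, hom-ref = non-carrier, missing = unknown),
#' picks the proband (the flagged index case if it carries the variant,
#' otherwise the earliest-diagnosed sequenced carrier), and computes
#' the co-segregation Bayes factor.
#'
#' @param cohort A \code{famexome_cohort}.
#' @param family_id Family to analyse.
#' @param site_key Candidate variant site.
#' @param causal_model A [penetrance_model()].
#' @return A \code{segregation_result}, or \code{NULL} (with a message)
#'   when no sequenced member carries the variant.
#' @export
cosegregate_family <- function(cohort, family_id, site_key,
                               causal_model = penetrance_model()) {
  ped <- cohort$pedigrees[[family_id]]
  if (is.null(ped)) stop("unknown family: ", family_id, call. = FALSE)
  m <- ped$members
  seq_ids <- m$individual_id[m$is_sequenced]
  calls <- cohort$calls[cohort$calls$site_key == site_key &
                          cohort$calls$sample_id %in% seq_ids, ]
  if (!nrow(calls)) {
    message("no calls at ", site_key, " for family ", family_id)
    return(NULL)
  }
  status <- ifelse(calls$genotype %in% c("het", "hom_alt"), "carrier",
                   ifelse(calls$genotype == "hom_ref", "noncarrier",
                          "unknown"))
  obs <- setNames(status, calls$sample_id)
  carriers <- names(obs)[obs == "carrier"]
  if (!length(carriers)) {
    message("no sequenced carrier of ", site_key, " in family ", family_id)
    return(NULL)
  }
  index_id <- m$individual_id[m$is_index]
  proband <- if (length(index_id) && index_id %in% carriers) {
    index_id
  } else {
    cm <- m[m$individual_id %in% carriers, ]
    cm$individual_id[order(cm$age_dx_or_censor, cm$individual_id)][1]
  }
  cosegregation_bayes_factor(ped, obs, causal_model, proband,
                             site_key = site_key)
}
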