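# Independent oracles used to cross-check the implementation. These are
# deliberately written along different paths than the package code:
# exhaustive enumeration instead of peeling, a literal codon table
# instead of Biostrings, choose() arithmetic instead of fisher.test.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- exhaustive pedigree likelihood ----------------------------------------
# sums the joint probability over every 3^n genotype configuration
enum_likelihood <- function(ped, obs, model) {
  m <- ped$members
  n <- nrow(m)
  obs <- as.list(obs %||% character(0))
  states <- as.matrix(expand.grid(rep(list(0:2), n)))
  lik <- rep(1, nrow(states))
  prior <- c((1 - model$q)^2, 2 * model$q * (1 - model$q), model$q^2)
  ptrans <- c(0, 0.5, 1)
  for (i in seq_len(n)) {
    gi <- states[, i]
    if (is.na(m$father_id[i])) {
      lik <- lik * prior[gi + 1]
    } else {
      gf <- states[, match(m$father_id[i], m$individual_id)]
      gm <- states[, match(m$mother_id[i], m$individual_id)]
      pf <- ptrans[gf + 1]
      pm <- ptrans[gm + 1]
      pc <- cbind((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm,
                  pf * pm)
      lik <- lik * pc[cbind(seq_along(gi), gi + 1)]
    }
    fc <- if (m$sex[i] == "male") model$f_carrier_male else model$f_carrier
    fn <- if (m$sex[i] == "male") model$f_noncarrier_male else
      model$f_noncarrier
    pen <- c(fn, fc, fc)[gi + 1]
    if (m$affection[i] == "affected") lik <- lik * pen
    if (m$affection[i] == "unaffected") lik <- lik * (1 - pen)
    st <- obs[[m$individual_id[i]]] %||% "unknown"
    ind <- switch(st, carrier = c(0, 1, 0), noncarrier = c(1, 0, 0),
                  c(1, 1, 1))
    lik <- lik * ind[gi + 1]
  }
  sum(lik)
}

enum_bayes_factor <- function(ped, obs, causal, proband_id) {
  neutral <- causal
  neutral$f_carrier <- neutral$f_noncarrier
  neutral$f_carrier_male <- neutral$f_noncarrier_male
  pro <- stats::setNames("carrier", proband_id)
  (enum_likelihood(ped, obs, causal) / enum_likelihood(ped, pro, causal)) /
    (enum_likelihood(ped, obs, neutral) / enum_likelihood(ped, pro, neutral))
}

# -- random loop-free pedigrees --------------------------------------------
random_pedigree <- function(n_members, fam = "RP",
                            p_affected = 0.4, p_observed = 0.5) {
  ids <- sprintf("%s%02d", fam, seq_len(n_members))
  father <- mother <- rep(NA_character_, n_members)
  sex <- c("male", "female", sample(c("male", "female"), n_members - 2,
                                    replace = TRUE))
  couples <- list(c(1L, 2L))
  i <- 3L
  while (i <= n_members) {
    cp <- couples[[sample.int(length(couples), 1)]]
    father[i] <- ids[cp[1]]
    mother[i] <- ids[cp[2]]
    child <- i
    i <- i + 1L
    if (i <= n_members && runif(1) < 0.4) {
      # marry the child to a new founder
      sex[i] <- if (sex[child] == "male") "female" else "male"
      couples[[length(couples) + 1L]] <-
        if (sex[child] == "male") c(child, i) else c(i, child)
      i <- i + 1L
    }
  }
  members <- data.frame(
    individual_id = ids, family_id = fam, father_id = father,
    mother_id = mother, sex = sex,
    affection = sample(c("affected", "unaffected", "unknown"), n_members,
                       replace = TRUE,
                       prob = c(p_affected, 1 - p_affected - 0.1, 0.1))
  )
  ped <- famexome::new_pedigree(members)
  status <- sample(c("carrier", "noncarrier", "unknown"), n_members,
                   replace = TRUE,
                   prob = c(p_observed / 2, p_observed / 2, 1 - p_observed))
  list(pedigree = ped, obs = stats::setNames(status, ids))
}

# -- literal-codon-table translation ---------------------------------------
oracle_codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(oracle_codon_table[codons], collapse = "")
}

# brute-force classification of a single-base deletion at position p
oracle_deletion_class <- function(cds, p) {
  edited <- paste0(substr(cds, 1, p - 1), substring(cds, p + 1))
  ref_prot <- oracle_translate(cds)
  new_prot <- oracle_translate(edited)
  nmin <- min(nchar(ref_prot), nchar(new_prot))
  rp <- strsplit(ref_prot, "")[[1]]
  np <- strsplit(new_prot, "")[[1]]
  diff <- which(rp[seq_len(nmin)] != np[seq_len(nmin)])
  first <- if (length(diff)) diff[1] else nmin + 1L
  stops <- which(np == "*" & seq_along(np) >= first)
  list(codon_index = first,
       fs_term_offset = if (length(stops)) stops[1] - first + 1L else NA_integer_)
}

# random CDS of n_codons coding codons plus a terminal stop, no internal stop
random_cds <- function(n_codons) {
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 1, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# -- hypergeometric tail by direct enumeration -----------------------------
oracle_fisher_p <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  js <- max(k1, K - n2):min(n1, K)
  js <- js[js >= k1]
  if (!length(js)) return(0)
  # log-scale enumeration so study-scale tables do not overflow choose()
  lw <- lchoose(K, js) + lchoose(N - K, n1 - js) - lchoose(N, n1)
  m <- max(lw)
  exp(m) * sum(exp(lw - m))
}

# -- Poisson-binomial via polynomial convolution ---------------------------
poisson_binomial_tail <- function(probs, k_min) {
  coef <- 1  # coef[k+1] = P(K = k)
  for (p in probs) coef <- c(coef * (1 - p), 0) + c(0, coef * p)
  sum(coef[seq_along(coef) >= k_min + 1])
}
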