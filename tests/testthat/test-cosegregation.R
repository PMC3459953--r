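founder_only_ped <- function(affection = "unaffected") {
  new_pedigree(data.frame(individual_id = "A", family_id = "F",
                          father_id = NA_character_,
                          mother_id = NA_character_, sex = "female",
                          affection = affection))
}

sib_pedigree <- function(n_sibs = 2, affection = "affected") {
  ids <- c("P1", "P2", sprintf("S%d", seq_len(n_sibs)))
  new_pedigree(data.frame(
    individual_id = ids, family_id = "F",
    father_id = c(NA, NA, rep("P1", n_sibs)),
    mother_id = c(NA, NA, rep("P2", n_sibs)),
    sex = c("male", "female", rep("female", n_sibs)),
    affection = c("unknown", "unknown", rep(affection, n_sibs))
  ))
}

test_that("a single observed founder has the closed-form likelihood", {
  m <- penetrance_model(f_carrier = 0.1, f_noncarrier = 0.1, q = 0.01)
  L <- pedigree_genotype_likelihood(founder_only_ped(), c(A = "carrier"), m)
  expect_equal(L, 2 * 0.01 * 0.99 * 0.9, tolerance = 1e-12)
  # affected founder: penetrance term flips to f
  La <- pedigree_genotype_likelihood(founder_only_ped("affected"),
                                     c(A = "carrier"), m)
  expect_equal(La, 2 * 0.01 * 0.99 * 0.1, tolerance = 1e-12)
})

test_that("a fully observed nuclear family matches the hand product", {
  m <- penetrance_model(f_carrier = 0.6, f_noncarrier = 0.1, q = 0.05,
                        f_carrier_male = 0.3, f_noncarrier_male = 0.02)
  ped <- sib_pedigree(2)
  obs <- c(P1 = "carrier", P2 = "noncarrier", S1 = "carrier",
           S2 = "noncarrier")
  # founders: het father x hom-ref mother; children: inherit with p = 1/2
  # each; both sibs affected females
  by_hand <- (2 * 0.05 * 0.95) * (0.95^2) * 0.5 * 0.5 * 0.6 * 0.1
  L <- pedigree_genotype_likelihood(ped, obs, m)
  expect_equal(L, by_hand, tolerance = 1e-12)
})

test_that("peeling equals exhaustive enumeration on random pedigrees", {
  set.seed(401)
  for (rep in 1:30) {
    rp <- random_pedigree(sample(4:10, 1))
    m <- penetrance_model(
      f_carrier = runif(1, 0.3, 0.9), f_noncarrier = runif(1, 0.01, 0.25),
      q = runif(1, 0.001, 0.2),
      f_carrier_male = runif(1, 0.05, 0.3),
      f_noncarrier_male = runif(1, 0.001, 0.04)
    )
    L_peel <- pedigree_genotype_likelihood(rp$pedigree, rp$obs, m)
    L_enum <- enum_likelihood(rp$pedigree, rp$obs, m)
    if (L_enum == 0) {
      expect_equal(as.numeric(L_peel), 0)
    } else {
      expect_equal(as.numeric(L_peel), L_enum, tolerance = 1e-10)
    }
  }
})

test_that("a Mendelian impossibility yields zero likelihood with diagnostic", {
  ped <- sib_pedigree(1)
  obs <- c(P1 = "noncarrier", P2 = "noncarrier", S1 = "carrier")
  L <- pedigree_genotype_likelihood(ped, obs, penetrance_model())
  expect_equal(as.numeric(L), 0)
  expect_match(attr(L, "diagnostic"), "probability 0")
})

test_that("mating loops are detected and refused", {
  # first cousins marrying: loop through the shared grandparental couple
  members <- data.frame(
    individual_id = c("G1", "G2", "A", "B", "SA", "SB", "CA", "CB", "X"),
    family_id = "L",
    father_id = c(NA, NA, "G1", "G1", NA, NA, "A", "B", "CA"),
    mother_id = c(NA, NA, "G2", "G2", NA, NA, "SA", "SB", "CB"),
    sex = c("male", "female", "male", "male", "female", "female", "male",
            "female", "female"),
    affection = "unknown"
  )
  ped <- new_pedigree(members)
  expect_true(has_mating_loop(ped))
  expect_error(pedigree_genotype_likelihood(ped, NULL, penetrance_model()),
               "loop")
  expect_false(has_mating_loop(sib_pedigree(3)))
})

test_that("the Bayes factor is 1 whenever causal and neutral models coincide", {
  set.seed(402)
  for (rep in 1:10) {
    rp <- random_pedigree(sample(4:9, 1))
    obs <- rp$obs
    obs[1] <- "carrier"  # make the proband an observed carrier
    m <- penetrance_model(f_carrier = 0.2, f_noncarrier = 0.2, q = 0.05,
                          f_carrier_male = 0.05, f_noncarrier_male = 0.05)
    res <- cosegregation_bayes_factor(rp$pedigree, obs,
                                      causal_model = m,
                                      proband_id = names(obs)[1],
                                      neutral_model = m)
    expect_equal(res$log_bayes_factor, 0, tolerance = 1e-12)
  }
})

test_that("a pedigree with genotype data only on the proband is uninformative", {
  ped <- sib_pedigree(2)
  res <- cosegregation_bayes_factor(ped, c(S1 = "carrier"),
                                    penetrance_model(), "S1")
  expect_equal(res$bayes_factor, 1, tolerance = 1e-12)
  expect_equal(res$n_genotyped_relatives, 0L)
})

test_that("an affected carrier sib doubles the odds under full penetrance", {
  ped <- sib_pedigree(2)
  cm <- penetrance_model(f_carrier = 1, f_noncarrier = 1e-12, q = 1e-6,
                         f_carrier_male = 1, f_noncarrier_male = 1e-12)
  obs <- c(S1 = "carrier", S2 = "carrier")
  res <- cosegregation_bayes_factor(ped, obs, cm, "S1")
  expect_equal(res$bayes_factor, 2, tolerance = 1e-3)
  expect_equal(res$bayes_factor, enum_bayes_factor(ped, obs, cm, "S1"),
               tolerance = 1e-10)
})

test_that("Bayes factors match the enumeration oracle on random pedigrees", {
  set.seed(403)
  for (rep in 1:15) {
    rp <- random_pedigree(sample(4:9, 1))
    obs <- rp$obs
    obs[1] <- "carrier"
    cm <- penetrance_model(f_carrier = 0.6, f_noncarrier = 0.1, q = 0.01,
                           f_carrier_male = 0.1, f_noncarrier_male = 0.01)
    res <- tryCatch(
      cosegregation_bayes_factor(rp$pedigree, obs, cm, names(obs)[1]),
      error = function(e) e
    )
    oracle <- enum_bayes_factor(rp$pedigree, obs, cm, names(obs)[1])
    if (inherits(res, "error")) {
      # observation set impossible under Mendelian transmission
      expect_true(!is.finite(oracle) || is.nan(oracle))
    } else {
      expect_equal(res$bayes_factor, oracle, tolerance = 1e-10)
    }
  }
})

test_that("adding a fully unknown individual leaves the Bayes factor unchanged", {
  ped <- sib_pedigree(2)
  cm <- penetrance_model(f_carrier = 0.5, f_noncarrier = 0.1, q = 0.01)
  obs <- c(S1 = "carrier", S2 = "noncarrier")
  base <- cosegregation_bayes_factor(ped, obs, cm, "S1")
  bigger <- sib_pedigree(3)  # S3: unknown genotype AND phenotype
  bigger$members$affection[bigger$members$individual_id == "S3"] <- "unknown"
  ext <- cosegregation_bayes_factor(bigger, obs, cm, "S1")
  expect_equal(ext$log_bayes_factor, base$log_bayes_factor,
               tolerance = 1e-12)
})

test_that("preconditions on the proband are enforced", {
  ped <- sib_pedigree(2)
  m <- penetrance_model()
  expect_error(cosegregation_bayes_factor(ped, c(S1 = "noncarrier"), m,
                                          "S1"), "observed carrier")
  expect_error(cosegregation_bayes_factor(ped, c(S2 = "carrier"), m, "S1"),
               "observed carrier")
  expect_error(cosegregation_bayes_factor(ped, c(S1 = "carrier"), m,
                                          "NOBODY"), "not a member")
})

test_that("the packaged sibship fixture supports co-segregation under moderate penetrance", {
  peds <- read_pedigree(
    system.file("extdata", "family3.ped", package = "famexome"),
    system.file("extdata", "family3_phenotypes.tsv", package = "famexome")
  )
  ped <- peds[["FAM3"]]
  obs <- c(S1 = "carrier", S2 = "carrier", S3 = "carrier",
           S4 = "noncarrier", S5 = "noncarrier")
  cm <- penetrance_model(f_carrier = 0.3, f_noncarrier = 0.1, q = 0.003)
  res <- cosegregation_bayes_factor(ped, obs, cm, "S1")
  expect_true(is.finite(res$log_bayes_factor))
  expect_gt(res$bayes_factor, 1)
  expect_equal(res$bayes_factor, enum_bayes_factor(ped, obs, cm, "S1"),
               tolerance = 1e-10)
})
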