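two_founder_sibship <- function(n_kids, fam = "GD") {
  ids <- c("FA", "MO", sprintf("K%04d", seq_len(n_kids)))
  new_pedigree(data.frame(
    individual_id = ids, family_id = fam,
    father_id = c(NA, NA, rep("FA", n_kids)),
    mother_id = c(NA, NA, rep("MO", n_kids)),
    sex = c("male", "female", rep("female", n_kids)),
    affection = "unknown"
  ))
}

test_that("gene dropping is Mendelian and penetrance-faithful", {
  set.seed(101)
  # degenerate penetrance: every affected member is a carrier
  ped <- two_founder_sibship(8)
  model <- penetrance_model(f_carrier = 1, f_noncarrier = 1e-12, q = 0.2,
                            f_carrier_male = 1, f_noncarrier_male = 1e-12)
  for (i in 1:20) {
    g <- drop_genotypes(ped, model)
    expect_true(all(g$carrier[g$affected]))
  }
  # carrier x non-carrier mating: offspring carrier fraction 1/2
  big <- two_founder_sibship(10000)
  tiny_q <- penetrance_model(q = 1e-9)
  g <- drop_genotypes(big, tiny_q, forced_carrier = "FA")
  frac <- mean(g$carrier[!g$individual_id %in% c("FA", "MO")])
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
  # essentially-zero allele frequency: no carriers anywhere
  g0 <- drop_genotypes(big, tiny_q)
  expect_false(any(g0$carrier))
})

test_that("no Mendelian violations ever occur in dropped genotypes", {
  set.seed(102)
  cfg <- simulation_config(seed = 5L)
  for (i in 1:10) {
    fam <- simulate_pedigree(cfg, "MV", causal = (i %% 2 == 0))
    m <- fam$pedigree$members
    carrier <- setNames(fam$genotypes$carrier, fam$genotypes$individual_id)
    kids <- m[!is.na(m$father_id), ]
    # a carrier child needs a carrier parent (de novo events not modelled)
    for (k in seq_len(nrow(kids))) {
      if (carrier[kids$individual_id[k]]) {
        expect_true(carrier[kids$father_id[k]] || carrier[kids$mother_id[k]])
      }
    }
  }
})

test_that("founder carrier frequency converges to the Hardy-Weinberg value", {
  set.seed(103)
  q <- 0.05
  model <- penetrance_model(q = q)
  founder_only <- new_pedigree(data.frame(
    individual_id = sprintf("F%03d", 1:200), family_id = "HW",
    father_id = NA_character_, mother_id = NA_character_,
    sex = "female", affection = "unknown"
  ))
  n_draws <- 500  # 100,000 founder genotypes in total
  hits <- 0L
  for (i in seq_len(n_draws)) {
    hits <- hits + sum(drop_genotypes(founder_only, model)$carrier)
  }
  p_hat <- hits / (200 * n_draws)
  p_exp <- 2 * q * (1 - q)
  se <- sqrt(p_exp * (1 - p_exp) / (200 * n_draws))
  expect_lt(abs(p_hat - p_exp), 4 * se)
})

test_that("ascertained families meet the ascertainment conditions", {
  set.seed(104)
  cfg <- simulation_config(seed = 6L)
  fam <- simulate_pedigree(cfg, "ASC", causal = TRUE, n_sequenced = 2L)
  m <- fam$pedigree$members
  expect_gte(sum(m$affection == "affected"), cfg$min_affected)
  expect_equal(sum(m$is_sequenced), 2L)
  expect_equal(sum(m$is_index), 1L)
  expect_true(all(m$affection[m$is_sequenced] == "affected"))
  carrier <- setNames(fam$genotypes$carrier, fam$genotypes$individual_id)
  expect_gte(sum(carrier[m$individual_id[m$is_sequenced]]), 2L)
  # sequenced members are the earliest-diagnosed affected
  aff <- m[m$affection == "affected", ]
  aff <- aff[order(aff$age_dx_or_censor, aff$individual_id), ]
  expect_setequal(m$individual_id[m$is_sequenced], aff$individual_id[1:2])
  expect_equal(m$individual_id[m$is_index], aff$individual_id[1])
})

test_that("the affected-count distribution matches an analytic oracle", {
  # fixed 9-member structure; expectation enumerated over the generator's
  # own carrier model (2/3 het given carrier-x-carrier after redraw) with
  # a Poisson-binomial over penetrance
  members <- data.frame(
    individual_id = c("F", "M", "C1", "C2", "C3", "C4", "S1", "G1", "G2"),
    family_id = "AN",
    father_id = c(NA, NA, "F", "F", "F", "F", NA, "C1", "C1"),
    mother_id = c(NA, NA, "M", "M", "M", "M", NA, "S1", "S1"),
    sex = c("male", "female", "male", "female", "female", "female",
            "female", "female", "female"),
    affection = "unknown"
  )
  ped <- new_pedigree(members)
  model <- penetrance_model(f_carrier = 0.5, f_noncarrier = 0.15, q = 0.1,
                            f_carrier_male = 0.3, f_noncarrier_male = 0.05)

  # enumerate carrier configurations with generator transmission rules
  founders_idx <- c(1, 2, 7)
  p_child <- function(fa, mo) if (fa && mo) 2 / 3 else if (fa || mo) 0.5 else 0
  prior <- 2 * model$q * (1 - model$q)
  ids <- members$individual_id
  p_four_plus <- 0
  for (bits in 0:(2^9 - 1)) {
    carrier <- as.logical(bitwAnd(bits, 2^(0:8)))
    names(carrier) <- ids
    pr <- 1
    for (i in seq_len(9)) {
      if (i %in% founders_idx) {
        pr <- pr * if (carrier[i]) prior else 1 - prior
      } else {
        pc <- p_child(carrier[members$father_id[i]],
                      carrier[members$mother_id[i]])
        pr <- pr * if (carrier[i]) pc else 1 - pc
      }
      if (pr == 0) break
    }
    if (pr == 0) next
    pens <- ifelse(members$sex == "male",
                   ifelse(carrier, model$f_carrier_male,
                          model$f_noncarrier_male),
                   ifelse(carrier, model$f_carrier, model$f_noncarrier))
    p_four_plus <- p_four_plus + pr * poisson_binomial_tail(pens, 4)
  }

  set.seed(105)
  n_rep <- 1000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    hits <- hits + (sum(drop_genotypes(ped, model)$affected) >= 4)
  }
  p_hat <- hits / n_rep
  se <- sqrt(p_four_plus * (1 - p_four_plus) / n_rep)
  expect_lt(abs(p_hat - p_four_plus), 4 * se)
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_families = 3, n_background_genes = 10,
                           n_common_sites = 4, seed = 21L)
  d1 <- tempfile("det1_")
  d2 <- tempfile("det2_")
  p1 <- emit_cohort(cfg, d1)
  p2 <- emit_cohort(cfg, d2)
  for (f in c("vcf_path", "ped_path", "phenotype_path", "truth_path")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("zero background and common variants leaves only causal records", {
  cfg <- simulation_config(n_families = 3, n_causal_families = 2,
                           n_background_genes = 0, n_common_sites = 0,
                           seed = 22L)
  co <- simulate_cohort(cfg)
  expect_true(all(co$variants$gene == "FANCC"))
  expect_equal(nrow(co$variants), 2)
  expect_true(all(co$truth$class == "causal"))
})

test_that("cohort-common sites exceed the recurrence threshold as designed", {
  # population frequency chosen so expected carriers are 20 of 33
  f <- 1 - sqrt(1 - 20 / 33)
  cfg <- simulation_config(n_common_sites = 10, common_af_range = c(f, f),
                           n_background_genes = 0, seed = 23L)
  exceed <- 0L
  total <- 0L
  for (s in 1:10) {
    cfg$seed <- 23L + s
    co <- simulate_cohort(cfg)
    common <- co$variants[co$variants$gene %in%
                            sprintf("CMN%02d", 1:10), ]
    exceed <- exceed + sum(common$cohort_carrier_count > 10)
    total <- total + nrow(common)
  }
  expect_gte(exceed / total, 0.95)
})

test_that("screening cohort simulation honours rates and seeds", {
  zero <- emit_screen_cohorts(100, 50, 0, 0, seed = 1)
  expect_false(any(zero$cases$carrier))
  expect_false(any(zero$controls$carrier))

  again <- emit_screen_cohorts(100, 50, 0.3, 0.1, seed = 9)
  again2 <- emit_screen_cohorts(100, 50, 0.3, 0.1, seed = 9)
  expect_identical(again, again2)

  set.seed(31)
  n_rep <- 2000
  counts <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    counts[i] <- sum(emit_screen_cohorts(1395, 10, 4 / 1395, 0,
                                         seed = 1000 + i)$cases$carrier)
  }
  se <- sqrt(4 / n_rep)  # variance ~ mean for a rare binomial
  expect_lt(abs(mean(counts) - 4), 4 * se)
})
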