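# Simulate one family for co-segregation evaluation: pedigree structure
# from the cohort generator, genotypes re-dropped under a chosen truth
# penetrance with a founder forced to carry the variant, affection
# resampled from that truth, and the family accepted when it has at
# least `min_aff` affected members and a carrier proband (the
# ascertainment the Bayes factor's proband conditioning corrects for).
simulate_coseg_family <- function(truth_model, min_aff = 3, n_seq = 3) {
  structure_cfg <- famexome::simulation_config(
    pedigree_depth = 3, sibship_size_mean = 3, marry_prob = 0.8,
    min_affected = 2,
    penetrance = famexome::penetrance_model(f_carrier = 0.3,
                                            f_noncarrier = 0.3,
                                            f_carrier_male = 0.05,
                                            f_noncarrier_male = 0.05)
  )
  repeat {
    fam <- famexome::simulate_pedigree(structure_cfg, "CS", causal = FALSE,
                                       n_sequenced = 2)
    ped <- fam$pedigree
    founder_ids <- famexome::founders(ped)$individual_id
    g <- famexome::drop_genotypes(ped, truth_model,
                                  forced_carrier = founder_ids[1])
    aff <- g$individual_id[g$affected]
    if (length(aff) < min_aff) next
    genotyped <- sample(aff, min(n_seq, length(aff)))
    proband <- genotyped[1]
    carrier <- stats::setNames(g$carrier, g$individual_id)
    if (!carrier[proband]) next
    m <- ped$members
    m$affection <- ifelse(m$individual_id %in% aff, "affected",
                          "unaffected")
    m$is_sequenced <- m$individual_id %in% genotyped
    m$is_index <- m$individual_id == proband
    obs <- stats::setNames(
      ifelse(carrier[genotyped], "carrier", "noncarrier"), genotyped)
    return(list(pedigree = famexome::new_pedigree(m), obs = obs,
                proband = proband))
  }
}
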