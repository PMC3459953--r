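write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

trio_ped_lines <- c(
  "T1\tDAD\t0\t0\t1\t1",
  "T1\tMUM\t0\t0\t2\t1",
  "T1\tKID\tDAD\tMUM\t2\t2"
)

test_that("a trio PED parses into one pedigree with two founders", {
  peds <- read_pedigree(write_lines_tmp(trio_ped_lines, ".ped"))
  expect_length(peds, 1)
  ped <- peds[["T1"]]
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped$members), 3)
  expect_equal(nrow(founders(ped)), 2)
  expect_equal(ped$members$affection,
               c("unaffected", "unaffected", "affected"))
})

test_that("the packaged sibship fixture loads with phenotypes attached", {
  peds <- read_pedigree(
    system.file("extdata", "family3.ped", package = "famexome"),
    system.file("extdata", "family3_phenotypes.tsv", package = "famexome")
  )
  ped <- peds[["FAM3"]]
  m <- ped$members
  expect_equal(nrow(m), 7)
  expect_equal(nrow(founders(ped)), 2)
  expect_equal(sum(m$affection == "affected"), 3)
  expect_equal(sort(m$age_dx_or_censor[m$affection == "affected"]),
               c(39, 39, 41))
  expect_equal(sum(m$is_sequenced), 2)
  expect_equal(m$individual_id[m$is_index], "S1")
})

test_that("structural pedigree errors are detected and named", {
  self_father <- c("T1\tKID\tKID\tMUM\t2\t2", "T1\tMUM\t0\t0\t2\t1")
  expect_error(read_pedigree(write_lines_tmp(self_father, ".ped")),
               "cycle.*KID")
  dup <- c(trio_ped_lines, "T1\tKID\tDAD\tMUM\t2\t2")
  expect_error(read_pedigree(write_lines_tmp(dup, ".ped")),
               "duplicate.*KID")
  orphan_parent <- c("T1\tKID\tGHOST\tMUM\t2\t2", "T1\tMUM\t0\t0\t2\t1")
  expect_error(read_pedigree(write_lines_tmp(orphan_parent, ".ped")),
               "unresolvable.*GHOST")
  one_parent <- c("T1\tKID\tDAD\t0\t2\t2", "T1\tDAD\t0\t0\t1\t1")
  expect_error(read_pedigree(write_lines_tmp(one_parent, ".ped")),
               "one recorded parent")
  # deeper ancestor cycle
  cyc <- data.frame(individual_id = c("A", "B", "Z"), family_id = "F",
                    father_id = c("B", "A", "A"), mother_id = c("Z", "Z", NA),
                    sex = "male", affection = "unknown")
  cyc$mother_id[3] <- NA
  cyc$father_id[3] <- NA
  expect_error(new_pedigree(cyc), "cycle")
})

test_that("two index cases in one family are rejected", {
  m <- data.frame(individual_id = c("A", "B"), family_id = "F",
                  father_id = NA_character_, mother_id = NA_character_,
                  sex = "female", affection = "affected",
                  is_index = c(TRUE, TRUE))
  expect_error(new_pedigree(m), "more than one index")
})

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
  "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
  "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"d\">",
  "##INFO=<ID=HGMD,Number=0,Type=Flag,Description=\"h\">",
  "##INFO=<ID=KPATH,Number=0,Type=Flag,Description=\"k\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
  "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
  "##FORMAT=<ID=ADF,Number=A,Type=Integer,Description=\"adf\">",
  "##FORMAT=<ID=ADR,Number=A,Type=Integer,Description=\"adr\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2"
)

test_that("VCF calls parse with allele fractions and missing genotypes", {
  lines <- c(vcf_header,
             paste("1", "100", ".", "A", "G", ".", "PASS",
                   "GENE=GENEA;CSQ=stop_gained", "GT:GQ:DP:ADF:ADR",
                   "0/1:60:40:9:8", "./.:.:.:.:.", sep = "\t"))
  x <- read_variant_calls(write_lines_tmp(lines, ".vcf"))
  expect_equal(nrow(x$variants), 1)
  expect_equal(x$variants$gene, "GENEA")
  expect_equal(x$variants$cohort_carrier_count, 1L)
  s1 <- x$calls[x$calls$sample_id == "S1", ]
  expect_equal(s1$genotype, "het")
  expect_equal(s1$allele_fraction, 17 / 40)
  s2 <- x$calls[x$calls$sample_id == "S2", ]
  expect_equal(s2$genotype, "missing")
})

test_that("multi-allelic records decompose into per-allele variants", {
  lines <- c(vcf_header,
             paste("1", "200", ".", "A", "G,T", ".", "PASS",
                   "GENE=GENEB;CSQ=missense,stop_gained",
                   "GT:GQ:DP:ADF:ADR", "1/2:50:60:10,5:12,6",
                   "0/1:55:50:8,0:9,0", sep = "\t"))
  x <- read_variant_calls(write_lines_tmp(lines, ".vcf"))
  expect_equal(nrow(x$variants), 2)
  expect_equal(x$variants$alt, c("G", "T"))
  expect_equal(x$variants$consequence, c("missense", "stop_gained"))
  expect_equal(unique(paste(x$variants$chrom, x$variants$pos,
                            x$variants$ref)), "1 200 A")
  g_calls <- x$calls[x$calls$site_key == "1:200:A:G", ]
  expect_equal(g_calls$genotype, c("het", "het"))
  t_calls <- x$calls[x$calls$site_key == "1:200:A:T", ]
  expect_equal(t_calls$genotype, c("het", "hom_ref"))
  # decomposition conserves total alt-supporting reads
  s1 <- x$calls[x$calls$sample_id == "S1", ]
  expect_equal(sum(s1$alt_fwd) + sum(s1$alt_rev), 10 + 5 + 12 + 6)
})

test_that("a missing mandatory FORMAT field is a named error", {
  bad_header <- vcf_header
  lines <- c(bad_header,
             paste("1", "100", ".", "A", "G", ".", "PASS", "GENE=X;CSQ=other",
                   "GT:GQ:DP", "0/1:60:40", "0/0:60:42", sep = "\t"))
  expect_error(read_variant_calls(write_lines_tmp(lines, ".vcf")), "ADF")
})

test_that("cohort validation reports orphans and Mendelian inconsistencies", {
  peds <- read_pedigree(write_lines_tmp(trio_ped_lines, ".ped"))
  mk <- function(kid_gt) {
    lines <- c(sub("S1\tS2", "DAD\tMUM\tKID", vcf_header),
               paste("1", "100", ".", "A", "G", ".", "PASS",
                     "GENE=X;CSQ=other", "GT:GQ:DP:ADF:ADR",
                     "0/0:60:40:0:0", "0/0:60:40:0:0",
                     paste0(kid_gt, ":60:40:10:10"), sep = "\t"))
    read_variant_calls(write_lines_tmp(lines, ".vcf"))
  }
  ok <- validate_cohort(peds, mk("0/0"))
  expect_equal(nrow(ok$mendelian), 0)
  expect_equal(nrow(ok$orphan_samples), 0)
  bad <- validate_cohort(peds, mk("0/1"))
  expect_equal(nrow(bad$mendelian), 1)
  expect_equal(bad$mendelian$child, "KID")

  lines <- c(vcf_header,
             paste("1", "100", ".", "A", "G", ".", "PASS", "GENE=X;CSQ=other",
                   "GT:GQ:DP:ADF:ADR", "0/1:60:40:9:8", "0/0:60:40:0:0",
                   sep = "\t"))
  orph <- validate_cohort(peds, read_variant_calls(write_lines_tmp(lines,
                                                                   ".vcf")))
  expect_equal(sort(orph$orphan_samples$sample_id), c("S1", "S2"))
})

test_that("an emitted synthetic cohort round-trips through VCF/PED identically", {
  config <- simulation_config(n_families = 4, n_causal_families = 1,
                              n_background_genes = 15, n_common_sites = 5,
                              n_sequenced = 2L, seed = 11L)
  out <- tempfile("rt_")
  paths <- emit_cohort(config, out)
  mem <- attr(paths, "cohort")
  back <- assemble_cohort(paths$vcf_path, paths$ped_path,
                          paths$phenotype_path)

  v1 <- as.data.frame(mem$variants)
  v2 <- as.data.frame(back$variants)
  v2 <- v2[match(v1$site_key, v2$site_key), ]
  rownames(v1) <- rownames(v2) <- NULL
  expect_equal(v2, v1)

  key <- function(df) df[order(df$site_key, df$sample_id), ]
  c1 <- as.data.frame(key(mem$calls))
  c2 <- as.data.frame(key(back$calls))
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c2, c1)

  for (fam in names(mem$pedigrees)) {
    m1 <- as.data.frame(mem$pedigrees[[fam]]$members)
    m2 <- as.data.frame(back$pedigrees[[fam]]$members)
    m2 <- m2[match(m1$individual_id, m2$individual_id), ]
    rownames(m1) <- rownames(m2) <- NULL
    expect_equal(m2, m1)
  }

  # clean validation report on the round-tripped cohort
  rep <- validate_cohort(back$pedigrees,
                         list(variants = back$variants, calls = back$calls))
  expect_equal(nrow(rep$orphan_samples), 0)
  expect_equal(nrow(rep$missing_sequenced), 0)
  expect_equal(nrow(rep$mendelian), 0)
})

test_that("pedigree validation is order-independent", {
  peds <- read_pedigree(
    system.file("extdata", "family3.ped", package = "famexome"),
    system.file("extdata", "family3_phenotypes.tsv", package = "famexome")
  )
  m <- peds[["FAM3"]]$members
  set.seed(1)
  for (i in 1:5) {
    shuffled <- m[sample.int(nrow(m)), ]
    ped <- new_pedigree(shuffled)
    expect_equal(sort(founders(ped)$individual_id), c("FA", "MO"))
  }
})
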