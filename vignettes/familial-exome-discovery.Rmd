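---
title: "Methods: familial exome candidate-gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial exome candidate-gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famexome)
```

# The problem

Multiplex breast-cancer families without BRCA1/2 mutations are the
setting where moderate-penetrance susceptibility alleles hide: exome
sequencing of two or three affected relatives per family produces
thousands of rare variants, of which the interesting ones are
heterozygous, overtly disruptive, shared within a family or recurrent
across families, co-segregating with disease, and absent from
controls. famexome implements that whole chain of evidence as testable
components. Because each link is individually weak — incomplete
penetrance, phenocopies, tiny per-gene family counts — the package
treats quantification of the weakness (Bayes factors, exact tests) as
part of the method, not an afterthought.

# The filtering cascade

The cascade mirrors standard practice for post-GATK germline exome
calls and is parameterized by `filter_thresholds()`:

| parameter | default | units | role |
|---|---|---|---|
| `min_qual` | 30 | phred | per-call quality floor (inclusive) |
| `min_depth` | 10 | reads | per-call depth floor (inclusive) |
| `min_allele_fraction` | 0.15 | fraction | alt reads / depth floor (inclusive) |
| `require_bidirectional` | TRUE | — | ≥ 1 alt read on each strand |
| `max_cohort_carriers` | 10 | individuals | recurrence cut, strictly greater-than |
| `cohort_size` | 33 | exomes | sequenced discovery cohort |

Interpretation choices worth making explicit:

* "Allele frequency ≥ 0.15" is read as the per-sample variant allele
  fraction, not a population frequency — it sits among per-call
  confidence criteria and a germline het call near 0.5 is the
  alternative hypothesis; 0.15 guards against alignment artefacts and
  cross-sample contamination.
* Bidirectional support is encoded as strand-resolved alt read counts
  (FORMAT `ADF`/`ADR`, one count per alt allele); the filter requires
  at least one alt read on each strand.
* The recurrence cut counts individuals carrying any non-reference
  genotype, and is exclusive (a variant in exactly 10 of 33 exomes
  survives), matching the stated "more than 10 of 33" semantics.
* The known-gene pre-check runs on confidence-filtered calls *before*
  database removal, because known pathogenic alleles (e.g. catalogued
  BRCA2 frameshifts) frequently carry dbSNP identifiers and would
  otherwise be discarded; database removal spares dbSNP variants also
  present in HGMD for the same reason.
* The final consequence selection is strict (nonsense, frameshift,
  essential splice, complex indel). Registry-validated pathogenic
  missense alleles are *not* admitted there; they matter only for the
  broader screening classifier used in burden counting, where the
  rule is "four classes OR registry-validated".

# Prioritization

Two views are computed because they answer different questions:
`pairwise_shared()` intersects candidate *sites* between sequenced
relatives (identical variant, not merely the same gene), while
`recurrent_genes()` aggregates at gene level across families, where
independent mutations in the same gene are the signal. The ranking in
`rank_genes()` is a deterministic composite key: families where the
gene is shared by all sequenced members (descending), families hit
(descending), DNA-repair membership, individuals hit, then gene symbol.
The field's stated priorities order the first three keys; the composite
and its tie-breaks are this package's own design so that the ranking is
a reproducible total order under input permutation.

# The co-segregation model

`pedigree_genotype_likelihood()` computes the joint probability of the
observed carrier states and phenotypes under a two-point penetrance
model: genotype states are risk-allele counts (0/1/2); founders draw
from Hardy–Weinberg at allele frequency `q`; non-founders follow
Mendelian transmission; each member contributes
P(phenotype | genotype). Unobserved genotypes — including untested
obligate carriers — are summed out exactly by peeling: sum-product
variable elimination on the pedigree factor graph, eliminating
children before parents, which bounds clique size at a parent couple
plus grandparents on loop-free pedigrees. Running normalization keeps
the computation in log scale, so large pedigrees cannot underflow.

Numerical and modeling choices:

* An observed "carrier" is treated as heterozygous. These are rare
  alleles (`q` defaults to 0.003); homozygotes are vanishingly rare
  and the screening context reports het carriers. This makes the
  single-founder closed form exactly `2q(1-q) x P(phenotype | het)`.
* Penetrance is sex-specific (`penetrance_model()` carries male
  risks), which is what lets pedigrees with male breast cancer
  contribute rather than break.
* Mating loops (inbreeding, two-family double marriages) are detected
  on the marriage graph and refused with an error — exact peeling on
  loops needs loop-breaking machinery that the target pedigrees do not
  require. Mendelian impossibilities among observed genotypes yield
  likelihood zero with a diagnostic rather than an error.

`cosegregation_bayes_factor()` forms the retrospective likelihood
ratio P(genotypes | phenotypes, proband carrier) between the causal
model and the neutral model (carrier risk set equal to non-carrier
risk), each conditional computed as a ratio of two peeled likelihoods.
Conditioning on a single proband is an explicit design choice: the
ascertainment correction appropriate when one index case's screening
result brought the family in. Full family-history conditioning would
require modeling the recruitment rule itself, which is out of scope
and rarely known.

Two exact properties anchor the test suite: the BF is identically 1
when the hypotheses coincide, and under the neutral hypothesis the BF
is a martingale with expectation exactly 1 — so on neutral-simulated
families the *mean BF* sits at 1 within Monte-Carlo error while the
mean *log* BF sits slightly below zero (minus the per-family KL
divergence, which is materially negative here because each simulated
family carries three genotyped relatives at a 3-fold penetrance
ratio). The suite asserts the martingale form of the null property and
positive mean log-BF under the causal simulation.

# Carrier burden

`fisher_exact_burden()` uses the one-sided hypergeometric tail
(carriers enriched in cases) and the cross-product odds ratio with the
Haldane–Anscombe +0.5 correction only when a zero cell exists. The
packaged screening fixture encodes the qualifying variants of a
FANCC/BLM screen: 438 fully screened case families, 957 families
screened at FANCC hotspot exons only, 464 controls; the combined
control denominator of 2,210 for FANCC (adding 654 independent-study
controls and 1,092 reference-panel genomes, all mutation-free) is
fixture metadata taken as printed. External population-database
frequencies are deliberately excluded from the computation. One
fixture row (BLM c.1993C>T) is published as truncating protein at
residue 645 although codon arithmetic on the stated cDNA position
gives 665; the fixture counts it as truncating, as published, and the
report carries the inconsistency as a note rather than silently
correcting either number. The damaging-missense follow-up observation
(FANCC p.Arg185Gln) is listed but never counted as deleterious.

# HGVS consequence mapping

`codon_of()` maps a coding position to `floor((pos - 1)/3) + 1`; all
nine published cDNA/protein pairs used in testing satisfy this rule.
HGVS canonical frameshift naming can shift right of the first edited
base when the first altered codon's residue is preserved;
`protein_consequence()` therefore derives the first affected codon and
the `fs*N` stop offset by translating the edited sequence and
comparing, rather than from position arithmetic. Intronic descriptions
(offsets like `+4`) are parsed and flagged, never coerced to coding
positions. Essential-splice and complex-indel classes are assigned by
the annotation source (in synthetic data, by the generator), as they
were upstream annotations in the original analyses, not computed here.

# What the synthetic cohort emulates

`simulation_config()` defaults encode the study design the analysis
assumes: 15 multi-generational families ascertained for at least four
cancer cases, 33 sequenced exomes (twelve families contribute two
affected relatives, three contribute three), two families segregating
a private truncating variant in a DNA-repair gene, mean target depth
80x, and confidence-call noise degrading 5% of true variant calls per
threshold (2% for strand dropout). Where the design did not pin a
value, the defaults are one-time choices of what a practitioner would
call realistic for this setting: female carrier lifetime risk 0.30
versus 0.10 baseline (a 3-fold, "moderate penetrance" allele over a
realistic lifetime phenocopy rate), male risks 0.06/0.001, causal
allele frequency q = 0.003, 60 background genes acquiring rare
founder variants at rate 0.08 per family-gene, 25 cohort-common
dbSNP-flagged polymorphisms at population frequencies 0.2–0.6, and
het allele fractions Beta(20, 20). Carriers receive earlier diagnosis
ages (truncated normal, mean 45 vs 58 on [25, 80]), which makes the
"sequence the earliest-diagnosed affected members" rule favor
carriers the way index-case selection does in practice. Causal
families are additionally required to have at least two sequenced
carriers, emulating families in which the familial cluster is
attributable to the injected allele.

What it does *not* emulate — hence what passing tests do not show
about real data: genotype-calling errors (emitted genotypes are true;
noise degrades quality, depth, allele fraction and strand balance, not
the genotype string), platform coverage structure, population
stratification, relatedness between families, de novo mutations, and
X-linked inheritance. The truth table emitted alongside each cohort is
a leakage firewall: analysis functions never read it; tests compare
against it.

Common-variant genotypes are dropped through each pedigree from
Hardy–Weinberg founders, so within-family calls are Mendelian-
consistent and the cohort-validation report stays clean on simulated
data.

# Problem sizes and runtime choices

The default test and acceptance runs use the cohort at its design
size (15 families, 33 exomes) across 100 seeded replicates for the
cascade and prioritization properties; peeling-versus-enumeration
equality uses 100 random pedigrees of 4–12 members (3^12 genotype
configurations is the practical ceiling for the exhaustive oracle);
Bayes-factor direction recovery uses 200 families per hypothesis at a
slightly smaller pedigree size (mean sibship 3) chosen so the whole
suite completes in minutes on one CPU. The exact-test oracle sweep is
exhaustive over all 2x2 tables with per-arm sizes up to 12 plus the
study-scale table.

# Known limitations

* Penetrance is a fixed two-point risk; age-banded liability classes
  and maximum-likelihood penetrance estimation are out of scope.
* Single-proband conditioning is the only ascertainment correction
  offered.
* Looped pedigrees are refused rather than loop-broken.
* The HGVS parser covers the coding-DNA subset used for small germline
  mutations (substitution, del, ins, delins, dup); genomic/protein
  descriptions and UTR/intronic arithmetic are out of scope.
* The cohort emitter writes one VCF dialect (GT:GQ:DP:ADF:ADR with
  GENE/CHGVS/CSQ/DBSNP/HGMD/KPATH INFO keys); the reader requires GT,
  DP, ADF, ADR and falls back to site QUAL when GQ is absent.
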