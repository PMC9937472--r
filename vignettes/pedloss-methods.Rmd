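---
title: "Family-based variant prioritization for pregnancy-loss cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization for pregnancy-loss cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedloss)
library(data.table)
```

## The problem

One to two percent of couples experience recurrent pregnancy loss, and in
over half of them no cause is found. When whole-genome sequencing is
available for an entire family — both parents, the losses (products of
conception), and healthy live-born siblings — candidate variants can be
prioritized by how they travel through the pedigree. A lethal allele may
arise de novo in the conceptus; it may be inherited dominantly from a
carrier parent; two healthy carrier parents may each contribute one
damaged copy of the same gene (a compound heterozygote disrupting both
copies); or a carrier mother may transmit an X-linked recessive allele
expressed in a hemizygous son. pedloss implements this analysis as a
tested, reusable pipeline, together with a synthetic cohort generator so
that every stage can be exercised and scored without access to any
private patient data.

Losses are stratified into developmental epochs by gestational age,
because etiologies differ across development: embryonic loss below 10
completed weeks, fetal death from 10 to just under 20 weeks, and
stillbirth at 20 weeks or later. The epochs partition all gestational
ages; the 20-week boundary belongs to stillbirth (a 20-week demise is a
stillbirth) and the 10-week boundary to fetal death. Internally ages are
compared in total days (`7 * weeks + days`), so `9w6d` (69 days) is
embryonic and `10w0d` (70 days) is fetal.

## Inputs

* A multi-sample VCF 4.2 with per-sample `GT` (required) and `GQ`, `DP`,
  `AD` (optional), and per-variant annotations: gene symbol, impact
  class, gnomAD and TopMed allele frequencies, gnomAD homozygote count,
  pLI, LOEUF, spliceAI. Annotation INFO key names differ between
  annotation tools, so they are config-mapped
  (`default_config()$annotation_keys`) rather than hard-coded.
  Multi-allelic records are decomposed on read: the record of alt allele
  *k* counts alleles equal to *k* as alt and everything else as ref,
  which conserves each sample's total alt dosage across the decomposed
  records. Missing annotation stays `NA` everywhere — a variant absent
  from gnomAD is *not* a variant observed at frequency zero.
* A pedigree in an extended PED dialect: the six standard columns plus
  `outcome` (`parent` / `live_birth` / `loss`) and gestational age as
  `<W>w<D>d`. A loss without a gestational age is rejected, because its
  epoch cannot be assigned. A ninth optional column `sampled` (1/0)
  records whether a WGS sample exists, so conceptuses without DNA can
  still be part of the family record; the two extension columns alone
  cannot express that distinction.

## Sample QC: the sex-concordance check

Sample swaps and contamination are detected by comparing
genotype-inferred sex with the pedigree. The statistic is the
heterozygous fraction among a sample's **alt-bearing** X genotypes
(het / (het + hom_alt + hemi_alt)), not among all genotyped X sites: a
site that is reference-homozygous in a sample carries no information
about its sex, and with a realistically rare-skewed frequency spectrum
the all-sites fraction would sit uncomfortably close to any fixed
threshold for true females. A female carries most of her rare X alleles
heterozygously (fraction near 1); a hemizygous male can carry none
(fraction 0). Defaults: female above 0.1, male below 0.02, otherwise
unknown; at least 200 genotyped and 20 alt-bearing X sites are required,
else the sample is reported unknown with a warning (never a hard
failure). Unknown inferred or recorded sex is concordant by default;
discordant samples are flagged for exclusion. The thresholds are
deliberately conservative and configurable — the check is a stand-in for
whatever QC the sequencing pipeline provides upstream.

## The inheritance engine

Every (variant, offspring) pair in a family with both parents sampled is
classified from the trio genotypes; offspring include live births,
because the loss-versus-live-birth contrast downstream needs their
calls. Families without both sampled parents are skipped with a logged
reason.

* **De novo**: child heterozygous (hemizygous-alt on the male X), both
  parents reference. A quality gate separates confident calls:
  child GQ >= 20; DP >= 10 in all three members; child allele balance in
  [0.2, 0.8] (lower bound only for hemizygous calls, where balance is
  expected near 1); and zero alt-supporting reads in either parent.
  Missing quality fields fail the gate — a de novo claim demands positive
  evidence (fail-closed), while inherited calls tolerate missing quality
  (fail-open). Gate outcomes are recorded in `quality_pass` rather than
  silently dropping calls.
* **Autosomal dominant**: child het, exactly one parent het, the other
  reference, so the parent of origin is unambiguous. Sites where both
  parents carry the allele are not called: origin would be ambiguous and
  such sites inflate counts without adding interpretable signal.
* **Compound heterozygote**: two child-het sites in one gene, one
  inherited from each parent. Without read-backed phasing, trans
  configuration is asserted only when parental carriage is disjoint:
  at each site exactly one parent carries the allele and the carrying
  parents differ between sites. A parent het at both sites cannot
  exclude the cis configuration, so such sites are quarantined to a side
  table, not called. In genes with more than two phasable sites, each
  member call records the gene's first opposite-origin site as its
  partner (one call per variant-sample-mode).
* **X-linked recessive**: a hemizygous-alt son with carrier (het) mother
  and reference father (origin: mother), or a homozygous-alt daughter
  with carrier mother and hemizygous-alt father (origin: both, recorded
  `ambiguous`). Children of unknown sex are not called on the X.

Precedence makes the per-(variant, sample) mode assignment disjoint —
`de_novo` over `comp_het` over `autosomal_dominant`. A compound-het
member always also matches the dominant genotype pattern (child het, one
het parent), so without precedence every pair would be double-counted;
with it, mode counts partition the call set, which the reporting module
relies on. Homozygous-alt children on autosomes are outside the four
modes and are not called.

## The prioritization ladder

Candidacy requires rarity and impact; all further criteria are recorded
as flags so that reports can select without re-running the pipeline:

* `is_rare` — every available population frequency strictly below the
  ceiling (default 0.001; the compound-het ladder has its own ceiling,
  `af_max_comphet`, because biallelic hypotheses tolerate slightly more
  common alleles). Missing frequency counts as 0: a novel allele is
  maximally rare. The boundary fails (`AF = 0.001` is not `< 0.001`).
* `is_impactful` — impact in {missense, frameshift, in-frame indel,
  stop gained, stop retained, splice region}.
* `loss_only` — at least one pregnancy-loss carrier and no live-birth
  carrier, cohort-wide, at genotype level (any alt-bearing genotype
  counts regardless of mode bookkeeping, and a live-birth carrier in any
  family refutes a lethality hypothesis). Parents do not enter the
  contrast. Removing a live-birth carrier can therefore only switch the
  flag on, never off.
* `is_pathogenic` — the gene is loss-of-function intolerant on both
  constraint metrics: pLI > 0.9 and LOEUF < 0.36, strictly. Missing
  constraint fails. Note the deliberate asymmetry with rarity: rarity is
  an inclusion filter where absence of evidence is evidence of absence
  (panels are deep), while pathogenicity is an assertion that needs
  support.
* `control_hom_absent` — no homozygote in population controls
  (`gnomAD hom count = 0`); for a compound-het member the partner must
  be clean too, since one control homozygote refutes the
  biallelic-lethality hypothesis for the pair. Missing counts are
  treated as 0 with a caveat flag.
* `in_phenotype_genes` — membership in an optional user-supplied gene
  list (one symbol per line); an empty list disables the filter.

All flags are pure functions of the inputs: recomputation, in any order,
is bit-identical.

## Enrichment statistics

**De novo LoF burden.** The observed total of quality-passed de novo
loss-of-function calls (frameshift, stop gained, splice region;
configurable) across the loss samples is compared with a per-sample
background expectation: one-sided Poisson,
`p = P(X >= observed)` with `X ~ Poisson(rate * n_samples)` — the
simplest model consistent with asking whether the observed mean exceeds
the expected mean. The expected rate is a required input (default 0.2
per sample); the package does not derive it, because any such derivation
depends on a mutation-rate model out of scope here. A seeded Monte-Carlo
variant (`method = "permutation"`) is provided as a robustness check.
`simulate_null_burden()` draws replicate cohorts under the null so the
test's type-I error can be estimated empirically; at the default
conditions (rate 0.2, 6 samples, 1000 replicates) it sits at or below
the nominal 0.05 within Monte-Carlo error, as expected for a discrete,
conservative tail test.

**Gene recurrence.** The statistic is the number of genes hit by more
than one de novo protein-altering call. The null redistributes the calls
uniformly (optionally weighted by a user-supplied length/mutability
vector) over a gene universe, and the p-value uses the add-one
convention, `p = (1 + #{perm >= obs}) / (1 + B)`, so its minimum is
`1/(1+B)` and it is never zero. Seeded, hence bit-reproducible.

**Proportion tests.** Two-sided 1-df Pearson chi-squared (continuity
correction off by default, switchable) on 2x2 tables comparing the share
of candidate SNVs in each mode between losses and live births, via
`stats::chisq.test`.

## The synthetic cohort generator

The generator emulates the study design end to end: by default three
families, each with two parents, two live births, and four sampled
losses (a stillbirth at 20w0d and fetal deaths at 15w6d, 16w0d and
13w6d, all male), plus an unsampled female embryonic loss at 6w6d so the
pedigree contains a conceptus without a sample. Each sampled loss
carries planted variants realizing every mode exactly: 4 de novo (impact
distribution putting half its mass on LoF classes, so the expected de
novo LoF mean per loss is 2 against the 0.2 background expectation), 2
dominant (alternating transmitting parent), 1 compound-het pair (one
site from each parent in a shared gene), and 1 X-linked recessive
(sex-consistent hemizygous pattern). All planted sites are rare,
impactful, absent from control homozygotes, and carried by no live
birth; half sit in constrained (pLI/LOEUF-pathogenic) genes.

The background (default 10,000 sites, 10% on X) draws annotations from
configurable spectra: allele frequency as a mixture of a novel component
(missing AF, 10%), a common component (uniform on 0.01–0.5, 30%), and a
rare Beta(0.5, 50) component; impact dominated by missense and `other`;
a 10% fraction of constrained genes. Parental genotypes are drawn
**conditioned on at least one alt allele among the cohort's parents**
(truncated-binomial allele count placed uniformly over the parental
allele slots, X-aware): a cohort VCF only contains sites somebody
carries, and without this ascertainment a realistic rare spectrum would
make rare background carriage — and hence live-birth candidate calls,
the loss-only contrast, and the proportion tests — essentially empty.
Offspring genotypes are Mendelian random transmissions (sons receive
their X from the mother; daughters receive the father's X allele
deterministically).

Genomic coordinates are synthetic (chr1, chr2, chrX with gene intervals
`GENE0001...`); REF/ALT bases are drawn uniformly, since no stage of the
pipeline touches sequence context. A configurable set of autosomal genes
(default 60) is reserved for planted variants and excluded from
background placement, so a planted site's gene context — and therefore
its partner structure and flag ledger — is fully determined by the
design; within a child, each planted autosomal event gets its own
reserved gene. Requesting more planted events than reserved genes is a
generation error naming the constraint.

Two noise processes are available, both off by default. A uniform
genotype-error process replaces genotypes at a configured rate. An
FFPE-style artifact process injects false heterozygous calls **only into
loss samples** (placental DNA from formalin-fixed blocks is degraded;
buccal-swab live births are not), at background autosomal sites where
the sample is reference, with an odds multiplier (default 4) toward
C>T/G>A substitutions mimicking cytosine deamination. Artifact allele
balance is drawn from Unif(0.08, 0.35), deliberately straddling the
de novo gate's 0.2 lower bound: some artifacts are caught by the gate,
some pass and become false de novo candidates — the qualitative failure
mode the artifact model exists to reproduce. Artifacts can also land on
sites where a parent happens to be a carrier, creating false inherited
calls, which mirrors the behaviour of real degraded samples.

### Ground truth and how recovery is scored

The generator emits, besides the VCF/pedigree, a per-variant truth table
(planted mode or `background`, target sample, flag ledger) and an
**expected-call table derived from its internal, noise-free dosage
matrices for all variants**. The reason the expected calls cannot be
"planted variants only": background sites realize genuine inherited-mode
configurations by Mendelian chance (one het parent transmitting *is* an
autosomal-dominant configuration), and those are correct calls, not
false positives. The derivation runs inside the generator on arrays the
VCF path never sees, so set equality between engine output and expected
calls exercises the whole write–read–classify chain. Recovery is
scored per mode on (variant, sample, mode, parent-of-origin); under
artifact noise, planted-site recovery is the stable metric (artifacts
never touch planted sites), while cohort-wide inherited precision
degrades realistically.

What the generator does **not** emulate: linkage disequilibrium,
read-level evidence (no FASTQ/BAM), mosaicism, multi-generation
pedigrees, sequence context, fragment-length effects of FFPE, or
gene-specific mutation rates. Passing tests therefore demonstrate the
correctness of the classification, filtering, counting and testing
machinery under the stated genotype-level model — not robustness to
alignment or calling artifacts beyond the simple noise processes above.

## Numerical and design choices

* Coordinates are 1-based fully closed throughout, as in VCF.
* Continuous annotations are generated at 6 significant digits and
  printed as such, so VCF round-trips are exact (`identical`, not just
  approximately equal).
* Diploid-coded male X calls are normalized to hemizygous on read;
  mixed het male X calls are kept as het and never satisfy a calling
  pattern.
* Records on contigs outside the configured whitelist are skipped and
  counted; a pedigree sample missing from the VCF is an error, an
  unparseable annotation degrades to missing.
* Ties and boundaries: all filter thresholds are strict inequalities;
  the epoch boundaries assign 70 days to fetal death and 140 days to
  stillbirth.
* Seeds: every stochastic routine (generator, permutation tests, null
  replicates) takes an explicit seed and restores the caller's RNG
  state, so pipelines are reproducible byte for byte.
* Test problem sizes: the recovery suite uses 3 families, 60 planted
  variants per mode (72 compound-het SNVs) over a 10,000-site
  background; calibration uses 1000 null replicates of 6 samples;
  statistical examples use 1000–20,000 permutations. These sizes keep
  each property estimable with comfortable Monte-Carlo margins while
  the full suite runs in about a minute.

## Known limitations

* Trio/quad logic only: no multi-generation pedigrees, no Y-chromosome
  logic, no pseudo-autosomal-region handling on the synthetic X.
* Comp-het phasing is carriage-based; read-backed phasing would rescue
  the quarantined ambiguous pairs and is out of scope.
* The burden test's expected rate is consumed, not derived; no
  gene-specific mutation-rate model (denovolyze-style) is included
  beyond the optional weight vector of the recurrence test.
* The filtering ladder consumes annotations; it computes none (no
  ACMG/ClinVar logic, no in-silico effect prediction).
* Hom-alt autosomal children (classical autosomal-recessive
  homozygotes) are outside the four modes and are only visible in the
  genotype tables, not the call set.
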