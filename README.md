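# pedloss

Family-based variant prioritization for recurrent pregnancy-loss cohorts.

When whole-genome sequencing covers a full family — both parents, the
products of conception (losses), and healthy live-born siblings —
candidate lethal variants can be prioritized by mode of inheritance.
pedloss classifies every variant × offspring pair from parental
genotypes into:

* **de novo** — child het (hemizygous-alt on the male X), both parents
  reference, behind a quality gate (GQ ≥ 20, DP ≥ 10 in all trio
  members, child allele balance in [0.2, 0.8], zero parental alt reads);
* **inherited autosomal dominant** — child het with exactly one het
  parent, so the parent of origin is unambiguous;
* **compound heterozygous** — two het sites in one gene, one from each
  parent; trans phase is asserted only when parental carriage is
  disjoint between the sites, otherwise the pair is quarantined;
* **X-linked recessive** — hemizygous-alt son with carrier mother (or
  homozygous-alt daughter with carrier mother and hemizygous-alt
  father).

Calls then pass a prioritization ladder: population rarity
(gnomAD/TopMed AF < 0.001, missing = novel), protein-altering impact
(missense, frameshift, in-frame indel, stop gained/retained, splice
region), a cohort-wide loss-versus-live-birth carriage contrast,
loss-of-function constraint (pLI > 0.9 and LOEUF < 0.36), absence of
control homozygotes (for compound hets, both pair members), and an
optional phenotype gene list. The statistical layer tests the de novo
loss-of-function burden in losses against a per-sample expected rate
(one-sided Poisson, `p = P(X ≥ observed)` with
`X ~ Poisson(rate · n)`), gene recurrence of de novo protein-altering
calls (seeded permutation test, add-one convention), and per-mode 2×2
chi-squared contrasts between losses and live births.

Pregnancy losses are stratified by gestational age into embryonic loss
(< 10 weeks), fetal death (10 to < 20 weeks) and stillbirth (≥ 20
weeks); the pedigree dialect carries pregnancy outcome and gestational
age alongside the six standard PED columns.

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates the
three-family study design — 2 parents, 2 live births, 4 sampled losses
per family — with planted variants under every mode, configurable
allele-frequency/impact/constraint spectra, and optional genotype-error
and FFPE-artifact noise, emitting ground-truth tables so the whole
pipeline is testable without external data. See the methods vignette
(`vignettes/pedloss-methods.Rmd`) for the models, conventions, and
limitations.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort (each stage writes its tables under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R     # cohort VCF + pedigree + truth
Rscript analysis/02_classify_inheritance.R
Rscript analysis/03_prioritize.R
Rscript analysis/04_reports.R
Rscript analysis/05_enrichment.R
```

Stage 1 simulates 3 families (24 sampled individuals: 12 losses, 10,108
variants of which 108 are planted). Stage 3 prints the filter ladder —
3,947 candidate calls survive the rarity/impact gate, 749 are carried by
losses only, 115 of those sit in constrained genes, and 80 also have no
control homozygote:

```
                                                     step n_calls n_snvs
1:                                                    all    3947   1397
2:                                                   rare    3947   1397
3:                                         rare+impactful    3947   1397
4:                               rare+impactful+loss_only     749    413
5:                    rare+impactful+loss_only+pathogenic     115     86
6: rare+impactful+loss_only+pathogenic+control_hom_absent      80     73
7:                                            full_ladder      80     73
```

and recovery against the simulator's expected-call table — sensitivity
and precision 1.0 in every mode on this error-free cohort:

```
                 mode n_expected n_observed n_correct sensitivity precision
1: autosomal_dominant       2125       2125      2125           1         1
2:           comp_het      29604      29604     29604           1         1
3:            de_novo         48         48        48           1         1
4: x_linked_recessive       1897       1897      1897           1         1
```

Stage 4 tabulates candidate SNVs (and distinct genes) by family and
loss epoch, with a total row deduplicated across families, plus the
clinical-style compound-het table (`Male stillbirth (20 weeks)`,
variant, impact, gene, pair). Stage 5 prints the enrichment statistics:

```
De novo LoF burden: 21 calls in 12 samples (mean 1.75 vs expected 0.20); one-sided poisson p = 1.922e-13
gene recurrence: 12 genes with >1 de novo protein-altering SNV, p = 1e-04
burden test type-I error at alpha = 0.05 under the null: 0.031
```

The planted design puts 4 de novo calls per loss with half their impact
mass on loss-of-function classes, so the observed mean near 2 per loss
against the 0.2 expectation — and the tiny burden p-value — is the
planted signal being recovered, and the null type-I error shows the test
is calibrated (conservative) under its own null.

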