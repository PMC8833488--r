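# lofseg

Pedigree-aware prioritization of rare germline loss-of-function (LOF)
variants in cancer families, for statistical geneticists and clinical
bioinformaticians working on autosomal-dominant predisposition screens.

Family studies of colorectal cancer (CRC) sequence a handful of affected
relatives per pedigree and ask which rare variants *segregate* with the
disease. `lofseg` implements that analysis as a reusable, tested
pipeline:

- **Pedigrees with phenotype events.** An extended PED dialect records
  CRC, polyp and other-cancer diagnoses with ages. Members are assigned
  study roles: CRC diagnoses are *cases*; polyp carriers, and unaffected
  offspring of a case younger than the family's earliest CRC onset, are
  *possible carriers* (unconstrained); adequately observed unaffected
  members are *controls*. Married-in spouses are recognized as non-blood,
  so an affected spouse (a phenocopy) does not invalidate segregation.
- **Variant filtering.** Annotated multi-sample VCFs are filtered on
  QUAL > 20, per-genotype depth ≥ 5, population allele frequency < 0.1%,
  and a local-cohort carrier frequency < 5% (technical-artefact guard).
- **Dominant-model segregation.** A variant segregates in a family when
  every genotyped blood case carries it, no genotyped control does, and
  at least one case carrier exists:

  &nbsp;&nbsp;&nbsp;&nbsp;pass ⇔ (#{blood cases without allele} = 0) ∧
  (#{controls with allele} = 0) ∧ (#{case carriers} ≥ 1)

  LOF classes are stop-gain, frameshift and canonical ±1/2 splice
  variants; last-exon (NMD-escaping) and non-coding-transcript hits are
  excluded, and candidates are tiered by CADD PHRED (>20 = top 1%,
  >30 = top 0.1%).
- **Molecular consequence.** A maximum-entropy 3′ splice-site model
  (23-mer acceptor windows, nine joint submodels combined by
  inclusion–exclusion, log₂ odds vs background) scores canonical and de
  novo acceptors; acceptor shifts become transcript edits, and CDS edits
  become HGVS protein consequences (`p.Lys2Asnfs*2`, `p.Lys2del`, …).
- **Association.** Carrier case–control 2×2 tables with the odds ratio
  OR = ad/bc and the Woolf interval exp(ln OR ± z·√(1/a+1/b+1/c+1/d)).
- **Cohort simulator.** Mendelian multi-generation families with an
  age-gated penetrance model, planted novel LOF variants, phenocopies in
  married-in spouses, background variants with Beta-distributed
  population frequencies, an unrelated local reference panel, and
  incomplete genotyping — emitted as PED + VCF + gene models + CDS FASTA
  with a ground-truth table, fully reproducible from one seed.

## Worked example

```r
library(lofseg)

cfg    <- noiseless(sim_config(n_families = 15, seed = 42))
cohort <- simulate_cohort(cfg)
res    <- run_prioritization(cohort$variants, cohort$families)
head(res$candidates[, c("variant", "gene", "lof_class", "cadd_phred",
                        "cadd_tier", "families")], 5)
#>            variant     gene        lof_class cadd_phred cadd_tier families
#> 1    1:5387895:G:T SGENE001 canonical_splice       32.5 top0.1pct      F01
#> 2 10:50042852:AC:A SGENE010       frameshift       35.9 top0.1pct      F10
#> 3 11:55051071:CC:C SGENE011       frameshift       37.0 top0.1pct      F11
#> 4  12:60812110:G:T SGENE012 canonical_splice       37.9 top0.1pct      F12
#> 5  14:70429247:C:T SGENE014        stop_gain       34.2 top0.1pct      F14
```

Each of the 15 planted variants is recovered by exactly its own family
(`res$candidates` has one row per planted variant; `res$trail` holds the
per-filter audit for every variant, including the ~300 rejected
background variants). With the generator's default noise model (sporadic
cases, silent carriers, per-call missingness) recovery drops to roughly
half the families — the realistic yield of such screens.

Carrier association for a variant seen in 5 of 1705 familial cases and
2 of 1674 healthy elderly controls:

```r
carrier_association(contingency_2x2(5, 2, 1700, 1672))
#>   a b    c    d odds_ratio     lower    upper level
#> 1 5 2 1700 1672   2.458824 0.4763847 12.69103  0.95
```

i.e. OR 2.46, 95% CI 0.48–12.69: an enrichment in cases that does not
reach significance at these carrier counts.

A thin command-line wrapper lives at `inst/cli/lofseg.R`
(`simulate`, `prioritize`, `associate`, `run-all` subcommands).

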