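---
title: "Family-based prioritization of loss-of-function variants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based prioritization of loss-of-function variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofseg)
```

`lofseg` implements the variant-prioritization arm of a family-based
germline screen for autosomal-dominant cancer predisposition: pedigrees
with a strong aggregation of colorectal cancer (CRC) are sequenced in a
few affected members, and rare loss-of-function (LOF) variants are kept
when their carriage pattern is consistent with dominant transmission of
a single causal allele. This vignette explains the models, the tunable
parameters and the design decisions, in the order the pipeline applies
them.

## Roles in the segregation model

Each family member receives exactly one role, derived from recorded
phenotype events:

* **case** — a CRC diagnosis (one per member, with age).
* **possible carrier** — a colonic-polyp diagnosis, or an unaffected
  offspring of a case who is younger than the family's youngest CRC
  onset. Adenomas are on the causal path to CRC under surveillance
  colonoscopy, and a member who has not lived through the family's risk
  window carries no information either way; both are left
  *unconstrained* by the filter.
* **control** — an unaffected member observed adequately: either an
  explicit negative colonoscopy on record, or a known age at or beyond
  the family's youngest CRC onset. We deliberately extend the
  "has not yet reached the youngest onset age" reasoning from the
  possible-carrier rule to the control definition: a 35-year-old
  unaffected member of a family whose cases present in their 40s is not
  evidence against carriage, so using them as a control would be an
  error in exactly the situations the screen cares about.
* **uninformative** — everyone else, including members with a
  non-colorectal cancer and no colonoscopy record (their colorectal
  status is simply unknown; with a negative colonoscopy they are
  controls for the colorectal model). Members with no events and no
  recorded age are never controls.

**Blood membership.** The dominant model constrains only the biological
lineage. We define the lineage founders as the parentless member(s) with
the most CRC-case descendants (self included) and close the set
downward over parent links; every other parentless member is a
married-in spouse. An affected spouse — a *phenocopy* — is thereby
exempted from the carrier requirement and reported separately in each
verdict, rather than sinking an otherwise perfectly segregating
variant. This rule is deliberately stronger than "ancestor of a case":
a married-in spouse remains exempt even when one of their children is
affected, because the variant under test descends from the lineage
founder, not from the spouse.

## The filter cascade

For each variant, in order (the candidate *set* is invariant to the
order of the variant-level filters; only the audit trail changes):

| filter | rule | default |
|---|---|---|
| QC | record QUAL strictly > `min_qual`; genotypes with depth < `min_depth` become missing | 20; 5 reads |
| local cohort | carrier fraction among all genotyped samples < `max_local_af` (recurrent technical artefacts) | 5% |
| population | max allele frequency over reference panels < `max_pop_af` | 0.1% |
| LOF class | stop-gain, frameshift, canonical ±1/2 splice | — |
| gene position | exclude last-exon (NMD escape) and non-coding-transcript annotations | — |
| segregation | per family: all genotyped blood cases carry, no control carries, ≥1 case carrier | — |
| CADD tier | annotate: >30 top 0.1%, >20 top 1%, else below 20 | — |

Boundary directions mirror the screening design (strict `>` for QUAL,
`≥` for depth, strict `<` for the frequency ceilings) and are fixed in
`qc_thresholds()`. Missing genotypes are unconstrained everywhere. The
local-cohort filter counts *carriers*, not alleles, consistent with the
dominant model. A variant qualifies when any protein-coding transcript
annotation passes the LOF and position rules (most-damaging-transcript
logic); splice-site annotations are expected to carry the affected
(downstream) exon's index, so a canonical acceptor of exon 2 of 25 is
retained while a last-exon stop-gain is not. Candidates are ranked by
CADD tier, then number of passing families, then coordinate — a
deterministic order. The final step of a real screen, manual literature
review, is out of scope by design: the pipeline ends at the ranked,
audited candidate list.

## Splice-site model

The 3′ acceptor model scores 23-mer windows (20 intronic nt ending in
the near-obligate AG, then 3 exonic nt) as log₂ odds of a
maximum-entropy distribution of true acceptors against background
composition. Following the published model layout, the two AG positions
are scored by consensus/background nucleotide odds and the remaining
21-mer by nine joint submodels over overlapping position subsets
combined by inclusion–exclusion (five numerator blocks of 7 nt, four
denominator blocks of 3–4 nt). The loader reads the published
distribution's file layout (one float per k-mer in base-4 lexicographic
order) as well as a sparse two-column down-sampled form; table values
may be genuine probabilities (the scorer divides by background) or the
distribution's precombined probability/background ratios
(`tables_are_ratios = TRUE`). The package ships no model tables: they
are user-supplied input (`inst/extdata/reference/README.md`), and the
synthetic uniform model — every submodel uniform, consensus equal to
background — provides the closed-form reference point at which every
window scores exactly 0, used throughout the tests.

`scan_de_novo_acceptors()` slides the window over all offsets within a
radius of the canonical intron end and scores every AG-bearing
position. When a variant destroys the canonical acceptor and the best
alternative lies *k* nucleotides downstream inside the exon, the spliced
transcript loses the exon's first *k* nucleotides
(`predict_splice_outcome()`); upstream or intronic alternatives (exon
extension, intron retention, skipping) are reported as unsupported
rather than guessed, because a shifted downstream acceptor is the only
outcome the package can state in CDS coordinates without a full splice
graph.

## Protein consequences

`protein_consequence()` applies a CDS edit, translates both sequences
(Biostrings), and reports HGVS three-letter notation. Frameshifts are
`p.<Ref><pos><New>fs*N`, where the position is the first codon whose
residue changes and `N` counts the termination codon of the new frame
with that first changed residue as 1 — so a truncation "17 codons
downstream" of Ser9 is `p.Ser9Leufs*17`. A first changed codon that is
itself a stop is a nonsense call; a shifted frame that never terminates
is reported as `no_stop` (`fs*?`). In-frame deletions that remove whole
codons get `del` notation, other in-frame changes a best-effort
`delins`; edits of length ≡ 0 (mod 3) can never be frameshifts. The
test suite checks the caller against an independent translator (a
seqinr-based codon walk written separately) on 1000 random CDS/deletion
pairs.

## Association

For a single variant, carriers are counted in disjoint case and control
sample sets (dominant model: a homozygote counts once; missing
genotypes drop out of the totals) and summarized by the odds ratio
`ad/bc` with the Woolf log-normal interval
`exp(ln OR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`; the normal quantile is
computed, not hard-coded, so any level works. Zero cells raise an
explicit error by default — the optional Haldane–Anscombe +0.5
correction must be requested (`correct = TRUE`), because silent
corrections hide data problems. On the motivating screen's counts
(5/1705 cases vs 2/1674 controls) this reproduces OR 2.46 with 95% CI
0.48–12.69, and a 10,000-replicate null simulation in the acceptance
suite shows ~95% empirical coverage at n=500 per arm and a 10% carrier
rate.

## The cohort simulator

`simulate_cohort()` generates the study conditions the analysis
assumes, so that every module is testable offline; the protected
whole-genome data of real screens is never consumed. Defaults:

* **Families.** 15 three-generation pedigrees, sibships of
  1 + Poisson(2.5), spouses married in with probability 0.85,
  generation ages ~N(90/63/38, 4). Families are rejection-sampled until
  they hold ≥3 CRC cases among blood members and ≤30 members (the scale
  of drawn clinical pedigrees; the cap also stops the case requirement
  from selecting only enormous sibships).
* **Penetrance.** One founder is a heterozygous carrier; the allele
  transmits with probability 1/2 per meiosis. A carrier develops CRC by
  age 70 with probability 0.8 (onset uniform on 40–70, realized only
  once reached — so "penetrance 1" makes every carrier past the window
  a case, not every young carrier). Adult carriers without CRC show
  polyps with probability 0.5 with detection by their current age
  (surveillance colonoscopy); the remainder are *silent carriers*, a
  deliberate noise channel. Non-carriers develop sporadic CRC at rate
  0.02 and polyps at 0.15; married-in spouses develop phenocopy CRC at
  rate 0.08. The two earliest-onset cases per family are always
  genotyped ("the sequenced pair"); others are genotyped with
  probability 0.8.
* **Variants.** One planted variant per family: a novel (population
  frequency 0 in every simulated source) heterozygous stop-gain,
  frameshift or canonical-acceptor allele in an internal exon of a
  protein-coding transcript, CADD drawn from 25–44; each planted gene
  gets a synthetic ATG-initiated CDS whose shifted reading frames are
  guaranteed to contain stops, so frameshift consequences are exercised
  end to end. 300 background variants draw frequencies from
  Beta(0.2, 50), mixed consequence classes, arbitrary exon positions
  and occasional low QUAL. A panel of 200 unrelated local reference
  individuals joins the VCF: the 5% artefact filter is defined against
  a sequencing center's local datasets, and without unrelated samples a
  single large pedigree could push its own private variant above the
  threshold — a modeling artifact, not a property of the screen.
* **Noise and truth.** Genotype errors and per-call missingness at the
  planted site are configurable (defaults 0 and 0.02). `noiseless()`
  zeroes the channels that can legitimately defeat segregation —
  sporadic cases, silent carriers, genotype errors, call missingness —
  and under it planted-variant recovery is exact *by construction*,
  which is what the end-to-end acceptance check asserts. Under default
  noise, recovery falls to roughly half the families, the yield pattern
  a real screen shows. Everything derives from one seed,
  byte-for-byte: fixture bundles carry a manifest with the
  configuration and per-file MD5s.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype structure, recombination maps, population demography,
relatedness across families, realistic per-base sequencing error
profiles, or CNVs. Passing tests on simulated cohorts therefore
validate the *filtering logic* under Mendelian transmission and the
stated noise channels — not calling accuracy on real reads, nor the
biological prior that the planted gene is causal.

## Numerical and degenerate-input choices

* Score arithmetic in log₂ space; submodel evaluation order is
  irrelevant to 1e-9 and the scan at offset 0 equals the direct
  canonical score exactly.
* A family with no genotyped blood case cannot pass segregation (it has
  no evidence), reported with its own reason code.
* Exonic consequences whose exon cannot be located are excluded as
  `unlocatable` — conservative, since the last-exon rule could not be
  checked.
* Multi-allelic VCF records are decomposed per ALT allele; annotation
  entries follow their allele; `Number=A` INFO fields are split
  positionally.
* Candidate ties are broken by (CADD tier, passing families, genomic
  coordinate) for deterministic output.
* Problem sizes in the acceptance suite — 15 families (~450 samples,
  ~315 variants), 3⁸ = 6561 genotype vectors, 1000 CDS pairs, 10,000
  interval replicates — were chosen to exercise the study-scale
  configuration while keeping a complete run in the low tens of
  seconds.

## Known limitations

* The segregation model is strictly autosomal-dominant: no recessive or
  compound-heterozygous models, no X-linked handling, no LOD-score
  linkage.
* The splice model covers 3′ acceptors; donor-site (5′) scoring is not
  required by any analysis here and is not implemented.
* HGVS output covers the consequence classes the pipeline produces
  (frameshift, nonsense, in-frame del/ins, synonymous); it is not a
  general HGVS engine.
* Reproducing published maximum-entropy scores requires the published
  model tables and reference sequence as user-supplied files; the
  package never downloads, and the corresponding integration checks
  report failure until those files are provided.
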