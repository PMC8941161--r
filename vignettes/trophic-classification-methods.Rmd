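---
title: "Methods: trophic classification of sponge symbionts and the radiotracer carbon budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trophic classification of sponge symbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongetroph)
```

## The inference problem

Sponge microbiomes mix trophic strategies: a minority of symbionts fix
inorganic carbon (CBB, rTCA or 3-HP/4-HB cycles), many more are
lithoheterotrophs that respire organic carbon but draw energy from
inorganic donors — above all carbon monoxide via the aerobic
molybdenum-dependent CO dehydrogenase (Mo-CODH) — and the rest are plain
organoheterotrophs. None of this is observable directly from a MAG; it is
inferred from the gene complement. `spongetroph` formalises that inference
as a rule system over merged KO + COG + HMM evidence and keeps every rule
in an editable YAML file, because marker lists are knowledge, not code.

## Evidence model

A MAG's evidence set is the union of its KO accessions, COG accessions and
HMM models that passed their per-model bit-score cutoffs. Three choices
matter:

* **Gene identity is preserved across sources.** A gene annotated both as
  K03520 (KO) and COG1529 (COG) is one gene with two evidence tags; gene
  counts are never inflated by multi-source annotation.
* **HMM filtering happens at ingestion.** A record whose score falls below
  its model's threshold never reaches the index, so no downstream rule can
  resurrect it. The shipped thresholds are placeholders: score cutoffs are
  calibrated per HMM collection and must be overridden for real analyses.
* **Conflicting KO assignments all survive.** The same CoxL-like gene may
  legitimately re-annotate to different substrate KOs; pathway rules, not
  ingestion, decide which assignments matter.

## Pathway rules and the lifestyle decision

A pathway is a set of gene symbols, each a disjunction of accessions, plus
a rule (`all_of`, `any_of`, `k_of_n`). Completeness is the matched
fraction of gene symbols; presence applies the rule. The lifestyle
decision is a fixed precedence:

1. any complete fixation pathway → autotroph (`autotroph_CBB` when CBB is
   among them, else `chemoautotroph_other`);
2. else any complete inorganic-energy pathway → `lithoheterotroph`;
3. else `organoheterotroph`.

One dominant lifestyle per MAG, with fixation capacity overriding energy
capacity, matches how these communities are summarised in practice.
Capability flags (CO oxidation, thiosulfate oxidation, H₂, arsenite,
ammonia/nitrite/methane oxidation, anaplerotic carboxylation, PFOR
fermentation) are set independently of the label, so a CBB autotroph that
also oxidises CO keeps both facts.

Deliberate asymmetries and special cases:

* **Mo-CODH is strict on genomes.** Genomic CO-oxidation potential
  requires all four subunits *coxSMLG*; expression analysis separately
  tolerates a silent *coxG*, since bona fide CO dehydrogenases without it
  are known. `detect_mo_codh()` implements the strict genomic criterion.
* **PFOR never implies rTCA.** Pyruvate:ferredoxin oxidoreductase serves
  non-autotrophic roles; it only sets the `PFOR_fermentation` flag, and
  only when acetyl-CoA synthetase (COG1042) co-occurs.
* **Anaplerotic carboxylases are flag-only.** PYC/PPC/PCKA/MEZ replenish
  TCA intermediates; they never change a lifestyle label.
* **amoABC/pmoABC ambiguity** (ammonia vs methane) is resolved by a
  configurable phylum override table (default: Thaumarchaeota → ammonia,
  Desulfobacterota → methane, otherwise ammonia), because the distinction
  is a sequence-similarity judgement the rule system cannot make.
* **MAG completeness never alters a call.** It is reported alongside, but
  a 62%-complete genome is classified on what it shows; incompleteness is
  quantified instead by the dropout analysis below.
* **Nickel-CODH** (the anaerobic Wood–Ljungdahl marker) is screened by
  `check_wl_absence()`; in this system the expected report is empty, and a
  non-empty one is a red flag worth manual review.

The shipped accession lists (`inst/extdata/pathways.yaml`) are provisional
defaults from standard KEGG/COG usage — e.g. CBB = rbcL (K01601) +
phosphoribulokinase (K00855), rTCA = ATP-citrate-lyase markers + PFOR —
and are meant to be replaced by curated lists for production use.

## CoxL (COG1529) partitioning

The substrate of a CoxL-like protein is not determined by the COG
assignment: the orthologous group spans CO, xanthine, nicotinate,
isoquinoline and other dehydrogenase large subunits. The package
partitions members by **single-linkage clustering at a percent-identity
threshold** (connected components of the ≥ threshold graph, default 50%),
a deliberately simple and fully reproducible definition of
"sequence-based clustering": it is oracle-checkable (the test suite
compares it to brute-force transitive closure), idempotent,
order-invariant, and monotone — raising the threshold can only refine the
partition. Cluster names are deterministic (smallest member id).

Labels are majority votes over annotated members only; unassigned members
count toward cluster size but not the denominator, ties yield no label.
Per-genome copy numbers use the sample (n−1) standard deviation and
include zero-count genomes of the taxon; a one-genome taxon reports an
undefined SD.

## Expression linkage

Transcript-to-MAG assignment keeps, per transcript and sample, the hit
with the highest bit score among hits passing E ≤ 1e−10 and identity
≥ 55%, breaking ties by lowest E-value and then lexicographic protein id
(the last key exists purely for determinism). Both thresholds are
inclusive. The fraction of transcripts assigned is exposed as a QC
attribute, never used as a filter. Read-support confirmation (≥5 mapped
reads) is optional and applied **per (gene, sample)** — the plausible
alternative, pooling reads across samples, would let one deep sample
confirm expression everywhere.

The expression matrix is binary by design: rows are (function, MAG) pairs
(transcripts with the same function and MAG affiliation merge), a cell
records whether any confirmed transcript supports the pair in the sample.
Prevalence is the row mean; the prevalent-expression flag is inclusive at
the cutoff (0.90 by default, so 36/39 samples qualifies and 35/39 does
not). Row–row association uses Spearman rank correlation with midranks
and the large-sample t approximation for the p-value; on binary rows this
is degenerate (documented, allowed), the intended input is continuous
abundances.

## Radiotracer calculation

The fixed-carbon equation is the standard ¹⁴C primary-productivity form:
per matching cell (experiment × condition × phenotype × section), DPM is
divided by the counted extract fraction and the wet weight, the mean of
live replicates minus the matched kill control gives ΔDPM, and

fixed C (µg g⁻¹) = ΔDPM / tDPM × total Ci × d,

with tDPM the medium's total label activity, total Ci its inorganic
carbon (µg) and d an isotope discrimination factor, default 1.05,
configurable. Normalisation precedes subtraction so that live and kill
cylinders of different weights are comparable. Kill matching is by
condition and phenotype (a pink-light live group subtracts the pink-light
kill), reflecting how kill controls are incubated.

Counting noise can push live below kill; the raw (possibly negative)
value is preserved in `fixed_c_raw` while `fixed_c` clamps at zero with a
warning, so downstream percentages cannot go negative. Note the
corollary: in a true zero-fixation setting the raw estimator is symmetric
around zero and roughly half the replicates clamp — unbiasedness must be
assessed on the raw values, which is what the test suite does.

Light/dark partitioning sums sections within condition; the two shares
sum to 100 exactly whenever total fixation is positive, and a zero total
reports `NA` rather than an arbitrary split. Section gradients use
Spearman correlation of fixed carbon against 1-based 2-mm section depth
(a constant profile is reported as "none" rather than propagating an
undefined coefficient). The dark-turnover experiment is analysed as
per-phase least-squares slopes of medium DPM against time, phases split
at the event times (crush, chemical amendment); release is declared when
the first post-crush reading exceeds the last pre-crush one, and kill
containers are expected flat.

## What the synthetic data emulate — and what they do not

All generators are pure functions of `(config, seed)`; a single master
seed is split into fixed per-generator streams so each fixture is
reproducible in isolation.

* `gen_mag_annotations()` plants a lifestyle per MAG, writes the full
  marker complement of that lifestyle from the active rule set, drops each
  gene i.i.d. with probability `gene_dropout` (the stand-in for MAG
  incompleteness; metadata completeness is set to ~100·(1−dropout)), and
  adds background KOs drawn from a pool disjoint from every rule
  accession. That disjointness makes misclassification provably one-way:
  dropout can only lose evidence, so autotrophs can degrade to litho- or
  organoheterotrophs, never the reverse.
* `gen_coxl_families()` plants families with within-family identity
  (default 85%) far above and between-family identity (default 30%) far
  below the 50% threshold, majority substrate KOs per family with one
  deliberately unassigned family, and lengths from a truncated normal
  (682 ± 207 aa, bounds 35–1250) matching the observed length range of
  COG1529 members.
* `gen_transcript_hits()` emits a passing hit per planted (function, MAG)
  and sample with probability equal to the planted prevalence
  (default functions pckA 0.95, coxL 0.90, rbcL 0.75, mez 0.50 over 39
  samples, mirroring the scale of the real transcriptome panel), plus
  decoys that fail exactly one threshold each.
* `gen_tracer()` inverts the fixed-carbon equation to produce live DPM
  from planted per-section fixation (defaults: light 100/20/5, dark 3/2/1
  µg g⁻¹ across three 2-mm sections — a cortex-concentrated photic
  profile; kill background 100 DPM; tDPM 10⁶; total Ci 25 000 µg; counted
  fraction 0.2; 0.5 g cylinders; 3 live replicates; 2 h incubation) with
  Gaussian noise proportional to the expected count (default SD 5%).

The noise models are deliberately simple — i.i.d. Bernoulli dropout,
i.i.d. Gaussian counting error — and the generators plant no correlation
structure, no contamination, no chimeric bins, no compositional effects.
Passing tests therefore demonstrate that the *logic* is correct and the
estimators recover planted truth under idealised stochasticity; they do
not validate the provisional marker lists against real annotations, nor
the behaviour under structured artefacts real MAGs exhibit.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: 200 MAGs for recovery and
dropout-direction checks, 100 random identity graphs of ≤50 proteins
against the clustering oracle, 200 samples for prevalence recovery
(binomial 3·SE tolerance), 100 Monte-Carlo tracer replicates (2·SE
tolerances against the planted 100 µg g⁻¹ and the zero null). Determinism
is enforced everywhere ties could make output order ambiguous: radix
sorts on identifiers, lexicographic tie-breaks, named deterministic
cluster ids. Degenerate inputs have defined behaviour rather than errors
where a value is meaningful (empty index → empty tables; all-zero
expression row → prevalence 0; constant section profile → no trend) and
errors where silence would corrupt results (duplicate MAG ids, asymmetric
identity entries, missing kill controls, unordered time stamps, negative
read counts).

## Known limitations

* Marker accession lists and HMM thresholds are provisional; lifestyle
  calls are only as good as the rule file supplied.
* Single-linkage components are one defensible reading of "sequence-based
  clustering"; centroid or graph-layout methods would partition borderline
  families differently.
* The package never touches sequences: identity tables, annotation tables
  and hit tables are inputs, produced by upstream tools.
* The read-support threshold is per sample; pooled-read designs need
  their support tables aggregated before input.
* The fixed-carbon constants (discrimination factor, total Ci) are
  user-supplied; no DIC chemistry is modelled.
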