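---
title: "Surveying iron and sulfur metabolism genes across archaeal proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying iron and sulfur metabolism genes across archaeal proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesurvey)
```

## The problem

Archaeal methanogens, methanotrophs, and alkanotrophs have an unusually
high demand for iron and sulfur: their core energy metabolism runs on
[Fe-S]-cluster proteins, F430, and — in some lineages — heme-dependent
cytochromes. Comparative surveys of these lineages ask, genome by genome,
which systems each organism encodes for acquiring Fe(II) (FeoAB),
liberating sulfide from cysteine (SufS), assembling [Fe-S] clusters
(SufBC), and synthesizing and deploying the tetrapyrrole cofactors
siroheme (SirA/SirC), heme b (AhbABCD), and heme c (CcmCF), alongside
iron storage proteins.

`fesurvey` implements that survey as a reusable, testable pipeline over
per-genome predicted proteomes:

1. **Motif scanning** — a small grammar for cofactor-binding sequence
   motifs (heme c `CXXCH` and variants, heme b `GX(H/R)XCXGX`, the
   siroheme / [Fe-S] cysteine clusters `CX4-5CXnCX3C`), scanned exactly
   over every protein.
2. **Tiered homolog classification** — similarity-search hits filtered by
   E-value, query coverage, and percent identity, with a 20–30% identity
   *rescue band* requiring independent domain evidence, stricter
   thresholds for siroheme-destination searches, and operon-synteny
   upgrades for partial hits in incomplete genomes.
3. **Pathway calling** — family bits combined by explicit counting rules
   into pathway features, plus derived flags for heme auxotrophy and
   "siroheme orphans".
4. **Per-taxon summaries** — group prevalence tables and the per-genome
   [Fe-S]-motif proteome fraction.
5. **Ordination** — Jaccard dissimilarity over the presence/absence
   matrix and principal coordinates analysis with per-axis variance
   explained.
6. **A synthetic cohort generator** with planted ground truth, so the
   entire pipeline can be validated end to end without downloading any
   genome.

## Motif grammar and scanner

Motifs are written in the field's shorthand: capital letters are fixed
residues, `X` a single wildcard, `(H/R)` an alternation, `X{4,5}` a
bounded gap, and the literal token `Xn` an open-length gap. Published
motif notation leaves the `Xn` spacer unbounded; a scanner must
terminate, so the open gap is compiled to a bounded `(1, 50)` gap by
default. Fifty residues comfortably spans the cysteine-cluster spacings
observed in sulfite reductases, and the bound is a configuration knob
(`open_gap=`), not a constant.

```{r}
p <- parse_motif("CX{4,5}CXnCX{3}C")
c(p$min_len, p$max_len)
scan_protein("CAAAACAACAAAC", p)
```

Scanning conventions, stated because motif counting depends on them:

* Coordinates are 1-based inclusive residue spans.
* Every distinct start position is reported, including overlapping
  matches; a variable-gap pattern reports **one** match per start, using
  the shortest-gap expansion (leftmost gap minimized first). Downstream
  statistics count *proteins* with at least one match, never match
  multiplicity, so enumerating gap assignments would add nothing.
* Sequence ambiguity codes (`B Z J U O X`) satisfy wildcard and gap
  positions but never a fixed residue or an alternation: an ambiguous
  residue must not manufacture a fixed-anchor hit.

The per-genome **[Fe-S] fraction** is the share of proteins carrying at
least one [Fe-S] motif. The default [Fe-S] library holds the [4Fe-4S]
ferredoxin pattern `CX{2}CX{2}CX{3}C` and the broader cluster
`CX{4,5}CXnCX{3}C`. This is a sequence-motif approximation of
HMM/domain-based [Fe-S] prediction: it captures canonical cysteine
clusters but not structurally diagnosed sites, so absolute fractions on
real proteomes are not comparable with domain-model tools — only
relative, within-pipeline comparisons are meaningful. Note that the
siroheme cysteine cluster is itself an [Fe-S]-type motif (the cofactor
is coupled to a [4Fe-4S] center), so sulfite reductases legitimately
count toward the fraction.

## Homolog classification

Each hit carries E-value, bit score, percent identity, and percent query
coverage — either from the built-in pairwise backend or from an external
BLASTp run ingested as 12-column tabular output. Classification depends
only on those fields, so both routes flow through identical logic.

The tiers, with boundary conventions stated explicitly because published
threshold prose rarely resolves them:

1. `E > 1e-5` → rejected (`evalue`). `E == 1e-5` passes.
2. coverage `<= 30%` → rejected (`coverage`); coverage must exceed the
   cutoff strictly.
3. identity `>= 30%` (and required motifs present) → **accepted**.
4. identity in `[20%, 30%)` with independent domain evidence →
   **rescued**. The identity cutoff is read as "at least 30% accepts
   directly"; any other reading would leave the rescue band meaningless.
5. required motif absent → rejected (`motif_failed`).
6. otherwise rejected (`identity` or `no_domain_evidence`).

Siroheme-destination families (Dsr/Fsr-type sulfite reductases) override
the defaults with `E <= 1e-30`, coverage `> 50%`, identity `>= 50%`, and
no rescue band, and additionally require the diagnostic
`CX4-5CXnCX3C` binding motif.

*Domain evidence* for the rescue band abstracts COG/Pfam-style
functional-grouping checks as a pluggable provider. Bundling those
databases is out of scope; the built-in desk-scale provider treats
satisfaction of the family's required motifs as evidence, and a
user-supplied table of externally computed domain hits can replace it.

*Bit-score filtering* is implemented as best-hit-per-subject selection
by bit score before classification, with ties broken by lower E-value
and then lexicographic subject id. With several seeds per family, the
best-scoring seed's hit per subject is classified.

*Synteny support*: `ahb`, `cyd`, and `suf` genes sit in well-conserved
operons, so a partial hit rejected on coverage or identity is upgraded
to rescued when at least `k = 2` other families of the same operon have
accepted or rescued calls within `w = 5` loci. Published practice does
not quantify how many neighbors make synteny "well-conserved"; `k` and
`w` are exposed parameters with those defaults. E-value rejections are
never upgraded — synteny compensates for truncation, not for absent
similarity.

The built-in backend is a Smith–Waterman local alignment (BLOSUM62, gap
open 11 / extend 1, via `Biostrings::pairwiseAlignment`), with the
gapped Karlin–Altschul E-value `K·m·n·exp(-λS)` (λ = 0.267, K = 0.041,
the standard constants for that scoring system). The E-value is
approximate and documented as such; nothing in the package depends on
its absolute scale, only on the separation between genuine homologs and
background, which is many orders of magnitude.

## Pathway rules and flags

* `SufBC = SufB AND SufC` — the scaffold requires both subunits.
* `HemBCD = HemB OR HemC OR HemD` — any-of, so an incomplete draft
  genome with one trunk enzyme still scores the pathway.
* `AhbABCD` = all four subunits. The heme pathway has no published
  any-of concession, and downstream reasoning is about *complete*
  pathways, so all-of is the conservative call; a companion
  `Ahb_partial` (any-of) feature preserves draft-genome signal.
* Fe(II) import is categorical over FeoA/FeoB co-occurrence
  (`FeoAB` / `FeoA_only` / `FeoB_only` / `none`); the ordination matrix
  encodes it as three binary columns by default (`feo_as_columns`
  switches this off) since a categorical column cannot enter a binary
  Jaccard computation directly.
* `heme_auxotroph_candidate`: at least one heme-user family (VhoC, HdrE,
  KatG, CydA/B) present while `AhbABCD = 0` — heme usage without heme
  biosynthesis implies environmental heme acquisition.
* `siroheme_orphan`: `SirA AND SirC AND NOT Dsr AND NOT Fsr` — siroheme
  biosynthesis with no known siroheme destination.
* Known homologs sitting outside search thresholds can be recorded as
  per-feature manual overrides in the rule set; each application is
  logged.

Prevalences are reported as half-up-rounded integer percents (95.4 → 95,
76.8 → 77), matching how such surveys print them; [Fe-S] fractions as
percents at two decimals. Group means weight genomes equally, not by
proteome size. Denominators are always derived from the matrix, never
taken from caller-supplied counts.

```{r}
prevalence(311, 326)   # e.g. SufBC carriers across a 326-genome cohort
```

## Ordination

Jaccard dissimilarity `d(i,j) = 1 - |A∩B| / |A∪B|` over each pair of
genome feature sets, then classical principal coordinates: Gower
double-centering of `-D²/2`, symmetric eigendecomposition, coordinates
scaled by `√λ`. Conventions:

* A pair of feature-free genomes gets distance 0 (identical emptiness),
  with a warning — such genomes are degenerate inputs.
* Negative eigenvalues (non-Euclidean dissimilarities) are reported but
  excluded from the variance-explained denominator; no Cailliez/Lingoes
  correction is applied, keeping the variance-explained quantity exactly
  `100·λ/Σλ⁺`.
* Axis signs are fixed by making the largest-magnitude coordinate
  positive on each axis, so reruns and platforms agree.

The three-point equilateral configuration is the closed-form anchor:
eigenvalues (0.5, 0.5, 0), axes 1 and 2 each explaining 50%.

```{r}
D <- matrix(1, 3, 3) - diag(3); dimnames(D) <- list(letters[1:3], letters[1:3])
r <- pco(D)
round(r$eigenvalues, 4); round(r$variance_explained, 1)
```

## The synthetic cohort generator

The generator emulates the structure of a mixed cultivar/MAG survey
cohort — what matters to the pipeline, not what makes sequences look
biological:

* **Taxon groups** with per-family carriage probabilities (the
  group-profile analogue of lineage-characteristic gene repertoires).
* **Planted homologs**: substitution-only mutants of family seed
  sequences at a controlled percent identity — exactly
  `round(L·(1-id/100))` positions substituted — so identity and coverage
  are analytically known. An indel-free model keeps the construction
  exact; it does not exercise alignment gap handling, which the local
  aligner covers independently. Required diagnostic motifs are restored
  after mutation, mirroring the functional conservation real homologs
  show.
* **Operons** planted as adjacent loci, exercising the synteny rule.
* **Planted motifs** into designated background proteins at known spans.
* **Dropout**: exactly `round(N·completeness)` proteins retained in
  original order, simulating MAG incompleteness. Published cohorts state
  only a completeness floor (<50% excluded), not a distribution, so
  completeness is a free parameter rather than a fitted one.
* **Background**: i.i.d. sequences; the `cysteine_free` policy (which
  also excludes G and H, the other motif anchor residues) guarantees
  zero accidental motif hits, separating scanner correctness from
  background-hit statistics. Substitutions in planted homologs draw from
  the same restricted alphabet so mutation cannot reintroduce anchors.

The built-in family seeds are themselves synthetic — deterministic
pseudo-random proteins with diagnostic motifs planted where a family
requires one. They exercise the pipeline exactly, but passing tests on
this cohort demonstrates *pipeline* correctness (scanning,
classification, counting, ordination), not annotation accuracy on real
proteomes, which additionally depends on seed choice, real E-value
calibration, and domain databases. SirB-type chelatases are deliberately
unsupported: they cannot be demarcated from paralogs on primary
sequence, so the family list marks them out of scope.

Everything is seeded: a fixed master seed yields byte-identical FASTA,
truth manifests, and downstream artifact bundles.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
the scanner against exhaustive enumeration of start positions and gap
assignments (all short sequences over a reduced alphabet, plus large
random corpora at realistic protein length); Jaccard against explicit
set arithmetic and `vegan::vegdist`; PCO against closed forms,
distance reconstruction, and `stats::cmdscale`; the classifier against
its decision table at every threshold boundary; and the full pipeline
against planted truth (sensitivity and specificity of 1.0 are required
on noise-free cohorts with identities ≥ 40% on cysteine-free
backgrounds). Routine runs use cohorts of 2 groups × 6–20 genomes with
5–8 background proteins per genome — large enough that every rule
fires, small enough to iterate on; carriage-probability recovery uses
250 genomes per group against a four-standard-error binomial band.

## Known limitations

* [Fe-S] detection is motif-based, not domain-model-based; absolute
  [Fe-S] fractions are approximations (see above).
* The built-in aligner is rigorous Smith–Waterman but desk-scale; for
  hundreds of real proteomes, run BLASTp externally and ingest the
  tabular output.
* The exact tryptophan-rich motif used to screen heme-c maturation
  (CcmC/F) candidates is not standardized in the literature; it is a
  per-family configurable required pattern with no hard-coded default.
* The generator does not model phylogenetic correlation between groups,
  nucleotide-level artifacts, or gene prediction errors.
* No significance testing is attached to group differences or
  ordination structure; the survey is descriptive.
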