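---
title: "Methods: predicting and classifying polymorphic miRNA target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and classifying polymorphic miRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymirts)
```

## The problem

Single-nucleotide variants in 3′-UTRs can abolish, weaken or create miRNA
binding sites and thereby change how strongly a transcript is repressed.
Calling such *polymorphic miRNA target sites* (poly-miRTSs) from RNA-Seq
data requires four ingredients that this package implements as separable,
individually tested modules: (i) target-site prediction on both alleles of
every candidate SNP, under several complementary criteria; (ii) a
classification rule that turns per-allele site-set differences into
created/disrupted/perturbed calls; (iii) variant-level filters that remove
artefacts of short-read evidence (low call quality, thin coverage,
multi-mapping regions); and (iv) expression read-outs (allele-specific
expression and cross-tissue inverse expression) that connect predictions to
observable repression.

## Site prediction

### Canonical seed sites

A mature miRNA is stored with its seed (nt 2–7, 1-based miRNA numbering)
and extended seed (nt 2–8). `find_seed_sites()` reports every maximal
occurrence of the four canonical site types — 8mer, 7mer-m8, 7mer-A1, 6mer
— on the sense-orientation UTR. "Maximal" means an 8mer occurrence is
reported once, not additionally as its nested 7mers and 6mer. Spans cover
the matched nucleotides including the A1 adenosine where the type includes
it. `N` never matches, and spans may not intersect the record's
unknown-sequence mask. The scan is validated against a brute-force
oracle (every offset × every type pattern) on random sequences up to 5 kb.

The seed is stated as nt 2–7 in the canonical-pairing sense but nt 2–8 for
accessibility assessment; both subsequences are first-class fields
(`seed6`, `seed7`) rather than resolving the discrepancy silently. The
family key for conservation checks is `seed7`.

### Context score

The full five-feature context model of seed-plus-context predictors is not
reproducible from its citation alone, so `context_score()` is an explicit
three-term surrogate:

* **type term**: 8mer 1.0 > 7mer-m8 0.6 > 7mer-A1 0.4 > 6mer 0.2 —
  preserves the canonical efficacy ordering;
* **AU term**: fraction of A/T in the 30-nt flanks on each side of the
  span (clipped at UTR ends), in [0, 1] — local AU content correlates with
  site accessibility and efficacy;
* **position term**: a bonus (default 0.3) when the site start lies within
  15–500 nt of either UTR end, where sites tend to be more effective.

The sum is multiplied by `context_scale` (default 10) so that one "unit"
of the >2-unit perturbation rule corresponds to 0.1 of the raw term sum;
the full type swing (8mer→6mer) is 8 units and the full AU swing 10 units,
so realistic score differences are commensurate with the rule. The score
makes ordinal claims only; it does not claim numeric equivalence with any
published context score.

### Accessibility and over-representation

`assess_accessibility()` folds a window (default 150 nt) centred on the
site and requires at least four of the seven UTR nucleotides that pair
miRNA nt 2–8 to be unpaired in the predicted structure. The folding
backend is a Nussinov-style maximum-weight pairing dynamic program
(GC = 3, AU = 2, GU = 1, minimum hairpin loop 3 nt) implemented in C++,
standing in for minimum-free-energy folding: no thermodynamic ensemble, no
stacking energies. This is a deliberate trade — the accessibility *rule*
(≥ 4 of 7 in an open loop) is the contract being implemented, and the
structural tests use fixtures whose pairing status is forced by
construction (full G/C duplexes with unpairable A spacers in T-free
context), so they hold under any reasonable pairing-maximising folder.
Traceback tie-breaks are deterministic (prefer leaving the right end
unpaired; then the smallest pairing partner), making the whole predictor
deterministic.

`rank_overrepresentation()` ranks a UTR's accessible sites by the
upper-tail binomial probability of seeing at least the observed number of
extended-seed matches, under a null where each of the `L − 6` 7-mer start
positions matches independently with probability given by the UTR's
mononucleotide composition. A count of 0 scores 1.0 exactly. The per-site
score recorded for the accessibility predictor is `−log10` of this
probability so that perturbation deltas live on an additive scale.

### 3′-compensatory sites

`find_compensatory_sites()` is a rule-based surrogate for trained
non-canonical predictors, capturing the stated mechanism: pairing of miRNA
nt 2–8 with **exactly one defect** — a mismatch, a G:U wobble, or a
single-nucleotide bulge — compensated by **≥ 4 consecutive Watson–Crick
pairs** between miRNA nt 13–17 and the UTR 1–6 nt upstream (5′) of the
seed match. G:U counts as a defect within the seed but never counts toward
the 3′-pairing run. The bulge branch loops one internal UTR base out of an
8-nt window; a miRNA-side bulge (a 6-nt UTR window skipping one miRNA
base) is a recognised omission, chosen to keep spans unambiguous for the
exact-key classifier. Perfect-seed windows are never reported, and no
reported span equals a canonical span.

### Conservation

`check_conservation()` is presence-based: a site counts as conserved when
the ortholog UTR contains at least one canonical site of the same miRNA
family (same seed-7), with no positional alignment. This matches how
conservation is used here — a qualitative corroboration, not a
phylogenetic score — and avoids committing to an alignment method the
input data cannot support.

## Poly-miRTS classification

Sites are matched between alleles by the exact key
`(miRNA, start, end, type, predictor)`. Substitution SNPs preserve
coordinates, so no gapped matching is needed (indels are out of scope).
The rules, in order:

* key only in the variant → **created**;
* key only in the reference → **disrupted**, *except* when the reference
  span overlaps the variant's unknown-sequence mask → **unknown**.
  Truncated allele sequences would otherwise inflate disruption counts and
  deflate creation counts, so absence of sequence information is never
  counted as disruption;
* key in both alleles with per-predictor |Δscore| > `perturbation_delta`
  (default 2 units, strict) → **perturbed**. Scores are never compared
  across predictors, and the rule is two-sided because the source states a
  magnitude without a sign convention;
* otherwise, no record.

Any reference/variant prediction difference is attributed to the applied
SNP, including sites distant from it — accessibility can change through
secondary structure alone — and the distance between SNP and span is
recorded so downstream users can filter on it. Whether attribution should
require overlap was genuinely open; recording the distance keeps both
readings available.

One SNP producing records for several miRNAs yields independent records
(the same substitution can create a site for one miRNA while disrupting
another's), and `tally_created_disrupted()` keeps `unknown` out of both
tallies, reporting it separately. `summarize_consensus()` partitions
distinct `(miRNA, span)` sites into the seven exclusive Venn regions over
the three predictor sets.

## Variant filters

* **Quality/depth**: retained iff quality ≥ 50 *and* depth ≥ 15 — the
  thresholds are described as minima, hence inclusive — and the position
  lies in ≥ 1 annotated 3′-UTR. The quality compared is the caller's
  site-level QUAL (not genotype quality); this is a documented reading.
* **Known-SNP merge**: union keyed by `(contig, position, ref, alt)`;
  collisions collapse to one record with provenance `both`. Database SNPs
  carry no RNA-Seq call metadata and therefore bypass the quality gate.
* **Coverage**: a UTR is "covered" when strictly more than 50 % of its
  bases have depth ≥ 1.
* **Mappability**: for read length *L* (35/50/70/90 in the source
  datasets) and *m* = 2 mismatches, the track counts for every L-mer start
  position the number of genomic start positions within Hamming distance
  *m* (forward strand by default; a both-strands mode includes
  reverse-complement matches — the upstream tool's strand convention is
  not restated in the source, so the choice is exposed as a flag).
  L-mers containing `N` match nothing: count 1, flagged low-confidence.
  A SNP is retained only when the mean count over window starts in
  `[pos − L, pos + L)` — start-position convention, width exactly 2L,
  clipped at contig ends — equals 1.0 exactly. Counting is exact all-pairs
  with early exit, correct at desk scale by oracle equivalence; production
  whole-genome indexing is out of scope.

`region_read_proportion()` rounds half-up to one decimal to match the
printed style of mapping-statistics tables (base R's banker's rounding
would turn 0.15 % into 0.1 %).

## Expression read-outs

FPKM is computed as `count × 10⁹ / (length_bp × total_mapped)`. The
co-expression gate is strict on both sides: miRNA > 10 reads and mRNA > 1
FPKM.

Both exact tests use the minimum-likelihood two-sided convention — the
p-value sums all outcomes whose point probability does not exceed the
observed one, with a 1 + 10⁻⁷ relative guard against floating-point ties
(the convention of standard implementations):

* `binomial_ase_test()` at success probability 0.5; for a symmetric null
  this equals the doubled smaller tail. Significance at α = 0.001.
* `fisher_allelic_proportion_test()` on the 2×2 table of (ref, var) reads
  in two tissues, by hypergeometric enumeration over the support.
  Significance at α = 0.05.

No multiple-testing correction is applied anywhere: the workflow this
package follows applies raw per-test thresholds, and adding a correction
would change its operating point. This is a faithfulness choice, noted
here rather than silently "improved".

**Inverse expression** is inherently a qualitative pattern (miRNA up,
targeted allele down); `flag_inverse_expression()` formalises it as: the
pair must be co-expressed with observable allelic counts in ≥ 2 tissues;
at least one tissue pair must differ significantly in allelic proportion
(Fisher, α = 0.05); and across all co-expressed tissue pairs with strictly
different miRNA expression, the tissue with more miRNA must have a strictly
lower targeted-allele proportion, with at least one such ordered pair.
Ties in miRNA expression impose no constraint. The targeted allele is the
variant for created sites and the reference for disrupted sites. This
strict-concordance rule is a stated formalisation of a visual criterion,
not a claim about any published procedure.

## The synthetic world

`synth_polymirts_scenario()` builds one uniform-composition random UTR per
gene (own contig, plus strand, default 300 nt) and plants at most one SNP
per gene: created sites are 8mers (the strongest type, so seed-predictor
recovery is unambiguous) broken at one seed-core position in the
reference; disrupted sites are intact reference 8mers broken by the
variant; neutral SNPs change no site. Every placement is verified at
generation time by scanning both alleles against *all* miRNAs and
requiring the canonical site-set difference to be exactly the intended one
(bounded rejection sampling, 1000 retries), so recovery tests isolate
pipeline defects from generator accidents. Allelic counts are binomial
(depth 60, p = 0.5) and call metadata passes all filters by construction.

`synth_expression_matrix()` plants inverse pairs as a 30/90/270-read miRNA
ramp against a 0.85→0.15 targeted-proportion ramp at depth 400 — effect
sizes large enough that the extreme tissue pair is Fisher-significant —
and verifies the flag rule on the *observed* counts at generation,
resampling when binomial noise breaks strict monotonicity. Non-planted
pairs alternate between rank-concordant ramps and flat pairs with constant
miRNA expression; both fail the flag rule deterministically, which is what
makes exact-recovery assertions possible.

What the generators do **not** emulate: linkage between SNPs, haplotype
structure, overlapping UTRs, sequencing error in the counts, GC-biased
composition (available as an option but off by default), indels, and
expression correlation structure beyond the planted pattern. A green
recovery test therefore establishes that the pipeline's logic implements
its stated rules, not that those rules are well-powered on real tissue
panels.

`synth_repeat_genome()` plants exact or diverged repeat copies between
unique spacers and derives the expected multi-mapping status of every
within-copy window directly from the copy strings, giving the mappability
module a second, independent expectation besides the all-pairs oracle.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; VCF positions convert once
  at the boundary. Minus-strand UTRs hold sense sequence; SNP alleles are
  complemented at `apply_variant()` time.
* Allele deduplication keys on exact full-sequence identity (`N` literal):
  no similarity threshold is stated by the source, so none is invented.
* `nucleotide_variation()` is the fraction of alignment columns with ≥ 2
  distinct non-gap, non-N characters among columns with ≥ 2 non-gap
  characters, 0 when no column is eligible. How the source normalised its
  printed "~" percentages is unknown; this column definition is the
  documented choice and is permutation-invariant.
* Empty inputs return empty, correctly-typed tables; zero-total exact
  tests and zero-length/zero-total FPKM raise errors rather than NaN.
* `rank_overrepresentation()` returns exactly 1.0 at count 0; the
  `−log10` transform clamps at the double minimum to avoid infinities.
* All generator randomness flows through an explicit seed, and generators
  restore the caller's RNG state.

## Known limitations

* The three predictors are explicit surrogates: no trained model, no
  thermodynamic ensemble, no conservation-weighted context. They implement
  the *criteria* (seed + context, seed + accessibility + over-
  representation, 3′-compensation), not the numeric outputs of the tools
  that inspired them.
* Indels, multi-SNP haplotype alleles and phasing are out of scope; each
  SNP is applied singly to the reference.
* Mappability is exact but quadratic; it is meant for desk-scale regions
  (a few kb to tens of kb), not whole genomes.
* Fisher-test oracle equivalence is verified exhaustively for table totals
  ≤ 26 and by seeded random sweep up to 200 (the full enumeration of all
  tables to N = 200 is combinatorially infeasible in a test budget).
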