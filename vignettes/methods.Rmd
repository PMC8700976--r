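---
title: "Methods: base-editor amenability scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-editor amenability scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

This vignette is the package's own account of its model and the design
choices taken where the problem left them open. It states no empirical
result that the test suite does not itself compute.

## The procedure

`bescan` decides, for each pathogenic single-nucleotide variant (SNV) of a
gene, (i) which DNA base-editor class can revert the mutant allele to
reference, and (ii) which Cas proteins offer a protospacer placement that
puts the target base inside their editing window with a matching PAM. The
stages are: harmonize two database-export dialects; call mutational
consequence from a transcript model; classify editability; scan a Cas
library; aggregate.

### Significance harmonization

Raw significance strings are collapsed to three ACMG-style levels —
benign/likely benign, uncertain significance, pathogenic/likely pathogenic —
plus `unclassified` for anything unrecognised (a warning, not an error:
real exports contain free text). A variant is *conflicting* when its labels
across sources span at least two of the three levels; "pathogenic" vs
"likely pathogenic" is therefore not a conflict. The analysis set is: all
pathogenic-level records plus conflicting records with at least one
pathogenic-level label (which keep their conflict flag). A record classified
in one source and unclassified in the other takes the existing
classification.

Two conventions the underlying problem does not fix, made explicit here:

* **Merge key.** Records merge on gene symbol plus the whitespace-stripped,
  case-canonicalised HGVS c. string. The alternative — parsing to
  (position, ref, alt) tuples — would silently merge syntactically distinct
  descriptions; the string key is conservative and auditable.
* **Report counts.** Each row of a source counts once unless the export
  carries an explicit count column; within-source duplicate keys are
  combined with their counts summed before the cross-source merge, and
  rows flagged by the source database as incorrect are dropped first.
* **Scalar level of a conflicting record.** The record keeps its full label
  set; its scalar `collapsed` value is the maximum-severity level present
  (pathogenic > VUS > benign), with the `conflict` flag carrying the
  multi-level information. Inclusion depends only on "has a pathogenic-level
  label", so this convention cannot change the analysis set.

### Consequence calling

Work happens entirely in coding (c.) coordinates over a transcript model:
per-exon coding lengths, the CDS, and optional intron flank sequences per
junction. Exonic substitutions are classified by codon translation (alt
codon is a stop → nonsense; same amino acid → synonymous; else missense —
stop-loss is folded into missense, as the source breakdown has no such
category). Intron offsets ±1/±2 are splice, ±3 intronic; deeper offsets are
kept as `intronic-deep` and excluded from the standard breakdown. UTR
positions parse but classify as `other`. Translation uses the standard
genetic code with no initiator-codon special-casing, so codon-1 edits
compare positionwise. A mismatch between the HGVS reference base and the
CDS is a hard error — it is the cheapest detector of off-by-one coordinate
bugs and of variant tables paired with the wrong transcript.

### Editability

Correction (alt back to ref), not installation, defines editability: the
editor must deaminate the *mutant* base. This puts the substrate on the
sense strand for G>A, T>C, G>C and on the antisense strand for their
complements. All transitions are editable (ABE or CBE); among transversions
only G:C↔C:G is (GBE); the ordered-pair partition is ABE 2, CBE 2, GBE 2,
none 6. Note the distinct transversion count is 8, not 12 — an enumeration
with duplicates circulates in the literature; the arithmetic here is forced.
Splice and intronic SNVs are included in editability denominators by
default (they are substitutions on pre-mRNA context); the consequence
column lets a user condition them away.

### The scanner

Protospacer positions are numbered 1–20, 5′→3′ on the protospacer strand.
Cas9-family PAMs sit downstream (positions 21+), Cas12-family PAMs upstream
(immediately 5′ of position 1). Three mechanistic commitments:

* **The substrate strand is the protospacer strand.** Deaminases act on the
  R-loop's displaced strand, which is the PAM-bearing strand matching the
  gRNA spacer sequence. This determines the search strand uniquely per
  variant; nothing else in the placement search is strand-free.
* **Scanning happens on the mutant allele.** The patient's molecule carries
  the variant base, which therefore participates in PAM matching — a
  placement that only exists on the reference sequence is therapeutically
  meaningless.
* **Pre-mRNA context at junctions.** The biological neighbour of an exon
  edge is the intron, so junction-proximal contexts splice in the stored
  intron flanks; splice/intronic variants live inside them. Variants whose
  flanks are not stored report "context unavailable" rather than silently
  scanning a cDNA joint that does not exist in the nucleus.

For each window position *w*, the protospacer is placed so the substrate
base sits at *w*; the placement is kept iff the adjacent PAM k-mer matches
one of the Cas's IUPAC patterns and protospacer+PAM fit inside the context
(truncated contexts warn). Bystanders are the other in-window positions
carrying the substrate base. Overlapping placements (several valid *w* for
one PAM) are reported as distinct rows; deduplication is a reporting choice,
not a scanning one. The default library (SpCas9, xCas/SpCas9-NG, SaCas9,
SaCas9-KKH, LbCas12a, enAsCas12a-RR/RVR as one entry with two alternative
PAMs, CasMINI) restricts editor pairings to demonstrated mammalian-cell
couplings: CasMINI is ABE-only; GBE pairs only with SpCas9 and
xCas/SpCas9-NG. A context width of 26 nt per side (protospacer 20 + longest
PAM 6) is the minimum that never truncates; intron flanks must be ≥26 nt
for junction-complete scans (the generator stores 30).

Per-variant Cas accounting is mutually exclusive: `assign_primary_cas`
takes the first Cas in a configurable precedence order (default: SpCas9,
xCas/SpCas9-NG, SaCas9, SaCas9-KKH, LbCas12a, enAsCas12a, CasMINI) with at
least one placement. Any mutually-exclusive per-Cas percentage implies such
a rule; making it explicit and configurable is the honest version of an
unstated tie-break.

### Aggregation

Denominators are stated because they differ per breakdown: significance is
over all merged records; consequence, transition/transversion and editor
class over the analyzed records (SNVs for the latter two); the per-Cas
assignment breakdown over *editable* SNVs, with "no PAM" completing it to 1.
Display rounding is half-up to integer percent; JSON output keeps full
precision. Ranked report tables break ties lexicographically on the variant
key so runs are byte-reproducible.

## The synthetic generator

The generator emulates the structure the analysis assumes — two overlapping
sources with discordant labels, a realistic substitution/indel/splice/
intronic mix, planted PAM contexts — not any real gene's allele spectrum or
the full column inventory of real exports. Its defaults restate the
published cohort structure: 1115 variants, 211 shared between sources, 49%
of records carrying a pathogenic-level label (41% cleanly pathogenic, 8%
conflicting-pathogenic), consequence mix 46/30/16/6/1.5/0.5 percent
(missense/indel/nonsense/splice/intronic/synonymous; the published rounded
percentages sum to 101, so missense takes the rounding slack and the
sub-percent synonymous class is set to 0.5%), and a substitution mix
(G>A 23%, T>C 14%, C>T 11%, A>G 5%, G>C = C>G = 4.5%, remaining six
transversions equal shares of 38%) that induces 53% transitions and an
ABE/CBE/GBE/none split of 34/19/9/38. These are the generator's stated
world; they were chosen once from the published breakdowns and are not
tuning knobs.

Compositions are planted by exact largest-remainder counts by default
(`exact = TRUE`), so recovery tests assert equality, not approximation.
Substitution type and consequence are planted *jointly*: every (CDS
position, substitution type) pair is pre-bucketed by direct codon
translation — a vectorized brute-force route independent of the pipeline's
consequence caller — and an allocator fills the type × consequence matrix
respecting bucket availability (e.g. no alt-C substitution can create a
stop codon, so nonsense quotas can only draw from feasible types; an
infeasible exact request errors rather than drifting). Splice and intronic
variants draw from junction slots whose reference bases come from the
stored flanks, with canonical GT/AG planted at every junction. Each
generator operation draws from its own labeled RNG substream of the master
seed, so adding a generator never perturbs existing fixtures; a given seed
yields identical bytes.

Ground truth records every planted attribute (class, consequence,
substitution type, editor, overlap, conflict status, per-source counts),
and the acceptance suite reruns the full pipeline and checks exact
agreement at 10^5 variants. One scale note: a 4-kb CDS admits only ~12k
distinct SNVs, so the 10^5-variant cohort runs on a correspondingly larger
synthetic transcript (300 exons, ~68 kb CDS) — a structural necessity for
distinct-variant planting, not a performance dodge.

What a green planted-recovery test does **not** establish: agreement with
any real database snapshot (content drifts and the original exports are not
deposited), realistic linkage between significance and consequence,
realistic per-exon clustering, or editing efficiency — the package predicts
geometric amenability, not editing outcomes, and models no deaminase
sequence-context preference or off-target behaviour.

## The reference stand-in

Worked examples need the CRB1-A transcript (RefSeq NM_201253), which is
neither redistributable nor fetchable in an offline build.
`crb1a_synthetic_model()` is a clearly-labelled synthetic stand-in: a
random ORF with the documented structural facts planted deterministically —
12 exons, 4221-bp CDS, exons 6+7+9 spanning 2448 bp, c.2843 as the first
base of exon 9 in a TGC (Cys948) codon, Asn codons at c.93/c.1647 making
the C>T changes there synonymous, and a Ser1025 neighbourhood around
c.3074 whose NNNRRT PAM yields the SaCas9-KKH placement with the target
adenine at window position 10 and bystanders exactly at positions 6, 8, 9.
Tests against it verify the package's arithmetic on those planted facts;
they are not evidence about the real gene beyond what was planted. Two
published inconsistencies are resolved deliberately: c.2843G>A is encoded
as Cys→Tyr (G>A at the codon's second position cannot give Arg), and
codon numbering counts from Met1, so c.93 falls in codon 31 (the package
asserts the synonymous consequence, not the published residue number 30).

## Numerical and degenerate-input choices

* Tie-breaks: apportionment ties by vector order; report ranking ties
  lexicographic; equal-PAM alternatives report the first matching pattern.
* Empty inputs: empty cohorts give zero-count reports; an editor-class
  breakdown of zero SNVs is all-zero with `n = 0`, not an error.
* `assign_primary_cas` validates precedence names (a typo would otherwise
  silently demote every variant to "no PAM").
* Insufficient flank truncates the scan with a warning and can legitimately
  return no placement — variants near the CDS ends genuinely have less
  targetable sequence.
* Seeds derive per-operation substreams below 2^31; the caller's RNG state
  is saved and restored around every generator call.

## Known limitations

No genomic liftover (everything is transcript-space), no gRNA efficacy or
off-target scoring, no deaminase context preference, no prime editing, no
isoform-aware reporting beyond exon numbering, and no statistical
comparison between sources. The per-Cas percentages of any real cohort
depend on the precedence rule chosen; the default mirrors a conventional
presentation order and is configurable precisely because it is a
convention.
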