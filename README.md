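# bescan

Base-editor amenability scanning for pathogenic transcript variants.

## The problem

DNA base editors chemically rewrite single bases without a double-strand
break: adenine base editors (ABE) convert A:T→G:C, cytosine base editors
(CBE) convert C:G→T:A, and glycosylase base editors (GBE) convert C:G→G:C.
Whether a pathogenic single-nucleotide variant (SNV) can be *corrected* by
one of these machines is a sequence question with three parts:

1. **Chemistry.** Correcting the mutant allele back to reference fixes the
   editor class. Writing a substitution as ref>alt, the mapping is

   | mutation | editor | substrate base | substrate strand |
   |----------|--------|----------------|------------------|
   | G>A      | ABE    | A              | sense            |
   | C>T      | ABE    | A              | antisense        |
   | T>C      | CBE    | C              | sense            |
   | A>G      | CBE    | C              | antisense        |
   | G>C      | GBE    | C              | sense            |
   | C>G      | GBE    | C              | antisense        |

   All four transitions are editable; of the eight transversions only the
   G:C↔C:G pair is (via GBE). The remaining six have no current editor.

2. **Geometry.** The editor only works when a Cas protein can bind next to
   the target: a PAM (e.g. 5′-NGG-3′ for SpCas9, 5′-TTTV-3′ for LbCas12a)
   must sit adjacent to a 20-nt protospacer on the substrate strand, with
   the substrate base inside that Cas's editing window (e.g. protospacer
   positions 4–8 for SpCas9, 2–15 for SaCas9-KKH; positions numbered 5′→3′).
   Any other substrate base inside the window is a potential bystander edit.

3. **Evidence.** Variants come from database exports with free-text clinical
   significance that disagrees between sources. Labels are collapsed to
   three ACMG-style levels (benign/likely benign; uncertain; pathogenic/
   likely pathogenic); a variant whose labels span ≥2 levels is *conflicting*,
   and conflicting variants with at least one pathogenic-level label are kept
   in the analysis alongside the cleanly pathogenic ones.

`bescan` implements this end to end for variants given in HGVS coding (c.)
notation against a transcript model (exon structure + CDS + intron flanks),
plus a seedable synthetic-data generator that emulates the two-source
database structure, so every stage is testable without any download.

## Worked example

The most intricate call in the pipeline is the bystander analysis. Take the
pathogenic missense variant c.3074G>A (Ser1025Asn) on the packaged synthetic
stand-in for the CRB1-A transcript (see note below):

```r
library(bescan)
model  <- crb1a_synthetic_model()
change <- parse_hgvs_c("c.3074G>A")
call_consequence(change, model)
#> $category "missense"   $exon 9   $codon_number 1025   $aa_ref "S"   $aa_alt "N"

required_editor(change$ref, change$alt)
#>         titv editor substrate_base substrate_strand
#> 1 transition    ABE              A            sense

ctx <- build_context(model, change)          # mutant-allele context
find_placements(ctx, as.list(required_editor("G", "A")),
                default_cas_library()[["SaCas9-KKH"]])
#>          cas strand protospacer_start          protospacer pam_observed
#> 1 SaCas9-KKH  sense                17 CCTGCACAAACTGCCTGGTC       CAGGAT
#>   target_window_pos bystander_positions n_bystanders
#> 1                10               6,8,9            3
```

Read: the mutant adenine sits at position 10 of SaCas9-KKH's 2–15 editing
window (PAM `CAGGAT` matches `NNNRRT`), and three further adenines at window
positions 6, 8 and 9 would likely be co-deaminated — a placement that exists
but demands bystander scrutiny. A cohort run looks like:

```r
paths <- simulate_cohort("sim", cohort_spec(seed = 1))   # synthetic 2-source cohort
cfg <- run_config(paths["source_a"], paths["source_b"],
                  paths["transcript_json"], paths["transcript_fasta"],
                  outdir = "out")
res <- run_pipeline(cfg)
res$report
#> <summary_report> 1115 records, 546 analyzed (49%), 382 SNVs
#>   editor classes: ABE 34%, CBE 19%, GBE 9%, none 38%
#>   editable: 62% of analyzed SNVs
#>   Cas assignment (editable SNVs): SpCas9 24%, xCas/SpCas9-NG 52%, SaCas9 3%,
#>     SaCas9-KKH 10%, LbCas12a 0%, enAsCas12a 4%, CasMINI 0%, none 8%, ...
```

The percentages here are the generator's planted defaults (recovered exactly
by the pipeline — that is what the acceptance suite asserts), not empirical
claims about any real database snapshot. `out/` contains the harmonized
variant table (TSV + JSON-lines), per-variant placements, single-Cas
assignments, one TSV per breakdown and a run manifest. The same run is
available from the command line via `inst/scripts/bescan`
(`bescan simulate ...`, `bescan run ...`).

**Note on the reference transcript.** The real CRB1-A reference sequence
(RefSeq NM_201253) is not redistributable with the package, so worked
examples use `crb1a_synthetic_model()`: a synthetic ORF with the documented
structural facts planted (4221-bp CDS; exons 6+7+9 = 2448 bp; c.2843 opens
exon 9; the c.3074 neighbourhood shown above). Everything outside those
planted features is random filler; see the methods vignette.

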