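# vcurate

An offline R toolkit for clinical germline variant curation: the ACMG/AMP
evidence-criteria engine, a reviewed-curation workflow with immutable
snapshots, structured evidence capture, and standards-compatible exports —
everything a curation platform computes, with no web service attached.

## Who this is for

Biocurators, clinical genetics groups and tool developers who need the
*computational* core of variant classification as a library: evaluating the
28 ACMG/AMP criteria (PVS1, PS1–PS4, PM1–PM6, PP1–PP5, BA1, BS1–BS4,
BP1–BP7) at possibly modified evidence strengths, combining them
automatically into a five-tier classification, moving a classification
record through a reviewed approval workflow, and emitting
ClinVar-submission-compatible and SEPIO-aligned interpretation documents.

## The classification model

Every criterion evaluation is either Met, Not Met, or Not Evaluated; a Met
criterion contributes at its *effective strength* — its default (by prefix:
PVS = Very Strong, PS/BS = Strong, PM = Moderate, PP/BP = Supporting, BA =
Stand-alone) or a curator-modified level such as PP1_Strong. Met counts per
tier feed the default 2015 combining rules:

* **Pathogenic**: 1 VS and (≥1 S | ≥2 M | 1 M + 1 P | ≥2 P); or ≥2 S; or
  1 S and (≥3 M | 2 M + ≥2 P | 1 M + ≥4 P)
* **Likely pathogenic**: 1 VS + 1 M; 1 S + 1–2 M; 1 S + ≥2 P; ≥3 M;
  2 M + ≥2 P; 1 M + ≥4 P
* **Benign**: 1 BA1, or ≥2 BS — **Likely benign**: 1 BS + 1 BP, or ≥2 BP
* Both sides firing is contradictory evidence → Uncertain significance with
  a conflict flag; neither side firing → Uncertain significance.

A second Very Strong criterion counts into the Strong tier, so added
very-strong evidence is never worthless. Not Met and Not Evaluated criteria
contribute nothing. The combining rules, allowed-strength table and
criterion-to-tab grouping live in a pluggable rule set
(`default_ruleset()`, `load_ruleset()`), so expert-panel specifications can
be swapped in from YAML/JSON.

Around the engine: classification records (variant + Mondo disease + HPO
mode of inheritance + owner) persist as canonical JSON in a directory
store; the workflow state machine (In-progress → Provisional → Approved →
New-Provisional / Published) captures a content-addressed, fully
dereferenced snapshot at each review step; evidence (article notes,
method/material/effect functional narratives, case/segregation counts with
a PHI guard) is shared between users while evaluations stay private until
approval.

## Worked example

```r
library(vcurate)

dir <- tempfile(); dir.create(dir)
fixtures <- file.path(dir, "fixtures.json")
generate_fixture_bundle(generator_config(seed = 42, n_variants = 10), file = fixtures)
fx    <- load_fixture_bundle(fixtures)
store <- store_init(file.path(dir, "store"))

panel <- owner_ref("cardio-vcep", kind = "affiliation", is_vcep = TRUE,
                   members = c("curator-1", "curator-2"))
set.seed(42)
rec <- create_classification_record(
  resolve_variant("CA000001", fx),
  disease_ref("MONDO:0005021", "hypertrophic cardiomyopathy"),
  moi_ref("HP:0000006", "Autosomal dominant inheritance"),
  panel, store, now = "2026-06-01T00:00:00Z")

rec <- add_case_observation(rec,
         case_observation("PM3", "in_trans_with_pathogenic", 2),
         article_ref(pmid = "30311386"), store = store)
rec <- evaluate(rec, "PS3", "Met", explanation = "minigene assay shows exon skipping",
                store = store)
rec <- evaluate(rec, "PM2", "Met", explanation = "absent from gnomAD", store = store)
rec <- evaluate(rec, "PP1", "Met", strength = "Moderate",
                explanation = "segregation in two families", store = store)
rec$computed_classification
#> [1] "Likely pathogenic"

rec <- transition(rec, "save_provisional", store = store)
rec <- transition(rec, "approve", store = store)
clinvar_submission(rec)$comment
#> [1] "PS3; PM2; PP1_Moderate"
writeLines(write_summary_text(evaluation_summary(rec, store)))
#> EVALUATION SUMMARY
#> Variant:        MYH7(NM_326254.4):c.3960T>A (p.Val1320Arg)
#> Disease:        hypertrophic cardiomyopathy [MONDO:0005021]
#> Inheritance:    Autosomal dominant inheritance [HP:0000006]
#> Owner:          cardio-vcep
#> Status:         Approved
#> Classification: Likely pathogenic
#> Conflict:       no
#> Met criteria:   PS3, PM2, PP1_Moderate
#> ...
```

One Strong (PS3, a damaging functional assay) plus two Moderate (PM2 rare
in population databases; PP1 segregation upgraded to Moderate) satisfies
the "1 Strong and 1–2 Moderate" row: Likely pathogenic. The ClinVar comment
lists exactly the Met codes, modified strengths rendered as
`CODE_Strength`.

The same workflow is scriptable from a shell via the bundled CLI
(`inst/cli/vcurate`): `generate-fixtures`, `init-store`, `resolve`,
`create`, `evaluate`, `classify`, `evidence-add`, `aggregate`,
`transition`, `snapshot-list`, `export summary|clinvar|interpretation`.

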