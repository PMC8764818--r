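---
title: "Methods: the classification engine, workflow semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the classification engine, workflow semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcurate)
```

# The problem

Clinical laboratories classify germline variants into five categories —
Pathogenic, Likely pathogenic, Uncertain significance, Likely benign,
Benign — by weighing 28 named evidence criteria: 16 pathogenic (a
very-strong loss-of-function criterion PVS1; four strong PS1–PS4; six
moderate PM1–PM6; five supporting PP1–PP5) and 12 benign (the stand-alone
frequency criterion BA1; four strong BS1–BS4; seven supporting BP1–BP7).
Curation practice adds two twists that this package models explicitly:
criteria may be applied at *modified* strengths (segregation evidence PP1,
for example, may be upgraded to Moderate or Strong as family data
accumulate), and classification is a reviewed, multi-step workflow in which
a record's evidence state at each review decision must be preserved
verbatim. `vcurate` implements that computational core as a library plus a
thin CLI; rendering, authentication and live annotation services are
deliberately out of scope.

# The combining calculus

## Tallies and effective strength

An evaluation is Met, Not Met or Not Evaluated. Only Met evaluations enter
the calculus, each at its effective strength. `effective_counts()` reduces
a record's evaluations to a tally of per-tier counts — pathogenic
(Very Strong, Strong, Moderate, Supporting) and benign (Stand-alone,
Strong, Supporting). Treating Not Met identically to Not Evaluated for
calculation (they differ only in the criteria-bar display) is a deliberate
choice: a criterion assessed and found not to apply contributes no
evidence, exactly like one never assessed. This is what makes the ignore
rule (tested property: deleting all Not Met/Not Evaluated entries never
changes the result) hold by construction.

## The rule table

`compute_classification()` implements the default 2015 combining rules
listed in the README. Two genuinely open points had to be decided:

**Multiple very-strong criteria.** The published table has no row for two
Very Strong criteria. We let surplus very-strong criteria count into the
strong tier, so VS=2 satisfies "1 VS + ≥1 S" and classifies Pathogenic.
Any weaker reading makes a second very-strong criterion literally
worthless, which would break the monotonicity property (adding pathogenic
evidence must never lower the classification rank) that the test suite
enforces over seeded random tallies.

**Contradictory evidence.** We flag a conflict exactly when *both* sides
fire a category: a pathogenic-side result (P or LP) and a benign-side
result (B or LB) simultaneously. The result is then Uncertain significance
with `conflict_flag = TRUE`. Met criteria that fire no category do not
contradict anything: one Strong pathogenic criterion alone plus two Benign
Strong criteria yields Benign, not a conflict, because a lone PS code never
reaches even Likely pathogenic. The alternative reading — any Met
pathogenic criterion neutralizes a benign call — would let a single
supporting code veto a stand-alone frequency classification, which is
neither standard practice nor monotone in any useful sense. Because
evolved practice differs on BA1 specifically, the rule set exposes
`ba1_standalone_wins`: when enabled, a met BA1 dominates a conflict and
classifies Benign un-flagged.

Both decisions are pinned by an exhaustive test: all 4^7 = 16,384 tallies
with tier counts ≤ 3 are compared against an independently written
row-by-row transcription of the table (in `tests/testthat/helper-oracle.R`
and re-derived inside `scripts/acceptance.R`).

## Allowed strengths

The only criterion whose pulldown options are fixed by published practice
is PP1 (Supporting default, Moderate, Strong). The shipped defaults
generalize this: pathogenic codes may move across Very Strong–Supporting,
benign codes (except BA1) across Strong/Supporting, and BA1 is stand-alone
only. This table is an explicit configuration surface
(`load_ruleset()`), not a claim about any particular expert panel's rules:
whether, say, benign codes may be upgraded beyond Strong is unspecified in
the source material, so the default is permissive where practice is
documented and conservative where it is not.

# Workflow semantics

The status machine has exactly six legal transitions:

| from | action | to | snapshot |
|---|---|---|---|
| InProgress | save_provisional | Provisional | yes |
| Provisional | approve | Approved | yes |
| Approved | edit | NewProvisional | no |
| NewProvisional | approve | Approved | yes |
| Approved | publish | Published | yes |
| Published | attach_scv | Published | no |

Everything else raises `IllegalTransition` — there are no silent no-ops, so
an audit trail is complete by construction. `edit` is triggered
automatically by any evaluation or evidence mutation on an Approved record;
a Published record is frozen. Edits to a Provisional record do not demote
it: the primary curator is still iterating before expert review, and
requiring a fresh save would create a cycle the status model does not
describe. Publishing defaults to expert-panel (VCEP-flagged) affiliations,
with a rule-set override for other groups; approval is performed by the
owning user or affiliation — intra-affiliation curator-versus-approver
roles are collapsed, as the package models ownership, not org charts.

Snapshots are fully dereferenced deep copies (evidence references resolved
to the items themselves) with a SHA-256 digest over the canonical JSON
serialization. Canonical means: keys sorted at every level, `NULL` fields
dropped, scalars unboxed — so equal content yields equal bytes and the
digest is a genuine immutability witness. The suite fuzzes this with 1,000
seeded random edits against live records and verifies no stored digest
moves.

Visibility follows the sharing contract: evidence items are visible to any
user at any status; evaluations and computed classifications are private
to the owner until the record is Approved (or Published), after which all
users get a read-only view.

# Evidence capture

Functional evidence uses the method / material / effect narrative with an
optional quantifier; the quantifier must carry a unit, and ontology terms
are stored as CURIE + label without live ontology validation (a deliberate
offline-first choice). Case and segregation evidence uses a count-bearing
observation vocabulary (proband counts, confirmed/unconfirmed de novo,
in-trans with a pathogenic variant, homozygote counts, segregations and
non-segregations, unaffected carriers, plus a free-text note type). The
vocabulary is representative, not authoritative — the underlying forms are
not published — and is configuration-extensible. Aggregation sums counts
per observation type across evidence items with a per-source breakdown,
and the conservation property (aggregate = brute-force sum) is tested on
seeded random observation sets.

The PHI guard is heuristic by design: a length cap (500 characters) plus
identifier-like regexes (9+ digit runs, email addresses, date-like
patterns). It is advisory screening, not a compliance control. The rule
set's `phi_mode` defaults to `"strict"` (the add operation refuses the
text with `PHIViolation`) because a guard that only warns cannot be relied
on by calling code; `"warn"` mode is available where a workflow prefers
curator discretion.

# The resolver and the synthetic generator

The resolver is fixture-backed: a local JSON bundle keyed by CAid (with a
ClinVar-ID secondary index) stands in for the remote annotation services.
It emulates the *interface* of live resolution — dual-ID lookup, MANE
Select-first display titles, tab-shaped evidence bundles, per-transcript
consequences — not the data itself. The title hierarchy below MANE Select
(any transcript HGVS, then genomic HGVS, then the bare CAid) is this
package's own construction; only the MANE-first rule is fixed by
convention.

`generate_fixture_bundle()` emulates what the bundle would contain:
allele frequencies drawn from a Beta(0.2, 30) (a rare-variant-shaped
spectrum), REVEL/SIFT/PolyPhen2 in [0, 1], CADD in [0, 60], phyloP in
[−14, 10], 1–3 transcripts per variant with at most one MANE Select, and a
scenario tag (pathogenic-rich, benign-rich, conflicting, empty) per
variant so tests can pick representatives of each evaluation regime. The
defaults (10 variants; 80% MANE, 70% ClinVar-ID, 85% frequency coverage;
scenario weights 0.3/0.3/0.2/0.2) were chosen once as plausible for a
small curation panel's worth of variants. What passing tests on generated
data do *not* show: real HGVS nomenclature edge cases (indels, intronic
offsets), genome-build arithmetic, inter-source frequency inconsistencies,
or annotation drift over time — the generator's values are internally
consistent by construction.

# Determinism and numerical choices

* All identifiers are drawn from R's seeded RNG (UUID4-shaped), so record
  and snapshot IDs reproduce under `set.seed()`; the generator saves and
  restores the caller's RNG state.
* Timestamps are injectable (`now =` arguments); exports read time from
  the document, never the wall clock, which is what makes repeated exports
  byte-identical.
* Canonical JSON uses full-precision number rendering (no rounding), so a
  store write–read round trip preserves the content hash.
* Tie-breaks: the criteria bar and all exports use one canonical criterion
  order (pathogenic by descending default strength, then benign);
  aggregation breakdowns order by source string; snapshots order by an
  explicit capture sequence number rather than timestamp (two review steps
  can share a second).
* Degenerate inputs: an empty evaluation set classifies Uncertain
  significance un-flagged; a variant with no transcripts yields an empty
  consequence table and falls back to its identifier for the title;
  missing fixture sections are empty, never errors.

# Problem sizes

The test suite and acceptance script run the exhaustive 16,384-tally rule
comparison, the 25-cell transition grid, 1,000-edit snapshot fuzzing over
20 records, 500 random evaluation sets for the ignore rule, 1,000 tallies
for monotonicity (two probes each), ~300 aggregation checks, and 200
finalized snapshots for export round-trips. These sizes exercise every
rule row and transition cell while keeping a full run in the tens of
seconds on one CPU.

# Known limitations

* Criterion-specific evidence logic (PVS1 decision trees, PM2 frequency
  thresholds, PP3 calibrated score bands) is out of scope: evaluations are
  curator judgments, as in interactive curation.
* The record store is single-process, last-writer-wins; there is no
  concurrency control or networking.
* The ClinVar export is a minimal compatible column subset, not the full
  submission workbook; the interpretation document is SEPIO-*aligned*
  (statement / evidence line / provenance) but uses a self-contained
  schema rather than importing the ontology.
* The PHI guard can be fooled by any determined free-text; it is a seat
  belt, not a compliance program.
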