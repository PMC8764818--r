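# The ACMG/AMP criterion catalog and evaluation semantics.
#
# 28 criteria: 16 pathogenic (PVS1, PS1-4, PM1-6, PP1-5) and 12 benign
# (BA1, BS1-4, BP1-7). Each has a default evidence strength implied by its
# prefix; ClinGen practice allows applying a criterion at a modified strength
# (e.g. PP1_Strong for segregation in multiple families), which is modelled
# as an effective strength on the evaluation.

#' Evidence strength levels, strongest first
#' @export
STRENGTH_LEVELS <- c("StandAlone", "VeryStrong", "Strong", "Moderate", "Supporting")

#' Classification categories, most pathogenic first
#' @export
CLASSIFICATION_CATEGORIES <- c(
  "Pathogenic", "Likely pathogenic", "Uncertain significance",
  "Likely benign", "Benign"
)

#' Evaluation statuses
#' @export
EVALUATION_STATUSES <- c("NotEvaluated", "Met", "NotMet")

#' Evidence tabs
#' @export
EVIDENCE_TABS <- c("Population", "VariantType", "Experimental",
                   "CaseSegregation", "GeneCentric", "BasicInfo")

# Rank used for monotonicity reasoning: Benign = 0 ... Pathogenic = 4.
#' Numeric rank of a classification category
#'
#' @param category One of the five classification categories.
#' @return Integer rank: Benign 0, Likely benign 1, Uncertain significance 2,
#'   Likely pathogenic 3, Pathogenic 4.
#' @export
classification_rank <- function(category) {
  r <- match(category, rev(CLASSIFICATION_CATEGORIES)) - 1L
  if (any(is.na(r))) vc_abort("UnknownCategory",
                              paste0("unknown classification category: ", category))
  r
}

.criterion_descriptions <- c(
  PVS1 = "Null variant (nonsense, frameshift, canonical splice site, initiation codon, exon deletion) in a gene where loss of function is a known disease mechanism",
  PS1  = "Same amino acid change as a previously established pathogenic variant regardless of nucleotide change",
  PS2  = "De novo (both maternity and paternity confirmed) in a patient with the disease and no family history",
  PS3  = "Well-established in vitro or in vivo functional studies supportive of a damaging effect",
  PS4  = "Prevalence of the variant in affected individuals significantly increased compared with controls",
  PM1  = "Located in a mutational hot spot and/or critical, well-established functional domain without benign variation",
  PM2  = "Absent from controls (or at extremely low frequency if recessive) in population databases",
  PM3  = "For recessive disorders, detected in trans with a pathogenic variant",
  PM4  = "Protein length changes as a result of in-frame deletions/insertions or stop-loss variants",
  PM5  = "Novel missense change at an amino acid residue where a different pathogenic missense change has been seen",
  PM6  = "Assumed de novo, but without confirmation of paternity and maternity",
  PP1  = "Co-segregation with disease in multiple affected family members in a gene definitively known to cause the disease",
  PP2  = "Missense variant in a gene with a low rate of benign missense variation where missense is a common mechanism",
  PP3  = "Multiple lines of computational evidence support a deleterious effect",
  PP4  = "Patient phenotype or family history is highly specific for a disease with a single genetic etiology",
  PP5  = "Reputable source recently reports variant as pathogenic without accessible evidence",
  BA1  = "Allele frequency above the stand-alone benign threshold in population databases",
  BS1  = "Allele frequency greater than expected for the disorder",
  BS2  = "Observed in healthy adults with full penetrance expected at an early age",
  BS3  = "Well-established functional studies show no damaging effect",
  BS4  = "Lack of segregation in affected members of a family",
  BP1  = "Missense variant in a gene for which primarily truncating variants cause disease",
  BP2  = "Observed in trans with a pathogenic variant for a dominant disorder, or in cis with a pathogenic variant",
  BP3  = "In-frame deletions/insertions in a repetitive region without a known function",
  BP4  = "Multiple lines of computational evidence suggest no impact",
  BP5  = "Variant found in a case with an alternate molecular basis for disease",
  BP6  = "Reputable source recently reports variant as benign without accessible evidence",
  BP7  = "Synonymous variant with no predicted splice impact and weak conservation"
)

.default_tab_map <- list(
  Population      = c("BA1", "BS1", "BS2", "PM2", "PS4"),
  VariantType     = c("PVS1", "PS1", "PM4", "PM5", "PP2", "PP3", "BP1", "BP3", "BP4", "BP7"),
  Experimental    = c("PS3", "BS3", "PM1"),
  CaseSegregation = c("PS2", "PM3", "PM6", "PP1", "PP4", "PP5", "BS4", "BP2", "BP5", "BP6")
)

# Canonical presentation order: pathogenic by decreasing default strength,
# then benign.
.criteria_order <- c(
  "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
  "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
)

.default_strength_for <- function(code) {
  prefix <- sub("[0-9]+$", "", code)
  switch(prefix,
    PVS = "VeryStrong", PS = "Strong", PM = "Moderate", PP = "Supporting",
    BA = "StandAlone", BS = "Strong", BP = "Supporting",
    vc_abort("UnknownCriterion", paste0("unknown criterion code: ", code))
  )
}

#' Direction (pathogenic or benign) of a criterion code
#' @param code Criterion code, e.g. `"PM2"`.
#' @return `"pathogenic"` or `"benign"`.
#' @export
criterion_direction <- function(code) {
  if (!code %in% .criteria_order) {
    vc_abort("UnknownCriterion", paste0("unknown criterion code: ", code))
  }
  if (startsWith(code, "B")) "benign" else "pathogenic"
}

.tab_for_code <- function(code, tab_map = .default_tab_map) {
  for (tab in names(tab_map)) {
    if (code %in% tab_map[[tab]]) return(tab)
  }
  NA_character_
}

#' The ACMG/AMP criterion catalog
#'
#' One row per criterion code in canonical presentation order, with the
#' default strength, direction, evidence tab, and a short description of the
#' guideline the code encodes.
#'
#' @param ruleset A rule set (see [default_ruleset()]); controls the tab map.
#' @return A data.frame with columns `code`, `direction`, `default_strength`,
#'   `tab`, `description`.
#' @export
criterion_catalog <- function(ruleset = default_ruleset()) {
  codes <- .criteria_order
  data.frame(
    code = codes,
    direction = vapply(codes, criterion_direction, character(1)),
    default_strength = vapply(codes, .default_strength_for, character(1)),
    tab = vapply(codes, .tab_for_code, character(1), tab_map = ruleset$tab_map),
    description = unname(.criterion_descriptions[codes]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Strength options permitted for a criterion
#'
#' The default table allows pathogenic codes to move between VeryStrong,
#' Strong, Moderate and Supporting; benign codes other than BA1 between
#' Strong and Supporting; BA1 is stand-alone only. The table is part of the
#' rule set, so expert-panel specifications can widen or narrow it.
#'
#' @param code Criterion code.
#' @param ruleset Rule set carrying the allowed-strength table.
#' @return Character vector of strength levels, strongest first; the code's
#'   default strength is always among them.
#' @export
allowed_strengths <- function(code, ruleset = default_ruleset()) {
  if (!code %in% .criteria_order) {
    vc_abort("UnknownCriterion", paste0("unknown criterion code: ", code))
  }
  tbl <- ruleset$allowed_strengths
  if (!is.null(tbl[[code]])) return(tbl[[code]])
  if (code == "BA1") return("StandAlone")
  if (criterion_direction(code) == "benign") return(c("Strong", "Supporting"))
  c("VeryStrong", "Strong", "Moderate", "Supporting")
}

#' Construct a criterion evaluation
#'
#' @param code Criterion code.
#' @param status `"Met"`, `"NotMet"` or `"NotEvaluated"`.
#' @param strength Effective strength; defaults to the code's default.
#'   May differ from the default only when `status == "Met"`.
#' @param explanation Curator free-text rationale.
#' @param ruleset Rule set for the allowed-strength check.
#' @return A `vc_evaluation` list.
#' @export
criterion_evaluation <- function(code, status = "NotEvaluated", strength = NULL,
                                 explanation = "", ruleset = default_ruleset()) {
  if (!code %in% .criteria_order) {
    vc_abort("UnknownCriterion", paste0("unknown criterion code: ", code))
  }
  if (!status %in% EVALUATION_STATUSES) {
    vc_abort("InvalidStatus", paste0("unknown evaluation status: ", status))
  }
  default <- .default_strength_for(code)
  if (is.null(strength)) strength <- default
  if (!strength %in% allowed_strengths(code, ruleset)) {
    vc_abort("StrengthNotAllowed",
             paste0(strength, " is not an allowed strength for ", code,
                    " (allowed: ", paste(allowed_strengths(code, ruleset), collapse = ", "), ")"))
  }
  if (!identical(strength, default) && status != "Met") {
    vc_abort("StrengthNotAllowed",
             "strength may differ from the default only for Met evaluations")
  }
  structure(
    list(code = code, status = status, effective_strength = strength,
         explanation = explanation),
    class = "vc_evaluation"
  )
}

#' Tally Met evaluations by direction and effective strength
#'
#' NotEvaluated and NotMet evaluations contribute nothing: only criteria a
#' curator has positively applied enter the classification calculus.
#'
#' @param evaluations Named list of `vc_evaluation` objects (name = code).
#' @return A `vc_tally`: `$pathogenic` counts named VeryStrong/Strong/
#'   Moderate/Supporting, `$benign` counts named StandAlone/Strong/Supporting.
#' @export
effective_counts <- function(evaluations) {
  path <- c(VeryStrong = 0L, Strong = 0L, Moderate = 0L, Supporting = 0L)
  ben  <- c(StandAlone = 0L, Strong = 0L, Supporting = 0L)
  for (ev in evaluations) {
    if (is.null(ev) || !identical(ev$status, "Met")) next
    s <- ev$effective_strength
    if (criterion_direction(ev$code) == "pathogenic") {
      path[s] <- path[s] + 1L
    } else {
      ben[s] <- ben[s] + 1L
    }
  }
  structure(list(pathogenic = path, benign = ben), class = "vc_tally")
}

#' Build a tally directly from tier counts
#'
#' Convenience constructor used by property tests and the rule-set
#' documentation: counts of Met criteria at each effective tier.
#'
#' @param vs,s,m,p Pathogenic very-strong / strong / moderate / supporting.
#' @param ba,bs,bp Benign stand-alone / strong / supporting.
#' @return A `vc_tally`.
#' @export
strength_tally <- function(vs = 0, s = 0, m = 0, p = 0, ba = 0, bs = 0, bp = 0) {
  stopifnot(all(c(vs, s, m, p, ba, bs, bp) >= 0))
  structure(
    list(
      pathogenic = c(VeryStrong = as.integer(vs), Strong = as.integer(s),
                     Moderate = as.integer(m), Supporting = as.integer(p)),
      benign = c(StandAlone = as.integer(ba), Strong = as.integer(bs),
                 Supporting = as.integer(bp))
    ),
    class = "vc_tally"
  )
}

#' Automatic pathogenicity classification from a strength tally
#'
#' Implements the default 2015 combining rules over effective-strength
#' counts. The pathogenic side fires Pathogenic when a very-strong criterion
#' is joined by sufficient corroboration (one strong, two moderate, one
#' moderate plus one supporting, or two supporting), when two strong-tier
#' criteria are met, or when one strong-tier criterion is joined by three
#' moderate, two moderate plus two supporting, or one moderate plus four
#' supporting. Likely pathogenic requires a weaker combination (very-strong
#' or strong plus one moderate, strong plus two supporting, three moderate,
#' two moderate plus two supporting, or one moderate plus four supporting).
#' The benign side fires Benign on a stand-alone criterion or two strong,
#' Likely benign on one strong plus one supporting or two supporting.
#'
#' Very-strong criteria beyond the first count into the strong tier, so a
#' second very-strong criterion satisfies any strong-tier requirement
#' (otherwise added very-strong evidence would be worthless, breaking
#' monotonicity).
#'
#' If both sides fire the evidence is contradictory: the result is Uncertain
#' significance with `conflict_flag = TRUE` (unless the rule set's
#' `ba1_standalone_wins` switch lets a met BA1 dominate).
#'
#' @param tally A `vc_tally` (from [effective_counts()] or [strength_tally()]).
#' @param ruleset Rule set; controls the BA1-conflict behaviour.
#' @return A list with `category`, `conflict_flag`, and `rank`.
#' @export
compute_classification <- function(tally, ruleset = default_ruleset()) {
  stopifnot(inherits(tally, "vc_tally"))
  vs <- tally$pathogenic[["VeryStrong"]]
  m  <- tally$pathogenic[["Moderate"]]
  p  <- tally$pathogenic[["Supporting"]]
  # surplus very-strong criteria satisfy strong-tier requirements
  s  <- tally$pathogenic[["Strong"]] + max(0L, vs - 1L)
  ba <- tally$benign[["StandAlone"]]
  bs <- tally$benign[["Strong"]]
  bp <- tally$benign[["Supporting"]]

  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    (s >= 2) ||
    (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
  likely_pathogenic <- !pathogenic && (
    (vs >= 1 && m >= 1) ||
    (s >= 1 && m >= 1) ||
    (s >= 1 && p >= 2) ||
    (m >= 3) ||
    (m >= 2 && p >= 2) ||
    (m >= 1 && p >= 4)
  )
  benign <- ba >= 1 || bs >= 2
  likely_benign <- !benign && ((bs >= 1 && bp >= 1) || bp >= 2)

  path_fired <- pathogenic || likely_pathogenic
  ben_fired  <- benign || likely_benign

  if (path_fired && ben_fired) {
    if (isTRUE(ruleset$ba1_standalone_wins) && ba >= 1) {
      category <- "Benign"; conflict <- FALSE
    } else {
      category <- "Uncertain significance"; conflict <- TRUE
    }
  } else if (path_fired) {
    category <- if (pathogenic) "Pathogenic" else "Likely pathogenic"
    conflict <- FALSE
  } else if (ben_fired) {
    category <- if (benign) "Benign" else "Likely benign"
    conflict <- FALSE
  } else {
    category <- "Uncertain significance"
    conflict <- FALSE
  }
  list(category = category, conflict_flag = conflict,
       rank = classification_rank(category))
}

#' Criteria-bar display states for a record
#'
#' One entry per catalog code in canonical order; codes never touched report
#' NotEvaluated. Mirrors the header bar a curator tracks progress with.
#'
#' @param record A classification record.
#' @param ruleset Rule set (for the catalog order).
#' @return data.frame with columns `code` and `display_state`.
#' @export
criteria_bar <- function(record, ruleset = default_ruleset()) {
  codes <- .criteria_order
  states <- vapply(codes, function(code) {
    ev <- record$evaluations[[code]]
    if (is.null(ev)) "NotEvaluated" else ev$status
  }, character(1))
  data.frame(code = codes, display_state = unname(states),
             row.names = NULL, stringsAsFactors = FALSE)
}
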