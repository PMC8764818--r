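# Document data model: variant, disease, mode of inheritance, owner,
# classification record. Records are JSON-serializable lists with light S3
# classes; the classification record stores evidence by reference (evidence
# item IDs) — full copies of evidence appear only inside snapshots.

.CAID_PATTERN    <- "^CA[0-9]+$"
.CLINVAR_PATTERN <- "^[0-9]+$"
.MONDO_PATTERN   <- "^MONDO:[0-9]{7}$"
.HPO_PATTERN     <- "^HP:[0-9]{7}$"

#' Construct a variant reference
#'
#' A variant is identified by a ClinGen Allele Registry canonical ID (CAid)
#' and/or a ClinVar Variation ID; at least one must be present. HGVS names
#' carry at most one MANE Select entry, which drives the display title.
#'
#' @param caid CAid string (`"CA"` followed by digits), or `NULL`.
#' @param clinvar_id ClinVar Variation ID (digits as string), or `NULL`.
#' @param hgvs_names List of entries, each a list with `reference`
#'   (transcript or genomic accession), `hgvs` (the c./p./g. expression),
#'   `is_mane_select` flag, and optionally `protein_hgvs`.
#' @param gene_symbol HGNC symbol or `NULL`.
#' @return A `vc_variant`.
#' @export
variant_ref <- function(caid = NULL, clinvar_id = NULL, hgvs_names = list(),
                        gene_symbol = NULL) {
  if (is.null(caid) && is.null(clinvar_id)) {
    vc_abort("InvalidIdentifier", "a variant needs a CAid or a ClinVar Variation ID")
  }
  if (!is.null(caid) && !grepl(.CAID_PATTERN, caid)) {
    vc_abort("InvalidIdentifier", paste0("malformed CAid: ", caid))
  }
  if (!is.null(clinvar_id)) {
    clinvar_id <- as.character(clinvar_id)
    if (!grepl(.CLINVAR_PATTERN, clinvar_id)) {
      vc_abort("InvalidIdentifier", paste0("malformed ClinVar Variation ID: ", clinvar_id))
    }
  }
  n_mane <- sum(vapply(hgvs_names, function(h) isTRUE(h$is_mane_select), logical(1)))
  if (n_mane > 1) {
    vc_abort("InvalidIdentifier", "at most one HGVS name may be MANE Select")
  }
  structure(
    list(caid = caid, clinvar_id = clinvar_id, hgvs_names = hgvs_names,
         gene_symbol = gene_symbol),
    class = "vc_variant"
  )
}

# Canonical store key: prefer the globally unique CAid; fall back to the
# ClinVar ID namespaced to avoid collisions.
canonical_variant_key <- function(variant) {
  variant$caid %||% paste0("clinvar:", variant$clinvar_id)
}

#' Construct a disease reference (Mondo term)
#' @param mondo_id Mondo CURIE, pattern `MONDO:\\d{7}`.
#' @param label Human-readable disease name.
#' @return A `vc_disease`.
#' @export
disease_ref <- function(mondo_id, label = "") {
  if (!grepl(.MONDO_PATTERN, mondo_id)) {
    vc_abort("InvalidIdentifier", paste0("malformed Mondo CURIE: ", mondo_id))
  }
  structure(list(mondo_id = mondo_id, label = label), class = "vc_disease")
}

#' Construct a mode-of-inheritance reference (HPO term)
#' @param hpo_id HPO CURIE, pattern `HP:\\d{7}`.
#' @param label Term name, e.g. "autosomal dominant inheritance".
#' @return A `vc_moi`.
#' @export
moi_ref <- function(hpo_id, label = "") {
  if (!grepl(.HPO_PATTERN, hpo_id)) {
    vc_abort("InvalidIdentifier", paste0("malformed HPO CURIE: ", hpo_id))
  }
  structure(list(hpo_id = hpo_id, label = label), class = "vc_moi")
}

#' Construct an owner (individual curator or affiliation)
#'
#' A record belongs to the individual or affiliation that created it and can
#' only be edited by them; affiliation members share edit rights. Only
#' affiliations can be flagged as expert panels (VCEPs), which gates
#' publishing.
#'
#' @param owner_id Opaque identifier.
#' @param kind `"individual"` or `"affiliation"`.
#' @param is_vcep Expert-panel flag; affiliations only.
#' @param members Character vector of member user IDs (affiliations).
#' @return A `vc_owner`.
#' @export
owner_ref <- function(owner_id, kind = c("individual", "affiliation"),
                      is_vcep = FALSE, members = character(0)) {
  kind <- match.arg(kind)
  if (isTRUE(is_vcep) && kind != "affiliation") {
    vc_abort("InvalidOwner", "only affiliations can be expert panels (is_vcep)")
  }
  structure(
    list(owner_id = owner_id, kind = kind, is_vcep = isTRUE(is_vcep),
         members = as.list(members)),
    class = "vc_owner"
  )
}

# Does `actor` hold edit rights on a record owned by `owner`?
owner_can_edit <- function(actor, owner) {
  if (identical(actor$owner_id, owner$owner_id)) return(TRUE)
  identical(owner$kind, "affiliation") &&
    actor$owner_id %in% unlist(owner$members)
}

new_classification_record <- function(variant, disease, moi, owner, now) {
  structure(
    list(
      record_id = vc_uuid(),
      variant = unclass(variant),
      disease = unclass(disease),
      moi = unclass(moi),
      owner = unclass(owner),
      evaluations = stats::setNames(list(), character(0)),
      evidence = list(),
      status = "InProgress",
      published = FALSE,
      scv = NULL,
      computed_classification = "Uncertain significance",
      conflict_flag = FALSE,
      override_classification = NULL,
      override_rationale = NULL,
      created = now,
      modified = now
    ),
    class = "vc_record"
  )
}

# Re-attach classes after JSON round trip.
as_vc_record <- function(x) {
  class(x) <- "vc_record"
  x$evaluations <- lapply(x$evaluations, function(ev) {
    class(ev) <- "vc_evaluation"; ev
  })
  if (length(x$evaluations) == 0) {
    x$evaluations <- stats::setNames(list(), character(0))
  }
  x
}

#' Validate a classification record against the model invariants
#'
#' Total function: returns a character vector of violation descriptions in a
#' stable order; empty exactly when every invariant holds.
#'
#' @param record A `vc_record`.
#' @param ruleset Rule set used to recompute the classification and check
#'   strengths/tabs.
#' @param store Optional record store; when given, evidence references are
#'   checked for existence.
#' @return Character vector of violations (possibly empty).
#' @export
validate_record <- function(record, ruleset = default_ruleset(), store = NULL) {
  v <- character(0)
  var <- record$variant
  if (is.null(var$caid) && is.null(var$clinvar_id)) {
    v <- c(v, "variant lacks both CAid and ClinVar ID")
  }
  if (!is.null(var$caid) && !grepl(.CAID_PATTERN, var$caid)) {
    v <- c(v, "malformed CAid")
  }
  n_mane <- sum(vapply(var$hgvs_names, function(h) isTRUE(h$is_mane_select), logical(1)))
  if (n_mane > 1) v <- c(v, "multiple MANE Select HGVS names")
  if (!grepl(.MONDO_PATTERN, record$disease$mondo_id %||% "")) {
    v <- c(v, "malformed Mondo CURIE")
  }
  if (!grepl(.HPO_PATTERN, record$moi$hpo_id %||% "")) {
    v <- c(v, "malformed HPO CURIE")
  }
  if (isTRUE(record$owner$is_vcep) && !identical(record$owner$kind, "affiliation")) {
    v <- c(v, "is_vcep on a non-affiliation owner")
  }
  for (code in names(record$evaluations)) {
    ev <- record$evaluations[[code]]
    if (!ev$effective_strength %in% allowed_strengths(code, ruleset)) {
      v <- c(v, paste0("disallowed strength for ", code))
    } else if (!identical(ev$effective_strength, .default_strength_for(code)) &&
               !identical(ev$status, "Met")) {
      v <- c(v, paste0("modified strength on non-Met evaluation ", code))
    }
  }
  recomputed <- compute_classification(effective_counts(record$evaluations), ruleset)
  if (!identical(recomputed$category, record$computed_classification)) {
    v <- c(v, "stale classification")
  }
  if (!is.null(record$override_classification) &&
      !nzchar(trimws(record$override_rationale %||% ""))) {
    v <- c(v, "override without rationale")
  }
  if (!is.null(store)) {
    for (eid in unlist(record$evidence)) {
      if (!file.exists(evidence_path(store, eid))) {
        v <- c(v, paste0("dangling evidence reference ", eid))
      }
    }
  }
  v
}

#' Asserted classification of a record
#'
#' The override when present, otherwise the computed classification.
#' @param record A `vc_record`.
#' @return Classification category string.
#' @export
asserted_classification <- function(record) {
  record$override_classification %||% record$computed_classification
}
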