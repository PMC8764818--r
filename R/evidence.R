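# Structured evidence capture: article notes, functional (method/material/
# effect) evidence, and case/segregation observations with per-criterion
# aggregation and a heuristic PHI guard.

.EVIDENCE_KINDS <- c("article_note", "functional", "case_observation", "segregation")

#' Case/segregation observation vocabulary
#'
#' Count-bearing observation types plus a free-text note type. The vocabulary
#' is configuration-extensible; this is the shipped default.
#' @export
OBSERVATION_TYPES <- c(
  "proband_count", "de_novo_confirmed", "de_novo_unconfirmed",
  "in_trans_with_pathogenic", "homozygote_count", "segregations",
  "non_segregations", "unaffected_carrier_count", "phenotype_specificity_note"
)

.COUNT_BEARING <- setdiff(OBSERVATION_TYPES, "phenotype_specificity_note")

#' Construct an article reference
#' @param pmid PubMed ID (digits) or `NULL`.
#' @param doi DOI string or `NULL`.
#' @param citation Free-text citation.
#' @return A `vc_article` list; at least one identifier must be present.
#' @export
article_ref <- function(pmid = NULL, doi = NULL, citation = "") {
  if (is.null(pmid) && is.null(doi)) {
    vc_abort("InvalidIdentifier", "an article reference needs a PMID or a DOI")
  }
  if (!is.null(pmid) && !grepl("^[0-9]+$", as.character(pmid))) {
    vc_abort("InvalidIdentifier", paste0("malformed PMID: ", pmid))
  }
  structure(list(pmid = if (is.null(pmid)) NULL else as.character(pmid),
                 doi = doi, citation = citation),
            class = "vc_article")
}

evidence_source_label <- function(source) {
  if (inherits(source, "vc_article") ||
      (is.list(source) && !is.null(source$pmid %||% source$doi))) {
    if (!is.null(source$pmid)) return(paste0("PMID:", source$pmid))
    return(source$doi)
  }
  as.character(source)
}

#' Heuristic guard against protected health information in free text
#'
#' Advisory, not a compliance tool: flags notes that exceed a length cap or
#' contain identifier-like patterns (long digit runs such as MRNs or SSNs,
#' email addresses, date-of-birth-like dates).
#'
#' @param text Character scalar to screen.
#' @param max_chars Length cap (default 500).
#' @return A list with `ok` (logical) and `violations` (character vector of
#'   rule names that fired: `length_cap`, `digit_run`, `email`, `date_like`).
#' @export
phi_guard <- function(text, max_chars = 500L) {
  violations <- character(0)
  if (nchar(text) > max_chars) violations <- c(violations, "length_cap")
  if (grepl("[0-9]{9,}", text)) violations <- c(violations, "digit_run")
  if (grepl("[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}", text)) {
    violations <- c(violations, "email")
  }
  if (grepl("\\b[0-9]{1,2}[/-][0-9]{1,2}[/-][0-9]{2,4}\\b", text) ||
      grepl("\\b(19|20)[0-9]{2}-[0-9]{2}-[0-9]{2}\\b", text)) {
    violations <- c(violations, "date_like")
  }
  list(ok = length(violations) == 0, violations = violations)
}

enforce_phi <- function(text, ruleset) {
  res <- phi_guard(text, ruleset$phi_max_chars %||% 500L)
  if (!res$ok) {
    msg <- paste0("free text failed the PHI guard (",
                  paste(res$violations, collapse = ", "), ")")
    if (identical(ruleset$phi_mode, "warn")) warning(msg) else
      vc_abort("PHIViolation", msg)
  }
  invisible(res)
}

new_evidence_item <- function(record, tab, kind, source, payload, actor, now) {
  structure(
    list(
      evidence_id = vc_uuid(),
      record_id = record$record_id,
      tab = tab,
      kind = kind,
      source = evidence_source_label(source),
      source_detail = if (inherits(source, "vc_article")) unclass(source) else NULL,
      payload = payload,
      added_by = actor$owner_id,
      added_at = now
    ),
    class = "vc_evidence"
  )
}

attach_evidence <- function(record, item, actor, store, now) {
  record <- maybe_auto_edit(record, actor, store, now)
  vc_write_json(item, evidence_path(store, item$evidence_id))
  record$evidence <- c(record$evidence, list(item$evidence_id))
  record$modified <- now
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "evidence_add", evidence_id = item$evidence_id,
                          kind = item$kind, actor = actor$owner_id))
  record
}

#' Attach an article-based note to an evidence tab
#'
#' @param record A `vc_record`.
#' @param tab Evidence tab name (see `EVIDENCE_TABS`).
#' @param article A `vc_article`.
#' @param note Free-text note.
#' @param actor Editing owner (defaults to the record owner).
#' @param store Store handle.
#' @param ruleset Rule set.
#' @param now Timestamp.
#' @return Updated record.
#' @export
add_article_evidence <- function(record, tab, article, note = "", actor = NULL,
                                 store, ruleset = default_ruleset(), now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  if (!tab %in% EVIDENCE_TABS) {
    vc_abort("UnknownTab", paste0("unknown evidence tab: ", tab))
  }
  item <- new_evidence_item(record, tab, "article_note", article,
                            list(note = note), actor, now)
  attach_evidence(record, item, actor, store, now)
}

#' Construct a functional-evidence payload
#'
#' The structured narrative for experimental evidence: (1) method, (2)
#' material, (3) effect, with an optional quantifier. Terms are ontology
#' CURIEs plus labels, stored without live ontology validation.
#'
#' @param method_id,method_label Assay type (e.g. an OBI/ECO term).
#' @param material_id,material_label Experimental material (e.g. patient
#'   fibroblasts, model organism).
#' @param effect Controlled effect term (e.g. "exon skipping").
#' @param quantifier_value Optional numeric quantifier.
#' @param quantifier_unit Unit for the quantifier (required when a value is
#'   given).
#' @param supports `"PS3-like damaging"`, `"BS3-like benign"` or
#'   `"inconclusive"`.
#' @return A `vc_functional` payload.
#' @export
functional_evidence <- function(method_id, method_label, material_id,
                                material_label, effect,
                                quantifier_value = NULL, quantifier_unit = NULL,
                                supports = c("inconclusive", "PS3-like damaging",
                                             "BS3-like benign")) {
  supports <- match.arg(supports)
  for (fld in list(method_id = method_id, method_label = method_label,
                   material_id = material_id, material_label = material_label,
                   effect = effect)) {
    if (is.null(fld) || !nzchar(fld)) {
      vc_abort("SchemaViolation",
               "functional evidence requires method, material and effect")
    }
  }
  if (!is.null(quantifier_value) &&
      (is.null(quantifier_unit) || !nzchar(quantifier_unit))) {
    vc_abort("UnitMissing", "a quantifier value requires a unit")
  }
  structure(
    list(method = list(id = method_id, label = method_label),
         material = list(id = material_id, label = material_label),
         effect = effect,
         quantifier = if (is.null(quantifier_value)) NULL else
           list(value = quantifier_value, unit = quantifier_unit),
         supports = supports),
    class = "vc_functional"
  )
}

#' Attach functional evidence (Experimental tab)
#'
#' @param record A `vc_record`.
#' @param payload A `vc_functional` payload.
#' @param source A `vc_article` or `"unpublished:<label>"` string.
#' @param actor Editing owner.
#' @param store Store handle.
#' @param ruleset Rule set.
#' @param now Timestamp.
#' @return Updated record.
#' @export
add_functional_evidence <- function(record, payload, source, actor = NULL,
                                    store, ruleset = default_ruleset(),
                                    now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  if (!inherits(payload, "vc_functional")) {
    vc_abort("SchemaViolation", "payload must be built with functional_evidence()")
  }
  item <- new_evidence_item(record, "Experimental", "functional", source,
                            unclass(payload), actor, now)
  attach_evidence(record, item, actor, store, now)
}

#' Construct a case/segregation observation payload
#'
#' @param criterion Case/Segregation-tab criterion the observation bears on
#'   (e.g. PM3, PP1, BS4).
#' @param observation_type One of `OBSERVATION_TYPES`.
#' @param count Non-negative integer count (required for count-bearing
#'   types; 0 allowed for note types).
#' @param free_text Bounded note (screened by the PHI guard on attach).
#' @param ruleset Rule set (tab map).
#' @return A `vc_case_obs` payload.
#' @export
case_observation <- function(criterion, observation_type, count = 0L,
                             free_text = "", ruleset = default_ruleset()) {
  if (!observation_type %in% OBSERVATION_TYPES) {
    vc_abort("SchemaViolation",
             paste0("unknown observation type: ", observation_type))
  }
  cs_codes <- ruleset$tab_map$CaseSegregation
  if (!criterion %in% cs_codes) {
    vc_abort("WrongTabCriterion",
             paste0(criterion, " is not a Case/Segregation criterion"))
  }
  if (observation_type %in% .COUNT_BEARING) {
    if (is.null(count) || is.na(count) || count < 0 || count != as.integer(count)) {
      vc_abort("SchemaViolation",
               paste0(observation_type, " requires a non-negative integer count"))
    }
  }
  structure(
    list(criterion = criterion, observation_type = observation_type,
         count = as.integer(count), free_text = free_text),
    class = "vc_case_obs"
  )
}

#' Attach a case/segregation observation
#'
#' Free text is screened by the PHI guard (strict mode rejects, warn mode
#' warns). Segregation-type observations are stored as kind `segregation`,
#' others as `case_observation`; all live on the Case/Segregation tab.
#'
#' @param record A `vc_record`.
#' @param payload A `vc_case_obs` payload.
#' @param source A `vc_article` or `"unpublished:<label>"` string.
#' @param actor Editing owner.
#' @param store Store handle.
#' @param ruleset Rule set.
#' @param now Timestamp.
#' @return Updated record.
#' @export
add_case_observation <- function(record, payload, source, actor = NULL,
                                 store, ruleset = default_ruleset(),
                                 now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  if (!inherits(payload, "vc_case_obs")) {
    vc_abort("SchemaViolation", "payload must be built with case_observation()")
  }
  enforce_phi(payload$free_text %||% "", ruleset)
  kind <- if (payload$observation_type %in% c("segregations", "non_segregations"))
    "segregation" else "case_observation"
  item <- new_evidence_item(record, "CaseSegregation", kind, source,
                            unclass(payload), actor, now)
  attach_evidence(record, item, actor, store, now)
}

#' Remove an evidence item from a record
#'
#' Removes the reference and deletes the stored item, invalidating cached
#' aggregates (which are computed on demand, so simply recomputed).
#'
#' @param record A `vc_record`.
#' @param evidence_id Evidence identifier.
#' @param actor Editing owner.
#' @param store Store handle.
#' @param now Timestamp.
#' @return Updated record.
#' @export
remove_evidence <- function(record, evidence_id, actor = NULL, store,
                            now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  ids <- unlist(record$evidence)
  if (!evidence_id %in% ids) {
    vc_abort("EvidenceNotFound", paste0("no evidence item ", evidence_id))
  }
  record <- maybe_auto_edit(record, actor, store, now)
  record$evidence <- as.list(setdiff(ids, evidence_id))
  unlink(evidence_path(store, evidence_id))
  record$modified <- now
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "evidence_remove", evidence_id = evidence_id,
                          actor = actor$owner_id))
  record
}

#' Load the evidence items referenced by a record
#' @param record A `vc_record`.
#' @param store Store handle.
#' @return List of evidence item lists.
#' @export
list_evidence <- function(record, store) {
  lapply(unlist(record$evidence), function(eid) {
    p <- evidence_path(store, eid)
    if (!file.exists(p)) {
      vc_abort("EvidenceNotFound", paste0("dangling evidence reference ", eid))
    }
    vc_read_json(p)
  })
}

#' Aggregate case/segregation counts for one criterion
#'
#' Individual counts for each distinct observation type are summed over all
#' matching evidence items, with a per-source breakdown, so pooled evidence
#' from several articles can be assessed in aggregate.
#'
#' @param record A `vc_record`.
#' @param criterion Case/Segregation criterion code (e.g. `"PM3"`).
#' @param store Store handle.
#' @return A list with `totals` (named integer vector over all observation
#'   types) and `breakdown` (per type, a data.frame of `source`, `count`
#'   ordered by source).
#' @export
aggregate_case_counts <- function(record, criterion, store) {
  items <- list_evidence(record, store)
  items <- Filter(function(it) {
    it$kind %in% c("case_observation", "segregation") &&
      identical(it$payload$criterion, criterion)
  }, items)
  totals <- stats::setNames(integer(length(OBSERVATION_TYPES)), OBSERVATION_TYPES)
  breakdown <- stats::setNames(vector("list", length(OBSERVATION_TYPES)),
                               OBSERVATION_TYPES)
  for (ot in OBSERVATION_TYPES) {
    matching <- Filter(function(it) identical(it$payload$observation_type, ot), items)
    if (length(matching) == 0) {
      breakdown[[ot]] <- data.frame(source = character(0), count = integer(0),
                                    stringsAsFactors = FALSE)
      next
    }
    src <- vapply(matching, function(it) it$source, character(1))
    cnt <- vapply(matching, function(it) as.integer(it$payload$count %||% 0L), integer(1))
    agg <- stats::aggregate(cnt, by = list(source = src), FUN = sum)
    agg <- agg[order(agg$source, method = "radix"), , drop = FALSE]
    breakdown[[ot]] <- data.frame(source = agg$source, count = as.integer(agg$x),
                                  row.names = NULL, stringsAsFactors = FALSE)
    totals[[ot]] <- sum(cnt)
  }
  list(criterion = criterion, totals = totals, breakdown = breakdown)
}

#' Export functional evidence as a TSV template
#'
#' Columns mirror the structured functional-data template: `method_id`,
#' `method_label`, `material_id`, `material_label`, `effect`,
#' `quantifier_value`, `quantifier_unit`, `source`.
#'
#' @param record A `vc_record`.
#' @param store Store handle.
#' @param file Output path; when `NULL` the data.frame is returned only.
#' @return The data.frame of functional evidence rows, invisibly when writing.
#' @export
write_functional_tsv <- function(record, store, file = NULL) {
  items <- Filter(function(it) identical(it$kind, "functional"),
                  list_evidence(record, store))
  df <- data.frame(
    method_id = vapply(items, function(it) it$payload$method$id, character(1)),
    method_label = vapply(items, function(it) it$payload$method$label, character(1)),
    material_id = vapply(items, function(it) it$payload$material$id, character(1)),
    material_label = vapply(items, function(it) it$payload$material$label, character(1)),
    effect = vapply(items, function(it) it$payload$effect, character(1)),
    quantifier_value = vapply(items, function(it)
      if (is.null(it$payload$quantifier)) NA_real_ else as.numeric(it$payload$quantifier$value),
      numeric(1)),
    quantifier_unit = vapply(items, function(it)
      if (is.null(it$payload$quantifier)) NA_character_ else it$payload$quantifier$unit,
      character(1)),
    source = vapply(items, function(it) it$source, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", eol = "\n", fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}

#' Read a functional-evidence TSV template
#' @param file Path to a TSV written by [write_functional_tsv()] (or filled
#'   in by hand from the template).
#' @return List of `vc_functional` payloads with their `source` attached as
#'   an attribute-free `source` element alongside.
#' @export
read_functional_tsv <- function(file) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    payload <- functional_evidence(
      method_id = row$method_id, method_label = row$method_label,
      material_id = row$material_id, material_label = row$material_label,
      effect = row$effect,
      quantifier_value = if (is.na(row$quantifier_value)) NULL else row$quantifier_value,
      quantifier_unit = if (is.na(row$quantifier_unit)) NULL else row$quantifier_unit
    )
    list(payload = payload, source = row$source)
  })
}
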