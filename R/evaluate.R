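# Saving criterion evaluations on a record and overriding the computed
# classification. Each saved evaluation immediately recomputes the automatic
# pathogenicity, mirroring the interactive behaviour where the classification
# updates every time an evaluation is saved.

recompute_record <- function(record, ruleset) {
  cls <- compute_classification(effective_counts(record$evaluations), ruleset)
  record$computed_classification <- cls$category
  record$conflict_flag <- cls$conflict_flag
  record
}

#' Save (upsert) a criterion evaluation on a record
#'
#' Validates the strength against the code's allowed options, stores the
#' evaluation, recomputes the automatic classification and conflict flag, and
#' persists the record. Editing an Approved record demotes it to
#' New-Provisional; a Published record cannot be edited.
#'
#' @param record A `vc_record`.
#' @param code Criterion code (e.g. `"PM2"`).
#' @param status `"Met"`, `"NotMet"` or `"NotEvaluated"`.
#' @param strength Effective strength; defaults to the code's default.
#' @param explanation Curator rationale text.
#' @param actor Owner performing the edit (defaults to the record owner).
#' @param store Store handle.
#' @param ruleset Rule set.
#' @param now Timestamp.
#' @return The updated record.
#' @export
evaluate <- function(record, code, status, strength = NULL, explanation = "",
                     actor = NULL, store, ruleset = default_ruleset(),
                     now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  ev <- criterion_evaluation(code, status, strength, explanation, ruleset)
  record <- maybe_auto_edit(record, actor, store, now)
  record$evaluations[[code]] <- unclass(ev)
  record <- recompute_record(record, ruleset)
  record$modified <- now
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "evaluate", criterion = code,
                          status = status, actor = actor$owner_id))
  record
}

#' Manually override the computed classification
#'
#' Expert opinion may override the automatic classification; the computed
#' value is retained alongside as provenance, and exports report the
#' override as the asserted classification.
#'
#' @param record A `vc_record`.
#' @param category One of the five classification categories, or `NULL` to
#'   clear an existing override (restoring asserted = computed).
#' @param rationale Non-empty free-text justification (required when setting).
#' @param actor Owner performing the override.
#' @param store Store handle.
#' @param now Timestamp.
#' @return The updated record.
#' @export
override_classification <- function(record, category, rationale = "",
                                    actor = NULL, store, now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  if (is.null(category)) {
    record$override_classification <- NULL
    record$override_rationale <- NULL
  } else {
    if (!category %in% CLASSIFICATION_CATEGORIES) {
      vc_abort("UnknownCategory", paste0("unknown classification category: ", category))
    }
    if (!nzchar(trimws(rationale))) {
      vc_abort("EmptyRationale",
               "a manual override requires a non-empty rationale")
    }
    record$override_classification <- category
    record$override_rationale <- rationale
  }
  record$modified <- now
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "override", actor = actor$owner_id))
  record
}
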