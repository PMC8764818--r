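# Deterministic exports: evaluation summary (JSON + plain text), a
# ClinVar-submission-compatible TSV row, and a SEPIO-aligned interpretation
# document (statement / evidence lines / provenance) with strict round-trip
# parsing. All outputs are pure functions of the record or snapshot: the
# timestamp is taken from the document, never the wall clock, so repeated
# exports are byte-identical.

is_snapshot <- function(x) inherits(x, "vc_snapshot") ||
  (is.list(x) && !is.null(x$full_copy))

export_record_of <- function(x) {
  if (is_snapshot(x)) as_vc_record(x$full_copy) else x
}

# Met codes in canonical criteria-bar order, rendered CODE or CODE_Strength
# when applied at a non-default strength.
met_code_labels <- function(record) {
  labels <- character(0)
  for (code in .criteria_order) {
    ev <- record$evaluations[[code]]
    if (is.null(ev) || !identical(ev$status, "Met")) next
    lab <- code
    if (!identical(ev$effective_strength, .default_strength_for(code))) {
      lab <- paste0(code, "_", ev$effective_strength)
    }
    labels <- c(labels, lab)
  }
  labels
}

#' Evaluation summary of a record or snapshot
#'
#' Summarizes all evaluated evidence: variant title, disease, mode of
#' inheritance, owner, status, the asserted classification (the override
#' when present, otherwise the computed one), the conflict flag, one row per
#' evaluated criterion, and per-tab evidence digests.
#'
#' @param x A `vc_record` or `vc_snapshot`.
#' @param store Store handle (to resolve evidence tabs for live records;
#'   snapshots are self-contained).
#' @return A `vc_summary` list.
#' @export
evaluation_summary <- function(x, store = NULL) {
  record <- export_record_of(x)
  items <- if (is_snapshot(x)) {
    x$full_copy$evidence_items %||% list()
  } else if (!is.null(store)) {
    list_evidence(record, store)
  } else {
    list()
  }
  rows <- lapply(
    .criteria_order[.criteria_order %in% names(record$evaluations)],
    function(code) {
      ev <- record$evaluations[[code]]
      list(code = code, status = ev$status,
           effective_strength = ev$effective_strength,
           explanation = ev$explanation %||% "")
    }
  )
  tab_digest <- lapply(EVIDENCE_TABS, function(tab) {
    in_tab <- Filter(function(it) identical(it$tab, tab), items)
    list(tab = tab, n_items = length(in_tab),
         sources = sort(unique(vapply(in_tab, function(it) it$source, character(1)))))
  })
  structure(
    list(
      variant_title = variant_title(structure(record$variant, class = "vc_variant")),
      disease = record$disease,
      moi = record$moi,
      owner_id = record$owner$owner_id,
      status = record$status,
      asserted_classification = asserted_classification(record),
      computed_classification = record$computed_classification,
      override_classification = record$override_classification,
      conflict_flag = record$conflict_flag,
      criterion_rows = rows,
      met_codes = met_code_labels(record),
      evidence_by_tab = tab_digest,
      generated_at = record$modified
    ),
    class = "vc_summary"
  )
}

#' Write an evaluation summary as canonical JSON
#' @param summary A `vc_summary`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, file) {
  vc_write_json(summary, file)
}

#' Render an evaluation summary as plain text
#'
#' Fixed field order and formatting; byte-identical across repeated calls on
#' the same input.
#'
#' @param summary A `vc_summary`.
#' @param file Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when writing to a file).
#' @export
write_summary_text <- function(summary, file = NULL) {
  lines <- c(
    "EVALUATION SUMMARY",
    paste0("Variant:        ", summary$variant_title),
    paste0("Disease:        ", summary$disease$label, " [", summary$disease$mondo_id, "]"),
    paste0("Inheritance:    ", summary$moi$label, " [", summary$moi$hpo_id, "]"),
    paste0("Owner:          ", summary$owner_id),
    paste0("Status:         ", summary$status),
    paste0("Classification: ", summary$asserted_classification,
           if (!is.null(summary$override_classification))
             paste0(" (override; computed: ", summary$computed_classification, ")")
           else ""),
    paste0("Conflict:       ", if (isTRUE(summary$conflict_flag)) "yes" else "no"),
    paste0("Met criteria:   ",
           if (length(summary$met_codes)) paste(summary$met_codes, collapse = ", ")
           else "(none)"),
    "",
    "Criterion evaluations:"
  )
  if (length(summary$criterion_rows) == 0) {
    lines <- c(lines, "  (no criteria evaluated)")
  } else {
    for (row in summary$criterion_rows) {
      lines <- c(lines, sprintf("  %-5s %-12s %-11s %s", row$code, row$status,
                                row$effective_strength, row$explanation))
    }
  }
  lines <- c(lines, "", paste0("Generated: ", summary$generated_at))
  if (!is.null(file)) {
    writeLines(lines, file, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

.CLINVAR_COLUMNS <- c(
  "local_id", "clinvar_variation_id", "gene_symbol", "condition_id",
  "clinical_significance", "date_last_evaluated", "mode_of_inheritance",
  "assertion_criteria", "comment"
)

#' ClinVar-submission-compatible row for a finalized record
#'
#' A minimal compatible subset of the submission template: one tab-separated
#' row per record. The comment field lists exactly the Met codes in
#' canonical order, with modified strengths rendered `CODE_Strength`. An
#' overridden classification is exported as the clinical significance, with
#' the computed value noted in the comment.
#'
#' @param x A `vc_record` or `vc_snapshot` in status Approved or Published.
#' @param ruleset Rule set (its name is cited in `assertion_criteria`).
#' @return A one-row data.frame with the submission columns.
#' @export
clinvar_submission <- function(x, ruleset = default_ruleset()) {
  record <- export_record_of(x)
  if (!record$status %in% c("Approved", "Published")) {
    vc_abort("NotFinalized",
             "only Approved or Published classifications may be exported for submission")
  }
  var <- record$variant
  variant_field <- var$clinvar_id %||%
    variant_title(structure(var, class = "vc_variant"))
  comment <- paste(met_code_labels(record), collapse = "; ")
  if (!is.null(record$override_classification)) {
    comment <- paste0(comment,
                      if (nzchar(comment)) " | " else "",
                      "computed: ", record$computed_classification,
                      "; override rationale: ", record$override_rationale)
  }
  df <- data.frame(
    local_id = record$record_id,
    clinvar_variation_id = variant_field,
    gene_symbol = var$gene_symbol %||% "",
    condition_id = record$disease$mondo_id,
    clinical_significance = asserted_classification(record),
    date_last_evaluated = record$modified,
    mode_of_inheritance = record$moi$label,
    assertion_criteria = paste0("ACMG/AMP 2015 + ", ruleset$name),
    comment = comment,
    stringsAsFactors = FALSE
  )
  df[, .CLINVAR_COLUMNS]
}

#' Write ClinVar submission rows as TSV
#'
#' UTF-8, LF line endings, one header row per file.
#'
#' @param rows A data.frame of rows from [clinvar_submission()] (rbind for
#'   several records).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_clinvar_tsv <- function(rows, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(paste(.CLINVAR_COLUMNS, collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  for (i in seq_len(nrow(rows))) {
    writeLines(paste(vapply(.CLINVAR_COLUMNS, function(cn)
      as.character(rows[i, cn]), character(1)), collapse = "\t"),
      con, sep = "\n", useBytes = TRUE)
  }
  invisible(file)
}

.INTERPRETATION_SCHEMA_VERSION <- "1.0"

.INTERPRETATION_TOP_FIELDS <- c("schema_version", "statement", "evidence_lines",
                                "provenance")
.STATEMENT_FIELDS <- c("subject", "predicate", "object", "condition",
                       "mode_of_inheritance")
.EVIDENCE_LINE_FIELDS <- c("criterion", "strength", "explanation",
                           "evidence_refs")
.PROVENANCE_FIELDS <- c("agent", "agent_kind", "captured_at", "status",
                        "computed_classification", "conflict_flag")

#' SEPIO-aligned interpretation document from a finalized snapshot
#'
#' The statement/evidence-line/provenance triad: the statement asserts the
#' variant's pathogenicity for a condition and mode of inheritance; one
#' evidence line per Met criterion carries its effective strength,
#' explanation and evidence references; provenance records the asserting
#' agent, capture time and review status.
#'
#' @param snapshot A `vc_snapshot` whose status at capture is Approved or
#'   Published.
#' @return A `vc_interpretation` list (serialize with [canonical_json()]).
#' @export
interpretation_json <- function(snapshot) {
  if (!is_snapshot(snapshot)) {
    vc_abort("SchemaViolation", "interpretation documents are built from snapshots")
  }
  if (!snapshot$status_at_capture %in% c("Approved", "Published")) {
    vc_abort("NotFinalized",
             "only Approved or Published snapshots may be transformed")
  }
  record <- as_vc_record(snapshot$full_copy)
  items <- snapshot$full_copy$evidence_items %||% list()
  refs_for_code <- function(code) {
    tab <- .tab_for_code(code)
    keep <- Filter(function(it) {
      identical(it$payload$criterion %||% NULL, code) ||
        (is.null(it$payload$criterion) && identical(it$tab, tab))
    }, items)
    as.list(vapply(keep, function(it) it$evidence_id, character(1)))
  }
  lines <- lapply(
    .criteria_order[.criteria_order %in% names(record$evaluations)],
    function(code) {
      ev <- record$evaluations[[code]]
      if (!identical(ev$status, "Met")) return(NULL)
      list(criterion = code, strength = ev$effective_strength,
           explanation = ev$explanation %||% "",
           evidence_refs = refs_for_code(code))
    }
  )
  lines <- Filter(Negate(is.null), lines)
  doc <- structure(
    list(
      schema_version = .INTERPRETATION_SCHEMA_VERSION,
      statement = list(
        subject = record$variant$caid %||%
          paste0("clinvar:", record$variant$clinvar_id),
        predicate = "has_pathogenicity",
        object = asserted_classification(record),
        condition = record$disease$mondo_id,
        mode_of_inheritance = record$moi$hpo_id
      ),
      evidence_lines = lines,
      provenance = list(
        agent = record$owner$owner_id,
        agent_kind = record$owner$kind,
        captured_at = snapshot$captured_at,
        status = snapshot$status_at_capture,
        computed_classification = record$computed_classification,
        conflict_flag = record$conflict_flag
      )
    ),
    class = "vc_interpretation"
  )
  doc
}

check_fields <- function(x, allowed, required, at, strict) {
  nm <- names(x) %||% character(0)
  missing <- setdiff(required, nm)
  if (length(missing)) {
    vc_abort("SchemaViolation",
             paste0("missing field at ", at, "/", missing[1]),
             pointer = paste0(at, "/", missing[1]))
  }
  if (strict) {
    extra <- setdiff(nm, allowed)
    if (length(extra)) {
      vc_abort("SchemaViolation",
               paste0("unknown field at ", at, "/", extra[1]),
               pointer = paste0(at, "/", extra[1]))
    }
  }
  invisible(TRUE)
}

#' Parse (and validate) an interpretation document
#'
#' Lossless with respect to [canonical_json()] serialization. Strict mode
#' (the default) rejects unknown fields; lenient mode preserves them.
#' Violations carry a JSON-pointer-style path to the offending field.
#'
#' @param json A JSON string, a path to a JSON file, or an already-parsed
#'   list.
#' @param strict Reject unknown fields?
#' @return A `vc_interpretation`.
#' @export
parse_interpretation <- function(json, strict = TRUE) {
  doc <- if (is.list(json)) {
    json
  } else if (file.exists(json)) {
    vc_read_json(json)
  } else {
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  }
  check_fields(doc, .INTERPRETATION_TOP_FIELDS, .INTERPRETATION_TOP_FIELDS,
               "", strict)
  check_fields(doc$statement, .STATEMENT_FIELDS, .STATEMENT_FIELDS,
               "/statement", strict)
  if (!doc$statement$object %in% CLASSIFICATION_CATEGORIES) {
    vc_abort("SchemaViolation", "invalid classification at /statement/object",
             pointer = "/statement/object")
  }
  if (!is.list(doc$evidence_lines)) {
    vc_abort("SchemaViolation", "evidence_lines must be an array",
             pointer = "/evidence_lines")
  }
  for (i in seq_along(doc$evidence_lines)) {
    at <- paste0("/evidence_lines/", i - 1)
    line <- doc$evidence_lines[[i]]
    check_fields(line, .EVIDENCE_LINE_FIELDS, .EVIDENCE_LINE_FIELDS, at, strict)
    if (!line$criterion %in% .criteria_order) {
      vc_abort("SchemaViolation", paste0("unknown criterion at ", at, "/criterion"),
               pointer = paste0(at, "/criterion"))
    }
    if (!line$strength %in% STRENGTH_LEVELS) {
      vc_abort("SchemaViolation", paste0("unknown strength at ", at, "/strength"),
               pointer = paste0(at, "/strength"))
    }
  }
  check_fields(doc$provenance, .PROVENANCE_FIELDS, .PROVENANCE_FIELDS,
               "/provenance", strict)
  class(doc) <- "vc_interpretation"
  doc
}
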