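# Review-workflow state machine, snapshots and the visibility contract.
#
# Statuses progress In-progress -> Provisional -> Approved; a revision to an
# approved interpretation moves it to New-Provisional, which requires a new
# approval. Publishing appends Published to an approved record (expert-panel
# affiliations only, unless the rule set overrides) and an SCV accession can
# then be attached. Every review step captures an immutable, fully
# dereferenced snapshot of the record.

.WORKFLOW_STATUSES <- c("InProgress", "Provisional", "Approved",
                        "NewProvisional", "Published")
.WORKFLOW_ACTIONS  <- c("save_provisional", "approve", "edit", "publish",
                        "attach_scv")

# (from_status, action) -> to_status; NA = illegal. Snapshot column marks
# which transitions capture a snapshot.
.TRANSITIONS <- list(
  list(from = "InProgress",     action = "save_provisional", to = "Provisional",    snapshot = TRUE),
  list(from = "Provisional",    action = "approve",          to = "Approved",       snapshot = TRUE),
  list(from = "Approved",       action = "edit",             to = "NewProvisional", snapshot = FALSE),
  list(from = "NewProvisional", action = "approve",          to = "Approved",       snapshot = TRUE),
  list(from = "Approved",       action = "publish",          to = "Published",      snapshot = TRUE),
  list(from = "Published",      action = "attach_scv",       to = "Published",      snapshot = FALSE)
)

#' Workflow statuses and actions
#' @export
WORKFLOW_STATUSES <- .WORKFLOW_STATUSES
#' @rdname WORKFLOW_STATUSES
#' @export
WORKFLOW_ACTIONS <- .WORKFLOW_ACTIONS

find_transition <- function(from, action) {
  for (tr in .TRANSITIONS) {
    if (identical(tr$from, from) && identical(tr$action, action)) return(tr)
  }
  NULL
}

#' Capture an immutable snapshot of a record
#'
#' The snapshot is a fully dereferenced deep copy: evidence references are
#' resolved to the full evidence items, so the snapshot is self-contained and
#' preserves the exact evidence state behind a review decision even if the
#' live record changes later. The snapshot carries a content digest over the
#' full copy.
#'
#' @param record A `vc_record`.
#' @param store Store handle (needed to resolve evidence references).
#' @param now Capture timestamp.
#' @param seq Monotone capture sequence number (assigned by [transition()]).
#' @return A `vc_snapshot`, already persisted.
#' @export
take_snapshot <- function(record, store, now = vc_now(), seq = NULL) {
  items <- lapply(unlist(record$evidence), function(eid) {
    p <- evidence_path(store, eid)
    if (!file.exists(p)) {
      vc_abort("SerializationError",
               paste0("dangling evidence reference ", eid,
                      ": snapshot would not be self-contained"))
    }
    vc_read_json(p)
  })
  full <- unclass(record)
  full$evidence_items <- items
  if (is.null(seq)) seq <- length(list_snapshots(store, record$record_id)) + 1L
  snap <- structure(
    list(
      snapshot_id = vc_uuid(),
      record_id = record$record_id,
      status_at_capture = record$status,
      full_copy = full,
      captured_at = now,
      capture_seq = seq,
      digest = content_hash(full)
    ),
    class = "vc_snapshot"
  )
  vc_write_json(snap, snapshot_path(store, snap$snapshot_id))
  snap
}

#' List the snapshots of a record in capture order
#'
#' @param store Store handle.
#' @param record_id Record identifier.
#' @return List of `vc_snapshot` objects ordered by capture sequence (the
#'   audit trail of review steps).
#' @export
list_snapshots <- function(store, record_id) {
  files <- list.files(file.path(store$path, "snapshots"), full.names = TRUE)
  snaps <- lapply(files, function(f) {
    s <- vc_read_json(f); class(s) <- "vc_snapshot"; s
  })
  snaps <- Filter(function(s) identical(s$record_id, record_id), snaps)
  ord <- order(vapply(snaps, function(s) s$capture_seq %||% 0, numeric(1)))
  snaps[ord]
}

#' Apply a workflow action to a record
#'
#' Exactly six transitions are legal: In-progress --save_provisional-->
#' Provisional, Provisional --approve--> Approved, Approved --edit-->
#' New-Provisional, New-Provisional --approve--> Approved, Approved
#' --publish--> Published, and Published --attach_scv--> Published. Every
#' other (status, action) pair raises `IllegalTransition`. Transitions into
#' Provisional, Approved and Published each capture one snapshot.
#'
#' @param record A `vc_record`.
#' @param action One of `save_provisional`, `approve`, `edit`, `publish`,
#'   `attach_scv`.
#' @param actor Owner performing the action; must hold edit rights.
#' @param store Store handle.
#' @param scv_id SCV accession (required for `attach_scv`; must start "SCV").
#' @param ruleset Rule set (publish permission switch).
#' @param now Timestamp.
#' @return The updated record.
#' @export
transition <- function(record, action, actor = NULL, store, scv_id = NULL,
                       ruleset = default_ruleset(), now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!action %in% .WORKFLOW_ACTIONS) {
    vc_abort("IllegalTransition", paste0("unknown workflow action: ", action))
  }
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may act on a record")
  }
  tr <- find_transition(record$status, action)
  if (is.null(tr)) {
    vc_abort("IllegalTransition",
             paste0("action ", action, " is not legal from status ", record$status))
  }
  if (identical(action, "publish")) {
    if (!isTRUE(record$owner$is_vcep) && !isTRUE(ruleset$allow_publish_non_vcep)) {
      vc_abort("PublishNotPermitted",
               "publishing is restricted to expert-panel affiliations")
    }
  }
  if (identical(action, "attach_scv")) {
    if (is.null(scv_id) || !grepl("^SCV", scv_id)) {
      vc_abort("InvalidIdentifier", "an SCV accession must start with 'SCV'")
    }
    record$scv <- scv_id
  }
  from <- record$status
  record$status <- tr$to
  if (identical(tr$to, "Published")) record$published <- TRUE
  record$modified <- now
  snap_id <- NULL
  if (isTRUE(tr$snapshot)) {
    seq <- length(list_snapshots(store, record$record_id)) + 1L
    snap <- take_snapshot(record, store, now = now, seq = seq)
    snap_id <- snap$snapshot_id
  }
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = action, from = from, to = record$status,
                          snapshot_id = snap_id, actor = actor$owner_id))
  record
}

# Editing an approved record (changing an evaluation or evidence) demotes it
# to New-Provisional automatically; a published record is frozen.
maybe_auto_edit <- function(record, actor, store, now) {
  if (identical(record$status, "Published")) {
    vc_abort("IllegalTransition",
             "a published record cannot be edited; it is frozen")
  }
  if (identical(record$status, "Approved")) {
    record <- transition(record, "edit", actor = actor, store = store, now = now)
  }
  record
}

#' Read-only view of a record for a requesting user
#'
#' Evidence added to a record is viewable by any user at any status, but a
#' curator's criterion evaluations and pathogenicity calculations stay
#' private until the classification is finalized (Approved, or Published):
#' only then do non-owners see the full classification, and even then
#' read-only.
#'
#' @param record A `vc_record`.
#' @param requester A `vc_owner`.
#' @return A `vc_view` list with `writable`, `evidence`, and — when visible —
#'   `evaluations`, `computed_classification`, `override_classification`,
#'   `conflict_flag`, `asserted_classification`, `status`.
#' @export
visible_view <- function(record, requester) {
  is_owner <- owner_can_edit(requester, record$owner)
  finalized <- record$status %in% c("Approved", "Published")
  view <- list(
    record_id = record$record_id,
    variant = record$variant,
    disease = record$disease,
    moi = record$moi,
    owner_id = record$owner$owner_id,
    writable = is_owner,
    evidence = record$evidence
  )
  if (is_owner || finalized) {
    view$status <- record$status
    view$evaluations <- record$evaluations
    view$computed_classification <- record$computed_classification
    view$override_classification <- record$override_classification
    view$conflict_flag <- record$conflict_flag
    view$asserted_classification <- asserted_classification(record)
  }
  structure(view, class = "vc_view")
}
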