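# The record store: a directory of canonical-JSON documents plus an index
# file — one document per record, evidence item and snapshot, and an
# append-only JSON-lines audit log of every saved curation action.
#
#   <path>/index.json             (owner|variant-key -> record_id)
#   <path>/records/<id>.json
#   <path>/evidence/<id>.json
#   <path>/snapshots/<id>.json
#   <path>/audit.jsonl

#' Initialize a new record store
#' @param path Directory to create (must not already hold a store).
#' @return A `vc_store` handle.
#' @export
store_init <- function(path) {
  if (file.exists(file.path(path, "index.json"))) {
    vc_abort("StoreError", paste0("a store already exists at ", path))
  }
  for (d in c("", "records", "evidence", "snapshots")) {
    dir.create(file.path(path, d), recursive = TRUE, showWarnings = FALSE)
  }
  vc_write_json(stats::setNames(list(), character(0)), file.path(path, "index.json"))
  file.create(file.path(path, "audit.jsonl"))
  store_open(path)
}

#' Open an existing record store
#' @param path Store directory.
#' @return A `vc_store` handle.
#' @export
store_open <- function(path) {
  if (!file.exists(file.path(path, "index.json"))) {
    vc_abort("StoreError", paste0("no record store at ", path))
  }
  structure(list(path = normalizePath(path)), class = "vc_store")
}

record_path   <- function(store, id) file.path(store$path, "records", paste0(id, ".json"))
evidence_path <- function(store, id) file.path(store$path, "evidence", paste0(id, ".json"))
snapshot_path <- function(store, id) file.path(store$path, "snapshots", paste0(id, ".json"))

store_read_index <- function(store) {
  idx <- vc_read_json(file.path(store$path, "index.json"))
  if (length(idx) == 0) stats::setNames(list(), character(0)) else idx
}

store_write_index <- function(store, idx) {
  vc_write_json(idx, file.path(store$path, "index.json"))
}

store_audit <- function(store, entry) {
  cat(canonical_json(entry), "\n", sep = "",
      file = file.path(store$path, "audit.jsonl"), append = TRUE)
}

#' Persist a record
#' @param store Store handle.
#' @param record A `vc_record`.
#' @return The record, invisibly.
#' @export
store_save_record <- function(store, record) {
  vc_write_json(record, record_path(store, record$record_id))
  invisible(record)
}

#' Load a record by ID
#' @param store Store handle.
#' @param record_id Record identifier.
#' @return A `vc_record`.
#' @export
store_load_record <- function(store, record_id) {
  p <- record_path(store, record_id)
  if (!file.exists(p)) {
    vc_abort("RecordNotFound", paste0("no record ", record_id))
  }
  as_vc_record(vc_read_json(p))
}

#' List record IDs in a store
#' @param store Store handle.
#' @return Character vector of record IDs.
#' @export
store_list_records <- function(store) {
  sort(unlist(store_read_index(store), use.names = FALSE))
}

#' Create a classification record
#'
#' Creates and persists a new record in status In-progress with no
#' evaluations (so the default classification is Uncertain significance).
#' Each owner is restricted to one record per variant: a repeat create for
#' the same (owner, canonical variant) raises `DuplicateRecord`.
#'
#' @param variant A `vc_variant` (see [variant_ref()]).
#' @param disease A `vc_disease`.
#' @param moi A `vc_moi`.
#' @param owner A `vc_owner`.
#' @param store An open store.
#' @param now Timestamp (injectable for reproducibility).
#' @return The persisted `vc_record`.
#' @export
create_classification_record <- function(variant, disease, moi, owner, store,
                                         now = vc_now()) {
  stopifnot(inherits(variant, "vc_variant"), inherits(disease, "vc_disease"),
            inherits(moi, "vc_moi"), inherits(owner, "vc_owner"))
  key <- paste(owner$owner_id, canonical_variant_key(variant), sep = "|")
  idx <- store_read_index(store)
  if (!is.null(idx[[key]])) {
    vc_abort("DuplicateRecord",
             paste0(owner$owner_id, " already has a classification record for ",
                    canonical_variant_key(variant)))
  }
  record <- new_classification_record(variant, disease, moi, owner, now)
  store_save_record(store, record)
  idx[[key]] <- record$record_id
  store_write_index(store, idx)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "create", actor = owner$owner_id))
  record
}

#' Re-associate a record with a different disease and/or mode of inheritance
#'
#' @param record A `vc_record`.
#' @param store Store handle.
#' @param disease New `vc_disease`, or `NULL` to keep.
#' @param moi New `vc_moi`, or `NULL` to keep.
#' @param actor Owner performing the change.
#' @param now Timestamp.
#' @return Updated record.
#' @export
reassociate_record <- function(record, store, disease = NULL, moi = NULL,
                               actor = NULL, now = vc_now()) {
  actor <- actor %||% structure(record$owner, class = "vc_owner")
  if (!owner_can_edit(actor, record$owner)) {
    vc_abort("NotOwner", "only the owning user or affiliation may edit a record")
  }
  if (!is.null(disease)) record$disease <- unclass(disease)
  if (!is.null(moi)) record$moi <- unclass(moi)
  record$modified <- now
  store_save_record(store, record)
  store_audit(store, list(time = now, record_id = record$record_id,
                          action = "reassociate", actor = actor$owner_id))
  record
}
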