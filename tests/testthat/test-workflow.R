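test_that("exactly the six legal transitions succeed over the full grid", {
  legal <- list(
    c("InProgress", "save_provisional", "Provisional"),
    c("Provisional", "approve", "Approved"),
    c("Approved", "edit", "NewProvisional"),
    c("NewProvisional", "approve", "Approved"),
    c("Approved", "publish", "Published"),
    c("Published", "attach_scv", "Published")
  )
  legal_keys <- vapply(legal, function(x) paste(x[1], x[2]), character(1))

  drive_to <- function(status, store, owner, i) {
    rec <- make_record(store, owner = owner, i = i)
    if (status == "InProgress") return(rec)
    rec <- transition(rec, "save_provisional", store = store)
    if (status == "Provisional") return(rec)
    rec <- transition(rec, "approve", store = store)
    if (status == "Approved") return(rec)
    if (status == "NewProvisional") return(transition(rec, "edit", store = store))
    transition(rec, "publish", store = store)
  }

  set.seed(10)
  store <- local_store()
  owner <- make_vcep()
  i <- 0
  for (status in WORKFLOW_STATUSES) {
    for (action in WORKFLOW_ACTIONS) {
      i <- i + 1
      rec <- drive_to(status, store, owner, i)
      key <- paste(status, action)
      if (key %in% legal_keys) {
        expected_to <- legal[[match(key, legal_keys)]][3]
        rec2 <- transition(rec, action, store = store, scv_id = "SCV000001")
        expect_equal(rec2$status, expected_to, info = key)
      } else {
        expect_error(transition(rec, action, store = store, scv_id = "SCV000001"),
                     class = "vc_IllegalTransition", info = key)
      }
    }
  }
})

test_that("each snapshot-producing transition appends exactly one snapshot", {
  set.seed(12)
  store <- local_store()
  owner <- make_vcep()
  rec <- make_record(store, owner = owner)
  expect_length(list_snapshots(store, rec$record_id), 0)

  rec <- transition(rec, "save_provisional", store = store, now = "2026-01-02T00:00:00Z")
  rec <- transition(rec, "approve", store = store, now = "2026-01-03T00:00:00Z")
  snaps <- list_snapshots(store, rec$record_id)
  expect_length(snaps, 2)
  expect_equal(vapply(snaps, function(s) s$status_at_capture, character(1)),
               c("Provisional", "Approved"))
  # chronological / capture order (ISO-8601 sorts lexicographically)
  times <- vapply(snaps, function(s) s$captured_at, character(1))
  expect_identical(times, sort(times))

  # edit (no snapshot) then re-approve (one snapshot), then publish (one more)
  rec <- transition(rec, "edit", store = store)
  expect_length(list_snapshots(store, rec$record_id), 2)
  rec <- transition(rec, "approve", store = store)
  rec <- transition(rec, "publish", store = store)
  snaps <- list_snapshots(store, rec$record_id)
  expect_length(snaps, 4)
  # a published record has at least one Approved snapshot behind it
  expect_true("Approved" %in% vapply(snaps, function(s) s$status_at_capture,
                                     character(1)))
})

test_that("snapshots are immutable under edits to the live record", {
  set.seed(13)
  store <- local_store()
  rec <- make_record(store)
  rec <- evaluate(rec, "PS3", "Met", store = store)
  rec <- transition(rec, "save_provisional", store = store)
  snap <- list_snapshots(store, rec$record_id)[[1]]
  digest_before <- snap$digest
  expect_identical(digest_before, content_hash(snap$full_copy))

  rec <- evaluate(rec, "PM2", "Met", store = store)
  rec <- evaluate(rec, "PS3", "NotMet", store = store)
  rec <- add_article_evidence(rec, "Population", article_ref(pmid = "123"),
                              store = store)
  snap_again <- list_snapshots(store, rec$record_id)[[1]]
  expect_identical(snap_again$digest, digest_before)
  expect_identical(content_hash(snap_again$full_copy), digest_before)
  # the live record has moved on
  expect_false(identical(content_hash(rec), digest_before))
})

test_that("snapshots dereference evidence and refuse dangling references", {
  set.seed(14)
  store <- local_store()
  rec <- make_record(store)
  rec <- add_article_evidence(rec, "Experimental", article_ref(pmid = "999"),
                              note = "assay report", store = store)
  snap <- take_snapshot(rec, store, now = "2026-01-05T00:00:00Z")
  expect_length(snap$full_copy$evidence_items, 1)
  expect_equal(snap$full_copy$evidence_items[[1]]$source, "PMID:999")

  # two snapshots of an unchanged record: same content digest, distinct ids
  snap2 <- take_snapshot(rec, store, now = "2026-01-05T00:00:00Z",
                         seq = snap$capture_seq + 1L)
  expect_identical(content_hash(snap$full_copy), content_hash(snap2$full_copy))
  expect_false(identical(snap$snapshot_id, snap2$snapshot_id))

  rec$evidence <- c(rec$evidence, list("dangling-id"))
  expect_error(take_snapshot(rec, store), class = "vc_SerializationError")
})

test_that("publishing is gated on expert-panel ownership and SCV format", {
  set.seed(15)
  store <- local_store()
  plain <- make_owner("solo")
  rec <- approve_record(make_record(store, owner = plain, i = 1), store,
                        owner = plain)
  expect_error(transition(rec, "publish", store = store),
               class = "vc_PublishNotPermitted")
  # a configuration override admits non-expert-panel owners
  rs <- default_ruleset(allow_publish_non_vcep = TRUE)
  rec <- transition(rec, "publish", store = store, ruleset = rs)
  expect_equal(rec$status, "Published")
  expect_true(rec$published)

  expect_error(transition(rec, "attach_scv", store = store, scv_id = "XCV1"),
               class = "vc_InvalidIdentifier")
  rec <- transition(rec, "attach_scv", store = store, scv_id = "SCV000123")
  expect_equal(rec$scv, "SCV000123")

  # a published record is frozen against evaluation edits
  expect_error(evaluate(rec, "PM2", "Met", store = store),
               class = "vc_IllegalTransition")
})

test_that("editing an approved record automatically demotes it", {
  set.seed(16)
  store <- local_store()
  rec <- approve_record(make_record(store), store)
  expect_equal(rec$status, "Approved")
  rec <- evaluate(rec, "PM6", "Met", store = store)
  expect_equal(rec$status, "NewProvisional")
  # provisional records accept edits without a status change
  rec2 <- make_record(store, i = 2)
  rec2 <- transition(rec2, "save_provisional", store = store)
  rec2 <- evaluate(rec2, "PM2", "Met", store = store)
  expect_equal(rec2$status, "Provisional")
})

test_that("affiliation members share edit rights; strangers hold none", {
  set.seed(17)
  store <- local_store()
  panel <- make_vcep("panel-9", members = c("alice", "bob"))
  rec <- make_record(store, owner = panel)
  alice <- make_owner("alice")
  rec <- evaluate(rec, "PM2", "Met", actor = alice, store = store)
  expect_equal(criteria_bar(rec)$display_state[criteria_bar(rec)$code == "PM2"], "Met")
  eve <- make_owner("eve")
  expect_error(evaluate(rec, "PM3", "Met", actor = eve, store = store),
               class = "vc_NotOwner")
  expect_error(transition(rec, "save_provisional", actor = eve, store = store),
               class = "vc_NotOwner")
})

test_that("evaluations stay private to non-owners until approval", {
  set.seed(18)
  store <- local_store()
  rec <- make_record(store)
  rec <- evaluate(rec, "PS3", "Met", store = store)
  rec <- add_article_evidence(rec, "Experimental", article_ref(pmid = "321"),
                              store = store)
  other <- make_owner("user-B")

  # in progress: evidence visible, evaluations absent, read-only
  view <- visible_view(rec, other)
  expect_false(view$writable)
  expect_length(view$evidence, 1)
  expect_null(view$evaluations)
  expect_null(view$computed_classification)

  # the owner always sees a writable, complete view
  own <- visible_view(rec, make_owner("user-A"))
  expect_true(own$writable)
  expect_length(own$evaluations, 1)

  # approved: full read-only view for everyone
  rec <- transition(rec, "save_provisional", store = store)
  rec <- transition(rec, "approve", store = store)
  view <- visible_view(rec, other)
  expect_false(view$writable)
  expect_length(view$evaluations, 1)
  expect_equal(view$asserted_classification, rec$computed_classification)
})

test_that("the audit log records every saved curation action", {
  set.seed(19)
  store <- local_store()
  rec <- make_record(store)
  rec <- evaluate(rec, "PM2", "Met", store = store)
  rec <- transition(rec, "save_provisional", store = store)
  log <- readLines(file.path(store$path, "audit.jsonl"))
  entries <- lapply(log, jsonlite::fromJSON)
  actions <- vapply(entries, function(e) e$action, character(1))
  expect_equal(actions, c("create", "evaluate", "save_provisional"))
})
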