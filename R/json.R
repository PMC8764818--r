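# Canonical JSON serialization and content addressing.
#
# All documents (records, snapshots, evidence items, fixture bundles,
# interpretation documents) are persisted as canonical JSON: UTF-8, keys of
# every object sorted, NULL fields dropped, scalars unboxed. Two documents
# with the same content therefore serialize to the same byte string, which is
# what makes content hashes usable as immutability witnesses for snapshots.

vc_canonicalize <- function(x) {
  if (is.function(x) || is.environment(x)) {
    vc_abort("SerializationError",
             "document contains non-serializable content (function/environment)")
  }
  if (is.list(x)) {
    x <- unclass(x)
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) {
      x <- x[!vapply(x, is.null, logical(1))]
      x <- x[order(names(x), method = "radix")]
    }
    return(lapply(x, vc_canonicalize))
  }
  attributes(x) <- if (is.null(names(x))) NULL else list(names = names(x))
  x
}

#' Serialize a document to canonical JSON
#'
#' @param x A list-like document.
#' @return A single JSON string with sorted keys and unboxed scalars.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(
    vc_canonicalize(x),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  ))
}

#' Content hash of a document
#'
#' SHA-256 over the canonical JSON serialization. Equal documents (up to
#' field order) hash equal; any field change yields a different digest.
#'
#' @param document A record, snapshot, or any serializable list document.
#' @return A hex digest string.
#' @export
content_hash <- function(document) {
  digest::digest(canonical_json(document), algo = "sha256", serialize = FALSE)
}

vc_read_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

vc_write_json <- function(x, path) {
  writeLines(canonical_json(x), path, useBytes = TRUE)
  invisible(path)
}

# ISO-8601 UTC timestamp; tests and the CLI inject fixed values so exports
# stay byte-identical.
vc_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# RNG-derived identifier: reproducible under set.seed(), UUID4-shaped.
vc_uuid <- function() {
  h <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
  h[13] <- "4"
  h[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(
    paste(h[1:8], collapse = ""), "-", paste(h[9:12], collapse = ""), "-",
    paste(h[13:16], collapse = ""), "-", paste(h[17:20], collapse = ""), "-",
    paste(h[21:32], collapse = "")
  )
}
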