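# Fixture-backed variant resolver.
#
# Stands in for the external-resources layer: a local JSON bundle maps
# canonical variant IDs to the evidence normally pulled from remote services
# (transcripts with MANE flags, allele frequencies, in silico and
# conservation scores, ClinVar summaries, gene-level annotation). The
# backend is read-only and pluggable; only the offline fixture backend
# ships — live adapters would implement the same three lookups
# (resolve, evidence bundle, consequences) against the remote APIs.

#' Load and validate a fixture bundle
#'
#' Structural validation on open: every variant entry must carry a
#' well-formed CAid and/or ClinVar ID, allele frequencies must lie in
#' \[0, 1\], at most one transcript per variant may be MANE Select, and no
#' two entries may claim the same identifier.
#'
#' @param path Path to a fixture-bundle JSON file.
#' @return A `vc_fixtures` object with `$variants`, `$by_caid`, `$by_clinvar`.
#' @export
load_fixture_bundle <- function(path) {
  raw <- vc_read_json(path)
  variants <- raw$variants %||% raw
  by_caid <- character(0)
  by_clinvar <- character(0)
  for (key in names(variants)) {
    v <- variants[[key]]
    caid <- v$caid
    cvid <- v$clinvar_id
    if (is.null(caid) && is.null(cvid)) {
      vc_abort("SchemaViolation",
               paste0("fixture entry ", key, " has neither CAid nor ClinVar ID"))
    }
    if (!is.null(caid)) {
      if (!grepl(.CAID_PATTERN, caid)) {
        vc_abort("SchemaViolation", paste0("fixture entry ", key, ": malformed CAid"))
      }
      if (caid %in% names(by_caid)) {
        vc_abort("AmbiguousId", paste0("two fixture entries claim CAid ", caid))
      }
      by_caid[[caid]] <- key
    }
    if (!is.null(cvid)) {
      cvid <- as.character(cvid)
      if (cvid %in% names(by_clinvar)) {
        vc_abort("AmbiguousId", paste0("two fixture entries claim ClinVar ID ", cvid))
      }
      by_clinvar[[cvid]] <- key
    }
    afs <- unlist(v$allele_frequencies)
    if (length(afs) && (any(afs < 0) || any(afs > 1))) {
      vc_abort("SchemaViolation",
               paste0("fixture entry ", key, ": allele frequency outside [0,1]"))
    }
    n_mane <- sum(vapply(v$transcripts %||% list(),
                         function(t) isTRUE(t$is_mane_select), logical(1)))
    if (n_mane > 1) {
      vc_abort("SchemaViolation",
               paste0("fixture entry ", key, ": multiple MANE Select transcripts"))
    }
  }
  structure(list(variants = variants, by_caid = by_caid, by_clinvar = by_clinvar),
            class = "vc_fixtures")
}

fixture_entry <- function(id, fixtures) {
  id <- as.character(id)
  key <- NA_character_
  if (grepl(.CAID_PATTERN, id)) key <- unname(fixtures$by_caid[id])
  if (is.na(key)) key <- unname(fixtures$by_clinvar[id])
  if (is.na(key)) {
    vc_abort("VariantNotFound", paste0("no fixture entry for variant ", id))
  }
  fixtures$variants[[key]]
}

#' Resolve a variant identifier to a populated variant reference
#'
#' Resolution is by CAid first, then by ClinVar Variation ID; both routes to
#' the same fixture entry yield the identical reference.
#'
#' @param id CAid (`"CA…"`) or ClinVar Variation ID (digits).
#' @param fixtures A loaded `vc_fixtures` bundle.
#' @return A `vc_variant` with the entry's HGVS names and gene symbol.
#' @export
resolve_variant <- function(id, fixtures) {
  v <- fixture_entry(id, fixtures)
  hgvs <- lapply(v$transcripts %||% list(), function(t) {
    list(reference = t$id, hgvs = t$hgvs_c,
         protein_hgvs = t$hgvs_p %||% NULL,
         is_mane_select = isTRUE(t$is_mane_select))
  })
  if (!is.null(v$genomic_hgvs)) {
    hgvs <- c(hgvs, list(list(reference = "genomic", hgvs = v$genomic_hgvs,
                              is_mane_select = FALSE)))
  }
  variant_ref(caid = v$caid, clinvar_id = v$clinvar_id, hgvs_names = hgvs,
              gene_symbol = v$gene_symbol %||% NULL)
}

# "p.(Lys34Glu)" -> "p.Lys34Glu" for title display
strip_protein_parens <- function(p) {
  sub("^p\\.\\((.*)\\)$", "p.\\1", p)
}

#' Display title for a variant
#'
#' Naming hierarchy: (1) the MANE Select transcript HGVS with gene symbol and
#' protein change, formatted `GENE(TRANSCRIPT):c.change (p.change)`; (2) any
#' other transcript-level HGVS in the same shape; (3) a genomic HGVS;
#' (4) the bare CAid (or ClinVar ID). Deterministic.
#'
#' @param variant A `vc_variant`.
#' @return A display string.
#' @export
variant_title <- function(variant) {
  hgvs <- variant$hgvs_names %||% list()
  transcript_title <- function(h) {
    base <- if (!is.null(variant$gene_symbol)) {
      paste0(variant$gene_symbol, "(", h$reference, "):", h$hgvs)
    } else {
      paste0(h$reference, ":", h$hgvs)
    }
    if (!is.null(h$protein_hgvs) && nzchar(h$protein_hgvs)) {
      base <- paste0(base, " (", strip_protein_parens(h$protein_hgvs), ")")
    }
    base
  }
  mane <- Filter(function(h) isTRUE(h$is_mane_select), hgvs)
  if (length(mane)) return(transcript_title(mane[[1]]))
  tx <- Filter(function(h) !identical(h$reference, "genomic"), hgvs)
  if (length(tx)) return(transcript_title(tx[[1]]))
  genomic <- Filter(function(h) identical(h$reference, "genomic"), hgvs)
  if (length(genomic)) return(genomic[[1]]$hgvs)
  variant$caid %||% paste0("clinvar:", variant$clinvar_id)
}

#' Fetch the evidence bundle for a variant
#'
#' Slices the fixture entry into tab-shaped sections: Population carries the
#' allele-frequency sources, VariantType the in silico and conservation
#' scores, BasicInfo the ClinVar summary and transcript list, GeneCentric the
#' gene-level annotation. Missing sources yield empty sections, never errors.
#'
#' @param variant A `vc_variant` (or a bare identifier string).
#' @param fixtures A `vc_fixtures` bundle.
#' @return A `vc_evidence_bundle` list keyed by tab.
#' @export
fetch_evidence_bundle <- function(variant, fixtures) {
  id <- if (is.character(variant)) variant else
    variant$caid %||% variant$clinvar_id
  v <- fixture_entry(id, fixtures)
  structure(
    list(
      Population = list(allele_frequencies = v$allele_frequencies %||%
                          stats::setNames(list(), character(0))),
      VariantType = list(
        insilico = v$insilico_scores %||% stats::setNames(list(), character(0)),
        conservation = v$conservation_scores %||% stats::setNames(list(), character(0))
      ),
      BasicInfo = list(clinvar_summary = v$clinvar_summary %||% NULL,
                       transcripts = v$transcripts %||% list()),
      GeneCentric = list(gene_info = v$gene_info %||% NULL,
                         gene_symbol = v$gene_symbol %||% NULL)
    ),
    class = "vc_evidence_bundle"
  )
}

#' Molecular consequences per transcript
#'
#' One row per fixture transcript with the MANE Select row first and the
#' remainder in fixture order.
#'
#' @param variant A `vc_variant` or identifier string.
#' @param fixtures A `vc_fixtures` bundle.
#' @return data.frame with columns `transcript`, `consequence`, `is_mane`.
#' @export
molecular_consequences <- function(variant, fixtures) {
  id <- if (is.character(variant)) variant else
    variant$caid %||% variant$clinvar_id
  v <- fixture_entry(id, fixtures)
  tx <- v$transcripts %||% list()
  if (length(tx) == 0) {
    return(data.frame(transcript = character(0), consequence = character(0),
                      is_mane = logical(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    transcript = vapply(tx, function(t) t$id, character(1)),
    consequence = vapply(tx, function(t) t$consequence %||% NA_character_, character(1)),
    is_mane = vapply(tx, function(t) isTRUE(t$is_mane_select), logical(1)),
    stringsAsFactors = FALSE
  )
  df[order(!df$is_mane), , drop = FALSE]
}
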