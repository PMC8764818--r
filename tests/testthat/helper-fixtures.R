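# Shared test builders: stores, owners, variants, records and small fixture
# bundles are constructed in code, never stored on disk.

local_store <- function(env = parent.frame()) {
  path <- withr::local_tempdir(.local_envir = env)
  store_init(file.path(path, "store"))
}

make_owner <- function(id = "user-A", kind = "individual", vcep = FALSE,
                       members = character(0)) {
  owner_ref(id, kind = kind, is_vcep = vcep, members = members)
}

make_vcep <- function(id = "vcep-1", members = c("user-A", "user-B")) {
  owner_ref(id, kind = "affiliation", is_vcep = TRUE, members = members)
}

make_variant <- function(i = 1, mane = TRUE, gene = "ABCD") {
  hgvs <- list(
    list(reference = "NM_000001.2", hgvs = "c.100A>G",
         protein_hgvs = "p.(Lys34Glu)", is_mane_select = mane),
    list(reference = "genomic", hgvs = "NC_000001.11:g.1000A>G",
         is_mane_select = FALSE)
  )
  variant_ref(caid = sprintf("CA%06d", i), clinvar_id = as.character(100000 + i),
              hgvs_names = hgvs, gene_symbol = gene)
}

make_disease <- function() disease_ref("MONDO:0004975", "Alzheimer disease")
make_moi <- function() moi_ref("HP:0000006", "Autosomal dominant inheritance")

make_record <- function(store, owner = make_owner(), i = 1, now = "2026-01-01T00:00:00Z") {
  create_classification_record(make_variant(i), make_disease(), make_moi(),
                               owner, store, now = now)
}

# drive a record to Approved with the given Met codes
approve_record <- function(record, store, met = c("PS3", "PM2"),
                           owner = NULL, now = "2026-01-02T00:00:00Z") {
  owner <- owner %||% structure(record$owner, class = "vc_owner")
  for (code in met) {
    record <- evaluate(record, code, "Met", store = store, actor = owner, now = now)
  }
  record <- transition(record, "save_provisional", actor = owner, store = store, now = now)
  transition(record, "approve", actor = owner, store = store, now = now)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-built fixture bundle with two variants (one MANE, one genomic-only)
make_bundle_file <- function(path) {
  bundle <- list(variants = list(
    CA000001 = list(
      caid = "CA000001", clinvar_id = "100001", gene_symbol = "ABCD",
      transcripts = list(
        list(id = "NM_000001.2", hgvs_c = "c.100A>G", hgvs_p = "p.(Lys34Glu)",
             is_mane_select = TRUE, consequence = "missense_variant"),
        list(id = "NM_000002.1", hgvs_c = "c.130A>G", hgvs_p = "p.(Lys44Glu)",
             is_mane_select = FALSE, consequence = "missense_variant"),
        list(id = "ENST0000003", hgvs_c = "c.88A>G",
             is_mane_select = FALSE, consequence = "intron_variant")
      ),
      genomic_hgvs = "NC_000001.11:g.5000A>G",
      clinvar_summary = list(overall_interpretation = "Uncertain significance",
                             n_submissions = 3),
      allele_frequencies = list(gnomAD = 1e-04, ExAC = 2e-04),
      insilico_scores = list(REVEL = 0.87, CADD = 25.1),
      conservation_scores = list(phyloP100way = 7.2, GERPpp = 5.1),
      gene_info = list(constraint_pLI = 0.99, uniprot_id = "P12345")
    ),
    CA000002 = list(
      caid = "CA000002",
      transcripts = list(),
      genomic_hgvs = "NC_000002.12:g.123456C>T",
      allele_frequencies = NULL
    )
  ))
  writeLines(canonical_json(bundle), path, useBytes = TRUE)
  path
}
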