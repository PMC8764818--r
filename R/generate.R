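# Seeded synthetic fixture generator.
#
# Produces a schema-valid fixture bundle emulating the external evidence
# sources: CAids/ClinVar IDs, transcripts with MANE flags, allele
# frequencies across population sources, in silico and conservation scores
# in realistic ranges, ClinVar summaries and gene annotation. Each variant
# is assigned an evaluation scenario (benign-rich, pathogenic-rich,
# conflicting, or empty) so the full classification pipeline can be
# exercised offline. A single RNG stream seeded from the config drives
# everything, so equal seeds give byte-identical bundles.

.SCENARIOS <- c("pathogenic_rich", "benign_rich", "conflicting", "empty")

#' Generator configuration
#'
#' @param seed Integer RNG seed.
#' @param n_variants Number of variants to generate.
#' @param p_mane Probability a variant has a MANE Select transcript.
#' @param p_clinvar Probability a variant carries a ClinVar Variation ID.
#' @param p_frequency Probability a variant has allele-frequency data.
#' @param scenario_weights Named weights over the four evaluation scenarios
#'   (`pathogenic_rich`, `benign_rich`, `conflicting`, `empty`); must sum
#'   to 1.
#' @return A `vc_genconfig`.
#' @export
generator_config <- function(seed = 1L, n_variants = 10L, p_mane = 0.8,
                             p_clinvar = 0.7, p_frequency = 0.85,
                             scenario_weights = c(pathogenic_rich = 0.3,
                                                  benign_rich = 0.3,
                                                  conflicting = 0.2,
                                                  empty = 0.2)) {
  probs <- c(p_mane, p_clinvar, p_frequency)
  if (any(probs < 0) || any(probs > 1)) {
    vc_abort("ConfigError", "probabilities must lie in [0, 1]")
  }
  if (!setequal(names(scenario_weights), .SCENARIOS)) {
    vc_abort("ConfigError", "scenario_weights must cover exactly the four scenarios")
  }
  if (abs(sum(scenario_weights) - 1) > 1e-8) {
    vc_abort("ConfigError", "scenario_weights must sum to 1")
  }
  if (n_variants < 1) vc_abort("ConfigError", "n_variants must be positive")
  structure(
    list(seed = as.integer(seed), n_variants = as.integer(n_variants),
         p_mane = p_mane, p_clinvar = p_clinvar, p_frequency = p_frequency,
         scenario_weights = scenario_weights[.SCENARIOS]),
    class = "vc_genconfig"
  )
}

.GENE_POOL <- c("BRCA2", "MYH7", "TP53", "CFTR", "LDLR", "SCN5A", "MLH1",
                "FBN1", "KCNQ1", "PTEN", "COL3A1", "RYR1")
.CONSEQUENCES <- c("missense_variant", "synonymous_variant", "stop_gained",
                   "splice_donor_variant", "frameshift_variant",
                   "intron_variant", "inframe_deletion")
.AA <- c("Ala", "Arg", "Asn", "Asp", "Gly", "Leu", "Lys", "Ser", "Thr", "Val")

generate_variant_entry <- function(i, config) {
  gene <- sample(.GENE_POOL, 1)
  n_tx <- sample(1:3, 1)
  has_mane <- stats::runif(1) < config$p_mane
  pos <- sample(50:5000, 1)
  ref_alt <- sample(c("A", "C", "G", "T"), 2)
  hgvs_c <- sprintf("c.%d%s>%s", pos, ref_alt[1], ref_alt[2])
  transcripts <- lapply(seq_len(n_tx), function(k) {
    list(
      id = sprintf("NM_%06d.%d", sample.int(999999, 1), sample(1:5, 1)),
      hgvs_c = hgvs_c,
      hgvs_p = sprintf("p.(%s%d%s)", sample(.AA, 1), ceiling(pos / 3), sample(.AA, 1)),
      is_mane_select = has_mane && k == 1,
      consequence = sample(.CONSEQUENCES, 1)
    )
  })
  afs <- NULL
  if (stats::runif(1) < config$p_frequency) {
    base <- stats::rbeta(1, 0.2, 30)   # rare-variant-shaped frequency spectrum
    afs <- list(
      gnomAD = min(1, base),
      ExAC = min(1, base * stats::runif(1, 0.5, 1.5)),
      `1000Genomes` = min(1, base * stats::runif(1, 0, 2))
    )
  }
  entry <- list(
    caid = sprintf("CA%06d", i),
    gene_symbol = gene,
    transcripts = transcripts,
    genomic_hgvs = sprintf("NC_0000%02d.11:g.%d%s>%s", sample(1:22, 1),
                           floor(stats::runif(1, 1e5, 2e8)), ref_alt[1], ref_alt[2]),
    clinvar_summary = list(
      overall_interpretation = sample(CLASSIFICATION_CATEGORIES, 1),
      n_submissions = sample(0:25, 1)
    ),
    allele_frequencies = afs,
    insilico_scores = list(
      REVEL = round(stats::runif(1), 3),
      CADD = round(stats::runif(1, 0, 60), 2),
      SIFT = round(stats::runif(1), 3),
      PolyPhen2 = round(stats::runif(1), 3)
    ),
    conservation_scores = list(
      phyloP100way = round(stats::runif(1, -14, 10), 3),
      phastCons100way = round(stats::runif(1), 3),
      GERPpp = round(stats::runif(1, -12, 6), 2),
      SiPhy = round(stats::runif(1, 0, 20), 2)
    ),
    gene_info = list(
      constraint_pLI = round(stats::runif(1), 3),
      uniprot_id = sprintf("P%05d", sample(1:99999, 1))
    )
  )
  if (stats::runif(1) < config$p_clinvar) {
    entry$clinvar_id <- as.character(100000 + i)
  }
  entry
}

# Criterion sets characteristic of each scenario; strengths at defaults.
scenario_evaluations <- function(scenario) {
  switch(scenario,
    pathogenic_rich = c("PVS1", "PS3", "PM2", "PP3"),
    benign_rich = c("BA1", "BS3", "BP4"),
    conflicting = c("PS3", "PM2", "BS1", "BS2"),
    empty = character(0)
  )
}

#' Generate a synthetic fixture bundle
#'
#' @param config A `vc_genconfig` (see [generator_config()]).
#' @param file Optional path to write the bundle JSON to.
#' @return The bundle as a list (invisibly when writing); each variant entry
#'   carries a `scenario` tag naming its evaluation scenario so pipeline
#'   tests can pick representatives of each class. At least one variant per
#'   scenario class is always present.
#' @export
generate_fixture_bundle <- function(config = generator_config(), file = NULL) {
  stopifnot(inherits(config, "vc_genconfig"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  n <- config$n_variants
  # guarantee scenario coverage, then fill by weight
  scenarios <- .SCENARIOS[seq_len(min(n, length(.SCENARIOS)))]
  if (n > length(.SCENARIOS)) {
    scenarios <- c(scenarios,
                   sample(.SCENARIOS, n - length(.SCENARIOS), replace = TRUE,
                          prob = config$scenario_weights))
  }
  variants <- stats::setNames(vector("list", n), character(n))
  for (i in seq_len(n)) {
    entry <- generate_variant_entry(i, config)
    entry$scenario <- scenarios[i]
    names(variants)[i] <- entry$caid
    variants[[i]] <- entry
  }
  bundle <- list(generator = list(seed = config$seed, n_variants = n),
                 variants = variants)
  if (!is.null(file)) {
    vc_write_json(bundle, file)
    return(invisible(bundle))
  }
  bundle
}
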