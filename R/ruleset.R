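# Pluggable rule sets.
#
# The combining rules, allowed-strength table, tab map and conflict handling
# are bundled into a rule set object so expert-panel specifications can be
# swapped in from a YAML/JSON configuration file without touching the engine.

#' The shipped default rule set
#'
#' Default 2015 combining rules, the default allowed-strength table, and the
#' four-tab criterion grouping (Population, Variant Type, Experimental,
#' Case/Segregation).
#'
#' @param ba1_standalone_wins If `TRUE`, a met BA1 dominates conflicting
#'   pathogenic evidence instead of flagging Uncertain significance.
#' @param allow_publish_non_vcep If `TRUE`, affiliations that are not
#'   expert panels (and individuals) may publish approved records.
#' @param phi_mode `"strict"` (reject text failing the PHI guard) or
#'   `"warn"` (accept with a warning).
#' @return A `vc_ruleset` object.
#' @export
default_ruleset <- function(ba1_standalone_wins = FALSE,
                            allow_publish_non_vcep = FALSE,
                            phi_mode = c("strict", "warn")) {
  phi_mode <- match.arg(phi_mode)
  structure(
    list(
      name = "acmg-amp-2015-default",
      ba1_standalone_wins = isTRUE(ba1_standalone_wins),
      allow_publish_non_vcep = isTRUE(allow_publish_non_vcep),
      phi_mode = phi_mode,
      phi_max_chars = 500L,
      allowed_strengths = list(),   # per-code overrides; empty = built-in table
      tab_map = .default_tab_map
    ),
    class = "vc_ruleset"
  )
}

#' Load a rule set from a YAML or JSON configuration file
#'
#' Recognised keys: `name`, `ba1_standalone_wins`, `allow_publish_non_vcep`,
#' `phi_mode`, `phi_max_chars`, `allowed_strengths` (mapping code -> list of
#' strength levels), `tab_map` (mapping tab -> list of codes). Unspecified
#' keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `vc_ruleset`.
#' @export
load_ruleset <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    vc_read_json(path)
  }
  rs <- default_ruleset()
  for (key in c("name", "ba1_standalone_wins", "allow_publish_non_vcep",
                "phi_mode", "phi_max_chars")) {
    if (!is.null(cfg[[key]])) rs[[key]] <- cfg[[key]]
  }
  if (!is.null(cfg$allowed_strengths)) {
    for (code in names(cfg$allowed_strengths)) {
      lv <- unlist(cfg$allowed_strengths[[code]])
      if (!all(lv %in% STRENGTH_LEVELS)) {
        vc_abort("ConfigError", paste0("unknown strength level for ", code))
      }
      rs$allowed_strengths[[code]] <- lv
    }
  }
  if (!is.null(cfg$tab_map)) {
    tm <- lapply(cfg$tab_map, function(x) unlist(x))
    if (!all(names(tm) %in% EVIDENCE_TABS)) {
      vc_abort("ConfigError", "tab_map keys must be evidence tabs")
    }
    all_codes <- unlist(tm, use.names = FALSE)
    if (anyDuplicated(all_codes)) {
      vc_abort("ConfigError", "a criterion may appear in only one tab")
    }
    rs$tab_map <- tm
  }
  rs
}
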