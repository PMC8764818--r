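# Independent brute-force transcription of the 2015 default combining table,
# written as literal rule rows (one predicate per published row) so it shares
# no code with compute_classification(). Surplus very-strong criteria count
# into the strong tier, matching the engine's documented convention.

oracle_classify <- function(vs, s, m, p, ba, bs, bp) {
  strong <- s + if (vs >= 2) vs - 1 else 0

  pathogenic_rows <- list(
    function() vs >= 1 && strong >= 1,            # Ia: 1 VS + >=1 S
    function() vs >= 1 && m >= 2,                 # Ib: 1 VS + >=2 M
    function() vs >= 1 && m >= 1 && p >= 1,       # Ic: 1 VS + 1 M + 1 P
    function() vs >= 1 && p >= 2,                 # Id: 1 VS + >=2 P
    function() strong >= 2,                       # II: >=2 S
    function() strong >= 1 && m >= 3,             # IIIa: 1 S + >=3 M
    function() strong >= 1 && m >= 2 && p >= 2,   # IIIb: 1 S + 2 M + >=2 P
    function() strong >= 1 && m >= 1 && p >= 4    # IIIc: 1 S + 1 M + >=4 P
  )
  likely_pathogenic_rows <- list(
    function() vs >= 1 && m >= 1,                 # i: 1 VS + 1 M
    function() strong >= 1 && m >= 1,             # ii: 1 S + 1-2 M
    function() strong >= 1 && p >= 2,             # iii: 1 S + >=2 P
    function() m >= 3,                            # iv: >=3 M
    function() m >= 2 && p >= 2,                  # v: 2 M + >=2 P
    function() m >= 1 && p >= 4                   # vi: 1 M + >=4 P
  )
  benign_rows <- list(
    function() ba >= 1,                           # i: 1 stand-alone
    function() bs >= 2                            # ii: >=2 BS
  )
  likely_benign_rows <- list(
    function() bs >= 1 && bp >= 1,                # i: 1 BS + 1 BP
    function() bp >= 2                            # ii: >=2 BP
  )

  fired <- function(rows) any(vapply(rows, function(f) f(), logical(1)))
  path_cat <- if (fired(pathogenic_rows)) "Pathogenic"
              else if (fired(likely_pathogenic_rows)) "Likely pathogenic"
              else NA_character_
  ben_cat <- if (fired(benign_rows)) "Benign"
             else if (fired(likely_benign_rows)) "Likely benign"
             else NA_character_

  if (!is.na(path_cat) && !is.na(ben_cat)) {
    return(list(category = "Uncertain significance", conflict = TRUE))
  }
  if (!is.na(path_cat)) return(list(category = path_cat, conflict = FALSE))
  if (!is.na(ben_cat)) return(list(category = ben_cat, conflict = FALSE))
  list(category = "Uncertain significance", conflict = FALSE)
}
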