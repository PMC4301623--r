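# Shared fixtures and independent oracles, built in code.

# Spec-literal episode oracle, implemented on a different route from the
# production detector: encode each day as '.' (no qualifying symptom),
# 'S' (exactly one of fever / fast-difficult-breathing) or 'C' (both), then
# let the regex engine find maximal symptomatic stretches whose internal
# symptom-free gaps are at most 6 days; keep stretches spanning >= 2 days
# that contain a 'C' day.
oracle_detect <- function(f, b) {
  code <- ifelse(f & b, "C", ifelse(f | b, "S", "."))
  s <- paste(code, collapse = "")
  m <- gregexpr("[SC](?:\\.{0,6}[SC])*", s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(cbind(start = integer(0), end = integer(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= 2L & vapply(seq_along(starts), function(i)
    grepl("C", substr(s, starts[i], starts[i] + lens[i] - 1L), fixed = TRUE),
    logical(1))
  cbind(start = starts[keep], end = starts[keep] + lens[keep] - 1L)
}

# production detector reduced to (start, end) pairs, for oracle comparison
core_detect <- function(f, b) {
  ep <- stovesim:::detect_core(f, b)
  cbind(start = unname(ep[, "start"]), end = unname(ep[, "end"]))
}

# build a one-child diary data frame from symptom vectors
mk_diary <- function(f, b, id = "a", start = as.Date("2011-01-01")) {
  data.frame(child_id = id, date = start + seq_along(f) - 1L,
             fever = f, fast_difficult_breathing = b)
}

# small desk-scale design and panel for GLMM tests: 12 groups x 1 sector
desk_design <- function(seed = 1)
  sw_design(sectors_per_group = 1,
            wedge_order = randomize_wedge_order(12, seed = seed))

desk_panel <- function(theta = 0, trend = "none", mean_children = 6,
                       seed = 1, design = desk_design()) {
  simulate_panel(design,
                 params = sim_params(theta = theta, trend = trend,
                                     mean_children_per_sector = mean_children),
                 seed = seed)
}
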