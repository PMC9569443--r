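# Shared fixtures: the printed transition-table values (frozen), a toy
# prelamin sequence, and a small fast absolute panel for simulations.

# Printed m/z values of the three published panels, keyed by
# "symbol|prec", "symbol|sel<i>" (MS3 selection of trace i) and
# "symbol|mon<i>" (monitored m/z of trace i). The hFP* NL trace is not
# listed: its printed value is inconsistent with the row's own label
# definition (it differs from the light NL by the Lys-label delta while
# the precursor and b12 shift by the Ala-label delta).
published_mz <- function() {
  list(
    mouse_relative = c(
      "IC|prec" = 703.8238, "IC|sel1" = 430.2296, "IC|mon1" = 333.1769,
      "IC|sel2" = 603.7657, "IC|mon2" = 933.4095,
      "LA|prec" = 783.8791, "LA|sel1" = 690.8288, "LA|mon1" = 774.4104,
      "LA|sel2" = 774.4104, "LA|mon2" = 602.3620,
      "mFP|prec" = 670.3374, "mFP|sel1" = 568.2435, "mFP|mon1" = 886.4013,
      "mFP|sel2" = 1135.4797, "mFP|mon2" = 993.4054),
    human_relative = c(
      "IC|prec" = 703.8238, "IC|sel1" = 430.2296, "IC|mon1" = 333.1769,
      "IC|sel2" = 603.7657, "IC|mon2" = 933.4095,
      "LA|prec" = 783.8791, "LA|sel1" = 690.8288, "LA|mon1" = 774.4104,
      "LA|sel2" = 774.4104, "LA|mon2" = 602.3620,
      "hFP|prec" = 741.8665, "hFP|sel1" = 639.7726, "hFP|mon1" = 717.3162,
      "hFP|sel2" = 1278.5379, "hFP|mon2" = 1260.5273),
    human_absolute = c(
      "IC|prec" = 703.8238, "IC|mon1" = 933.4095, "IC|mon2" = 603.7657,
      "IC*|prec" = 707.8309, "IC*|mon1" = 941.4237, "IC*|mon2" = 607.7728,
      "LA|prec" = 783.8791, "LA|mon1" = 690.8288, "LA|mon2" = 921.4789,
      "LA*|prec" = 788.8831, "LA*|mon1" = 695.8329, "LA*|mon2" = 931.4871,
      "hFP|prec" = 741.8665, "hFP|mon1" = 1278.5379, "hFP|mon2" = 1029.4596,
      "hFP*|prec" = 743.8700, "hFP*|mon2" = 1033.4667)
  )
}

# Collect a panel's m/z values under the same keys.
panel_mz <- function(panel) {
  out <- c()
  for (row in panel$rows) {
    out[paste0(row$symbol, "|prec")] <- row$precursor_mz
    for (i in seq_along(row$traces)) {
      tr <- row$traces[[i]]
      if (tr$stage == "MS3")
        out[paste0(row$symbol, "|sel", i)] <- tr$selection_path[2]
      out[paste0(row$symbol, "|mon", i)] <- tr$monitored_mz
    }
  }
  out
}

ic_peptide <- function() panel_peptides()$IC
hfp_peptide <- function() panel_peptides()$hFP

# Toy prelamin A: 29 residues ending CSIM, Cys at length - 3.
toy_prelamin <- function() "MTESTKAAAGGRLLQNSSKGGHEYVCSIM"

# Minimal single-pair absolute panel (IC + IC*) for fast simulations.
tiny_panel <- function() {
  pep <- panel_peptides()$IC
  strat <- list(stage = "MS2", z = 2L, traces = list(
    list(select = NULL, monitor = frag_spec_test("y", 9)),
    list(select = NULL, monitor = frag_spec_test("y", 11, 2))))
  p <- assay_panel("tiny", list(design_transitions(pep, strat)))
  p <- add_heavy_companions(p, list(IC = heavy_label(13, 6, 2)))
  schedule(p, list(IC = c(0, 4)))
}

# test-side ion-spec constructor (mirrors the package's internal recipe
# format, kept separate so panels in tests are declared independently)
frag_spec_test <- function(series, index, z = 1, defarnesylated = FALSE) {
  list(kind = "frag", series = series, index = as.integer(index),
       z = as.integer(z), defarnesylated = defarnesylated)
}

tiny_truth <- function(amount = 40, spike = 50, noise_cv = 0.05,
                       seed = 1L, noise_floor = 30) {
  ground_truth(amounts = c(IC = amount), spikes = c(IC = spike),
               elution = list(IC = c(2, 0.15)), noise_cv = noise_cv,
               noise_floor = noise_floor, seed = seed)
}
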