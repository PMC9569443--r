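## Assay design: turning panel peptides into executable PRM transition
## tables (precursors, MS3 selections, XIC trace definitions, heavy
## companions, RT scheduling).

## An ion spec is the declarative recipe for one m/z, so every number in a
## panel is recomputable from its peptide (nothing free-typed):
##   list(kind = "frag", series = "b"|"y", index, z, defarnesylated)
##   list(kind = "nl", z, losses = c("farnesyl", ...))   # precursor losses
compute_ion_mz <- function(peptide, spec,
                           registry = default_modifications()) {
  if (spec$kind == "frag") {
    fragment_mz(peptide, spec$series, spec$index, spec$z,
                defarnesylated = isTRUE(spec$defarnesylated),
                registry = registry)
  } else if (spec$kind == "nl") {
    mz <- precursor_mz(peptide, spec$z, registry)
    for (loss in spec$losses) mz <- neutral_loss_mz(mz, spec$z, loss,
                                                    registry)
    mz
  } else stop("unknown ion spec kind: ", spec$kind)
}

ion_spec_label <- function(spec) {
  if (spec$kind == "frag") {
    paste0(spec$series, spec$index, if (spec$z > 1L) paste0("^", spec$z, "+"))
  } else {
    lab <- if ("farnesyl" %in% spec$losses) "NL" else ""
    if ("water" %in% spec$losses) lab <- paste0(lab, "-H2O")
    if (spec$z > 1L) lab <- paste0(lab, "^", spec$z, "+")
    lab
  }
}

frag_spec <- function(series, index, z = 1L, defarnesylated = FALSE) {
  list(kind = "frag", series = series, index = as.integer(index),
       z = as.integer(z), defarnesylated = defarnesylated)
}

nl_spec <- function(z = 1L, losses = "farnesyl") {
  list(kind = "nl", z = as.integer(z), losses = losses)
}

#' XIC trace definition
#'
#' One monitored chromatographic trace: the stage it is read from, the
#' selection path leading to that scan (precursor m/z, plus the MS3
#' selection m/z for MS3 traces), and the monitored fragment m/z. Traces
#' sharing a `combine_group` are summed into one quantitative signal.
#'
#' @param stage `"MS2"` or `"MS3"`.
#' @param selection_path Numeric vector of selection m/z values (length 1
#'   for MS2 traces, 2 for MS3 traces).
#' @param monitored_mz Monitored m/z (Th).
#' @param ion_label Display label, e.g. `"y9"`, `"NL^2+"`, `"NL-H2O"`.
#' @param combine_group Identifier of the summation group.
#' @param monitor_spec,select_spec Internal ion recipes (kept so heavy
#'   companions can be recomputed rather than shifted numerically).
#' @return An object of class `trace_def`.
#' @export
trace_def <- function(stage, selection_path, monitored_mz, ion_label,
                      combine_group, monitor_spec = NULL,
                      select_spec = NULL) {
  stage <- match.arg(stage, c("MS2", "MS3"))
  selection_path <- as.numeric(selection_path)
  if (stage == "MS3" && length(selection_path) != 2L)
    stop("MS3 traces need a 2-element selection path")
  if (stage == "MS2" && length(selection_path) != 1L)
    stop("MS2 traces need a 1-element selection path")
  stopifnot(monitored_mz > 0, all(selection_path > 0))
  structure(list(stage = stage, selection_path = selection_path,
                 monitored_mz = monitored_mz, ion_label = ion_label,
                 combine_group = combine_group,
                 monitor_spec = monitor_spec, select_spec = select_spec),
            class = "trace_def")
}

#' Design the transition row for one peptide
#'
#' Computes the precursor target and XIC trace definitions for a panel
#' peptide from a declarative strategy. Two acquisition patterns are
#' supported: MS3 (each trace selects a fragment -- for farnesylated
#' peptides, the farnesyl neutral-loss ion -- and monitors a fragment of
#' that selection) and MS2 XIC (fragment traces read directly from the
#' precursor's MS2 scans).
#'
#' @param peptide A [modified_peptide()] with a `symbol`.
#' @param strategy List with elements `stage` (`"MS2"`/`"MS3"`), `z`
#'   (precursor charge, default 2) and `traces`: a list of
#'   `list(select = , monitor = )` ion specs (`select = NULL` for MS2
#'   traces). See the built-in panels in [lamin_panel()] for examples.
#' @param registry Modification registry.
#' @return An object of class `transition_row`.
#' @export
design_transitions <- function(peptide, strategy,
                               registry = default_modifications()) {
  stopifnot(inherits(peptide, "modified_peptide"))
  symbol <- peptide$symbol
  if (is.null(symbol)) stop("panel peptides need a symbol")
  z <- if (is.null(strategy$z)) 2L else as.integer(strategy$z)
  prec <- precursor_mz(peptide, z, registry)
  traces <- lapply(strategy$traces, function(tr) {
    if (is.null(tr$select)) {
      trace_def("MS2", prec, compute_ion_mz(peptide, tr$monitor, registry),
                ion_spec_label(tr$monitor), combine_group = symbol,
                monitor_spec = tr$monitor)
    } else {
      sel <- compute_ion_mz(peptide, tr$select, registry)
      trace_def("MS3", c(prec, sel),
                compute_ion_mz(peptide, tr$monitor, registry),
                ion_spec_label(tr$monitor), combine_group = symbol,
                monitor_spec = tr$monitor, select_spec = tr$select)
    }
  })
  structure(list(symbol = symbol, peptide = peptide, precursor_z = z,
                 precursor_mz = prec, traces = traces,
                 rt_window = c(NA_real_, NA_real_), strategy = strategy),
            class = "transition_row")
}

#' Assemble an assay panel
#'
#' @param name Panel name.
#' @param rows List of [design_transitions()] rows.
#' @param mode `"relative"` or `"absolute"`.
#' @param heavy_pairs Named character vector mapping light symbols to their
#'   heavy-companion symbols (absolute mode).
#' @return An object of class `assay_panel`.
#' @export
assay_panel <- function(name, rows, mode = c("relative", "absolute"),
                        heavy_pairs = character()) {
  mode <- match.arg(mode)
  syms <- vapply(rows, function(r) r$symbol, character(1))
  names(rows) <- syms
  structure(list(name = name, rows = rows, mode = mode,
                 heavy_pairs = heavy_pairs),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("<assay_panel> ", x$name, " (", x$mode, " mode, ",
      length(x$rows), " rows)\n", sep = "")
  for (r in x$rows) {
    w <- if (all(is.na(r$rt_window))) "" else
      sprintf("  RT %g-%g min", r$rt_window[1], r$rt_window[2])
    cat(sprintf("  %-5s %s  %.4f (%d+)%s\n", r$symbol, r$peptide$sequence,
                r$precursor_mz, r$precursor_z, w))
    for (tr in r$traces)
      cat("        ", paste(sprintf("%.4f", tr$selection_path),
                            collapse = " > "),
          sprintf(" > %.4f (%s)\n", tr$monitored_mz, tr$ion_label))
  }
  invisible(x)
}

#' Add heavy-standard companion rows to a panel
#'
#' For each labelled symbol, appends a row for the isotope-labelled
#' companion peptide with every trace recomputed from the labelled
#' peptide: the precursor and any fragment containing the labelled residue
#' shift by the label delta over their charge; a monitored fragment that
#' does not contain the labelled residue is still emitted, unshifted, with
#' a warning.
#'
#' @param panel An [assay_panel()].
#' @param labels Named list of [heavy_label()]s keyed by light symbol.
#' @return The panel with heavy rows appended, `mode = "absolute"` and
#'   `heavy_pairs` filled in.
#' @export
add_heavy_companions <- function(panel, labels) {
  stopifnot(inherits(panel, "assay_panel"))
  missing <- setdiff(names(labels), names(panel$rows))
  if (length(missing))
    stop("labels given for symbols absent from the panel: ",
         paste(missing, collapse = ", "))
  rows <- panel$rows
  pairs <- panel$heavy_pairs
  for (sym in names(labels)) {
    lab <- labels[[sym]]
    light <- rows[[sym]]
    if (label_delta(lab) == 0) next
    heavy_pep <- apply_heavy_label(light$peptide, lab)
    n <- peptide_length(heavy_pep)
    for (tr in light$strategy$traces) {
      ms <- tr$monitor
      if (ms$kind == "frag") {
        contains <- if (ms$series == "y") lab$position > n - ms$index
                    else lab$position <= ms$index
        if (!contains)
          warning("monitored fragment ", ion_spec_label(ms), " of ", sym,
                  "* does not contain the labelled residue; ",
                  "trace emitted unshifted")
      }
    }
    heavy_row <- design_transitions(heavy_pep, light$strategy)
    heavy_row$rt_window <- light$rt_window
    rows[[heavy_row$symbol]] <- heavy_row
    pairs[sym] <- heavy_row$symbol
  }
  # interleave heavy rows after their light partners
  ord <- unlist(lapply(names(panel$rows), function(s) c(s, unname(pairs[s]))))
  ord <- unique(ord[!is.na(ord)])
  assay_panel(panel$name, rows[ord], mode = "absolute", heavy_pairs = pairs)
}

#' Schedule RT windows for a panel
#'
#' Time-scheduled PRM acquires each target only inside its retention-time
#' window. Light/heavy partners share a window (the isotopologues
#' co-elute); a window given for the light symbol is applied to both.
#'
#' @param panel An [assay_panel()].
#' @param windows Named list of `c(start, end)` minutes keyed by symbol.
#'   Every row (or its light partner) must have a window; overlapping
#'   windows are allowed.
#' @return The scheduled panel.
#' @export
schedule <- function(panel, windows) {
  stopifnot(inherits(panel, "assay_panel"))
  light_of <- if (length(panel$heavy_pairs))
    stats::setNames(names(panel$heavy_pairs), unname(panel$heavy_pairs))
  else character()
  for (sym in names(panel$rows)) {
    w <- windows[[sym]]
    if (is.null(w) && sym %in% names(light_of))
      w <- windows[[light_of[[sym]]]]
    if (is.null(w)) stop("no RT window for symbol ", sym)
    w <- as.numeric(w)
    if (length(w) != 2L || !(w[1] < w[2]))
      stop("RT window for ", sym, " must be c(start, end) with start < end")
    panel$rows[[sym]]$rt_window <- w
  }
  panel
}

#' The published lamin A / progerin transition panels
#'
#' Regenerates, from peptide definitions alone, the three targeted assays:
#' * `mouse_relative`: MS3 assay for IC, LA and mFP (unscheduled). IC and
#'   LA select intense y ions and monitor a secondary y fragment; mFP
#'   selects the farnesyl neutral-loss ion (2+ and 1+) and monitors
#'   defarnesylated b/y fragments.
#' * `human_relative`: time-scheduled MS3 assay for IC, LA and hFP
#'   (hFP monitors a defarnesylated b9 and the water loss of the
#'   neutral-loss ion).
#' * `human_absolute`: time-scheduled MS2-XIC assay for IC, LA, hFP and
#'   their heavy companions IC*, LA*, hFP* (stable-isotope dilution).
#'
#' @param name One of `"mouse_relative"`, `"human_relative"`,
#'   `"human_absolute"`.
#' @return An [assay_panel()].
#' @examples
#' lamin_panel("mouse_relative")
#' @export
lamin_panel <- function(name = c("mouse_relative", "human_relative",
                                 "human_absolute")) {
  name <- match.arg(name)
  pep <- panel_peptides()

  ic_ms3 <- list(stage = "MS3", z = 2L, traces = list(
    list(select = frag_spec("y", 4), monitor = frag_spec("y", 3)),
    list(select = frag_spec("y", 11, z = 2), monitor = frag_spec("y", 9))))
  la_ms3 <- list(stage = "MS3", z = 2L, traces = list(
    list(select = frag_spec("y", 15, z = 2), monitor = frag_spec("y", 7)),
    list(select = frag_spec("y", 7), monitor = frag_spec("y", 5))))
  mfp_ms3 <- list(stage = "MS3", z = 2L, traces = list(
    list(select = nl_spec(z = 2),
         monitor = frag_spec("b", 11, defarnesylated = TRUE)),
    list(select = nl_spec(z = 1),
         monitor = frag_spec("y", 11, defarnesylated = TRUE))))
  hfp_ms3 <- list(stage = "MS3", z = 2L, traces = list(
    list(select = nl_spec(z = 2),
         monitor = frag_spec("b", 9, defarnesylated = TRUE)),
    list(select = nl_spec(z = 1),
         monitor = nl_spec(z = 1, losses = c("farnesyl", "water")))))

  if (name == "mouse_relative") {
    rows <- list(design_transitions(pep$IC, ic_ms3),
                 design_transitions(pep$LA, la_ms3),
                 design_transitions(pep$mFP, mfp_ms3))
    return(assay_panel("mouse_relative", rows, mode = "relative"))
  }

  if (name == "human_relative") {
    rows <- list(design_transitions(pep$IC, ic_ms3),
                 design_transitions(pep$LA, la_ms3),
                 design_transitions(pep$hFP, hfp_ms3))
    p <- assay_panel("human_relative", rows, mode = "relative")
    return(schedule(p, list(IC = c(0, 70), LA = c(0, 70),
                            hFP = c(70, 162))))
  }

  ic_ms2 <- list(stage = "MS2", z = 2L, traces = list(
    list(select = NULL, monitor = frag_spec("y", 9)),
    list(select = NULL, monitor = frag_spec("y", 11, z = 2))))
  la_ms2 <- list(stage = "MS2", z = 2L, traces = list(
    list(select = NULL, monitor = frag_spec("y", 15, z = 2)),
    list(select = NULL, monitor = frag_spec("y", 8))))
  hfp_ms2 <- list(stage = "MS2", z = 2L, traces = list(
    list(select = NULL, monitor = nl_spec(z = 1)),
    list(select = NULL, monitor = frag_spec("b", 12,
                                            defarnesylated = TRUE))))
  rows <- list(design_transitions(pep$IC, ic_ms2),
               design_transitions(pep$LA, la_ms2),
               design_transitions(pep$hFP, hfp_ms2))
  p <- assay_panel("human_absolute", rows, mode = "relative")
  p <- add_heavy_companions(p, panel_heavy_labels())
  schedule(p, list(IC = c(0, 35), LA = c(35, 70), hFP = c(70, 162)))
}

#' Automatic transition strategy for a generic surrogate peptide
#'
#' A default MS2-XIC design for peptides outside the published panels:
#' unmodified/carbamidomethylated peptides monitor two long y ions
#' (`y(n-2)` and `y(ceiling(n/2))`); farnesylated peptides monitor the
#' farnesyl neutral-loss ion and the defarnesylated `b(n-2)` fragment.
#'
#' @param peptide A [modified_peptide()].
#' @return A strategy list for [design_transitions()].
#' @export
auto_strategy <- function(peptide) {
  n <- peptide_length(peptide)
  if (n < 4L) stop("peptide too short to design transitions: ",
                   peptide$sequence)
  if (has_farnesyl(peptide)) {
    list(stage = "MS2", z = 2L, traces = list(
      list(select = NULL, monitor = nl_spec(z = 1)),
      list(select = NULL,
           monitor = frag_spec("b", n - 2L, defarnesylated = TRUE))))
  } else {
    list(stage = "MS2", z = 2L, traces = list(
      list(select = NULL, monitor = frag_spec("y", n - 2L)),
      list(select = NULL, monitor = frag_spec("y", ceiling(n / 2)))))
  }
}
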