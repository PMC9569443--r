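## Transition-list CSV interchange. One row per XIC trace; m/z columns are
## written at full precision plus a 4-decimal display column. Dialect:
## comma-separated, UTF-8, "." decimal separator.

serialize_mods <- function(mods) {
  if (is.null(mods) || !nrow(mods)) return("")
  paste(sprintf("%d:%s", mods$position, mods$name), collapse = ";")
}

parse_mods <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  data.frame(position = as.integer(vapply(parts, `[`, character(1), 1L)),
             name = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

serialize_label <- function(label) {
  if (is.null(label)) return("")
  sprintf("%d:%dx13C:%dx15N", label$position, label$n_13C, label$n_15N)
}

parse_label <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  m <- regmatches(s, regexec("^(\\d+):(\\d+)x13C:(\\d+)x15N$", s))[[1]]
  if (length(m) != 4L) stop("malformed label spec: ", s)
  heavy_label(as.integer(m[2]), as.integer(m[3]), as.integer(m[4]))
}

serialize_spec <- function(spec) {
  if (is.null(spec)) return("")
  if (spec$kind == "frag") {
    sprintf("frag:%s:%d:%d:%d", spec$series, spec$index, spec$z,
            as.integer(isTRUE(spec$defarnesylated)))
  } else {
    sprintf("nl:%d:%s", spec$z, paste(spec$losses, collapse = "+"))
  }
}

parse_spec <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  f <- strsplit(s, ":")[[1]]
  if (f[1] == "frag") {
    frag_spec(f[2], as.integer(f[3]), as.integer(f[4]),
              defarnesylated = f[5] == "1")
  } else if (f[1] == "nl") {
    nl_spec(as.integer(f[2]), strsplit(f[3], "+", fixed = TRUE)[[1]])
  } else stop("malformed ion spec: ", s)
}

#' Write / read a transition panel as CSV
#'
#' One row per XIC trace with columns `panel`, `mode`, `symbol`,
#' `sequence`, `mods`, `label`, `z`, `precursor_mz`, `stage`,
#' `selection_path` (`>`-joined), `select_spec`, `monitor_spec`,
#' `monitored_mz`, `monitored_mz_display` (4 decimals), `ion_label`,
#' `combine_group`, `rt_start`, `rt_end`. Reading rebuilds the panel by
#' recomputing every m/z from the peptide definitions, so
#' `read_transition_csv(write_transition_csv(p))` is an identity.
#'
#' @param panel An [assay_panel()].
#' @param path CSV path.
#' @return `write_transition_csv()` returns `path` invisibly;
#'   `read_transition_csv()` returns an [assay_panel()].
#' @export
write_transition_csv <- function(panel, path) {
  stopifnot(inherits(panel, "assay_panel"))
  rows <- lapply(panel$rows, function(r) {
    do.call(rbind, lapply(r$traces, function(tr) {
      data.frame(
        panel = panel$name, mode = panel$mode, symbol = r$symbol,
        sequence = r$peptide$sequence,
        mods = serialize_mods(r$peptide$mods),
        label = serialize_label(r$peptide$label),
        z = r$precursor_z,
        precursor_mz = sprintf("%.10f", r$precursor_mz),
        stage = tr$stage,
        selection_path = paste(sprintf("%.10f", tr$selection_path),
                               collapse = ">"),
        select_spec = serialize_spec(tr$select_spec),
        monitor_spec = serialize_spec(tr$monitor_spec),
        monitored_mz = sprintf("%.10f", tr$monitored_mz),
        monitored_mz_display = sprintf("%.4f", mz_round(tr$monitored_mz)),
        ion_label = tr$ion_label, combine_group = tr$combine_group,
        rt_start = r$rt_window[1], rt_end = r$rt_window[2],
        stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(panel = character(), mode = character(),
                     symbol = character(), sequence = character(),
                     mods = character(), label = character(), z = integer(),
                     precursor_mz = character(), stage = character(),
                     selection_path = character(), select_spec = character(),
                     monitor_spec = character(), monitored_mz = character(),
                     monitored_mz_display = character(),
                     ion_label = character(), combine_group = character(),
                     rt_start = numeric(), rt_end = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

csv_cols <- c("panel", "mode", "symbol", "sequence", "mods", "label", "z",
              "precursor_mz", "stage", "selection_path", "select_spec",
              "monitor_spec", "monitored_mz", "ion_label", "combine_group",
              "rt_start", "rt_end")

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(csv_cols, names(df))
  if (length(miss))
    stop("malformed transition CSV (line 1): missing columns ",
         paste(miss, collapse = ", "))
  if (!nrow(df))
    return(assay_panel("empty", list(), mode = "relative"))
  for (i in seq_len(nrow(df))) {
    z <- suppressWarnings(as.integer(df$z[i]))
    mz <- suppressWarnings(as.numeric(df$precursor_mz[i]))
    if (is.na(z) || is.na(mz))
      stop("malformed transition CSV (line ", i + 1L,
           "): non-numeric charge or precursor m/z")
  }
  rows <- list()
  pairs <- character()
  for (sym in unique(df$symbol)) {
    sub <- df[df$symbol == sym, , drop = FALSE]
    pep <- modified_peptide(sub$sequence[1], mods = parse_mods(sub$mods[1]),
                            label = parse_label(sub$label[1]), symbol = sym)
    traces <- lapply(seq_len(nrow(sub)), function(i) {
      sel <- parse_spec(sub$select_spec[i])
      mon <- parse_spec(sub$monitor_spec[i])
      if (is.null(mon))
        stop("malformed transition CSV (line ",
             which(df$symbol == sym)[i] + 1L, "): missing monitor spec")
      list(select = sel, monitor = mon)
    })
    strategy <- list(stage = sub$stage[1], z = as.integer(sub$z[1]),
                     traces = traces)
    row <- design_transitions(pep, strategy)
    row$rt_window <- suppressWarnings(
      as.numeric(c(sub$rt_start[1], sub$rt_end[1])))
    rows[[sym]] <- row
    if (endsWith(sym, "*")) pairs[sub("\\*$", "", sym)] <- sym
  }
  pairs <- pairs[names(pairs) %in% df$symbol]
  assay_panel(df$panel[1], rows,
              mode = if (df$mode[1] %in% c("relative", "absolute"))
                df$mode[1] else "relative",
              heavy_pairs = pairs)
}

#' Flatten an assay panel to a data frame
#'
#' Canonical tabular form (one row per trace) used for display and for
#' panel equality checks.
#'
#' @param x An [assay_panel()].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A `data.frame`.
#' @export
as.data.frame.assay_panel <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- lapply(x$rows, function(r) {
    do.call(rbind, lapply(r$traces, function(tr) {
      data.frame(symbol = r$symbol, sequence = r$peptide$sequence,
                 mods = serialize_mods(r$peptide$mods),
                 label = serialize_label(r$peptide$label),
                 z = r$precursor_z, precursor_mz = r$precursor_mz,
                 stage = tr$stage,
                 selection_path = paste(sprintf("%.6f", tr$selection_path),
                                        collapse = ">"),
                 monitored_mz = tr$monitored_mz, ion_label = tr$ion_label,
                 combine_group = tr$combine_group,
                 rt_start = r$rt_window[1], rt_end = r$rt_window[2],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
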