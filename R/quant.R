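#' Construct a PRM run
#'
#' A time-ordered collection of targeted centroid scans. `scans` holds one
#' row per scan with its selection annotations; `peaks` holds the centroid
#' peaks of all scans in long form.
#'
#' @param scans `data.frame` with columns `scan` (integer id), `rt`
#'   (minutes, non-decreasing), `ms_level` (2 or 3), `sel1` (precursor
#'   selection m/z) and `sel2` (MS3 selection m/z, `NA` for MS2 scans).
#' @param peaks `data.frame` with columns `scan`, `mz`, `intensity`
#'   (sorted by m/z within scan).
#' @param metadata List: `run_id`, `sample_id`, `protein_ug` (protein
#'   amount loaded), `spikes` (named fmol amounts of heavy standards,
#'   keyed by light symbol).
#' @return An object of class `prm_run`.
#' @export
prm_run <- function(scans, peaks, metadata = list()) {
  stopifnot(is.data.frame(scans),
            all(c("scan", "rt", "ms_level", "sel1", "sel2") %in%
                  names(scans)),
            is.data.frame(peaks),
            all(c("scan", "mz", "intensity") %in% names(peaks)))
  if (is.unsorted(scans$rt)) stop("scan retention times must be non-decreasing")
  structure(list(scans = scans, peaks = peaks, metadata = metadata),
            class = "prm_run")
}

#' @export
print.prm_run <- function(x, ...) {
  cat("<prm_run> ", x$metadata$run_id %||% "(unnamed)", ": ",
      nrow(x$scans), " scans, ", nrow(x$peaks), " peaks, RT ",
      if (nrow(x$scans)) sprintf("%.2f-%.2f min", min(x$scans$rt),
                                 max(x$scans$rt)) else "-", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract an ion chromatogram for one trace
#'
#' Collects, for every scan whose selection path matches the trace's path
#' (each level within the m/z tolerance) and whose RT lies in `rt_window`,
#' the summed intensity of peaks within the tolerance of the monitored
#' m/z. Matching scans with no peak in the window contribute intensity 0.
#' When no scan matches the selection path at all the result is an *empty*
#' trace (zero rows) -- absence of acquisition, distinct from an all-zero
#' signal.
#'
#' @param run A [prm_run()].
#' @param trace A [trace_def()].
#' @param tol_ppm m/z tolerance in ppm, applied at every selection level
#'   and to the monitored m/z (default 10, Orbitrap-class accuracy).
#' @param rt_window Optional `c(start, end)` minutes.
#' @return `data.frame` of class `xic` with columns `rt`, `intensity`.
#' @export
extract_xic <- function(run, trace, tol_ppm = 10, rt_window = NULL) {
  stopifnot(inherits(run, "prm_run"), inherits(trace, "trace_def"))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  path <- trace$selection_path
  sc <- run$scans
  keep <- sc$ms_level == length(path) + 1L &
    abs(sc$sel1 - path[1]) <= path[1] * tol_ppm * 1e-6
  if (length(path) == 2L)
    keep <- keep & !is.na(sc$sel2) &
      abs(sc$sel2 - path[2]) <= path[2] * tol_ppm * 1e-6
  if (!is.null(rt_window))
    keep <- keep & sc$rt >= rt_window[1] & sc$rt <= rt_window[2]
  sc <- sc[which(keep), , drop = FALSE]
  if (!nrow(sc)) {
    out <- data.frame(rt = numeric(0), intensity = numeric(0))
    class(out) <- c("xic", "data.frame")
    attr(out, "trace") <- trace
    return(out)
  }
  tol <- trace$monitored_mz * tol_ppm * 1e-6
  pk <- run$peaks[run$peaks$scan %in% sc$scan &
                    abs(run$peaks$mz - trace$monitored_mz) <= tol, ,
                  drop = FALSE]
  intens <- rep(0, nrow(sc))
  if (nrow(pk)) {
    agg <- tapply(pk$intensity, pk$scan, sum)
    i <- match(as.integer(names(agg)), sc$scan)
    intens[i] <- as.numeric(agg)
  }
  out <- data.frame(rt = sc$rt, intensity = intens)
  out <- out[order(out$rt), ]
  rownames(out) <- NULL
  class(out) <- c("xic", "data.frame")
  attr(out, "trace") <- trace
  out
}

#' Integrate an XIC
#'
#' Default is the trapezoidal rule over the full trace (the scheduled RT
#' window). `method = "peak"` restricts integration to the apex peak:
#' from the most intense point, the boundaries extend outward while
#' intensity is non-increasing (the first local minimum on each side).
#'
#' @param xic An [extract_xic()] result (at least one point).
#' @param method `"trapezoid"` or `"peak"`.
#' @return Area in intensity x minutes.
#' @export
integrate_xic <- function(xic, method = c("trapezoid", "peak")) {
  method <- match.arg(method)
  n <- nrow(xic)
  if (n == 0L) stop("cannot integrate an empty XIC")
  if (n == 1L) {
    warning("single-point XIC integrates to area 0")
    return(0)
  }
  rt <- xic$rt
  y <- xic$intensity
  if (method == "peak") {
    a <- which.max(y)
    lo <- a
    while (lo > 1L && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- a
    while (hi < n && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    rt <- rt[lo:hi]
    y <- y[lo:hi]
    if (length(rt) < 2L) return(0)
  }
  sum(diff(rt) * (y[-1] + y[-length(y)]) / 2)
}

#' Combine trace areas into one per-peptide signal
#'
#' Traces joined in the printed tables ("+") are summed into a single
#' quantitative signal. A missing member still yields the sum of the
#' present members, flagged via the `complete` attribute and a warning.
#'
#' @param areas Named numeric vector of per-trace areas (names = trace
#'   ion labels).
#' @param row A [design_transitions()] row defining the expected members.
#' @return Summed area with attribute `complete`.
#' @export
combine_traces <- function(areas, row) {
  expected <- vapply(row$traces, function(tr) tr$ion_label, character(1))
  present <- intersect(expected, names(areas))
  if (!length(present)) stop("no trace areas supplied for ", row$symbol)
  complete <- length(present) == length(expected)
  if (!complete)
    warning("missing trace(s) for ", row$symbol, ": ",
            paste(setdiff(expected, present), collapse = ", "))
  structure(sum(areas[present]), complete = complete)
}

#' Relative quantification against a reference peptide
#'
#' Scales every area to the reference peptide (the internal control),
#' which is assigned the value `scale` (100 by convention in the XIC
#' figures of such assays).
#'
#' @param areas Named numeric vector of per-symbol areas.
#' @param reference Reference symbol (default `"IC"`).
#' @param scale Value assigned to the reference (default 100).
#' @param run_id Optional run identifier used in error messages.
#' @return Named numeric vector of ratios; `ratios[reference] == scale`.
#' @export
relative_quant <- function(areas, reference = "IC", scale = 100,
                           run_id = NULL) {
  if (!reference %in% names(areas))
    stop("reference symbol ", reference, " not among areas")
  ref <- areas[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference area for ", reference, " is not positive",
         if (!is.null(run_id)) paste0(" in run ", run_id))
  scale * areas / ref
}

#' Absolute quantification by stable-isotope dilution
#'
#' Matches the endogenous (light) XIC area to the co-eluting heavy
#' standard spiked at a known amount:
#' `amount = (light / heavy) * spike_fmol * 100 / protein_ug`
#' in fmol per 100 ug of protein extract. Peptide losses upstream of the
#' spike (e.g. extraction from a gel matrix) are not corrected for, so
#' values are standardised rather than truly absolute.
#'
#' @param light_area,heavy_area Integrated areas of the endogenous and
#'   heavy-standard signals.
#' @param spike_fmol Spiked amount of the heavy standard (fmol).
#' @param protein_ug Protein amount loaded (ug).
#' @return List with `amount` (fmol / 100 ug; `NA` when not quantifiable)
#'   and `status` (`quantified`, `not_detected`, `not_quantifiable`).
#' @export
absolute_quant <- function(light_area, heavy_area, spike_fmol, protein_ug) {
  if (spike_fmol <= 0) stop("spike_fmol must be > 0")
  if (protein_ug <= 0) stop("protein_ug must be > 0")
  if (!is.finite(heavy_area) || heavy_area <= 0)
    return(list(amount = NA_real_, status = "not_quantifiable"))
  if (!is.finite(light_area) || light_area <= 0)
    return(list(amount = 0, status = "not_detected"))
  list(amount = (light_area / heavy_area) * spike_fmol * 100 / protein_ug,
       status = "quantified")
}

#' Replicate statistics
#'
#' @param amounts Numeric vector of replicate values (>= 1).
#' @return List with `mean`, `sd` (sample, n-1) and `cv_percent`
#'   (`100 * sd / mean`); `sd`/`cv_percent` are `NA` for one replicate.
#' @export
replicate_stats <- function(amounts) {
  amounts <- amounts[is.finite(amounts)]
  if (!length(amounts)) stop("no replicate values supplied")
  m <- mean(amounts)
  if (length(amounts) == 1L)
    return(list(mean = m, sd = NA_real_, cv_percent = NA_real_))
  s <- stats::sd(amounts)
  list(mean = m, sd = s,
       cv_percent = if (m == 0) NA_real_ else 100 * s / m)
}

#' Detection / quantification status call
#'
#' Three-way call mirroring targeted-assay practice: a signal at or below
#' the noise floor is `not_detected`; a light/heavy ratio below the
#' limit-of-quantification ratio is `detected_below_loq` (identified but
#' not reliably quantifiable, as for progerin in patient white blood
#' cells); anything else is `quantified`.
#'
#' @param light_area Endogenous signal area.
#' @param heavy_area Heavy-standard area (`NA` when no standard is used;
#'   the LOQ criterion is then skipped).
#' @param noise_floor Area at or below which the signal counts as absent
#'   (default 0).
#' @param loq_ratio Light/heavy ratio below which the analyte is only
#'   detectable (default 0.01).
#' @return One of `"not_detected"`, `"detected_below_loq"`,
#'   `"quantified"`.
#' @export
detection_call <- function(light_area, heavy_area = NA, noise_floor = 0,
                           loq_ratio = 0.01) {
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  if (!is.finite(light_area) || light_area <= noise_floor)
    return("not_detected")
  if (is.finite(heavy_area) && heavy_area > 0 &&
      light_area / heavy_area < loq_ratio)
    return("detected_below_loq")
  "quantified"
}

#' Quantify one PRM run against a panel
#'
#' Extracts and integrates every trace of every panel row (within its RT
#' window when scheduled) and combines trace areas per symbol.
#'
#' @param run A [prm_run()].
#' @param panel An [assay_panel()].
#' @param tol_ppm XIC tolerance in ppm.
#' @param integration Integration method, see [integrate_xic()].
#' @return `data.frame` with columns `run`, `symbol`, `area`, `n_points`,
#'   `complete`.
#' @export
quantify_run <- function(run, panel, tol_ppm = 10,
                         integration = "trapezoid") {
  out <- lapply(panel$rows, function(row) {
    w <- if (all(is.finite(row$rt_window))) row$rt_window else NULL
    areas <- numeric(0)
    npts <- 0L
    for (tr in row$traces) {
      x <- extract_xic(run, tr, tol_ppm = tol_ppm, rt_window = w)
      npts <- npts + nrow(x)
      a <- if (nrow(x) >= 2L) integrate_xic(x, integration) else
        if (nrow(x) == 1L) 0 else NA_real_
      areas[tr$ion_label] <- a
    }
    areas <- areas[is.finite(areas)]
    area <- if (length(areas)) combine_traces(areas, row) else NA_real_
    data.frame(run = run$metadata$run_id %||% NA_character_,
               symbol = row$symbol, area = as.numeric(area),
               n_points = npts,
               complete = isTRUE(attr(area, "complete")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quantify a replicate set of PRM runs
#'
#' Runs the full quantification pipeline over one or more runs. In
#' `"relative"` mode, per-symbol areas are normalised to the reference
#' peptide (= `scale`). In `"absolute"` mode, each light symbol with a
#' heavy companion is quantified by isotope dilution using the spike
#' amounts and protein load from the run metadata, with a
#' [detection_call()] per run. Replicate mean, sd and CV% are reported per
#' symbol.
#'
#' @param runs A `prm_run` or list of `prm_run`s (replicates).
#' @param panel An [assay_panel()].
#' @param mode `"absolute"` or `"relative"` (default: the panel's mode).
#' @param tol_ppm,integration Passed to [quantify_run()].
#' @param reference,scale Relative-mode normalisation, see
#'   [relative_quant()].
#' @param noise_floor,loq_ratio Detection thresholds, see
#'   [detection_call()].
#' @return List of class `quant_result`: `per_run` (one row per run and
#'   symbol) and `summary` (one row per symbol with replicate statistics
#'   and status).
#' @export
quantify_runs <- function(runs, panel, mode = NULL, tol_ppm = 10,
                          integration = "trapezoid", reference = "IC",
                          scale = 100, noise_floor = 0, loq_ratio = 0.01) {
  if (inherits(runs, "prm_run")) runs <- list(runs)
  mode <- mode %||% panel$mode
  mode <- match.arg(mode, c("relative", "absolute"))
  if (mode == "absolute" && !length(panel$heavy_pairs))
    stop("absolute mode needs a panel with heavy companions")

  per <- list()
  for (r in runs) {
    q <- quantify_run(r, panel, tol_ppm, integration)
    if (all(q$n_points == 0L))
      stop("no scans in run ", r$metadata$run_id %||% "(unnamed)",
           " match any panel row")
    areas <- stats::setNames(q$area, q$symbol)
    if (mode == "relative") {
      ratio <- relative_quant(areas, reference, scale,
                              run_id = r$metadata$run_id)
      q$ratio_to_reference <- as.numeric(ratio[q$symbol])
      q$light_heavy_ratio <- NA_real_
      q$amount_fmol_per_100ug <- NA_real_
      q$status <- ifelse(q$area > 0, "quantified", "not_detected")
    } else {
      q$ratio_to_reference <- NA_real_
      q$light_heavy_ratio <- NA_real_
      q$amount_fmol_per_100ug <- NA_real_
      q$status <- NA_character_
      spikes <- r$metadata$spikes
      ug <- r$metadata$protein_ug
      if (is.null(spikes) || is.null(ug))
        stop("absolute mode needs spike amounts and protein load in the ",
             "run metadata")
      for (sym in names(panel$heavy_pairs)) {
        hv <- panel$heavy_pairs[[sym]]
        i <- which(q$symbol == sym)
        la <- areas[[sym]]
        ha <- areas[[hv]]
        q$light_heavy_ratio[i] <- if (is.finite(ha) && ha > 0) la / ha
                                  else NA_real_
        aq <- absolute_quant(la, ha, spikes[[sym]], ug)
        q$amount_fmol_per_100ug[i] <- aq$amount
        q$status[i] <- if (aq$status == "not_quantifiable") aq$status else
          detection_call(la, ha, noise_floor, loq_ratio)
        if (q$status[i] == "detected_below_loq")
          q$amount_fmol_per_100ug[i] <- NA_real_
      }
    }
    per[[length(per) + 1L]] <- q
  }
  per <- do.call(rbind, per)

  value_col <- if (mode == "relative") "ratio_to_reference" else
    "amount_fmol_per_100ug"
  syms <- unique(per$symbol)
  summ <- lapply(syms, function(sym) {
    sub <- per[per$symbol == sym, , drop = FALSE]
    vals <- sub[[value_col]]
    st <- sub$status[!is.na(sub$status)]
    status <- if (!length(st)) NA_character_
      else if (all(st == "not_detected")) "not_detected"
      else if (any(st == "quantified")) "quantified"
      else "detected_below_loq"
    stats <- if (any(is.finite(vals))) replicate_stats(vals) else
      list(mean = NA_real_, sd = NA_real_, cv_percent = NA_real_)
    data.frame(symbol = sym, n_runs = nrow(sub),
               mean = stats$mean, sd = stats$sd,
               cv_percent = stats$cv_percent, status = status,
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  structure(list(per_run = per, summary = summ, mode = mode),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> ", x$mode, " mode, ",
      length(unique(x$per_run$run)), " run(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write quantification results as TSV
#'
#' Two tab-separated tables: `<path>` with the per-run rows and the
#' summary appended below a `# summary` marker line. All numerics at full
#' precision.
#'
#' @param result A [quantify_runs()] result.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(result$per_run, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("# summary", con)
  utils::write.table(result$summary, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
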