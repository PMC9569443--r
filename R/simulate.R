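#' Ground truth for a synthetic PRM run
#'
#' The known quantities a synthetic run is generated from, so design and
#' quantification can be validated end to end: true analyte amounts, heavy
#' spike amounts, a per-peptide response factor, Gaussian elution profiles
#' (light and heavy isotopologues co-elute by construction), multiplicative
#' scan-to-scan noise and an additive chemical-noise floor.
#'
#' @param amounts Named numeric vector: true analyte amount per light
#'   symbol, in fmol per 100 ug of protein extract.
#' @param spikes Named numeric vector keyed by light symbol: heavy-standard
#'   spike amounts in fmol (`NULL` for relative-mode runs).
#' @param protein_ug Protein amount loaded (default 100).
#' @param response Response factor: integrated area units per fmol on
#'   column (default 1e6, arbitrary instrument units).
#' @param elution Named list keyed by light symbol of `c(apex, sigma)`
#'   in minutes.
#' @param noise_cv Multiplicative scan-to-scan noise CV (default 0.05).
#' @param noise_floor Mean intensity of additive chemical-noise peaks
#'   (default 30 counts; 0 disables them).
#' @param n_noise_peaks Chemical-noise peaks per scan (default 2).
#' @param seed Integer seed; the generator is the only source of
#'   randomness and identical seeds give identical runs.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(amounts, spikes = NULL, protein_ug = 100,
                         response = 1e6, elution, noise_cv = 0.05,
                         noise_floor = 30, n_noise_peaks = 2L, seed = 1L) {
  stopifnot(is.numeric(amounts), !is.null(names(amounts)),
            all(amounts >= 0))
  if (!is.null(spikes)) stopifnot(all(spikes > 0))
  stopifnot(is.list(elution))
  structure(list(amounts = amounts, spikes = spikes,
                 protein_ug = protein_ug, response = response,
                 elution = elution, noise_cv = noise_cv,
                 noise_floor = noise_floor,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

base_symbol <- function(sym) sub("\\*$", "", sym)

## Signal fractions across the traces of one row (they sum to 1, so the
## combined area of a peptide equals response x fmol on column).
trace_fractions <- function(k) {
  if (k == 1L) return(1)
  f <- rev(seq_len(k)) + 1
  f / sum(f)
}

#' Simulate a targeted PRM run
#'
#' Generates time-scheduled targeted scans for every panel row: one scan
#' per cycle per selection path inside the row's RT window, with the
#' monitored ion of each trace carrying intensity
#' `response * fmol_on_column * dnorm(rt; apex, sigma) * fraction * (1 + e)`,
#' `e ~ N(0, noise_cv)`, plus uniformly placed chemical-noise peaks.
#' Zero-amount symbols produce only noise. Heavy rows use the spike amount
#' as fmol on column and share the light peptide's elution profile.
#'
#' @param panel An [assay_panel()] (scheduled, or `default_window` is used
#'   for unscheduled rows).
#' @param truth A [ground_truth()].
#' @param cycle_s Cycle time in seconds (default 1).
#' @param run_id,sample_id Run metadata.
#' @param default_window RT window for unscheduled rows (minutes).
#' @param seed Seed override (defaults to `truth$seed`); replicates use
#'   consecutive seeds via [simulate_replicates()].
#' @return A [prm_run()] with attributes `bookkeeping` (a `data.frame` of
#'   the sampled signal intensity per scan and trace -- the XIC oracle)
#'   and `truth`.
#' @export
simulate_run <- function(panel, truth, cycle_s = 1, run_id = "run1",
                         sample_id = run_id, default_window = c(0, 30),
                         seed = truth$seed) {
  stopifnot(inherits(panel, "assay_panel"), inherits(truth, "ground_truth"))
  light_syms <- setdiff(names(panel$rows), unname(panel$heavy_pairs))
  missing <- setdiff(base_symbol(light_syms), names(truth$amounts))
  if (length(missing))
    stop("no ground truth for panel symbol(s): ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  dt <- cycle_s / 60

  sig <- list()   # one element per (row, trace): intensities over the grid
  scan_keys <- list()
  for (ri in seq_along(panel$rows)) {
    row <- panel$rows[[ri]]
    sym <- row$symbol
    base <- base_symbol(sym)
    w <- if (all(is.finite(row$rt_window))) row$rt_window else default_window
    rts <- seq(w[1], w[2], by = dt)
    el <- truth$elution[[base]]
    if (is.null(el)) stop("no elution profile for symbol ", base)
    fmol <- if (sym %in% unname(panel$heavy_pairs)) {
      if (is.null(truth$spikes) || is.na(truth$spikes[base]))
        stop("no spike amount for heavy symbol ", sym)
      truth$spikes[[base]]
    } else {
      truth$amounts[[base]] * truth$protein_ug / 100
    }
    fr <- trace_fractions(length(row$traces))
    for (ti in seq_along(row$traces)) {
      tr <- row$traces[[ti]]
      path_key <- paste(sprintf("%.6f", tr$selection_path), collapse = ">")
      eps <- stats::rnorm(length(rts), 0, truth$noise_cv)
      base_int <- truth$response * fmol *
        stats::dnorm(rts, el[1], el[2]) * fr[ti]
      sig[[length(sig) + 1L]] <- data.frame(
        row = ri, rt = rts, path_key = path_key,
        sel1 = tr$selection_path[1],
        sel2 = if (length(tr$selection_path) == 2L) tr$selection_path[2]
               else NA_real_,
        ms_level = length(tr$selection_path) + 1L,
        symbol = sym, trace = tr$ion_label, mz = tr$monitored_mz,
        intensity = pmax(base_int * (1 + eps), 0),
        stringsAsFactors = FALSE)
    }
  }
  sig <- do.call(rbind, sig)

  # scans: one per (row, path, rt); order by rt then row then path
  skey <- paste(sig$row, sig$path_key, sprintf("%.8f", sig$rt))
  scans <- sig[!duplicated(skey), c("row", "path_key", "rt", "ms_level",
                                    "sel1", "sel2")]
  scans <- scans[order(scans$rt, scans$row, scans$path_key), ]
  scans$scan <- seq_len(nrow(scans))
  sig$scan <- scans$scan[match(skey, paste(scans$row, scans$path_key,
                                           sprintf("%.8f", scans$rt)))]

  book <- data.frame(scan = sig$scan, rt = sig$rt, symbol = sig$symbol,
                     trace = sig$trace, intensity = sig$intensity,
                     stringsAsFactors = FALSE)
  book <- book[order(book$scan, book$trace), ]
  rownames(book) <- NULL

  signal_peaks <- sig[sig$intensity > 0, c("scan", "mz", "intensity")]

  noise_peaks <- NULL
  if (truth$noise_floor > 0 && truth$n_noise_peaks > 0L) {
    # m/z range per scan from the monitored ions acquired in that scan
    rng <- do.call(rbind, lapply(split(sig$mz, sig$scan), range))
    ns <- nrow(rng)
    k <- truth$n_noise_peaks
    lo <- rep(rng[, 1] - 5, each = k)
    hi <- rep(rng[, 2] + 5, each = k)
    mz <- stats::runif(ns * k, lo, hi)
    # keep chemical noise out of the monitored windows
    mon <- sort(unique(sig$mz))
    for (it in 1:10) {
      near <- vapply(mz, function(x) any(abs(x - mon) < 0.05), logical(1))
      if (!any(near)) break
      mz[near] <- stats::runif(sum(near), lo[near], hi[near])
    }
    noise_peaks <- data.frame(
      scan = rep(as.integer(rownames(rng)), each = k), mz = mz,
      intensity = stats::rexp(ns * k, 1 / truth$noise_floor))
  }

  peaks <- rbind(signal_peaks, noise_peaks)
  peaks <- peaks[order(peaks$scan, peaks$mz), ]
  rownames(peaks) <- NULL

  run <- prm_run(
    scans = data.frame(scan = scans$scan, rt = scans$rt,
                       ms_level = scans$ms_level, sel1 = scans$sel1,
                       sel2 = scans$sel2),
    peaks = peaks,
    metadata = list(run_id = run_id, sample_id = sample_id,
                    protein_ug = truth$protein_ug,
                    spikes = truth$spikes, seed = seed))
  attr(run, "bookkeeping") <- book
  attr(run, "truth") <- truth
  run
}

#' Simulate a replicate series
#'
#' @param panel,truth,cycle_s,default_window As in [simulate_run()].
#' @param n Number of replicates.
#' @param run_prefix Run-id prefix; replicate `i` is seeded with
#'   `truth$seed + i - 1`.
#' @return List of [prm_run()]s.
#' @export
simulate_replicates <- function(panel, truth, n = 3L, cycle_s = 1,
                                run_prefix = "rep",
                                default_window = c(0, 30)) {
  lapply(seq_len(n), function(i)
    simulate_run(panel, truth, cycle_s = cycle_s,
                 run_id = paste0(run_prefix, i),
                 default_window = default_window,
                 seed = truth$seed + i - 1L))
}

#' Bundled simulation scenarios
#'
#' Panels plus ground truths shaped like the assay's study conditions:
#' * `hgps_fibroblasts`: absolute human panel; progerin present
#'   (43 fmol/100 ug) with lamin A reduced (133) relative to control;
#'   IC carries the summed proteoform pool (176).
#' * `control_fibroblasts`: progerin absent, lamin A 224 fmol/100 ug.
#' * `wbc_patient`: progerin detectable but below the quantification
#'   limit (0.3 fmol/100 ug against a 50 fmol spike).
#' * `wbc_donor`: progerin absent in white blood cells.
#' * `mouse_g609g`: relative mouse panel; LA/IC true ratio ~ 1/3 with
#'   progerin present.
#' * `mouse_wt`: LA/IC ~ 1, progerin absent.
#'
#' Human scenarios spike 50 fmol of each heavy standard into 100 ug of
#' digest. Elution apexes sit centrally in each scheduled window with
#' sigma 0.15 min; noise defaults are 5% multiplicative CV over a
#' 30-count chemical floor.
#'
#' @param name Scenario name.
#' @param seed Generator seed stored in the returned truth.
#' @return List with `scenario`, `panel`, `truth`, `mode`,
#'   `default_window`.
#' @export
scenario_fixtures <- function(name, seed = 1L) {
  valid <- c("hgps_fibroblasts", "control_fibroblasts", "wbc_patient",
             "wbc_donor", "mouse_g609g", "mouse_wt")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "))

  if (name %in% c("mouse_g609g", "mouse_wt")) {
    panel <- lamin_panel("mouse_relative")
    amounts <- switch(name,
      mouse_g609g = c(IC = 100, LA = 33, mFP = 60),
      mouse_wt = c(IC = 100, LA = 100, mFP = 0))
    truth <- ground_truth(
      amounts = amounts, spikes = NULL,
      elution = list(IC = c(8, 0.15), LA = c(15, 0.15), mFP = c(22, 0.15)),
      seed = seed)
    return(list(scenario = name, panel = panel, truth = truth,
                mode = "relative", default_window = c(0, 30)))
  }

  panel <- lamin_panel("human_absolute")
  amounts <- switch(name,
    hgps_fibroblasts = c(IC = 176, LA = 133, hFP = 43),
    control_fibroblasts = c(IC = 224, LA = 224, hFP = 0),
    wbc_patient = c(IC = 120, LA = 110, hFP = 0.3),
    wbc_donor = c(IC = 130, LA = 125, hFP = 0))
  truth <- ground_truth(
    amounts = amounts, spikes = c(IC = 50, LA = 50, hFP = 50),
    elution = list(IC = c(20, 0.15), LA = c(50, 0.15), hFP = c(100, 0.15)),
    seed = seed)
  list(scenario = name, panel = panel, truth = truth, mode = "absolute",
       default_window = c(0, 162))
}

#' Write / read a ground-truth sidecar
#'
#' JSON sidecar accompanying simulated mzML files, holding the scenario's
#' true amounts, spikes and generator settings (consumed by tests and by
#' anyone validating a pipeline against the synthetic data).
#'
#' @param truth A [ground_truth()].
#' @param path JSON path.
#' @return `read_ground_truth()` returns a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$amounts <- as.list(x$amounts)   # keep names in JSON
  if (!is.null(x$spikes)) x$spikes <- as.list(x$spikes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(amounts = unlist(x$amounts),
               spikes = if (length(x$spikes)) unlist(x$spikes) else NULL,
               protein_ug = x$protein_ug, response = x$response,
               elution = lapply(x$elution, as.numeric),
               noise_cv = x$noise_cv, noise_floor = x$noise_floor,
               n_noise_peaks = x$n_noise_peaks, seed = x$seed)
}
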