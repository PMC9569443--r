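# XIC extraction, integration and quantification arithmetic.

# a hand-built run with one MS2 scan per rt containing given peaks
manual_run <- function(rts, sel1, peaks_by_scan, ms_level = 2L,
                       sel2 = NA_real_, metadata = list(run_id = "m1")) {
  scans <- data.frame(scan = seq_along(rts), rt = rts,
                      ms_level = ms_level, sel1 = sel1, sel2 = sel2)
  peaks <- do.call(rbind, lapply(seq_along(peaks_by_scan), function(i) {
    p <- peaks_by_scan[[i]]
    if (is.null(p)) return(NULL)
    data.frame(scan = i, mz = p[, 1], intensity = p[, 2])
  }))
  if (is.null(peaks))
    peaks <- data.frame(scan = integer(0), mz = numeric(0),
                        intensity = numeric(0))
  prm_run(scans, peaks, metadata)
}

simple_trace <- function(mz = 500, prec = 700) {
  trace_def("MS2", prec, mz, "y1", "X")
}

test_that("extract_xic matches peaks within tolerance and keeps zeros", {
  tr <- simple_trace()
  run <- manual_run(1, 700, list(cbind(500, 1000)))
  x <- extract_xic(run, tr)
  expect_equal(nrow(x), 1L)
  expect_equal(x$intensity, 1000)

  # monitored m/z off by twice the tolerance: the scan matches, peak does not
  off <- 500 * (1 + 20e-6)
  run2 <- manual_run(1, 700, list(cbind(off, 1000)))
  x2 <- extract_xic(run2, tr, tol_ppm = 10)
  expect_equal(x2$intensity, 0)

  # within tolerance both peaks sum
  run3 <- manual_run(1, 700, list(rbind(c(500 * (1 + 4e-6), 10),
                                        c(500 * (1 - 4e-6), 5))))
  expect_equal(extract_xic(run3, tr)$intensity, 15)
  expect_error(extract_xic(run, tr, tol_ppm = 0), "tol_ppm")
})

test_that("off-path scans yield an empty trace, distinct from zeros", {
  tr <- simple_trace()
  run <- manual_run(c(1, 2), 812, list(cbind(500, 10), cbind(500, 20)))
  x <- extract_xic(run, tr)
  expect_equal(nrow(x), 0L)

  # MS3 path matching requires both levels
  tr3 <- trace_def("MS3", c(700, 430), 333, "y3", "X")
  run3 <- manual_run(c(1, 2), 700, list(cbind(333, 7), cbind(333, 9)),
                     ms_level = 3L, sel2 = c(430, 431))
  x3 <- extract_xic(run3, tr3)
  expect_equal(nrow(x3), 1L)   # second scan's MS3 selection is off
  expect_equal(x3$intensity, 7)

  # RT window restricts the points
  runw <- manual_run(c(1, 2, 3), 700,
                     list(cbind(500, 1), cbind(500, 2), cbind(500, 3)))
  xw <- extract_xic(runw, tr, rt_window = c(1.5, 3))
  expect_equal(xw$intensity, c(2, 3))
})

test_that("integration reproduces rectangle, triangle and Gaussian areas", {
  rt <- seq(0, 2, by = 0.05)
  rect <- structure(data.frame(rt = rt, intensity = 10),
                    class = c("xic", "data.frame"))
  expect_equal(integrate_xic(rect), 10 * 2)

  tri <- structure(data.frame(
    rt = c(0, 1, 2), intensity = c(0, 5, 0)),
    class = c("xic", "data.frame"))
  expect_equal(integrate_xic(tri), 5 * 2 / 2)

  # dense Gaussian vs the closed-form integral over the same bounds
  rt <- seq(0, 4, by = 1 / 600)
  g <- structure(data.frame(rt = rt, intensity = dnorm(rt, 2, 0.15)),
                 class = c("xic", "data.frame"))
  closed <- pnorm(4, 2, 0.15) - pnorm(0, 2, 0.15)
  expect_equal(integrate_xic(g), closed, tolerance = 1e-6)

  expect_warning(a1 <- integrate_xic(g[1, , drop = FALSE]), "single-point")
  expect_equal(a1, 0)
  expect_error(integrate_xic(g[0, , drop = FALSE]), "empty")

  # peak-bounded integration ignores a detached low noise bump
  y <- dnorm(rt, 2, 0.15)
  y[rt > 3.5] <- 0.5
  gp <- structure(data.frame(rt = rt, intensity = y),
                  class = c("xic", "data.frame"))
  expect_equal(integrate_xic(gp, "peak"),
               pnorm(3.5, 2, 0.15) - pnorm(0, 2, 0.15), tolerance = 1e-3)
})

test_that("trace combination sums members and flags missing ones", {
  row <- lamin_panel("human_absolute")$rows$IC
  a <- combine_traces(c("y9" = 10, "y11^2+" = 20), row)
  expect_equal(as.numeric(a), 30)
  expect_true(attr(a, "complete"))
  expect_warning(b <- combine_traces(c("y9" = 10), row), "missing trace")
  expect_equal(as.numeric(b), 10)
  expect_false(attr(b, "complete"))
  expect_error(combine_traces(c(zz = 1), row), "no trace areas")
})

test_that("relative quantification scales to the reference", {
  r <- relative_quant(c(IC = 500, LA = 500))
  expect_equal(unname(r), c(100, 100))
  r2 <- relative_quant(c(IC = 300, LA = 100))
  expect_equal(unname(r2["LA"] / r2["IC"]), 1 / 3)
  expect_equal(unname(relative_quant(c(IC = 7))), 100)
  expect_error(relative_quant(c(IC = 0, LA = 5), run_id = "r7"),
               "not positive.*run r7")
  expect_error(relative_quant(c(LA = 5)), "not among areas")
})

test_that("isotope-dilution arithmetic and statuses", {
  expect_equal(absolute_quant(10, 10, 50, 100)$amount, 50)
  expect_equal(absolute_quant(43, 100, 100, 100)$amount, 43)
  # half the protein load doubles the per-100-ug amount
  expect_equal(absolute_quant(10, 10, 50, 50)$amount, 100)
  expect_identical(absolute_quant(10, 0, 50, 100)$status,
                   "not_quantifiable")
  ld <- absolute_quant(0, 10, 50, 100)
  expect_identical(ld$status, "not_detected")
  expect_equal(ld$amount, 0)
  expect_error(absolute_quant(1, 1, 0, 100), "spike_fmol")
})

test_that("replicate statistics use the sample sd", {
  s <- replicate_stats(c(8, 10, 12))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 2)
  expect_equal(s$cv_percent, 20)
  s0 <- replicate_stats(c(10, 10, 10))
  expect_equal(s0$cv_percent, 0)
  s1 <- replicate_stats(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_error(replicate_stats(numeric(0)), "no replicate")
})

test_that("detection calls split not-detected / below-LOQ / quantified", {
  expect_identical(detection_call(0), "not_detected")
  expect_identical(detection_call(5, noise_floor = 10), "not_detected")
  expect_identical(detection_call(0.4, heavy_area = 100,
                                  loq_ratio = 0.01),
                   "detected_below_loq")
  expect_identical(detection_call(5, heavy_area = 100, loq_ratio = 0.01),
                   "quantified")
  expect_identical(detection_call(5), "quantified")  # no standard: no LOQ
  expect_error(detection_call(1, noise_floor = -1), "noise_floor")
})

test_that("recovered amounts are linear in light signal and spike-invariant", {
  panel <- tiny_panel()
  k <- 3.7
  light_paths <- panel$rows$IC$precursor_mz
  run <- simulate_run(panel, tiny_truth(amount = 40, noise_cv = 0.05,
                                        seed = 11),
                      default_window = c(0, 4))
  res <- quantify_runs(run, panel)
  base_amount <- res$summary$mean[res$summary$symbol == "IC"]

  # scale every peak in the light scans by k: amounts scale by k
  run_k <- run
  light_scans <- run$scans$scan[abs(run$scans$sel1 - light_paths) < 0.01]
  sel <- run_k$peaks$scan %in% light_scans
  run_k$peaks$intensity[sel] <- run_k$peaks$intensity[sel] * k
  res_k <- quantify_runs(run_k, panel)
  expect_equal(res_k$summary$mean[res_k$summary$symbol == "IC"],
               k * base_amount, tolerance = 1e-9)

  # doubling the spike and the heavy intensities leaves amounts unchanged
  run_2 <- run
  heavy_scans <- setdiff(run$scans$scan, light_scans)
  sel2 <- run_2$peaks$scan %in% heavy_scans
  run_2$peaks$intensity[sel2] <- run_2$peaks$intensity[sel2] * 2
  run_2$metadata$spikes <- run$metadata$spikes * 2
  res_2 <- quantify_runs(run_2, panel)
  expect_equal(res_2$summary$mean[res_2$summary$symbol == "IC"],
               base_amount, tolerance = 1e-6)
})

test_that("quantification fails loudly when no scans match the panel", {
  panel <- tiny_panel()
  run <- manual_run(1, 1234.5, list(cbind(500, 10)))
  expect_error(quantify_runs(run, panel), "match any panel row")
})
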