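# Transition-table design: panel regeneration, heavy companions,
# scheduling and CSV interchange.

test_that("regenerated panels reproduce every printed m/z value", {
  expected <- published_mz()
  for (nm in names(expected)) {
    got <- panel_mz(lamin_panel(nm))
    exp <- expected[[nm]]
    expect_true(all(names(exp) %in% names(got)), info = nm)
    diffs <- abs(got[names(exp)] - exp)
    expect_lt(max(diffs), 0.0015)
  }
})

test_that("published RT schedules are applied, shared by heavy partners", {
  p <- lamin_panel("human_absolute")
  expect_equal(p$rows$IC$rt_window, c(0, 35))
  expect_equal(p$rows$LA$rt_window, c(35, 70))
  expect_equal(p$rows$hFP$rt_window, c(70, 162))
  expect_equal(p$rows[["IC*"]]$rt_window, p$rows$IC$rt_window)
  expect_equal(p$rows[["hFP*"]]$rt_window, p$rows$hFP$rt_window)
  pr <- lamin_panel("human_relative")
  expect_equal(pr$rows$IC$rt_window, c(0, 70))
  expect_equal(pr$rows$hFP$rt_window, c(70, 162))
  # mouse panel is unscheduled
  expect_true(all(is.na(lamin_panel("mouse_relative")$rows$IC$rt_window)))
})

test_that("every monitored m/z is reachable from its peptide via the calculus", {
  for (nm in c("mouse_relative", "human_relative", "human_absolute")) {
    p <- lamin_panel(nm)
    for (row in p$rows) {
      expect_equal(row$precursor_mz,
                   precursor_mz(row$peptide, row$precursor_z),
                   tolerance = 1e-12)
      for (tr in row$traces) {
        # recompute independently from the stored recipe
        mon <- tr$monitor_spec
        ref <- if (mon$kind == "frag") {
          fragment_mz(row$peptide, mon$series, mon$index, mon$z,
                      defarnesylated = isTRUE(mon$defarnesylated))
        } else {
          mz <- precursor_mz(row$peptide, mon$z)
          for (l in mon$losses) mz <- neutral_loss_mz(mz, mon$z, l)
          mz
        }
        expect_equal(tr$monitored_mz, ref, tolerance = 1e-12)
        expect_equal(tr$selection_path[1], row$precursor_mz,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("heavy companions shift precursor and label-containing fragments", {
  p <- lamin_panel("human_absolute")
  dk <- 6 * DELTA_13C + 2 * DELTA_15N    # Lys label (IC*)
  da <- 3 * DELTA_13C + 1 * DELTA_15N    # Ala label (hFP*)
  expect_equal(p$rows[["IC*"]]$precursor_mz - p$rows$IC$precursor_mz,
               dk / 2, tolerance = 1e-12)
  expect_equal(p$rows[["hFP*"]]$precursor_mz - p$rows$hFP$precursor_mz,
               da / 2, tolerance = 1e-12)
  # y9 of IC contains the C-terminal Lys: shifts by the full delta
  expect_equal(p$rows[["IC*"]]$traces[[1]]$monitored_mz -
                 p$rows$IC$traces[[1]]$monitored_mz, dk, tolerance = 1e-12)
  # y11(2+): delta over 2
  expect_equal(p$rows[["IC*"]]$traces[[2]]$monitored_mz -
                 p$rows$IC$traces[[2]]$monitored_mz, dk / 2,
               tolerance = 1e-12)
  # NL trace of hFP* derives from the precursor: full Ala delta
  expect_equal(p$rows[["hFP*"]]$traces[[1]]$monitored_mz -
                 p$rows$hFP$traces[[1]]$monitored_mz, da, tolerance = 1e-12)
})

test_that("a monitored fragment without the labelled residue warns, unshifted", {
  pep <- modified_peptide("SVGGSGGGSFGDNLVTR", symbol = "LA")
  strat <- list(stage = "MS2", z = 2L, traces = list(
    list(select = NULL, monitor = frag_spec_test("y", 2))))
  p <- assay_panel("t", list(design_transitions(pep, strat)))
  # label on the N-terminal Ser: y2 does not contain it
  expect_warning(ph <- add_heavy_companions(p, list(LA = heavy_label(1, 3, 1))),
                 "does not contain the labelled residue")
  expect_equal(ph$rows[["LA*"]]$traces[[1]]$monitored_mz,
               p$rows$LA$traces[[1]]$monitored_mz, tolerance = 1e-12)
})

test_that("zero-count labels leave the panel unchanged", {
  p <- assay_panel("t", list(design_transitions(
    ic_peptide(), list(stage = "MS2", z = 2L, traces = list(
      list(select = NULL, monitor = frag_spec_test("y", 9)))))))
  p0 <- add_heavy_companions(p, list(IC = heavy_label(13, 0, 0)))
  expect_identical(names(p0$rows), names(p$rows))
  expect_equal(as.data.frame(p0)$monitored_mz,
               as.data.frame(p)$monitored_mz)
})

test_that("design rejects fragments beyond the peptide and missing windows", {
  expect_error(design_transitions(
    ic_peptide(), list(stage = "MS2", z = 2L, traces = list(
      list(select = NULL, monitor = frag_spec_test("y", 13))))),
    "1 <= n <")
  p <- lamin_panel("mouse_relative")
  expect_error(schedule(p, list(IC = c(0, 10), LA = c(10, 20))),
               "no RT window for symbol mFP")
  expect_error(schedule(p, list(IC = c(10, 0), LA = c(10, 20),
                                mFP = c(20, 30))), "start < end")
  # single-row panel with a window covering the run is trivially scheduled
  p1 <- assay_panel("one", list(p$rows$IC))
  p1 <- schedule(p1, list(IC = c(0, 60)))
  expect_equal(p1$rows$IC$rt_window, c(0, 60))
})

test_that("transition CSV round-trips panels exactly", {
  for (nm in c("mouse_relative", "human_absolute")) {
    p <- lamin_panel(nm)
    f <- withr::local_tempfile(fileext = ".csv")
    write_transition_csv(p, f)
    q <- read_transition_csv(f)
    expect_identical(q$name, p$name)
    expect_identical(q$mode, p$mode)
    expect_equal(as.data.frame(q), as.data.frame(p), tolerance = 1e-12)
    expect_equal(q$heavy_pairs[sort(names(q$heavy_pairs))],
                 p$heavy_pairs[sort(names(p$heavy_pairs))])
  }
  # the absolute panel carries 6 rows (3 light + 3 heavy)
  expect_length(lamin_panel("human_absolute")$rows, 6L)
})

test_that("empty panels and malformed CSVs are handled explicitly", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(assay_panel("empty", list()), f)
  expect_equal(length(readLines(f)), 1L)  # header only
  q <- read_transition_csv(f)
  expect_length(q$rows, 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_transition_csv(bad), "line 1")

  p <- lamin_panel("mouse_relative")
  write_transition_csv(p, f)
  lines <- readLines(f)
  lines[3] <- sub("^([^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,)2,",
                  "\\1xx,", lines[3])
  writeLines(lines, bad)
  expect_error(read_transition_csv(bad), "line 3")
})

test_that("auto strategies cover modified and unmodified peptides", {
  pep <- as_panel_peptide("ELRDNLAVYIDR", symbol = "X")
  row <- design_transitions(pep, auto_strategy(pep))
  expect_length(row$traces, 2L)
  expect_true(all(vapply(row$traces, function(tr) tr$stage, "") == "MS2"))
  farn <- as_panel_peptide("SQSSQNC", cterm_farnesylated = TRUE,
                           symbol = "F")
  rowf <- design_transitions(farn, auto_strategy(farn))
  labels <- vapply(rowf$traces, function(tr) tr$ion_label, "")
  expect_true("NL" %in% labels)
})
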