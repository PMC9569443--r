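# Proteoform derivation, tryptic digestion and signature selection.

test_that("tryptic digestion cleaves after K/R except before Pro", {
  d <- tryptic_digest("AAAKGGR")
  expect_equal(d$peptide, c("AAAK", "GGR"))
  expect_equal(d$start, c(1L, 5L))
  expect_equal(d$end, c(4L, 7L))
  expect_equal(tryptic_digest("AAKPGG")$peptide, "AAKPGG")
  # C-terminal peptide included without a K/R terminus
  expect_equal(tail(tryptic_digest("AAKGGC")$peptide, 1), "GGC")
  expect_error(tryptic_digest(""), "empty")
  expect_error(tryptic_digest("AAK", missed = -1), ">= 0")
})

test_that("missed cleavages produce all merged adjacent peptides", {
  d <- tryptic_digest("AAAKGGRTTK", missed = 1)
  expect_setequal(d$peptide[d$n_missed == 0], c("AAAK", "GGR", "TTK"))
  expect_setequal(d$peptide[d$n_missed == 1], c("AAAKGGR", "GGRTTK"))
})

test_that("digest peptides concatenate back to the sequence", {
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(names(AA_MONO), sample(10:80, 1), replace = TRUE),
                 collapse = "")
    d <- tryptic_digest(seq)
    expect_identical(paste(d$peptide, collapse = ""), seq)
    expect_identical(d$start[1], 1L)
    expect_identical(tail(d$end, 1), nchar(seq))
  }
})

test_that("processing rules yield the four proteoforms with correct arithmetic", {
  pf <- build_proteoforms(toy_prelamin())
  n <- nchar(toy_prelamin())
  expect_named(pf, c("prelamin_A", "farnesylated_prelamin_A",
                     "mature_lamin_A"))
  expect_equal(nchar(pf$mature_lamin_A$sequence), n - 18L)
  expect_equal(nchar(pf$farnesylated_prelamin_A$sequence), n - 3L)
  # the farnesylated form ends in the modified Cys
  fseq <- pf$farnesylated_prelamin_A$sequence
  expect_identical(substr(fseq, nchar(fseq), nchar(fseq)), "C")
  expect_setequal(pf$farnesylated_prelamin_A$terminal_mods,
                  c("farnesyl", "o_methyl"))
  expect_length(pf$mature_lamin_A$terminal_mods, 0)
  expect_error(build_proteoforms("MTESTKAAAGGRLLQNSSKGGHEYVASIM"),
               "CAAX")
})

test_that("progerin-type variants delete the interval and keep the farnesyl", {
  seqs <- prelamin_sequences()
  del <- attr(seqs, "deletion")
  for (nm in names(seqs)) {
    L <- nchar(seqs[[nm]])
    pf <- build_proteoforms(seqs[[nm]], deletion = del[[nm]])
    expect_equal(del[[nm]][2] - del[[nm]][1] + 1L, 50L)
    expect_equal(nchar(pf$progerin$sequence), L - 50L - 3L)
    expect_setequal(pf$progerin$terminal_mods, c("farnesyl", "o_methyl"))
    # deletion contains the Zmpste24 site, so no warning was raised above;
    # an interval missing the site warns
    expect_warning(build_proteoforms(seqs[[nm]], deletion = c(20L, 69L)),
                   "Zmpste24")
  }
})

test_that("processed progerin digests terminate in the junction peptide", {
  seqs <- prelamin_sequences()
  del <- attr(seqs, "deletion")
  pf_h <- build_proteoforms(seqs[["synthetic_human_prelaminA"]],
                            deletion = del[["synthetic_human_prelaminA"]])
  d <- digest_proteoform(pf_h$progerin)
  expect_identical(tail(d$peptide, 1), "ASASGSGAQSPQNC")
  expect_identical(tail(d$terminal_mods, 1), "farnesyl,o_methyl")
  pf_m <- build_proteoforms(seqs[["synthetic_mouse_prelaminA"]],
                            deletion = del[["synthetic_mouse_prelaminA"]])
  dm <- digest_proteoform(pf_m$progerin)
  expect_identical(tail(dm$peptide, 1), "AAGGAGAQSSQNC")
})

test_that("the LA peptide lies inside the progerin deletion interval", {
  seqs <- prelamin_sequences()
  del <- attr(seqs, "deletion")
  for (nm in names(seqs)) {
    d <- tryptic_digest(seqs[[nm]])
    row <- d[d$peptide == "SVGGSGGGSFGDNLVTR", ]
    expect_equal(nrow(row), 1L)
    expect_gte(row$start, del[[nm]][1])
    expect_lte(row$end, del[[nm]][2])
  }
})

test_that("signature assignment maps peptides to exact proteoform subsets", {
  seqs <- prelamin_sequences()
  del <- attr(seqs, "deletion")
  pf <- build_proteoforms(seqs[["synthetic_mouse_prelaminA"]],
                          deletion = del[["synthetic_mouse_prelaminA"]])
  set3 <- pf[c("mature_lamin_A", "farnesylated_prelamin_A", "progerin")]
  asg <- assign_signatures(set3)

  row <- function(seq, mods = "") asg[asg$sequence == seq &
                                        asg$terminal_mods == mods, ]
  expect_identical(row("TVLCGTCGQPADK")$status, "shared_all")
  expect_identical(row("SYLLGNSSPR")$status, "unique")
  expect_identical(row("SYLLGNSSPR")$found_in, "farnesylated_prelamin_A")
  expect_identical(row("SQSSQNC", "farnesyl,o_methyl")$found_in,
                   "farnesylated_prelamin_A")
  expect_identical(row("AAGGAGAQSSQNC", "farnesyl,o_methyl")$found_in,
                   "progerin")
  # terminal-modified peptides never match unmodified identical sequences
  expect_equal(nrow(asg[asg$sequence == "SQSSQNC" &
                          asg$terminal_mods == "", ]), 0L)
  # IC is also common to the full four-proteoform set
  asg4 <- assign_signatures(pf)
  expect_identical(asg4[asg4$sequence == "TVLCGTCGQPADK", ]$status,
                   "shared_all")

  # invariant to the order proteoforms are supplied
  asg_rev <- assign_signatures(rev(set3))
  expect_identical(asg, asg_rev)
})

test_that("identical proteoforms share every peptide", {
  a <- proteoform("a", toy_prelamin())
  b <- proteoform("b", toy_prelamin())
  asg <- assign_signatures(list(a, b))
  expect_true(all(asg$status == "shared_all"))
  # and surrogate selection then yields explicit empty entries
  sel <- select_surrogates(asg, interest = c("a", "b"))
  expect_identical(sel$role[1], "control")
  expect_true(all(is.na(sel$sequence[sel$role == "surrogate"])))
  expect_identical(sel$status[sel$role == "surrogate"], c("none", "none"))
})

test_that("surrogate selection reproduces the published panels", {
  seqs <- prelamin_sequences()
  del <- attr(seqs, "deletion")

  pf_m <- build_proteoforms(seqs[["synthetic_mouse_prelaminA"]],
                            deletion = del[["synthetic_mouse_prelaminA"]])
  interest <- c("mature_lamin_A", "farnesylated_prelamin_A", "progerin")
  sel_m <- select_surrogates(assign_signatures(pf_m[interest]),
                             interest = interest)
  expect_equal(nrow(sel_m), 5L)
  expect_setequal(
    paste(sel_m$sequence, sel_m$terminal_mods),
    c("TVLCGTCGQPADK ", "SVGGSGGGSFGDNLVTR ", "SYLLGNSSPR ",
      "SQSSQNC farnesyl,o_methyl", "AAGGAGAQSSQNC farnesyl,o_methyl"))

  pf_h <- build_proteoforms(seqs[["synthetic_human_prelaminA"]],
                            deletion = del[["synthetic_human_prelaminA"]])
  interest_h <- c("mature_lamin_A", "progerin")
  sel_h <- select_surrogates(assign_signatures(pf_h[interest_h]),
                             interest = interest_h)
  expect_setequal(sel_h$sequence,
                  c("TVLCGTCGQPADK", "SVGGSGGGSFGDNLVTR",
                    "ASASGSGAQSPQNC"))

  # selection with an empty interest set returns the control only
  ctrl_only <- select_surrogates(assign_signatures(pf_h[interest_h]))
  expect_identical(ctrl_only$role, "control")
})

test_that("FASTA reading names and returns sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy some description", toy_prelamin()), f)
  seqs <- read_fasta(f)
  expect_identical(names(seqs), "toy")
  expect_identical(unname(seqs), toy_prelamin())
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
})
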