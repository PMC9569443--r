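#' Construct a proteoform
#'
#' A full-length protein product with its processing provenance: prelamin A
#' and the products of CAAX processing (farnesylation, AAX cleavage,
#' carboxymethylation, Zmpste24 cleavage), plus the internally deleted
#' progerin variant.
#'
#' @param name Proteoform name.
#' @param sequence Residue string.
#' @param terminal_mods Character vector of modification names carried by
#'   the C-terminal residue (e.g. `c("farnesyl", "o_methyl")`).
#' @param provenance Ordered character vector of processing steps applied.
#' @param deletion Optional `c(start, end)` residue interval (1-based,
#'   inclusive, in prelamin A coordinates) deleted from the precursor.
#' @return An object of class `proteoform`.
#' @export
proteoform <- function(name, sequence, terminal_mods = character(),
                       provenance = character(), deletion = NULL) {
  stopifnot(is.character(name), is.character(sequence), nzchar(sequence))
  if (!is.null(deletion)) {
    deletion <- as.integer(deletion)
    stopifnot(length(deletion) == 2L, deletion[1] <= deletion[2])
  }
  structure(list(name = name, sequence = sequence,
                 terminal_mods = terminal_mods, provenance = provenance,
                 deletion = deletion),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", x$name, " (", nchar(x$sequence), " aa)\n", sep = "")
  if (length(x$terminal_mods))
    cat("  C-terminal mods: ", paste(x$terminal_mods, collapse = " + "),
        "\n", sep = "")
  if (length(x$provenance))
    cat("  processing: ", paste(x$provenance, collapse = " -> "),
        "\n", sep = "")
  if (!is.null(x$deletion))
    cat("  deletion: ", x$deletion[1], "-", x$deletion[2],
        " (precursor coordinates)\n", sep = "")
  invisible(x)
}

#' Derive the lamin A proteoform set from a prelamin A sequence
#'
#' Applies the prelamin A maturation rules to a precursor sequence ending
#' in a CAAX motif (Cys at `length - 3`):
#' * `prelamin_A`: the input, unprocessed;
#' * `farnesylated_prelamin_A`: AAX removed, C-terminal Cys farnesylated
#'   and O-methylated (the species that accumulates when the final
#'   Zmpste24 cleavage is blocked);
#' * `mature_lamin_A`: the 18 C-terminal residues removed in total (3 by
#'   AAX cleavage, then 15 including the modified Cys by Zmpste24), no
#'   terminal modifications;
#' * `progerin` (when `deletion` is given): the 50-residue interval
#'   deleted, then processed as the farnesylated form; the Zmpste24 site is
#'   lost with the deletion so the farnesyl is retained permanently.
#'
#' @param prelamin_seq Prelamin A residue string ending in a CAAX motif.
#' @param deletion Optional `c(start, end)` 1-based inclusive interval to
#'   delete for the progerin-type variant. A warning (configurable via
#'   `warn_missing_site`) is emitted when the interval does not contain the
#'   Zmpste24 cleavage site.
#' @param warn_missing_site Warn when `deletion` excludes the Zmpste24 site.
#' @return A named list of [proteoform()] objects, class `proteoform_set`.
#' @examples
#' pf <- build_proteoforms(paste0(strrep("AGSTK", 10), "QNCSIM"))
#' nchar(pf$mature_lamin_A$sequence) - nchar(pf$prelamin_A$sequence)  # -18
#' @export
build_proteoforms <- function(prelamin_seq, deletion = NULL,
                              warn_missing_site = TRUE) {
  stopifnot(is.character(prelamin_seq), length(prelamin_seq) == 1L)
  n <- nchar(prelamin_seq)
  if (n < 19L) stop("prelamin sequence too short for -18 processing")
  if (substr(prelamin_seq, n - 3L, n - 3L) != "C")
    stop("no CAAX motif: expected Cys at position ", n - 3L,
         " (length - 3)")

  farn <- c("farnesyl", "o_methyl")
  out <- list(
    prelamin_A = proteoform("prelamin_A", prelamin_seq),
    farnesylated_prelamin_A = proteoform(
      "farnesylated_prelamin_A", substr(prelamin_seq, 1L, n - 3L),
      terminal_mods = farn,
      provenance = c("farnesylate_CAAX", "cleave_AAX", "carboxymethylate")),
    mature_lamin_A = proteoform(
      "mature_lamin_A", substr(prelamin_seq, 1L, n - 18L),
      provenance = c("farnesylate_CAAX", "cleave_AAX", "carboxymethylate",
                     "zmpste24_cleave_15"))
  )

  if (!is.null(deletion)) {
    deletion <- as.integer(deletion)
    stopifnot(length(deletion) == 2L)
    if (deletion[1] < 1L || deletion[2] > n - 4L)
      stop("deletion interval must lie within the sequence, upstream of ",
           "the CAAX motif")
    # Zmpste24 removes residues (n-17)..(n-3) of the AAX-cleaved form; the
    # cleavage site is the (n-18)|(n-17) bond.
    if (warn_missing_site &&
        !any(c(n - 18L, n - 17L) %in% seq(deletion[1], deletion[2])))
      warning("deletion interval [", deletion[1], ", ", deletion[2],
              "] does not contain the Zmpste24 cleavage site")
    del_seq <- paste0(substr(prelamin_seq, 1L, deletion[1] - 1L),
                      substr(prelamin_seq, deletion[2] + 1L, n))
    m <- nchar(del_seq)
    if (substr(del_seq, m - 3L, m - 3L) != "C")
      stop("deletion destroys the CAAX motif")
    out$progerin <- proteoform(
      "progerin", substr(del_seq, 1L, m - 3L),
      terminal_mods = farn,
      provenance = c("delete_interval", "farnesylate_CAAX", "cleave_AAX",
                     "carboxymethylate"),
      deletion = deletion)
  }
  structure(out, class = c("proteoform_set", "list"))
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal to Lys/Arg except when the next residue is Pro. The
#' protein C-terminal peptide is always included even without a K/R
#' terminus. Coordinates are 1-based inclusive.
#'
#' @param seq Residue string.
#' @param missed Maximum number of missed cleavages (default 0). All
#'   peptides with 0..`missed` internal cleavage sites are returned.
#' @return `data.frame` with columns `peptide`, `start`, `end`, `n_missed`.
#' @examples
#' tryptic_digest("AAAKGGR")$peptide   # "AAAK" "GGR"
#' tryptic_digest("AAKPGG")$peptide    # "AAKPGG" (no cleavage before Pro)
#' @export
tryptic_digest <- function(seq, missed = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot digest an empty sequence")
  missed <- as.integer(missed)
  if (missed < 0L) stop("missed cleavage count must be >= 0")
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- data.frame(start = starts, end = ends, n_missed = 0L)
  if (missed > 0L) {
    k <- length(starts)
    extra <- list()
    for (mm in seq_len(missed)) {
      if (k - mm < 1L) break
      i <- seq_len(k - mm)
      extra[[mm]] <- data.frame(start = starts[i], end = ends[i + mm],
                                n_missed = mm)
    }
    base <- rbind(base, do.call(rbind, extra))
  }
  base$peptide <- substring(seq, base$start, base$end)
  base <- base[order(base$start, base$end), c("peptide", "start", "end",
                                              "n_missed")]
  rownames(base) <- NULL
  base
}

#' Digest a proteoform, tracking terminal modifications
#'
#' Like [tryptic_digest()] on the proteoform sequence, with a
#' `terminal_mods` column: the proteoform's C-terminal modifications
#' (e.g. farnesyl + O-methyl) are carried by its C-terminal peptide only.
#'
#' @param pf A [proteoform()].
#' @param missed Missed cleavages.
#' @return `data.frame` with columns `peptide`, `start`, `end`, `n_missed`,
#'   `terminal_mods` (comma-joined names, `""` elsewhere).
#' @export
digest_proteoform <- function(pf, missed = 0L) {
  stopifnot(inherits(pf, "proteoform"))
  d <- tryptic_digest(pf$sequence, missed)
  d$terminal_mods <- ifelse(d$end == nchar(pf$sequence),
                            paste(pf$terminal_mods, collapse = ","), "")
  d
}

#' Map digest peptides to the proteoforms that contain them
#'
#' Each distinct (sequence, terminal modification) peptide is assigned the
#' exact subset of proteoforms whose digest produces it. A terminally
#' modified peptide never matches an unmodified peptide of identical
#' sequence. The result is invariant to the order in which proteoforms are
#' supplied.
#'
#' @param proteoforms A `proteoform_set` or list of [proteoform()]s
#'   (at least 2).
#' @param missed Missed cleavages passed to the digests.
#' @return `data.frame` with columns `sequence`, `terminal_mods`,
#'   `found_in` (comma-joined sorted proteoform names), `n_found`, `status`
#'   (`unique`, `shared_all` or `shared_some`).
#' @export
assign_signatures <- function(proteoforms, missed = 0L) {
  proteoforms <- unclass(proteoforms)
  if (length(proteoforms) < 2L)
    stop("signature assignment needs at least 2 proteoforms")
  nm <- vapply(proteoforms, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("proteoform names must be unique")
  per <- lapply(proteoforms, function(pf) {
    d <- digest_proteoform(pf, missed)
    unique(data.frame(sequence = d$peptide, terminal_mods = d$terminal_mods,
                      proteoform = pf$name, stringsAsFactors = FALSE))
  })
  all <- do.call(rbind, per)
  key <- paste(all$sequence, all$terminal_mods, sep = "\r")
  grp <- split(all$proteoform, key)
  found <- vapply(grp, function(g) paste(sort(unique(g)), collapse = ","),
                  character(1))
  nfound <- vapply(grp, function(g) length(unique(g)), integer(1))
  first <- all[!duplicated(key), ]
  o <- match(names(grp), paste(first$sequence, first$terminal_mods,
                               sep = "\r"))
  out <- data.frame(sequence = first$sequence[o],
                    terminal_mods = first$terminal_mods[o],
                    found_in = unname(found), n_found = unname(nfound),
                    stringsAsFactors = FALSE)
  out$status <- ifelse(out$n_found == 1L, "unique",
                       ifelse(out$n_found == length(proteoforms),
                              "shared_all", "shared_some"))
  out <- out[order(out$sequence, out$terminal_mods), ]
  rownames(out) <- NULL
  out
}

#' Select surrogate peptides for a proteoform panel
#'
#' Returns one shared-by-all internal-control peptide plus, for each
#' proteoform of interest, the qualifying peptides found in the smallest
#' proteoform subset containing that proteoform (unique peptides when they
#' exist). Qualifying peptides satisfy the length bounds of `policy`. A
#' proteoform with no qualifying candidate yields an explicit empty entry
#' rather than being silently dropped.
#'
#' @param assignments Output of [assign_signatures()].
#' @param interest Character vector of proteoform names to provide
#'   surrogates for. Empty vector: control peptide only.
#' @param policy List with `min_length` and `max_length` (residues;
#'   defaults 6 and 25, typical bounds for well-behaved tryptic
#'   surrogates).
#' @return `data.frame` with columns `role` (`control`/`surrogate`),
#'   `proteoform`, `sequence`, `terminal_mods`, `found_in`, `status`.
#' @export
select_surrogates <- function(assignments, interest = character(),
                              policy = list(min_length = 6L,
                                            max_length = 25L)) {
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0L)
  len <- nchar(assignments$sequence)
  ok <- assignments[len >= policy$min_length & len <= policy$max_length, ,
                    drop = FALSE]

  ctrl <- ok[ok$status == "shared_all", , drop = FALSE]
  ctrl <- ctrl[order(nchar(ctrl$sequence), ctrl$sequence), , drop = FALSE]
  rows <- list()
  if (nrow(ctrl)) {
    rows[[1]] <- data.frame(role = "control", proteoform = NA_character_,
                            sequence = ctrl$sequence[1],
                            terminal_mods = ctrl$terminal_mods[1],
                            found_in = ctrl$found_in[1],
                            status = ctrl$status[1],
                            stringsAsFactors = FALSE)
  }
  for (pf in interest) {
    hit <- ok[vapply(strsplit(ok$found_in, ","), function(s) pf %in% s,
                     logical(1)), , drop = FALSE]
    hit <- hit[hit$status != "shared_all", , drop = FALSE]
    if (!nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        role = "surrogate", proteoform = pf, sequence = NA_character_,
        terminal_mods = NA_character_, found_in = NA_character_,
        status = "none", stringsAsFactors = FALSE)
      next
    }
    hit <- hit[hit$n_found == min(hit$n_found), , drop = FALSE]
    hit <- hit[order(hit$sequence), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      role = "surrogate", proteoform = pf, sequence = hit$sequence,
      terminal_mods = hit$terminal_mods, found_in = hit$found_in,
      status = hit$status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled synthetic prelamin A sequences
#'
#' Reads the synthetic prelamin-A-like sequences shipped with the package
#' (`inst/extdata/synthetic_prelamin.fasta`). These are constructed stand-in
#' sequences, not database entries: they reproduce every feature the assay
#' depends on (CSIM CAAX terminus, the -3/-15 processing arithmetic, a
#' 50-residue deletion interval ending 9 residues from the C-terminus, and
#' all surrogate peptides in correct tryptic context) but the filler regions
#' between those landmarks are arbitrary.
#'
#' @param path Optional path to an alternative FASTA file.
#' @return Named character vector of sequences, plus attribute `deletion`
#'   (list of `c(start, end)` progerin deletion intervals per sequence).
#' @export
prelamin_sequences <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_prelamin.fasta",
                        package = "prmlamin", mustWork = TRUE)
  seqs <- read_fasta(path)
  n <- nchar(seqs)
  # progerin deletion: 50 residues ending 9 residues from the C-terminus
  deletion <- lapply(n, function(L) c(L - 58L, L - 9L))
  names(deletion) <- names(seqs)
  attr(seqs, "deletion") <- deletion
  seqs
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences found in FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write a surrogate-peptide panel as CSV
#'
#' @param panel Output of [select_surrogates()] (optionally with a `symbol`
#'   column prepended).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_surrogate_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
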