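#' Heavy isotope label specification
#'
#' Describes a stable-isotope label on a single residue of a peptide, as
#' used for AQUA-style internal standards: a count of 13C and 15N atoms
#' replacing 12C/14N. The mass shift is fully determined by the counts.
#'
#' @param position 1-based residue index carrying the label.
#' @param n_13C Number of 13C atoms.
#' @param n_15N Number of 15N atoms.
#' @return An object of class `heavy_label`.
#' @examples
#' heavy_label(13, n_13C = 6, n_15N = 2)  # fully labelled Lys
#' @export
heavy_label <- function(position, n_13C = 0, n_15N = 0) {
  position <- as.integer(position)
  n_13C <- as.integer(n_13C)
  n_15N <- as.integer(n_15N)
  if (length(position) != 1L || is.na(position) || position < 1L)
    stop("label position must be a single positive integer")
  if (n_13C < 0L || n_15N < 0L) stop("isotope counts must be >= 0")
  structure(list(position = position, n_13C = n_13C, n_15N = n_15N),
            class = "heavy_label")
}

#' Mass shift of a heavy label
#'
#' @param label A [heavy_label()].
#' @return Mass shift in Da: `n_13C * DELTA_13C + n_15N * DELTA_15N`.
#' @export
label_delta <- function(label) {
  if (is.null(label)) return(0)
  stopifnot(inherits(label, "heavy_label"))
  label$n_13C * DELTA_13C + label$n_15N * DELTA_15N
}

#' Construct a modified peptide
#'
#' The unit of all mass calculus: a peptide sequence in the standard
#' 20-letter alphabet plus per-residue modifications and an optional heavy
#' label. Farnesyl and O-methyl are only accepted on a C-terminal cysteine
#' (the CAAX-processing product), and at most one farnesyl is allowed.
#'
#' @param sequence Residue string (uppercase one-letter codes).
#' @param mods `NULL`, or a `data.frame` with columns `position` (1-based)
#'   and `name` (registry modification name).
#' @param label Optional [heavy_label()].
#' @param symbol Optional short panel name (e.g. `"IC"`, `"hFP"`).
#' @param registry Modification registry, see [default_modifications()].
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("TVLCGTCGQPADK",
#'   mods = data.frame(position = c(4, 7), name = "carbamidomethyl"),
#'   symbol = "IC")
#' @export
modified_peptide <- function(sequence, mods = NULL, label = NULL,
                             symbol = NULL,
                             registry = default_modifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("peptide sequence must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% names(AA_MONO)))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  n <- length(res)

  if (is.null(mods)) {
    mods <- data.frame(position = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(mods), all(c("position", "name") %in% names(mods)))
  mods$position <- as.integer(mods$position)
  mods$name <- as.character(mods$name)
  if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > n))
      stop("modification position out of sequence bounds: ",
           mods$position[which(mods$position < 1L | mods$position > n)[1]])
    idx <- match(mods$name, registry$name)
    if (anyNA(idx))
      stop("unknown modification: ", mods$name[which(is.na(idx))[1]])
    target <- registry$target[idx]
    for (i in seq_len(nrow(mods))) {
      p <- mods$position[i]
      tgt <- target[i]
      if (tgt == "C" && res[p] != "C")
        stop("modification '", mods$name[i], "' requires Cys at position ", p)
      if (tgt == "cterm-C" && (p != n || res[p] != "C"))
        stop("modification '", mods$name[i],
             "' is only allowed on a C-terminal Cys (position ", p, ")")
      if (tgt == "loss")
        stop("'", mods$name[i], "' is a neutral-loss species, ",
             "not a residue modification")
    }
    if (sum(mods$name == "farnesyl") > 1L)
      stop("at most one farnesyl modification is allowed")
    mods <- mods[order(mods$position, mods$name), , drop = FALSE]
    rownames(mods) <- NULL
  }

  if (!is.null(label)) {
    stopifnot(inherits(label, "heavy_label"))
    if (label$position > n)
      stop("heavy label position ", label$position,
           " beyond peptide length ", n)
  }

  structure(list(sequence = sequence, mods = mods, label = label,
                 symbol = symbol),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat("<modified_peptide>",
      if (!is.null(x$symbol)) paste0(" ", x$symbol), "\n", sep = "")
  cat("  sequence: ", x$sequence, " (", nchar(x$sequence), " aa)\n", sep = "")
  if (nrow(x$mods))
    cat("  mods:     ",
        paste(sprintf("%s@%d", x$mods$name, x$mods$position),
              collapse = ", "), "\n", sep = "")
  if (!is.null(x$label))
    cat(sprintf("  label:    residue %d, %dx13C + %dx15N (+%.4f Da)\n",
                x$label$position, x$label$n_13C, x$label$n_15N,
                label_delta(x$label)))
  invisible(x)
}

peptide_length <- function(p) nchar(p$sequence)

has_farnesyl <- function(p) any(p$mods$name == "farnesyl")

## Per-residue monoisotopic masses including residue modifications and the
## heavy-label shift at its position. Optionally with farnesyl removed
## (the species monitored after farnesyl neutral loss: O-methyl retained).
residue_mass_vector <- function(p, registry = default_modifications(),
                                defarnesylated = FALSE) {
  m <- unname(AA_MONO[strsplit(p$sequence, "")[[1]]])
  if (nrow(p$mods)) {
    keep <- !(defarnesylated & p$mods$name == "farnesyl")
    mm <- p$mods[keep, , drop = FALSE]
    if (nrow(mm)) {
      d <- mod_delta(mm$name, registry)
      for (i in seq_len(nrow(mm)))
        m[mm$position[i]] <- m[mm$position[i]] + d[i]
    }
  }
  if (!is.null(p$label))
    m[p$label$position] <- m[p$label$position] + label_delta(p$label)
  m
}
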