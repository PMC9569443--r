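#' Neutral monoisotopic mass of a modified peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus all modification
#' deltas and the heavy-label shift.
#'
#' @param p A [modified_peptide()].
#' @param registry Modification registry.
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass(modified_peptide("G"))  # 75.03203
#' @export
peptide_neutral_mass <- function(p, registry = default_modifications()) {
  stopifnot(inherits(p, "modified_peptide"))
  sum(residue_mass_vector(p, registry)) + WATER_MASS
}

#' Precursor m/z of a modified peptide
#'
#' @param p A [modified_peptide()].
#' @param z Positive integer charge.
#' @param registry Modification registry.
#' @return m/z in Th: `(M + z * PROTON_MASS) / z`. Full double precision;
#'   use [mz_round()] for 4-decimal table display.
#' @examples
#' ic <- modified_peptide("TVLCGTCGQPADK",
#'   mods = data.frame(position = c(4, 7), name = "carbamidomethyl"))
#' mz_round(precursor_mz(ic, 2))  # 703.8238
#' @export
precursor_mz <- function(p, z, registry = default_modifications()) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L)
    stop("charge must be a positive integer")
  (peptide_neutral_mass(p, registry) + z * PROTON_MASS) / z
}

#' b/y fragment ion m/z
#'
#' N-terminal b ions and C-terminal y ions, with residue modifications and
#' heavy-label shifts attributed to the residues they sit on. When
#' `defarnesylated = TRUE` the farnesyl delta is omitted (the O-methyl is
#' retained): this is the species monitored in MS3 scans acquired on a
#' farnesyl neutral-loss precursor.
#'
#' @param p A [modified_peptide()].
#' @param series `"b"` or `"y"`.
#' @param index Fragment index `n`, `1 <= n < length(p)`.
#' @param z Positive integer charge (default 1).
#' @param defarnesylated Compute on the farnesyl-loss species. Only
#'   meaningful when `p` carries a farnesyl group.
#' @param registry Modification registry.
#' @return m/z in Th.
#' @examples
#' ic <- modified_peptide("TVLCGTCGQPADK",
#'   mods = data.frame(position = c(4, 7), name = "carbamidomethyl"))
#' mz_round(fragment_mz(ic, "y", 4))  # 430.2296
#' @export
fragment_mz <- function(p, series = c("b", "y"), index, z = 1L,
                        defarnesylated = FALSE,
                        registry = default_modifications()) {
  series <- match.arg(series)
  stopifnot(inherits(p, "modified_peptide"))
  n <- peptide_length(p)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L || index >= n)
    stop("fragment index must satisfy 1 <= n < ", n,
         " for this peptide (got ", index, ")")
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("charge must be a positive integer")
  if (defarnesylated && !has_farnesyl(p))
    stop("defarnesylated fragment requested for a peptide without farnesyl")
  m <- residue_mass_vector(p, registry, defarnesylated = defarnesylated)
  if (series == "y") {
    (sum(m[(n - index + 1L):n]) + WATER_MASS + z * PROTON_MASS) / z
  } else {
    (sum(m[1:index]) + z * PROTON_MASS) / z
  }
}

#' Neutral-loss m/z
#'
#' m/z of an ion after loss of an uncharged species (farnesyl, water, ...).
#'
#' @param ion_mz m/z of the ion before the loss.
#' @param z Charge of the ion.
#' @param loss Registered loss/modification name, or a numeric delta in Da.
#' @param registry Modification registry.
#' @return `ion_mz - delta / z`.
#' @examples
#' neutral_loss_mz(741.8665, 2, "farnesyl")  # 639.7726
#' @export
neutral_loss_mz <- function(ion_mz, z, loss,
                            registry = default_modifications()) {
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("charge must be a positive integer")
  delta <- if (is.numeric(loss)) loss else mod_delta(loss, registry)
  ion_mz - delta / z
}

#' Attach a heavy-isotope label to a peptide
#'
#' Returns the same peptide carrying `spec`; the precursor m/z shifts by
#' `label_delta(spec) / z`. A zero-count label leaves all masses unchanged.
#'
#' @param p A [modified_peptide()].
#' @param spec A [heavy_label()].
#' @return A labelled `modified_peptide` (symbol suffixed with `*` when a
#'   symbol is set and the label is non-trivial).
#' @export
apply_heavy_label <- function(p, spec) {
  stopifnot(inherits(p, "modified_peptide"), inherits(spec, "heavy_label"))
  if (spec$position > peptide_length(p))
    stop("heavy label position ", spec$position,
         " beyond peptide length ", peptide_length(p))
  symbol <- p$symbol
  if (!is.null(symbol) && label_delta(spec) > 0)
    symbol <- paste0(symbol, "*")
  modified_peptide(p$sequence, mods = p$mods, label = spec, symbol = symbol)
}

#' Round m/z for table display
#'
#' Half-even rounding to 4 decimals, the convention used for printed
#' transition tables. Internal arithmetic stays at full double precision.
#'
#' @param x Numeric m/z value(s).
#' @param digits Decimals (default 4).
#' @export
mz_round <- function(x, digits = 4L) round(x, digits)
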