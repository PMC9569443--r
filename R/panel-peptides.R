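## The published surrogate peptides for the lamin A / progerin assays.
## Cysteines are carbamidomethylated (fixed alkylation) except the
## C-terminal farnesylated + O-methylated Cys of the CAAX-derived peptides.

cam_mods <- function(sequence, skip_cterm_farn = FALSE) {
  res <- strsplit(sequence, "")[[1]]
  pos <- which(res == "C")
  if (skip_cterm_farn) pos <- pos[pos != length(res)]
  if (!length(pos)) return(NULL)
  data.frame(position = pos, name = "carbamidomethyl",
             stringsAsFactors = FALSE)
}

farn_mods <- function(sequence) {
  n <- nchar(sequence)
  rbind(cam_mods(sequence, skip_cterm_farn = TRUE),
        data.frame(position = c(n, n), name = c("farnesyl", "o_methyl"),
                   stringsAsFactors = FALSE))
}

#' Build a panel peptide from a signature sequence
#'
#' Applies the fixed-modification convention of the assays: every Cys is
#' carbamidomethylated except a C-terminal farnesylated Cys, which carries
#' farnesyl + O-methyl instead.
#'
#' @param sequence Peptide sequence.
#' @param cterm_farnesylated Does the C-terminal Cys carry
#'   farnesyl + O-methyl (CAAX-derived peptides)?
#' @param symbol Optional panel symbol.
#' @return A [modified_peptide()].
#' @export
as_panel_peptide <- function(sequence, cterm_farnesylated = FALSE,
                             symbol = NULL) {
  mods <- if (cterm_farnesylated) farn_mods(sequence) else cam_mods(sequence)
  modified_peptide(sequence, mods = mods, symbol = symbol)
}

#' Surrogate peptides of the lamin A / progerin panels
#'
#' The six surrogate peptides used by the targeted assays, as
#' [modified_peptide()] objects:
#' * `IC` -- `TVLCGTCGQPADK`, internal control, common to all lamin A
#'   proteoforms (both Cys carbamidomethylated);
#' * `LA` -- `SVGGSGGGSFGDNLVTR`, prelamin A / mature lamin A signature
#'   (lies inside the progerin deletion);
#' * `pre-LA` -- `SYLLGNSSPR`, unique to farnesylated prelamin A (mouse);
#' * `zFP` -- `SQSSQNC`, farnesylated + O-methylated C-terminal peptide of
#'   mouse farnesylated prelamin A;
#' * `mFP` -- `AAGGAGAQSSQNC`, farnesylated + O-methylated C-terminal
#'   peptide of mouse progerin;
#' * `hFP` -- `ASASGSGAQSPQNC`, farnesylated + O-methylated C-terminal
#'   peptide of human progerin.
#'
#' @return Named list of `modified_peptide` objects.
#' @seealso [panel_heavy_labels()] for the matching isotope labels.
#' @export
panel_peptides <- function() {
  list(
    "IC" = as_panel_peptide("TVLCGTCGQPADK", symbol = "IC"),
    "LA" = as_panel_peptide("SVGGSGGGSFGDNLVTR", symbol = "LA"),
    "pre-LA" = as_panel_peptide("SYLLGNSSPR", symbol = "pre-LA"),
    "zFP" = as_panel_peptide("SQSSQNC", cterm_farnesylated = TRUE,
                             symbol = "zFP"),
    "mFP" = as_panel_peptide("AAGGAGAQSSQNC", cterm_farnesylated = TRUE,
                             symbol = "mFP"),
    "hFP" = as_panel_peptide("ASASGSGAQSPQNC", cterm_farnesylated = TRUE,
                             symbol = "hFP")
  )
}

#' Heavy labels of the absolute-quantification standards
#'
#' Label positions and isotope counts of the synthetic internal standards:
#' IC* carries a fully labelled C-terminal Lys (6x13C + 2x15N), LA* a fully
#' labelled C-terminal Arg (6x13C + 4x15N), and hFP* a labelled N-terminal
#' Ala (3x13C + 1x15N; the farnesylated C-terminus cannot carry the label).
#'
#' @return Named list of [heavy_label()] objects keyed by light symbol.
#' @export
panel_heavy_labels <- function() {
  list(
    "IC" = heavy_label(13, n_13C = 6, n_15N = 2),
    "LA" = heavy_label(17, n_13C = 6, n_15N = 4),
    "hFP" = heavy_label(1, n_13C = 3, n_15N = 1)
  )
}
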