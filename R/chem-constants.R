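#' @keywords internal
"_PACKAGE"

## Monoisotopic constants. Residue masses are the standard amino acid residue
## (i.e. dehydrated) monoisotopic masses; a neutral peptide is the residue sum
## plus one water.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino acid
#' residues (residue = amino acid minus water).
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @export
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic mass constants
#'
#' Proton mass, water mass and the single-atom heavy-isotope mass shifts
#' used throughout the m/z calculus (all in Da).
#'
#' @name mass-constants
#' @export
PROTON_MASS <- 1.007276

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.010565

#' @rdname mass-constants
#' @export
DELTA_13C <- 1.0033548

#' @rdname mass-constants
#' @export
DELTA_15N <- 0.9970349

#' Built-in modification registry
#'
#' The modifications needed for lamin A / progerin surrogate peptides:
#' carbamidomethylation of cysteine (iodoacetamide alkylation, a fixed
#' sample-preparation modification), farnesylation (C15 isoprenoid) and
#' O-methylation (carboxyl methyl ester) of the C-terminal cysteine of
#' CAAX-processed proteoforms, and water (registered as a neutral-loss
#' species).
#'
#' @return A `data.frame` with columns `name`, `target`
#'   (`"C"`, `"cterm-C"` or `"loss"`) and `delta` (monoisotopic Da).
#' @examples
#' default_modifications()
#' @export
default_modifications <- function() {
  data.frame(
    name = c("carbamidomethyl", "o_methyl", "farnesyl", "water"),
    target = c("C", "cterm-C", "cterm-C", "loss"),
    delta = c(57.021464, 14.015650, 204.187801, 18.010565),
    stringsAsFactors = FALSE
  )
}

#' Read or write a modification registry
#'
#' The registry is serialised as YAML: a list of entries with fields
#' `name`, `target` and `delta`. Registry names must be unique and all
#' deltas finite.
#'
#' @param path File path.
#' @param registry A registry `data.frame` as returned by
#'   [default_modifications()].
#' @return `read_modifications()` returns a registry `data.frame`;
#'   `write_modifications()` returns `path` invisibly.
#' @export
read_modifications <- function(path) {
  entries <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(entries, function(e) {
    data.frame(name = as.character(e$name), target = as.character(e$target),
               delta = as.numeric(e$delta), stringsAsFactors = FALSE)
  }))
  validate_registry(reg)
  reg
}

#' @rdname read_modifications
#' @export
write_modifications <- function(registry, path) {
  validate_registry(registry)
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    list(name = registry$name[i], target = registry$target[i],
         delta = registry$delta[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("name", "target", "delta") %in% names(registry)))
  if (anyDuplicated(registry$name))
    stop("modification registry names must be unique")
  if (!all(is.finite(registry$delta)))
    stop("modification delta masses must be finite")
  invisible(registry)
}

mod_delta <- function(name, registry = default_modifications()) {
  i <- match(name, registry$name)
  if (anyNA(i)) stop("unknown modification: ",
                     paste(name[is.na(i)], collapse = ", "))
  registry$delta[i]
}
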