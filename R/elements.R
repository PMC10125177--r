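# Element property tables used throughout the package. All lengths in
# Angstrom internally; nm appears only at analysis/reporting boundaries.

.element_table <- data.frame(
  symbol  = c("H", "C", "N", "O", "F", "Na", "P", "S", "Cl", "Au"),
  # standard atomic weights, amu
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 30.974,
              32.06, 35.45, 196.967),
  # single-bond covalent radii (Cordero), Angstrom
  covalent = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.66, 1.07, 1.05, 1.02, 1.36),
  # Bondi van der Waals radii, Angstrom (Au: common MD value)
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.47, 2.27, 1.80, 1.80, 1.75, 1.66),
  stringsAsFactors = FALSE
)

#' Look up an element property
#'
#' Case-normalizing lookup in the package element table. Unknown elements
#' raise an error naming the offending symbol.
#'
#' @param elements character vector of element symbols (e.g. `"Au"`, `"S"`).
#' @param what one of `"mass"` (amu), `"covalent"` (single-bond covalent
#'   radius, Angstrom) or `"vdw"` (van der Waals radius, Angstrom).
#' @return numeric vector of the requested property.
#' @examples
#' element_property(c("Au", "S"), "mass")
#' @export
element_property <- function(elements, what = c("mass", "covalent", "vdw")) {
  what <- match.arg(what)
  el <- normalize_element(elements)
  idx <- match(el, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(unique(el[is.na(idx)]), collapse = ", "))
  }
  .element_table[[what]][idx]
}

# "AU"/"au" -> "Au"; leaves valid mixed-case symbols alone
normalize_element <- function(elements) {
  el <- trimws(as.character(elements))
  bad <- !nzchar(el)
  if (any(bad)) stop("empty element symbol at position ", which(bad)[1])
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

is_known_element <- function(elements) {
  normalize_element(elements) %in% .element_table$symbol
}

# recognized per-atom component tags for the ligand shell
.components <- c("GOLD_CORE", "OL", "PL", "DL", "ION", "SOLVENT")

check_component <- function(component) {
  bad <- setdiff(unique(component), .components)
  if (length(bad) > 0) {
    stop("unknown component tag(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.components, collapse = ", "), ")")
  }
  component
}
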