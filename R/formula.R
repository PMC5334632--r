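# Elemental formulas and exact monoisotopic mass arithmetic.
#
# Mass convention used throughout the package: the m/z of an ion is the
# monoisotopic mass of the full formula of the charged species (added protons
# counted as plain H atoms) divided by the charge, with no electron-mass
# subtraction. This is the convention under which the diagnostic
# tetrahydropyridinium fragment C6H12N+ sits at m/z 98.0970; the
# electron-corrected value would be 98.0964.

#' Monoisotopic atomic masses known to the package
#'
#' Reads the versioned atomic-mass table shipped under `extdata/`. Only C, H,
#' N and O are defined; 3-APA chemistry does not require more.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
element_masses <- function() {
  cached <- get0("element_masses", envir = .apa_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "atomic_masses.tsv", package = "apascreen",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- stats::setNames(tab$monoisotopic_mass, tab$element)
  assign("element_masses", m, envir = .apa_cache)
  m
}

new_elemental_formula <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts)) stop("formula must contain at least one atom")
  if (any(counts != round(counts)) || any(counts < 0))
    stop("element counts must be non-negative integers")
  syms <- names(counts)
  known <- names(element_masses())
  bad <- setdiff(syms, known)
  if (length(bad))
    stop("unknown element symbol: ", paste(bad, collapse = ", "))
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  out <- as.integer(counts[hill])
  names(out) <- hill
  class(out) <- "elemental_formula"
  out
}

#' Parse a molecular formula string
#'
#' Accepts the usual element-count grammar over C, H, N, O
#' (e.g. `"C30H48N2"`). Underscores and spaces, as they appear in
#' subscript-mangled text, are stripped before parsing.
#'
#' @param text A single formula string.
#' @return An `elemental_formula`: a named integer vector of element counts
#'   in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C6H12N")
#' monoisotopic_mass(parse_formula("C30H48N2"))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  clean <- gsub("[_ ]", "", text)
  if (!nzchar(clean)) stop("empty formula string")
  toks <- regmatches(clean, gregexpr("[A-Z][a-z]?[0-9]*", clean))[[1]]
  if (sum(nchar(toks)) != nchar(clean))
    stop("cannot parse formula: '", text, "'")
  els <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Za-z]+", "", toks)
  counts <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  known <- names(element_masses())
  bad <- setdiff(unique(els), known)
  if (length(bad))
    stop("unknown element symbol: ", paste(bad, collapse = ", "))
  agg <- tapply(counts, els, sum)
  new_elemental_formula(stats::setNames(as.integer(agg), names(agg)))
}

#' Serialize a formula to its canonical (Hill order) string
#'
#' @param f An `elemental_formula` or formula string.
#' @return Canonical formula string; `parse_formula()` round-trips it.
#' @export
serialize_formula <- function(f) {
  f <- as_formula(f)
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
format.elemental_formula <- function(x, ...) serialize_formula(x)

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", serialize_formula(x), "\n")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) return(new_elemental_formula(f))
  stop("cannot interpret object as an elemental formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times monoisotopic atomic mass
#' (C = 12 exactly, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221).
#'
#' @param f An `elemental_formula`, a named count vector, or a formula string.
#' @return Mass in Da (full precision; round for display).
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(element_masses()[names(f)] * unclass(f))
}

#' Add protons to a formula
#'
#' Realizes the `[M + kH]^k+` bookkeeping: protons are counted as H atoms.
#'
#' @param f Formula (any form accepted by [monoisotopic_mass()]).
#' @param k Number of protons to add (non-negative integer).
#' @return The formula with its H count increased by `k`.
#' @export
add_protons <- function(f, k) {
  f <- as_formula(f)
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 0)
    stop("k must be a single non-negative integer")
  counts <- stats::setNames(as.numeric(f), names(f))
  counts["H"] <- (if ("H" %in% names(counts)) counts["H"] else 0) + k
  new_elemental_formula(counts)
}

#' m/z of a charged species
#'
#' The full formula of the charged species (protons already included as H
#' atoms, see [add_protons()]) divided by the charge. No electron-mass
#' correction is applied.
#'
#' @param ion_formula Formula of the intact charged species.
#' @param charge Positive integer charge.
#' @return m/z in Da per charge unit.
#' @examples
#' ion_mz(parse_formula("C30H48N2"), 2) # natively doubly charged macrocycle
#' @export
ion_mz <- function(ion_formula, charge) {
  if (length(charge) != 1L || is.na(charge) || charge != round(charge) ||
      charge < 1)
    stop("charge must be a positive integer")
  monoisotopic_mass(ion_formula) / charge
}
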