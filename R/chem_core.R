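# Elemental-formula engine: parsing, Hill canonicalization, monoisotopic mass,
# adduct m/z arithmetic. All downstream mass windows rest on these constants.

.msmatch_env <- new.env(parent = emptyenv())

#' Mass of a proton in Da
#'
#' Used for `[M+H]+` / `[M-H]-` adduct arithmetic. The electron mass is
#' included, i.e. this is the mass of H+ (1.007276466 Da), not of the hydrogen
#' atom.
#'
#' @return A single numeric value in Da.
#' @export
proton_mass <- function() 1.007276466

#' Monoisotopic isotope mass table
#'
#' Named numeric vector mapping element symbols to the mass in Da of their
#' most abundant isotope. Shipped as a plain-text key-value file
#' (`extdata/monoisotopic_masses.tsv`); loaded once and treated as immutable.
#'
#' @return Named numeric vector of masses in Da.
#' @examples
#' isotope_masses()[["C"]]  # exactly 12 by definition
#' @export
isotope_masses <- function() {
  if (is.null(.msmatch_env$isotopes)) {
    path <- system.file("extdata", "monoisotopic_masses.tsv",
                        package = "msmatch", mustWork = TRUE)
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", col.names = c("element", "mass"),
                             colClasses = c("character", "numeric"))
    masses <- stats::setNames(tab$mass, tab$element)
    stopifnot(masses[["C"]] == 12, all(masses > 0))
    .msmatch_env$isotopes <- masses
  }
  .msmatch_env$isotopes
}

#' Parse an elemental formula string
#'
#' Parses a molecular formula such as `"C8H10N4O2"` into an element->count
#' multiset. Internal whitespace is tolerated (metadata tables sometimes print
#' `"C12 H12N4O3S"`). Charges, isotope labels and any other decoration are
#' rejected: formulae of permanently charged species are not valid input.
#'
#' @param text Formula string. Tokens are `Element[count]`; a missing count
#'   means 1. No implicit hydrogens are added.
#' @return An `elemental_formula`: a named integer vector of counts in Hill
#'   order (C first, then H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C8H10N4O2")
#' parse_formula("C12 H12N4O3S")
#' @seealso [hill_string()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  stripped <- gsub("[[:space:]]+", "", text)
  if (!nzchar(stripped))
    stop("empty formula string")
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", stripped, perl = TRUE)[[1]]
  matched <- regmatches(stripped, gregexpr("([A-Z][a-z]?)([0-9]*)", stripped, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(stripped))
    stop("formula '", text, "' contains unparseable characters ",
         "(charges and isotope labels are not supported)")
  syms <- sub("[0-9]*$", "", matched)
  cnts <- sub("^[A-Za-z]+", "", matched)
  counts <- ifelse(nzchar(cnts), suppressWarnings(as.integer(cnts)), 1L)
  known <- names(isotope_masses())
  bad <- setdiff(syms, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  if (any(is.na(counts) | counts <= 0L))
    stop("element counts must be positive integers in '", text, "'")
  # merge repeated symbols (e.g. "CH3CH3") into one multiset
  merged <- tapply(counts, syms, sum)
  f <- stats::setNames(as.integer(merged), names(merged))
  new_elemental_formula(f)
}

new_elemental_formula <- function(counts) {
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "elemental_formula")
}

hill_order <- function(symbols) {
  # Hill convention: C first, H second (when C present), rest alphabetical.
  # Without carbon the order is purely alphabetical.
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    order(match(symbols, c("C", "H", rest)))
  } else {
    order(symbols)
  }
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' Canonical Hill-notation string of a formula
#'
#' @param f An `elemental_formula` or a formula string.
#' @return Canonical formula string: carbon first, hydrogen second, remaining
#'   symbols alphabetical; counts of 1 omitted. `parse_formula(hill_string(f))`
#'   recovers `f` exactly.
#' @examples
#' hill_string(parse_formula("H2O1"))   # "H2O"
#' hill_string("C12 H12N4O3S")          # "C12H12N4O3S"
#' @export
hill_string <- function(f) {
  f <- as_formula(f)
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", hill_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) hill_string(x)

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass. Matches
#' the "MS-Ready Monoisotopic Mass" convention of chemistry-dashboard metadata
#' exports at their printed precision (5-6 decimal places).
#'
#' @param f An `elemental_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C8H10N4O2")  # caffeine, 194.08038
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  masses <- isotope_masses()
  missing <- setdiff(names(f), names(masses))
  if (length(missing))
    stop("no isotope mass for element(s): ", paste(missing, collapse = ", "))
  sum(unclass(f) * masses[names(f)])
}

#' Adduct m/z for a neutral mass
#'
#' Shifts a neutral monoisotopic mass to the m/z of a singly charged adduct.
#' Supported forms: `"[M+H]+"` (adds one proton mass), `"[M-H]-"` (subtracts
#' it) and `"M"` (identity, for neutral-mass or EI workflows).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct label.
#' @return m/z in Da.
#' @examples
#' adduct_mz(194.08038, "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct = c("M", "[M+H]+", "[M-H]-")) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L || neutral_mass <= 0)
    stop("neutral_mass must be a single positive number")
  supported <- c("M", "[M+H]+", "[M-H]-")
  if (!is.character(adduct) || length(adduct) != 1L || !adduct %in% supported)
    stop("unknown adduct label; supported: ", paste(supported, collapse = ", "))
  switch(adduct,
         "M"      = neutral_mass,
         "[M+H]+" = neutral_mass + proton_mass(),
         "[M-H]-" = neutral_mass - proton_mass())
}

#' ppm mass error between two masses
#'
#' Relative error in parts per million with the *query* mass as denominator —
#' the convention used throughout the package for search windows.
#'
#' @param observed Candidate mass(es) in Da.
#' @param query Query mass in Da.
#' @return Signed ppm error(s): `(observed - query) / query * 1e6`.
#' @export
ppm_error <- function(observed, query) (observed - query) / query * 1e6
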