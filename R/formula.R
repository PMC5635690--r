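# Monoisotopic element masses (Da), CODATA/IUPAC values.
.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass constants used throughout the package
#'
#' Monoisotopic element masses (Da), the proton mass (the difference between
#' a protonated ion's m/z and its neutral monoisotopic mass, electron
#' included), and the monoisotopic mass of water.
#'
#' @return A named list with components `elements` (named numeric vector),
#'   `proton` and `water`.
#' @export
#' @examples
#' mass_constants()$water   # 18.0105646
mass_constants <- function() {
  list(
    elements = .element_masses,
    proton = 1.00727646,
    water = 2 * .element_masses[["H"]] + .element_masses[["O"]]
  )
}

.proton_mass <- 1.00727646

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of non-negative element
#' counts, carrying class `"elemental_formula"`. Zero counts are dropped;
#' elements are kept in Hill order (C, H, then alphabetical).
#'
#' @param ... Named integer counts, e.g. `ef(C = 7, H = 6, O = 4)`, or a
#'   single named numeric vector.
#' @return An `elemental_formula` object.
#' @export
#' @examples
#' ef(C = 7, H = 6, O = 4)
ef <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) counts <- numeric(0)
  if (length(counts) > 0L && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("element counts must be named")
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- tapply(counts, names(counts), sum)
  counts <- counts[counts > 0]
  structure(as.double(counts[.hill_order(names(counts))]),
            names = .hill_order(names(counts)),
            class = "elemental_formula")
}

.hill_order <- function(els) {
  if (length(els) == 0L) return(character(0))
  rest <- sort(setdiff(els, c("C", "H")))
  c(intersect(c("C", "H"), els), rest)
}

#' Parse a Hill-notation formula string
#'
#' @param text A formula string such as `"C7H6O4"`. Element symbols must be
#'   known to [mass_constants()].
#' @return An [ef()] object.
#' @export
#' @examples
#' parse_formula("C10H11NO6")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  s <- gsub("[[:space:]]", "", text)
  if (s == "") return(ef())
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(s))
    stop(sprintf("malformed formula string: %s (unparseable near '%s')",
                 text, substr(s, nchar(paste(toks, collapse = "")) + 1L,
                              nchar(s))))
  els <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Z][a-z]?", "", toks)
  ns <- ifelse(ns == "", 1L, suppressWarnings(as.integer(ns)))
  bad <- setdiff(els, names(.element_masses))
  if (length(bad) > 0L)
    stop(sprintf("unknown element symbol(s) in '%s': %s",
                 text, paste(bad, collapse = ", ")))
  ef(stats::setNames(ns, els))
}

#' Format an elemental formula as a Hill string
#'
#' @param f An [ef()] object.
#' @return A character scalar, e.g. `"C7H6O4"`; the empty formula formats
#'   as `""`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(unclass(f) == 1, "", as.integer(f)), collapse = "")
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (", sprintf("%.4f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  ef(stats::setNames(
    vapply(els, function(el) .count(e1, el) + .count(e2, el), 0), els))
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  res <- vapply(els, function(el) .count(e1, el) - .count(e2, el), 0)
  if (any(res < 0))
    stop(sprintf("formula subtraction yields negative count for %s",
                 paste(els[res < 0], collapse = ", ")))
  ef(stats::setNames(res, els))
}

#' @export
`*.elemental_formula` <- function(e1, e2) {
  if (is.numeric(e1)) { n <- e1; f <- e2 } else { n <- e2; f <- e1 }
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  ef(stats::setNames(unclass(f) * n, names(f)))
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(format_formula(e1), format_formula(e2))
}

.count <- function(f, el) if (el %in% names(f)) unclass(f)[[el]] else 0

#' Monoisotopic mass of a formula
#'
#' Plain sum of monoisotopic element masses; this is also the m/z convention
#' used for predicted fragment ions (no electron or proton correction), which
#' reproduces the published fragment tables for this pathway.
#'
#' @param f An [ef()] object or a formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C7H6O4")  # 154.0266 (2,3-dihydroxybenzoic acid)
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"))
  if (length(f) == 0L) return(0)
  bad <- setdiff(names(f), names(.element_masses))
  if (length(bad) > 0L)
    stop(sprintf("no mass entry for element(s): %s", paste(bad, collapse = ", ")))
  sum(unclass(f) * .element_masses[names(f)])
}

#' Protonated-ion m/z
#'
#' `[M+H]+` m/z of a neutral species: neutral mass plus the proton mass
#' (1.00727646 Da, electron accounted for).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (or an [ef()] object /
#'   formula string, whose mass is computed first).
#' @return m/z in Da.
#' @export
#' @examples
#' protonated_mz(monoisotopic_mass("C10H14N2O3"))  # 211.1077
protonated_mz <- function(neutral_mass) {
  if (inherits(neutral_mass, "elemental_formula") || is.character(neutral_mass))
    neutral_mass <- monoisotopic_mass(neutral_mass)
  if (!is.numeric(neutral_mass) || any(neutral_mass < 0))
    stop("neutral_mass must be non-negative")
  neutral_mass + .proton_mass
}

#' Condense two formulas with loss of water
#'
#' Amide/ester bond formation bookkeeping: returns `a + b - n_waters * H2O`.
#'
#' @param a,b [ef()] objects or formula strings.
#' @param n_waters Number of waters lost (non-negative integer).
#' @return An [ef()] object.
#' @export
#' @examples
#' condense("C7H6O4", "C3H10N2", 1)  # DHB + diaminopropane -> C10H14N2O3
condense <- function(a, b, n_waters = 1L) {
  if (is.character(a)) a <- parse_formula(a)
  if (is.character(b)) b <- parse_formula(b)
  stopifnot(n_waters >= 0, n_waters == round(n_waters))
  res <- tryCatch(a + b - n_waters * ef(H = 2, O = 1),
                  error = function(e) stop(
                    "infeasible condensation: not enough H/O to lose ",
                    n_waters, " water(s)", call. = FALSE))
  res
}

#' Round half to even at the display precision used for printed masses
#'
#' @param x Numeric.
#' @param digits Decimal places (default 4, the print precision of the
#'   reference tables).
#' @return Rounded numeric (base R `round`, which rounds half to even).
#' @export
display_mass <- function(x, digits = 4L) round(x, digits)
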