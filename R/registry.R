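#' Pathway building blocks
#'
#' The three fixed building blocks of the engineered pathway: the catechol
#' aryl acid 2,3-dihydroxybenzoic acid (DHB) and the two amino acids the
#' condensation enzyme can activate, L-serine and L-threonine.
#'
#' @param name One of `"DHB"`, `"Ser"`, `"Thr"`; omit for the full list.
#' @return A list with `name`, `formula` ([ef()]) and `role`, or a named list
#'   of all three.
#' @export
#' @examples
#' building_block("DHB")$formula  # C7H6O4
building_block <- function(name) {
  blocks <- list(
    DHB = list(name = "DHB", formula = parse_formula("C7H6O4"),
               role = "aryl-acid"),
    Ser = list(name = "Ser", formula = parse_formula("C3H7NO3"),
               role = "amino-acid"),
    Thr = list(name = "Thr", formula = parse_formula("C4H9NO3"),
               role = "amino-acid")
  )
  if (missing(name)) return(blocks)
  if (!name %in% names(blocks))
    stop("unknown building block: ", name)
  blocks[[name]]
}

#' Read a precursor registry
#'
#' The registry is tab-separated text with a header and columns
#' `id`, `name`, `formula`, `n_primary_amines`, `n_secondary_amines`,
#' `concentration`, plus two package extensions: `backbone` (a linear-chain
#' descriptor used by the fragment predictor; empty when no simple linear
#' model applies) and `validated` (`yes` when the derived formula is
#' cross-checked against a published product mass, `no` otherwise).
#'
#' @param path Path to a registry TSV; defaults to the registry shipped with
#'   the package, which mirrors the 25 precursors fed in the source study.
#' @return A data.frame of class `precursor_registry`.
#' @export
#' @examples
#' reg <- read_precursor_registry()
#' subset(reg, id == 5)$name   # putrescine
read_precursor_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "precursor_registry.tsv",
                        package = "mutasynth", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = TRUE)
  required <- c("id", "name", "formula", "n_primary_amines",
                "n_secondary_amines", "concentration")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"backbone" %in% names(df)) df$backbone <- character(nrow(df))
  if (!"validated" %in% names(df)) df$validated <- rep("no", nrow(df))
  df$id <- as.integer(df$id)
  df$n_primary_amines <- as.integer(df$n_primary_amines)
  df$n_secondary_amines <- as.integer(df$n_secondary_amines)
  if (anyNA(df$id) || anyNA(df$n_primary_amines) || anyNA(df$n_secondary_amines))
    stop("registry has non-integer id or amine counts")
  if (any(df$n_primary_amines < 0) || any(df$n_secondary_amines < 0))
    stop("amine counts must be non-negative")
  # validate formulas row by row so the error names the offending row
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_formula(df$formula[i]), error = function(e)
      stop(sprintf("registry row %d (%s): %s", i, df$name[i],
                   conditionMessage(e)), call. = FALSE))
  }
  df$backbone[is.na(df$backbone)] <- ""
  class(df) <- c("precursor_registry", "data.frame")
  df
}

#' Retrieve one precursor from a registry
#'
#' @param registry A `precursor_registry` (default: shipped registry).
#' @param id Integer registry id.
#' @return A one-row list with a parsed `formula`.
#' @export
precursor <- function(id, registry = read_precursor_registry()) {
  row <- registry[registry$id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("no unique precursor with id ", id)
  out <- as.list(row)
  out$formula <- parse_formula(row$formula)
  out
}
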