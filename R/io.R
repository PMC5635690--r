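# Format plumbing: MGF (Mascot generic format) peak lists, delimited
# spectra, candidate tables, and the JSON pipeline configuration.

#' Read spectra from a Mascot generic format (MGF) file
#'
#' `TITLE` is used as the sample label, `PEPMASS` as the precursor m/z;
#' peak lines contribute fragment m/z values (intensities, if present, are
#' kept).
#'
#' @param path Path to an MGF file.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_
      mz <- numeric(0); inten <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1])
        } else if (grepl("^[0-9]", ln)) {
          parts <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          mz <- c(mz, parts[1])
          inten <- c(inten, if (length(parts) > 1L) parts[2] else NA_real_)
        }
        i <- i + 1L
      }
      if (is.na(pepmass)) stop("MGF block without PEPMASS in ", path)
      out[[length(out) + 1L]] <-
        spectrum(pepmass, mz, sample = title,
                 intensities = if (all(is.na(inten))) NULL else inten)
    }
    i <- i + 1L
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(s$sample)) writeLines(paste0("TITLE=", s$sample), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (length(s$fragments) > 0L) {
      if (!is.null(s$intensities))
        writeLines(sprintf("%.6f %.4f", s$fragments, s$intensities), con)
      else
        writeLines(sprintf("%.6f", s$fragments), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from delimited text
#'
#' Tab-separated with header `sample`, `precursor_mz`, `fragment_mz`; the
#' fragment column is a `;`-separated list (may be empty).
#'
#' @param path File path.
#' @return List of [spectrum()] objects.
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop("cannot read spectra table: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample", "precursor_mz", "fragment_mz")
  if (!all(need %in% names(df)))
    stop("spectra table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    fr <- df$fragment_mz[i]
    fmz <- if (is.na(fr) || !nzchar(fr)) numeric(0)
           else as.numeric(strsplit(fr, ";", fixed = TRUE)[[1]])
    smp <- df$sample[i]
    spectrum(as.numeric(df$precursor_mz[i]), fmz,
             sample = if (nzchar(smp)) smp else NA_character_)
  })
}

#' Write a candidate table
#'
#' @param products List of `assembled_product`s.
#' @param path Output TSV path; a sibling `.json` with full provenance is
#'   written alongside when `json = TRUE`.
#' @param json Also write JSON (default TRUE).
#' @return `path`, invisibly.
#' @export
write_candidates <- function(products, path, json = TRUE) {
  tab <- candidate_table(products)
  tab$neutral_mass <- sprintf("%.6f", tab$neutral_mass)
  tab$mz <- sprintf("%.6f", tab$mz)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    jpath <- sub("\\.tsv$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(candidate_table(products), jpath, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path TSV path.
#' @return data.frame with numeric mass columns.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$neutral_mass <- as.numeric(df$neutral_mass)
  df$mz <- as.numeric(df$mz)
  df
}

.default_config <- function() {
  list(
    registry = NULL,                 # NULL -> shipped registry
    caps = c("Tc", "To", "Sc", "So"),
    tolerance_ppm = 10,
    secondary_amines = TRUE,
    ent_max_n = 3L,
    ent_cyclic = TRUE,
    out_dir = ".",
    seed = 1L,
    log_level = "info"
  )
}

#' Read / write the pipeline configuration
#'
#' The configuration is a flat JSON object; unknown keys are rejected so
#' typos fail loudly. Omitted keys take their defaults.
#'
#' @param path JSON file path.
#' @return For `read_pipeline_config`: the full config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- .default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  out$ent_max_n <- as.integer(out$ent_max_n)
  out$seed <- as.integer(out$seed)
  out
}

#' @rdname read_pipeline_config
#' @param config A config list (missing keys filled with defaults).
#' @export
write_pipeline_config <- function(config, path) {
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  jsonlite::write_json(utils::modifyList(defaults, config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Reference dataset: published product masses and fragments
#'
#' The published characterization of the engineered pathway's products: one
#' row per molecule with its calculated and observed `[M+H]+` exact mass
#' and the fed-precursor sample label (`products`), and one row per printed
#' calculated/observed fragment pair (`fragments`).
#'
#' `"known_unmatched"` returns the frozen list of printed calculated
#' fragment values that the depth-1 rule set does not reproduce (with the
#' reason per entry); the test suite asserts this list stays exact.
#'
#' @param which `"products"`, `"fragments"` or `"known_unmatched"`.
#' @return data.frame.
#' @export
reference_dataset <- function(which = c("products", "fragments",
                                        "known_unmatched")) {
  which <- match.arg(which)
  fn <- c(products = "reference_products.tsv",
          fragments = "reference_fragments.tsv",
          known_unmatched = "known_unmatched_fragments.tsv")[[which]]
  utils::read.delim(system.file("extdata", fn, package = "mutasynth",
                                mustWork = TRUE),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reference spectra: the published observed masses as a spectrum list
#'
#' Turns the reference dataset into [spectrum()] objects (observed
#' precursor mass plus the row's observed fragment m/z values), labelled
#' with the fed precursor id.
#'
#' @param labelled Keep sample labels (default TRUE); `FALSE` withholds
#'   them, which leaves isobaric candidates tied.
#' @return List of [spectrum()] objects, one per reference molecule.
#' @export
reference_spectra <- function(labelled = TRUE) {
  prod <- reference_dataset("products")
  frag <- reference_dataset("fragments")
  lapply(seq_len(nrow(prod)), function(i) {
    fr <- frag$obs_mz[frag$molecule == prod$molecule[i]]
    # the published table lists one fragment above its own precursor mass
    # (it belongs to the co-eluting capped analog); such peaks cannot live
    # in this spectrum and are dropped
    fr <- fr[fr < prod$obs_mz[i] + 1.0]
    lab <- prod$sample[i]
    spectrum(prod$obs_mz[i], fr,
             sample = if (labelled && nzchar(lab)) lab else NA_character_)
  })
}
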