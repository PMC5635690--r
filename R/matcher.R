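#' Construct an observed spectrum
#'
#' One observed precursor m/z with its fragment peak list. The sample label
#' records which precursor was fed to the culture the spectrum came from
#' (one precursor per culture); `NA` means unlabelled.
#'
#' @param precursor_mz Observed precursor m/z (> 0).
#' @param fragments Numeric vector of fragment m/z values (each must be
#'   below `precursor_mz + 1`).
#' @param sample Sample label (character or NA).
#' @param intensities Optional fragment intensities.
#' @return A list of class `ms_spectrum`.
#' @export
spectrum <- function(precursor_mz, fragments = numeric(0), sample = NA_character_,
                     intensities = NULL) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number")
  fragments <- as.numeric(fragments)
  if (any(fragments >= precursor_mz + 1.0))
    stop("fragment m/z must be below precursor m/z + 1")
  if (!is.null(intensities) && length(intensities) != length(fragments))
    stop("intensities must match fragments in length")
  structure(list(sample = as.character(sample), precursor_mz = precursor_mz,
                 fragments = fragments, intensities = intensities),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> sample=%s precursor=%.4f (%d fragments)\n",
              x$sample, x$precursor_mz, length(x$fragments)))
  invisible(x)
}

#' Annotate observed spectra against a candidate set
#'
#' A spectrum matches a candidate when the relative precursor error
#' `|obs - calc| / calc * 1e6` is at most `tol_ppm`. All matching candidates
#' are reported; candidates sharing the matched formula mass (within 1e-6
#' Da) are isobaric co-candidates and are listed together, never silently
#' dropped. When `use_labels = TRUE` and a spectrum carries a sample label,
#' precursor-derived candidates are restricted to the fed precursor
#' (one-precursor-per-culture design); unlabelled spectra and
#' precursor-free candidates (the enterobactin series) are unaffected.
#'
#' @param spectra List of [spectrum()] objects.
#' @param candidates List of `assembled_product`s.
#' @param tol_ppm Precursor tolerance in ppm (> 0), default 10.
#' @param use_labels Disambiguate isobars by sample label (default TRUE).
#' @param with_fragments Also score fragment coverage via
#'   [fragment_coverage()] for each match (default TRUE when any spectrum
#'   has fragment peaks).
#' @return data.frame of class `match_results`: one row per
#'   (spectrum, candidate) pair with ppm error, fragment coverage, and the
#'   isobaric co-candidate ids. Sorted by sample, then |ppm|.
#' @export
match_spectra <- function(spectra, candidates, tol_ppm = 10,
                          use_labels = TRUE, with_fragments = NULL) {
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  if (is.null(with_fragments))
    with_fragments <- any(vapply(spectra, function(s) length(s$fragments) > 0L,
                                 TRUE))
  cand_mz <- vapply(candidates, `[[`, 0, "mz")
  cand_id <- vapply(candidates, `[[`, "", "id")
  cand_prec <- vapply(candidates, `[[`, NA_integer_, "precursor_id")
  frag_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (si in seq_along(spectra)) {
    s <- spectra[[si]]
    ppm <- (s$precursor_mz - cand_mz) / cand_mz * 1e6
    hit <- abs(ppm) <= tol_ppm
    if (use_labels && !is.na(s$sample) && nzchar(s$sample)) {
      labelled <- !is.na(cand_prec)
      hit <- hit & (!labelled | as.character(cand_prec) == s$sample)
    }
    idx <- which(hit)
    if (length(idx) == 0L) next
    # isobar groups among the hits (same candidate mz within 1e-6 Da)
    for (j in idx) {
      iso <- idx[abs(cand_mz[idx] - cand_mz[j]) <= 1e-6]
      cov <- NA_real_
      if (with_fragments && length(s$fragments) > 0L) {
        key <- cand_id[j]
        if (is.null(frag_cache[[key]]))
          frag_cache[[key]] <- predict_fragments(candidates[[j]])
        cov <- fragment_coverage(frag_cache[[key]], s$fragments,
                                 tol_ppm)$coverage
      }
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum = si,
        sample = s$sample,
        precursor_mz = s$precursor_mz,
        candidate_id = cand_id[j],
        candidate_mz = cand_mz[j],
        ppm_error = ppm[j],
        fragment_coverage = cov,
        n_isobars = length(iso),
        isobar_ids = paste(sort(cand_id[iso]), collapse = ";"),
        precursor_id = cand_prec[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    res <- data.frame(spectrum = integer(0), sample = character(0),
                      precursor_mz = numeric(0), candidate_id = character(0),
                      candidate_mz = numeric(0), ppm_error = numeric(0),
                      fragment_coverage = numeric(0), n_isobars = integer(0),
                      isobar_ids = character(0), precursor_id = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
    res <- res[order(res$sample, abs(res$ppm_error), res$candidate_id), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("match_results", "data.frame")
  res
}

#' Summarize incorporation per precursor
#'
#' Reconstructs the partial/full incorporation matrix: a precursor scores
#' `partial = "yes"` when some DHB intermediate derived from it matched a
#' spectrum and `full = "yes"` when some capped analog matched; otherwise
#' `"nd"` (not detected). Optionally a minimum fragment coverage can be
#' required for a match to count as evidence.
#'
#' @param results A `match_results` data.frame from [match_spectra()].
#' @param registry A `precursor_registry`.
#' @param min_fragment_coverage Optional threshold in `[0,1]`; matches with
#'   known coverage below it are discarded (`NA` coverage, i.e. no fragment
#'   data, always passes).
#' @return data.frame of class `incorporation_report` with columns `id`,
#'   `name`, `partial`, `full`, `n_support`.
#' @export
summarize_incorporation <- function(results, registry = read_precursor_registry(),
                                    min_fragment_coverage = NULL) {
  if (!is.null(min_fragment_coverage)) {
    keep <- is.na(results$fragment_coverage) |
      results$fragment_coverage >= min_fragment_coverage
    results <- results[keep, , drop = FALSE]
  }
  is_full <- grepl("(Tc|To|Sc|So)$", results$candidate_id)
  out <- data.frame(
    id = sort(unique(registry$id)),
    stringsAsFactors = FALSE
  )
  out$name <- registry$name[match(out$id, registry$id)]
  out$partial <- vapply(out$id, function(i)
    if (any(!is.na(results$precursor_id) & results$precursor_id == i & !is_full))
      "yes" else "nd", "")
  out$full <- vapply(out$id, function(i)
    if (any(!is.na(results$precursor_id) & results$precursor_id == i & is_full))
      "yes" else "nd", "")
  out$n_support <- vapply(out$id, function(i)
    sum(!is.na(results$precursor_id) & results$precursor_id == i), 0L)
  class(out) <- c("incorporation_report", "data.frame")
  out
}
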