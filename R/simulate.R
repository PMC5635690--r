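# Seeded simulators for accurate-mass peak lists and OD growth curves.
# They emulate the statistical structure the analysis assumes: Orbitrap-style
# normally distributed ppm mass error with uniform decoy peaks, and
# exponential/logistic growth with lag and additive normal noise.

#' Simulate accurate-mass spectra for a set of compounds
#'
#' Each spiked compound yields one spectrum whose precursor m/z is the
#' calculated value perturbed by `calc * (1 + eps/1e6)` with
#' `eps ~ Normal(0, mass_error_ppm)`; predicted fragments are included the
#' same way subject to a per-peak dropout probability, and uniform decoy
#' peaks are added, avoiding a +/- 3 sd window around every true m/z so the
#' ground truth stays unambiguous. Spectra carry the compound's precursor
#' registry id as sample label (or NA for precursor-free compounds).
#'
#' @param compounds List of `assembled_product`s to spike.
#' @param mass_error_ppm Mass error standard deviation in ppm (>= 0).
#' @param n_decoys Decoy peaks added per spectrum.
#' @param decoy_range m/z range for decoys, default `c(70, 800)`.
#' @param dropout Per-fragment dropout probability in `[0, 1]`.
#' @param seed Integer seed; fully determines the output.
#' @param labelled Attach sample labels (default TRUE).
#' @return List with `spectra` (list of [spectrum()]) and `truth`
#'   (data.frame: spectrum index, compound id, true precursor m/z).
#' @export
simulate_spectra <- function(compounds, mass_error_ppm = 2, n_decoys = 0L,
                             decoy_range = c(70, 800), dropout = 0,
                             seed = 1L, labelled = TRUE) {
  if (length(compounds) == 0L && n_decoys == 0L)
    stop("nothing to emit: no compounds and no decoys")
  stopifnot(mass_error_ppm >= 0, dropout >= 0, dropout <= 1,
            length(decoy_range) == 2L, decoy_range[1] < decoy_range[2])
  set.seed(as.integer(seed))
  perturb <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, mass_error_ppm) / 1e6)
  spectra <- list()
  truth <- list()
  for (i in seq_along(compounds)) {
    p <- compounds[[i]]
    prec_obs <- perturb(p$mz)
    fr <- predict_fragments(p)
    fmz <- fr$mz[fr$mz < p$mz]         # intact ion is the precursor itself
    if (dropout > 0 && length(fmz) > 0L)
      fmz <- fmz[stats::runif(length(fmz)) >= dropout]
    fobs <- if (length(fmz) > 0L) perturb(fmz) else numeric(0)
    true_mz <- c(p$mz, fmz)
    if (n_decoys > 0L) {
      decoys <- .draw_decoys(n_decoys, decoy_range, true_mz,
                             pmax(mass_error_ppm, 1))
      fobs <- sort(c(fobs, decoys[decoys < prec_obs + 1.0]))
    }
    label <- if (labelled && !is.na(p$precursor_id))
      as.character(p$precursor_id) else NA_character_
    spectra[[i]] <- spectrum(prec_obs, fobs, sample = label)
    truth[[i]] <- data.frame(spectrum = i, compound_id = p$id,
                             true_mz = p$mz, stringsAsFactors = FALSE)
  }
  list(spectra = spectra,
       truth = if (length(truth) > 0L) do.call(rbind, truth)
               else data.frame(spectrum = integer(0), compound_id = character(0),
                               true_mz = numeric(0)))
}

# uniform decoys avoiding +/- 3 sd ppm windows around the true masses
.draw_decoys <- function(n, range, true_mz, sd_ppm) {
  out <- numeric(0)
  guard <- 3 * sd_ppm / 1e6
  tries <- 0L
  while (length(out) < n && tries < 1000L) {
    cand <- stats::runif(n - length(out), range[1], range[2])
    ok <- vapply(cand, function(x)
      all(abs(x - true_mz) > guard * true_mz), TRUE)
    out <- c(out, cand[ok])
    tries <- tries + 1L
  }
  out
}

#' Simulate replicated growth curves
#'
#' Logistic: `OD(t) = K / (1 + (K/OD0 - 1) exp(-r (t - lag)))` for
#' `t >= lag`, `OD0` before the lag ends. Exponential:
#' `OD0 * exp(r * max(t - lag, 0))`. Additive `Normal(0, noise_sd)` noise,
#' truncated at a small positive floor so log transforms stay defined.
#'
#' @param model `"logistic"` or `"exponential"`.
#' @param r True specific growth rate (per hour, > 0).
#' @param od0 Initial OD (> 0).
#' @param K Carrying capacity (logistic only; must exceed `od0`).
#' @param lag Lag time in hours (>= 0).
#' @param noise_sd Additive noise standard deviation.
#' @param times Sampling times (hours).
#' @param replicates Number of replicate curves.
#' @param condition Condition label.
#' @param seed Integer seed; fully determines the output.
#' @return List with `curves` (list of [growth_curve()]) and `truth`
#'   (data.frame: condition, replicate, r).
#' @export
simulate_growth <- function(model = c("logistic", "exponential"), r = 0.3,
                            od0 = 0.05, K = 2.0, lag = 0, noise_sd = 0.005,
                            times = seq(0, 24, by = 0.5), replicates = 3L,
                            condition = model[1], seed = 1L) {
  if (length(model) != 1L || !model %in% c("logistic", "exponential"))
    model <- tryCatch(match.arg(model),
                      error = function(e) stop("invalid model name: ",
                                               paste(model, collapse = "/")))
  stopifnot(r > 0, od0 > 0, noise_sd >= 0, lag >= 0, replicates >= 1L)
  if (model == "logistic" && K <= od0)
    stop("logistic model requires carrying capacity K > initial OD")
  set.seed(as.integer(seed))
  mean_od <- switch(model,
    logistic = ifelse(times < lag, od0,
                      K / (1 + (K / od0 - 1) * exp(-r * (times - lag)))),
    exponential = od0 * exp(r * pmax(times - lag, 0)))
  curves <- lapply(seq_len(replicates), function(rep) {
    od <- mean_od + stats::rnorm(length(times), 0, noise_sd)
    growth_curve(times, pmax(od, 1e-6), condition, rep)
  })
  list(curves = curves,
       truth = data.frame(condition = condition,
                          replicate = seq_len(replicates), r = r))
}
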