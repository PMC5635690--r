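# Rule-based MS/MS fragment prediction.
#
# Conventions (these reproduce the published fragment tables for this
# pathway):
#  * intact molecular ion: [M+H]+ = neutral + 1.00727646 (proton mass);
#  * every fragment ion: plain sum of the atomic monoisotopic masses of the
#    fragment's formula -- no proton addition, no electron subtraction.
# Cleavage chemistry at depth 1:
#  * amide CO-N heterolysis: acid side as acylium (acid formula - OH),
#    amine side as protonated amine (fragment + H);
#  * backbone C-N heterolysis on linear polyamines: alkyl-cation side as-is,
#    nitrogen side both as iminium (+0 H) and ammonium (+2 H);
#  * ester CO-O cleavage in the enterobactin series: chain acylium on the
#    acid side, protonated chain on the alcohol side; for the macrocycle the
#    acylium series doubles as the ring-opening template;
#  * each emitted species additionally minus one neutral loss (H2O or NH3).

.loss_formulas <- function(losses) {
  known <- list(H2O = ef(H = 2, O = 1), NH3 = ef(N = 1, H = 3))
  bad <- setdiff(losses, names(known))
  if (length(bad) > 0L) stop("unknown neutral loss: ", paste(bad, collapse = ", "))
  known[losses]
}

.oh <- function() ef(H = 1, O = 1)
.h <- function(n = 1L) ef(H = n)

# Parse a backbone descriptor: comma-separated divalent segments, each an
# integer k (-> CkH2k methylene chain) or an explicit formula (aromatic
# linkers); an optional ";<formula>" suffix is a monovalent group (e.g.
# benzyl C7H7) on the last amine. Amines sit between/around segments.
.parse_backbone <- function(spec) {
  if (is.null(spec) || is.na(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  seg_tokens <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  segments <- lapply(seg_tokens, function(t) {
    if (grepl("^[0-9]+$", t)) {
      k <- as.integer(t)
      ef(C = k, H = 2 * k)
    } else parse_formula(t)
  })
  terminal <- if (length(parts) > 1L) parse_formula(parts[2]) else NULL
  list(segments = segments, terminal = terminal)
}

# Build the linear group sequence for one acyl orientation.
# Groups: list(kind = "acyl"|"N"|"seg", formula). Amine H counts follow
# nitrogen valence 3 minus bonds (segments, acyl, branch).
.chain_groups <- function(bb, dhb_first, cap = NULL) {
  k <- length(bb$segments)
  n_amines <- k + 1L
  acyl_at <- integer(0)
  dhb_pos <- if (dhb_first) 1L else n_amines
  cap_pos <- if (dhb_first) n_amines else 1L
  dhb_acyl <- building_block("DHB")$formula - .oh()
  groups <- list()
  branch_on <- if (!is.null(bb$terminal)) n_amines else 0L
  amine_group <- function(i) {
    bonds <- (if (i > 1L) 1L else 0L) + (if (i < n_amines) 1L else 0L)
    if (i == dhb_pos) bonds <- bonds + 1L
    if (!is.null(cap) && i == cap_pos) bonds <- bonds + 1L
    if (i == branch_on) bonds <- bonds + 1L
    h <- max(0L, 3L - bonds)
    f <- ef(N = 1) + .h(h)
    # fold a monovalent branch (e.g. benzyl) into its amine so bond-side
    # sums stay complete; branch cleavage itself is emitted separately
    if (i == branch_on) f <- f + bb$terminal
    list(kind = "N", formula = f)
  }
  seq_groups <- list()
  if (dhb_pos == 1L) seq_groups[[length(seq_groups) + 1L]] <-
      list(kind = "acyl", formula = dhb_acyl)
  else if (!is.null(cap) && cap_pos == 1L) seq_groups[[length(seq_groups) + 1L]] <-
      list(kind = "acyl", formula = cap$acid - .oh())
  for (i in seq_len(n_amines)) {
    seq_groups[[length(seq_groups) + 1L]] <- amine_group(i)
    if (i <= k) seq_groups[[length(seq_groups) + 1L]] <-
        list(kind = "seg", formula = bb$segments[[i]])
  }
  if (dhb_pos == n_amines) seq_groups[[length(seq_groups) + 1L]] <-
      list(kind = "acyl", formula = dhb_acyl)
  else if (!is.null(cap) && cap_pos == n_amines) seq_groups[[length(seq_groups) + 1L]] <-
      list(kind = "acyl", formula = cap$acid - .oh())
  list(groups = seq_groups, branch = bb$terminal, branch_amine = branch_on)
}

.sum_groups <- function(groups) {
  f <- ef()
  for (g in groups) f <- f + g$formula
  f
}

# Enumerate depth-1 cleavage fragments (formula, description) for one chain.
.chain_fragments <- function(chain) {
  groups <- chain$groups
  frags <- list()
  add <- function(f, desc) frags[[length(frags) + 1L]] <<- list(formula = f, desc = desc)
  nb <- length(groups) - 1L
  for (b in seq_len(nb)) {
    left <- .sum_groups(groups[seq_len(b)])
    right <- .sum_groups(groups[(b + 1L):length(groups)])
    lk <- groups[[b]]$kind; rk <- groups[[b + 1L]]$kind
    if (lk == "acyl" || rk == "acyl") {
      # amide CO-N bond
      if (lk == "acyl") {
        add(left, "amide cleavage, acylium")
        add(right + .h(2L), "amide cleavage, protonated amine side")
      } else {
        add(right, "amide cleavage, acylium")
        add(left + .h(2L), "amide cleavage, protonated amine side")
      }
    } else {
      # backbone C-N bond
      cside <- if (lk == "seg") left else right
      nside <- if (lk == "seg") right else left
      add(cside, "C-N cleavage, alkyl cation side")
      add(nside, "C-N cleavage, iminium side")
      add(nside + .h(2L), "C-N cleavage, ammonium side")
    }
  }
  if (!is.null(chain$branch)) {
    whole <- .sum_groups(groups)   # branch folded into its amine group
    debranched <- whole - chain$branch
    add(chain$branch, "N-benzyl cleavage, benzylic cation")
    add(debranched, "N-benzyl cleavage, iminium side")
    add(debranched + .h(2L), "N-benzyl cleavage, ammonium side")
  }
  frags
}

#' Wrap a bare formula as a degenerate product
#'
#' Useful for fragmenting a free building block: with no condensation bonds
#' only the intact species (and its neutral losses) are emitted.
#'
#' @param formula An [ef()] object or formula string.
#' @param id Label for the species.
#' @return An `assembled_product` with empty provenance.
#' @export
raw_product <- function(formula, id = "species") {
  if (is.character(formula)) formula <- parse_formula(formula)
  .new_product(id, formula, provenance = list(type = "raw", steps = list()))
}

#' Predict MS/MS fragment ions for an assembled product
#'
#' Emits, deduplicated by formula and sorted by decreasing m/z: the intact
#' `[M+H]+` ion; the intact ion minus each neutral loss; for each cleavable
#' bond, both charge-retention sides (acylium on the acid side, protonated
#' amine on the amine side; plus iminium/ammonium pairs for backbone C-N
#' bonds of linear polyamines, and chain acylium species for the
#' enterobactin ester backbone); and each cleavage species minus each
#' neutral loss. Fragment m/z values use the plain formula-sum convention
#' (see the package vignette); the intact ion uses the proton-mass
#' convention.
#'
#' @param p An `assembled_product`.
#' @param losses Neutral losses to apply, subset of `c("H2O","NH3")`.
#' @param max_cleavages 0 (intact species only) or 1 (default).
#' @return A data.frame of class `predicted_fragments` with columns
#'   `parent_id`, `formula`, `mz`, `description`.
#' @export
#' @examples
#' m1 <- make_intermediate(precursor(1))
#' fr <- predict_fragments(m1)
#' any(abs(fr$mz - 137.0239) < 5e-4)  # DHB acylium
predict_fragments <- function(p, losses = c("H2O", "NH3"), max_cleavages = 1L) {
  stopifnot(inherits(p, "assembled_product"))
  if (!max_cleavages %in% c(0L, 1L))
    stop("unsupported cleavage depth: max_cleavages must be 0 or 1")
  loss_f <- .loss_formulas(losses)
  rows <- list()
  add <- function(formula, mz, desc)
    rows[[length(rows) + 1L]] <<- list(formula = format_formula(formula),
                                       mz = mz, desc = desc)
  # (i) intact [M+H]+ (proton convention)
  add(p$formula + .h(1L), p$mz, "intact [M+H]+")
  base_frags <- list()
  # (ii) intact minus neutral losses (plain-sum convention on [M+H] formula)
  for (ln in names(loss_f)) {
    f <- .try_subtract(p$formula + .h(1L), loss_f[[ln]])
    if (!is.null(f)) base_frags[[length(base_frags) + 1L]] <-
        list(formula = f, desc = paste0("intact - ", ln))
  }
  if (max_cleavages >= 1L) {
    base_frags <- c(base_frags, .cleavage_fragments(p))
  }
  for (fr in base_frags) {
    add(fr$formula, monoisotopic_mass(fr$formula), fr$desc)
    # (iv) each cleavage/loss species minus each neutral loss (one loss max)
    if (!grepl(" - ", fr$desc, fixed = TRUE)) {
      for (ln in names(loss_f)) {
        f2 <- .try_subtract(fr$formula, loss_f[[ln]])
        if (!is.null(f2))
          add(f2, monoisotopic_mass(f2), paste0(fr$desc, " - ", ln))
      }
    }
  }
  df <- data.frame(
    parent_id = p$id,
    formula = vapply(rows, `[[`, "", "formula"),
    mz = vapply(rows, `[[`, 0, "mz"),
    description = vapply(rows, `[[`, "", "desc"),
    stringsAsFactors = FALSE
  )
  df <- df[!duplicated(df$formula), , drop = FALSE]
  df <- df[order(-df$mz), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("predicted_fragments", "data.frame")
  df
}

.try_subtract <- function(a, b) tryCatch(a - b, error = function(e) NULL)

.cleavage_fragments <- function(p) {
  prov <- p$provenance
  switch(prov$type,
    raw = list(),
    ent = .ent_fragments(prov),
    .amine_product_fragments(p)
  )
}

.amine_product_fragments <- function(p) {
  prov <- p$provenance
  prec <- prov$precursor
  cap <- prov$cap
  bb <- .parse_backbone(prec$backbone)
  frags <- list()
  if (!is.null(bb)) {
    # both acyl orientations on asymmetric backbones; dedup happens later
    for (dhb_first in c(TRUE, FALSE)) {
      chain <- .chain_groups(bb, dhb_first, cap)
      frags <- c(frags, .chain_fragments(chain))
    }
  } else {
    # formula-level fallback: condensation-bond cleavages only
    dhb_acyl <- building_block("DHB")$formula - .oh()
    frags <- c(frags, list(
      list(formula = dhb_acyl, desc = "amide cleavage, DHB acylium"),
      list(formula = p$formula + ef(H = 2, O = 1) - building_block("DHB")$formula + .h(1L),
           desc = "amide cleavage, protonated amine side")
    ))
    if (!is.null(cap)) {
      frags <- c(frags, list(
        list(formula = cap$acid - .oh(), desc = "cap amide cleavage, acylium"),
        list(formula = p$formula - cap$addition + .h(1L),
             desc = "cap amide cleavage, protonated amine side")
      ))
    }
  }
  frags
}

.ent_fragments <- function(prov) {
  unit <- prov$unit
  n <- prov$n
  h2o <- ef(H = 2, O = 1)
  dhb_acyl <- building_block("DHB")$formula - .oh()
  frags <- list(
    list(formula = dhb_acyl, desc = "amide cleavage, DHB acylium")
  )
  whole <- n * unit - (n - 1L + if (prov$cyclic) 1L else 0L) * h2o
  # losing one DHB acyl group, protonated remainder
  f <- .try_subtract(whole + .h(1L), dhb_acyl)
  if (!is.null(f)) frags[[length(frags) + 1L]] <-
      list(formula = f, desc = "amide cleavage, protonated amine side")
  jmax <- n - 1L
  if (jmax >= 1L) {
    for (j in seq_len(jmax)) {
      frags[[length(frags) + 1L]] <- list(
        formula = j * unit - (j - 1L) * h2o - .oh(),
        desc = sprintf("ester cleavage, %d-unit chain acylium%s", j,
                       if (prov$cyclic) " (ring opening)" else ""))
      if (!prov$cyclic) {
        m <- n - j
        frags[[length(frags) + 1L]] <- list(
          formula = m * unit - (m - 1L) * h2o + .h(1L),
          desc = sprintf("ester cleavage, protonated %d-unit alcohol side", m))
      }
    }
  }
  frags
}

#' Fraction of observed peaks explained by predictions
#'
#' Greedy one-to-one nearest matching within a ppm tolerance: observed peaks
#' are processed in order of increasing best-match distance; each observed
#' peak and each predicted fragment is used at most once.
#'
#' @param predicted A `predicted_fragments` data.frame (or numeric m/z
#'   vector).
#' @param observed Numeric vector of observed fragment m/z.
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return List with `coverage` (matched fraction of observed peaks; 1.0
#'   with zero pairs when `observed` is empty) and `pairs` (data.frame
#'   `observed`, `predicted`, `ppm`).
#' @export
fragment_coverage <- function(predicted, observed, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  pmz <- if (is.data.frame(predicted)) predicted$mz else as.numeric(predicted)
  pairs <- data.frame(observed = numeric(0), predicted = numeric(0),
                      ppm = numeric(0))
  if (length(observed) == 0L)
    return(list(coverage = 1.0, pairs = pairs))
  if (length(pmz) == 0L)
    return(list(coverage = 0.0, pairs = pairs))
  obs <- sort(observed)
  used <- rep(FALSE, length(pmz))
  hits <- 0L
  for (o in obs) {
    d <- abs(pmz - o) / o * 1e6
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_ppm) {
      used[j] <- TRUE
      hits <- hits + 1L
      pairs <- rbind(pairs, data.frame(observed = o, predicted = pmz[j],
                                       ppm = (o - pmz[j]) / pmz[j] * 1e6))
    }
  }
  list(coverage = hits / length(obs), pairs = pairs)
}
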