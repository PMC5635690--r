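#' Acyl caps applied by the amino-acid-loading enzyme
#'
#' The second acylation of a DHB-polyamine intermediate attaches a
#' DHB-amino-acid group built from threonine (T) or serine (S), either
#' cyclodehydrated into a 2-(2,3-dihydroxyphenyl)-oxazoline ring
#' ("closed", c; one extra water lost) or left as the open
#' dihydroxybenzoyl-amino-acid amide ("open", o).
#'
#' Added compositions: Tc `C11H9NO4` (+219.0532 Da), To `C11H11NO5`
#' (+237.0637), Sc `C10H7NO4` (+205.0375), So `C10H9NO5` (+223.0481).
#'
#' @param codes Subset of `c("Tc","To","Sc","So")`; omit for all four.
#' @return A named list of caps; each has `code`, `amino_acid`, `cyclized`,
#'   `addition` (formula added to the intermediate), and `acid` (the free
#'   DHB-amino-acid carboxylic acid, used for fragment acylium bookkeeping).
#' @export
#' @examples
#' monoisotopic_mass(acyl_caps("Tc")$Tc$addition)  # 219.0532
acyl_caps <- function(codes = c("Tc", "To", "Sc", "So")) {
  codes <- match.arg(codes, c("Tc", "To", "Sc", "So"), several.ok = TRUE)
  make <- function(code) {
    aa <- if (substr(code, 1, 1) == "T") "Thr" else "Ser"
    cyc <- substr(code, 2, 2) == "c"
    nw <- if (cyc) 3L else 2L
    addition <- condense(building_block("DHB")$formula,
                         building_block(aa)$formula, nw)
    list(code = code, amino_acid = aa, cyclized = cyc, addition = addition,
         # free acid of the cap acyl group (addition + the water regained on
         # hydrolysis of the amide it forms)
         acid = addition + ef(H = 2, O = 1))
  }
  stats::setNames(lapply(codes, make), codes)
}

.new_product <- function(id, formula, provenance, precursor_id = NA_integer_,
                         multiplicity = 1L) {
  structure(list(
    id = id,
    formula = formula,
    neutral_mass = monoisotopic_mass(formula),
    mz = protonated_mz(monoisotopic_mass(formula)),
    precursor_id = precursor_id,
    multiplicity = multiplicity,
    provenance = provenance
  ), class = "assembled_product")
}

#' @export
print.assembled_product <- function(x, ...) {
  cat(sprintf("<%s>  %s  neutral %.4f Da  [M+H]+ %.4f\n", x$id,
              format_formula(x$formula), x$neutral_mass, x$mz))
  invisible(x)
}

#' @export
format.assembled_product <- function(x, ...) x$id

#' Number of acylation-competent amine sites on a precursor
#'
#' @param p A precursor row (see [precursor()]).
#' @param secondary_ok Count secondary amines as competent (default TRUE;
#'   the benzylethylenediamine analog, acylated on both its primary and
#'   secondary amine, shows secondary amines are accepted in vivo).
#' @return Integer site count.
#' @export
n_acyl_sites <- function(p, secondary_ok = TRUE) {
  as.integer(p$n_primary_amines) +
    if (secondary_ok) as.integer(p$n_secondary_amines) else 0L
}

#' Condense a precursor amine with DHB into an intermediate
#'
#' One amide bond between the DHB carboxyl and a precursor amine, losing one
#' water. The product id is `M<registry id>`, following the naming of the
#' source study's intermediates.
#'
#' @param p Precursor (from [precursor()] or a registry row).
#' @param secondary_ok Whether secondary amines count as acylation sites.
#' @return An `assembled_product`.
#' @export
#' @examples
#' make_intermediate(precursor(5))$mz  # 225.1234 (aminochelin)
make_intermediate <- function(p, secondary_ok = TRUE) {
  if (is.data.frame(p)) p <- precursor(p$id, p)
  sites <- n_acyl_sites(p, secondary_ok)
  if (sites < 1L)
    stop(sprintf("precursor %s (%s) has no acylatable amine; not a substrate",
                 p$id, p$name))
  f <- condense(building_block("DHB")$formula, p$formula, 1L)
  .new_product(
    id = paste0("M", p$id),
    formula = f,
    precursor_id = as.integer(p$id),
    multiplicity = sites,
    provenance = list(
      type = "intermediate",
      precursor = p,
      steps = list(list(block = "DHB", bond = "amide", waters = 1L)),
      cap = NULL
    )
  )
}

#' Acylate an intermediate with a DHB-amino-acid cap
#'
#' Attaches one cap (see [acyl_caps()]) to a second amine of the
#' intermediate's precursor, producing a full-sized analog with id
#' `M<id><cap code>`.
#'
#' @param intermediate Product from [make_intermediate()].
#' @param cap A cap object or one of `"Tc","To","Sc","So"`.
#' @param secondary_ok Whether the second site may be a secondary amine.
#' @return An `assembled_product`.
#' @export
#' @examples
#' m1 <- make_intermediate(precursor(1))
#' make_full_analog(m1, "Tc")$mz  # 430.1609 (serratiochelin)
make_full_analog <- function(intermediate, cap, secondary_ok = TRUE) {
  stopifnot(inherits(intermediate, "assembled_product"))
  if (is.character(cap)) cap <- acyl_caps(cap)[[1]]
  p <- intermediate$provenance$precursor
  if (is.null(p) || n_acyl_sites(p, secondary_ok) < 2L)
    stop(sprintf("%s: precursor lacks a second acylatable amine",
                 intermediate$id))
  f <- intermediate$formula + cap$addition
  prov <- intermediate$provenance
  prov$type <- "analog"
  prov$cap <- cap
  prov$steps <- c(prov$steps,
                  list(list(block = cap$code, bond = "amide",
                            waters = if (cap$cyclized) 3L else 2L)))
  .new_product(
    id = paste0(intermediate$id, cap$code),
    formula = f,
    precursor_id = intermediate$precursor_id,
    multiplicity = intermediate$multiplicity,
    provenance = prov
  )
}

#' Enumeration settings
#'
#' @param caps Cap codes to apply (subset of Tc, To, Sc, So).
#' @param secondary_ok Are secondary amines acylation-competent (default
#'   TRUE).
#' @param ent_max_n Maximum oligomer length of the enterobactin series
#'   (default 3; the pathway's native product is the trilactone).
#' @param allow_cyclic Emit the macrocyclic trilactone (default TRUE).
#' @param ent_residues Residues for the oligomer series (default both Ser
#'   and Thr, which the loading enzyme can activate).
#' @return A list of class `enumeration_config`.
#' @export
enumeration_config <- function(caps = c("Tc", "To", "Sc", "So"),
                               secondary_ok = TRUE,
                               ent_max_n = 3L,
                               allow_cyclic = TRUE,
                               ent_residues = c("Ser", "Thr")) {
  stopifnot(all(caps %in% c("Tc", "To", "Sc", "So")), ent_max_n >= 1L)
  structure(list(caps = caps, secondary_ok = secondary_ok,
                 ent_max_n = as.integer(ent_max_n),
                 allow_cyclic = allow_cyclic,
                 ent_residues = ent_residues),
            class = "enumeration_config")
}

#' Enumerate candidate products for a precursor registry
#'
#' For each precursor with at least one acylation site, one DHB intermediate;
#' for each precursor with at least two sites, one full analog per configured
#' cap. Regio-isomeric placements on asymmetric polyamines are mass-identical
#' and are collapsed to one product carrying a `multiplicity` count.
#' Precursors without sites are skipped with a warning. Order is
#' deterministic: by registry id, then cap code.
#'
#' @param registry A `precursor_registry` data.frame.
#' @param cfg An [enumeration_config()].
#' @return List of `assembled_product`s.
#' @export
enumerate_products <- function(registry, cfg = enumeration_config()) {
  out <- list()
  skipped <- character(0)
  for (id in sort(unique(registry$id))) {
    p <- precursor(id, registry)
    sites <- n_acyl_sites(p, cfg$secondary_ok)
    if (sites < 1L) { skipped <- c(skipped, p$name); next }
    im <- make_intermediate(p, cfg$secondary_ok)
    out[[length(out) + 1L]] <- im
    if (sites >= 2L) {
      for (code in sort(cfg$caps)) {
        out[[length(out) + 1L]] <-
          make_full_analog(im, acyl_caps(code)[[1]], cfg$secondary_ok)
      }
    }
  }
  if (length(skipped) > 0L)
    warning("skipped precursor(s) with no acylatable amine: ",
            paste(skipped, collapse = ", "))
  out
}

#' Enumerate the enterobactin oligomer series
#'
#' The unit is a DHB-amino-acid amide (DHB + residue - H2O). Linear chains
#' of n units are joined by n-1 ester bonds; the macrocyclic trilactone
#' closes one further ester. Ids follow the published naming: `Ent` is the
#' cyclic Ser trilactone, `Ent trimer` the linear (hydrolyzed) trimer,
#' `Ent dimer`/`Ent monomer` the shorter hydrolysis species; Thr analogs are
#' prefixed `Thr-`.
#'
#' @param residue `"Ser"` or `"Thr"`.
#' @param n Number of units (>= 1).
#' @param cyclic Macrocyclize; only n = 3 (the trilactone) is modeled.
#' @return An `assembled_product`.
#' @export
#' @examples
#' ent_oligomer("Ser", 3, cyclic = TRUE)$mz   # 670.1515
#' ent_oligomer("Thr", 2)$mz                  # 493.1453 (Thr-Ent dimer)
ent_oligomer <- function(residue = c("Ser", "Thr"), n = 3L, cyclic = FALSE) {
  residue <- match.arg(residue)
  stopifnot(n >= 1L, n == round(n))
  n <- as.integer(n)
  if (cyclic && n != 3L)
    stop("only the n = 3 macrocyclic trilactone is modeled")
  unit <- condense(building_block("DHB")$formula,
                   building_block(residue)$formula, 1L)
  nw <- (n - 1L) + if (cyclic) 1L else 0L
  f <- tryCatch(n * unit - nw * ef(H = 2, O = 1),
                error = function(e) stop("infeasible oligomer", call. = FALSE))
  prefix <- if (residue == "Thr") "Thr-Ent" else "Ent"
  id <- if (cyclic) prefix
        else if (n == 1L) paste(prefix, "monomer")
        else if (n == 2L) paste(prefix, "dimer")
        else paste(prefix, "trimer")
  .new_product(
    id = id, formula = f,
    provenance = list(type = "ent", residue = residue, n = n,
                      cyclic = cyclic, unit = unit)
  )
}

#' @rdname ent_oligomer
#' @param residues Residues to enumerate.
#' @param max_n Maximum chain length.
#' @param topologies Subset of `c("linear","cyclic")`.
#' @return For `enumerate_ent_series`: list of `assembled_product`s in
#'   deterministic order (residue, then n ascending, cyclic last).
#' @export
enumerate_ent_series <- function(residues = c("Ser", "Thr"), max_n = 3L,
                                 topologies = c("linear", "cyclic")) {
  stopifnot(max_n >= 1L)
  topologies <- match.arg(topologies, c("linear", "cyclic"), several.ok = TRUE)
  out <- list()
  for (res in residues) {
    if ("linear" %in% topologies)
      for (n in seq_len(max_n))
        out[[length(out) + 1L]] <- ent_oligomer(res, n, cyclic = FALSE)
    if ("cyclic" %in% topologies && max_n >= 3L)
      out[[length(out) + 1L]] <- ent_oligomer(res, 3L, cyclic = TRUE)
  }
  out
}

#' Enumerate the full default candidate set
#'
#' Registry products plus the enterobactin series, the candidate set used
#' for spectrum annotation.
#'
#' @inheritParams enumerate_products
#' @return List of `assembled_product`s.
#' @export
enumerate_candidates <- function(registry = read_precursor_registry(),
                                 cfg = enumeration_config()) {
  c(enumerate_products(registry, cfg),
    enumerate_ent_series(cfg$ent_residues, cfg$ent_max_n,
                         if (cfg$allow_cyclic) c("linear", "cyclic")
                         else "linear"))
}

#' Candidate table
#'
#' @param products List of `assembled_product`s.
#' @return data.frame with id, formula, neutral mass, m/z, precursor id,
#'   multiplicity and a provenance string.
#' @export
candidate_table <- function(products) {
  data.frame(
    id = vapply(products, `[[`, "", "id"),
    type = vapply(products, function(p) p$provenance$type, ""),
    formula = vapply(products, function(p) format_formula(p$formula), ""),
    neutral_mass = vapply(products, `[[`, 0, "neutral_mass"),
    mz = vapply(products, `[[`, 0, "mz"),
    precursor_id = vapply(products, `[[`, NA_integer_, "precursor_id"),
    multiplicity = vapply(products, `[[`, 0L, "multiplicity"),
    provenance = vapply(products, .provenance_string, ""),
    stringsAsFactors = FALSE
  )
}

.provenance_string <- function(p) {
  pr <- p$provenance
  if (pr$type == "ent") {
    sprintf("%s x%d %s", pr$residue, pr$n,
            if (pr$cyclic) "cyclic" else "linear")
  } else {
    paste(vapply(pr$steps, function(s)
      sprintf("%s(%s,-%dH2O)", s$block, s$bond, s$waters), ""),
      collapse = "+")
  }
}
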