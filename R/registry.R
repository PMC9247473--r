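#' Define a coarse-grained lipid species
#'
#' A `lipid_spec` is the static description of one lipid type: its bead
#' inventory, the bead taken to represent its position on the leaflet surface,
#' the head/tail partition of the inventory, the tail bond topology, and the
#' number of unsaturated (cis/trans double) bonds represented in the tails.
#'
#' The head/tail split follows the usual coarse-grained convention: headgroup
#' plus linker (glycerol / phosphosphingosine / sterol ring) beads count as
#' "head", acyl-chain beads as "tail". The split is data, not hard-coded, so
#' alternative conventions can be supplied.
#'
#' @param name Short species label, e.g. `"POPC"`.
#' @param bead_names Character vector of all bead names, in topology order.
#' @param headgroup_bead Name of the bead that defines the leaflet surface
#'   (the phosphate bead for phospholipids, the hydroxyl bead for cholesterol).
#' @param tails List of character vectors, one per acyl tail (0, 1 or 2
#'   tails), each a sequence of bead names along the tail.
#' @param n_unsaturated_bonds Number of unsaturated tail bonds.
#' @param head_beads Character vector of beads counted as "head"; defaults to
#'   all beads not in `tails`.
#' @return An object of class `lipid_spec`.
#' @export
lipid_spec <- function(name, bead_names, headgroup_bead, tails = list(),
                       n_unsaturated_bonds = 0L, head_beads = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bead_names <- as.character(bead_names)
  if (any(!nzchar(bead_names))) stop("all bead names must be nonempty")
  if (anyDuplicated(bead_names)) stop("duplicate bead names in species ", name)
  if (!headgroup_bead %in% bead_names)
    stop("headgroup bead '", headgroup_bead, "' not in bead inventory of ", name)
  tails <- lapply(tails, as.character)
  tail_beads <- unlist(tails, use.names = FALSE)
  if (!all(tail_beads %in% bead_names))
    stop("tail beads not in bead inventory of ", name)
  if (is.null(head_beads)) head_beads <- setdiff(bead_names, tail_beads)
  if (!all(head_beads %in% bead_names))
    stop("head beads not in bead inventory of ", name)
  n_tail_bonds <- sum(vapply(tails, function(t) max(length(t) - 1L, 0L), 1L))
  if (n_unsaturated_bonds > n_tail_bonds)
    stop("n_unsaturated_bonds exceeds tail bond count for ", name)
  if (length(head_beads) + length(tail_beads) > length(bead_names))
    stop("head/tail partition larger than bead inventory for ", name)
  structure(list(
    name = name,
    bead_names = bead_names,
    headgroup_bead = headgroup_bead,
    tails = tails,
    n_head_beads = length(head_beads),
    head_beads = head_beads,
    n_tail_beads = length(tail_beads),
    n_tail_bonds = n_tail_bonds,
    n_unsaturated_bonds = as.integer(n_unsaturated_bonds)
  ), class = "lipid_spec")
}

#' @export
print.lipid_spec <- function(x, ...) {
  cat(sprintf("<lipid_spec> %s: %d beads (%d head / %d tail), %d tail(s), %d unsaturated bond(s), surface bead %s\n",
              x$name, length(x$bead_names), x$n_head_beads, x$n_tail_beads,
              length(x$tails), x$n_unsaturated_bonds, x$headgroup_bead))
  invisible(x)
}

#' Bundled eight-species plasma-membrane registry
#'
#' Martini 2.x bead inventories for the eight lipid types of the asymmetric
#' plasma-membrane model analysed by this package: POPC, PAPC, POPE, DIPE,
#' DPSM, PAPS, PAP6 (a PIP2 lipid; P2 headgroup, G-G linkers, palmitoyl +
#' arachidonoyl tails) and CHOL. The leaflet surface bead defaults to the
#' phosphate bead (PO4) for the seven phospholipids and the hydroxyl bead
#' (ROH) for cholesterol; the choice is configurable because the observed
#' curvature depends on which bead is taken to define the surface.
#'
#' @return Named list of [lipid_spec()] objects.
#' @export
plasma_registry <- function() {
  specs <- list(
    lipid_spec("POPC",
      c("NC3", "PO4", "GL1", "GL2",
        "C1A", "D2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"),
      "PO4",
      tails = list(c("C1A", "D2A", "C3A", "C4A"), c("C1B", "C2B", "C3B", "C4B")),
      n_unsaturated_bonds = 1L),
    lipid_spec("PAPC",
      c("NC3", "PO4", "GL1", "GL2",
        "D1A", "D2A", "D3A", "D4A", "C5A", "C1B", "C2B", "C3B", "C4B"),
      "PO4",
      tails = list(c("D1A", "D2A", "D3A", "D4A", "C5A"),
                   c("C1B", "C2B", "C3B", "C4B")),
      n_unsaturated_bonds = 4L),
    lipid_spec("POPE",
      c("NH3", "PO4", "GL1", "GL2",
        "C1A", "D2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"),
      "PO4",
      tails = list(c("C1A", "D2A", "C3A", "C4A"), c("C1B", "C2B", "C3B", "C4B")),
      n_unsaturated_bonds = 1L),
    lipid_spec("DIPE",
      c("NH3", "PO4", "GL1", "GL2",
        "C1A", "D2A", "D3A", "C4A", "C1B", "D2B", "D3B", "C4B"),
      "PO4",
      tails = list(c("C1A", "D2A", "D3A", "C4A"), c("C1B", "D2B", "D3B", "C4B")),
      n_unsaturated_bonds = 4L),
    lipid_spec("DPSM",
      c("NC3", "PO4", "AM1", "AM2",
        "T1A", "C2A", "C3A", "C1B", "C2B", "C3B", "C4B"),
      "PO4",
      tails = list(c("T1A", "C2A", "C3A"), c("C1B", "C2B", "C3B", "C4B")),
      n_unsaturated_bonds = 1L),
    lipid_spec("PAPS",
      c("CNO", "PO4", "GL1", "GL2",
        "D1A", "D2A", "D3A", "D4A", "C5A", "C1B", "C2B", "C3B", "C4B"),
      "PO4",
      tails = list(c("D1A", "D2A", "D3A", "D4A", "C5A"),
                   c("C1B", "C2B", "C3B", "C4B")),
      n_unsaturated_bonds = 4L),
    lipid_spec("PAP6",
      c("C1", "C2", "C3", "PO4", "P1", "P2", "GL1", "GL2",
        "C1A", "C2A", "C3A", "C4A", "D1B", "D2B", "D3B", "D4B", "C5B"),
      "PO4",
      tails = list(c("C1A", "C2A", "C3A", "C4A"),
                   c("D1B", "D2B", "D3B", "D4B", "C5B")),
      n_unsaturated_bonds = 4L),
    lipid_spec("CHOL",
      c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2"),
      "ROH",
      tails = list(c("C1", "C2")),
      n_unsaturated_bonds = 0L)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Look up the surface (headgroup) bead for each species
#' @param registry Named list of [lipid_spec()] objects.
#' @return Named character vector, species -> headgroup bead name.
#' @export
headgroup_beads <- function(registry) {
  vapply(registry, `[[`, "", "headgroup_bead")
}

#' Construct a per-leaflet composition
#'
#' A composition holds, per leaflet, the species names with their fractional
#' abundances and/or explicit counts. Fractions must sum to 1 within 0.005
#' per leaflet. When explicit counts are given they take precedence over
#' apportioned fractions (printed per-species counts of published systems are
#' not always reproducible from their rounded fractions by any single
#' rounding rule).
#'
#' @param outer,inner Data frames with columns `species`, `fraction` and
#'   optionally `count`.
#' @return Object of class `composition`: named list of per-leaflet data
#'   frames with columns `species`, `fraction`, `count`.
#' @export
composition <- function(outer, inner) {
  leaflets <- list(outer = outer, inner = inner)
  out <- lapply(names(leaflets), function(lf) {
    d <- as.data.frame(leaflets[[lf]])
    stopifnot(all(c("species", "fraction") %in% names(d)))
    if (anyDuplicated(d$species))
      stop("duplicate species in ", lf, " leaflet")
    if (any(d$fraction < 0)) stop("negative fraction in ", lf, " leaflet")
    if (abs(sum(d$fraction) - 1) > 0.005)
      stop(sprintf("%s leaflet fractions sum to %.4f, outside 1 +/- 0.005",
                   lf, sum(d$fraction)))
    if (!is.null(d$count)) {
      if (any(d$count < 0) || any(d$count != round(d$count)))
        stop("counts must be nonnegative integers in ", lf, " leaflet")
      d$count <- as.integer(d$count)
    } else {
      d$count <- NA_integer_
    }
    d[, c("species", "fraction", "count")]
  })
  names(out) <- names(leaflets)
  structure(out, class = "composition")
}

#' Asymmetric plasma-membrane composition (eight species)
#'
#' The bundled asymmetric bilayer composition: 1350 outer-leaflet and 1348
#' inner-leaflet lipids with the fractional compositions of the average
#' plasma-membrane model (outer: POPC 0.243, PAPC 0.121, POPE 0.020, DIPE
#' 0.061, DPSM 0.242, CHOL 0.313; inner: POPC 0.139, PAPC 0.075, POPE 0.054,
#' DIPE 0.161, DPSM 0.108, PAPS 0.161, PAP6 0.022, CHOL 0.280). Explicit
#' per-species counts are carried alongside the fractions.
#'
#' @param symmetric If `TRUE`, both leaflets use the inner-leaf composition
#'   (the symmetric control build).
#' @return A [composition()] object.
#' @export
plasma_composition <- function(symmetric = FALSE) {
  sp <- c("POPC", "PAPC", "POPE", "DIPE", "DPSM", "PAPS", "PAP6", "CHOL")
  outer <- data.frame(
    species = sp,
    fraction = c(0.243, 0.121, 0.020, 0.061, 0.242, 0.000, 0.000, 0.313),
    count = c(328L, 163L, 27L, 82L, 327L, 0L, 0L, 423L))
  inner <- data.frame(
    species = sp,
    fraction = c(0.139, 0.075, 0.054, 0.161, 0.108, 0.161, 0.022, 0.280),
    count = c(187L, 101L, 73L, 217L, 146L, 217L, 29L, 378L))
  if (symmetric) outer <- inner
  composition(outer = outer, inner = inner)
}

#' Apportion fractional composition into integer counts
#'
#' Largest-remainder apportionment of `fraction * total` into nonnegative
#' integer counts that sum exactly to `total`. Ties in the remainders are
#' broken in favour of the first-listed species.
#'
#' @param fractions Numeric vector of per-species fractions (sum to 1 within
#'   0.005, all >= 0).
#' @param total Positive integer total lipid count.
#' @return Integer vector of counts summing to `total`.
#' @export
build_counts <- function(fractions, total) {
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 0.005)
    stop(sprintf("fractions sum to %.4f, outside 1 +/- 0.005", sum(fractions)))
  if (total <= 0 || total != round(total)) stop("total must be a positive integer")
  total <- as.integer(total)
  quota <- fractions / sum(fractions) * total
  counts <- floor(quota)
  short <- total - sum(counts)
  if (short > 0) {
    # order() is stable: equal remainders resolve to the first-listed species
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Resolve a composition into per-leaflet integer counts
#'
#' Explicit counts override apportionment; species with all-`NA` counts in a
#' leaflet are apportioned from fractions via [build_counts()] using the
#' leaflet totals supplied.
#'
#' @param comp A [composition()] object.
#' @param totals Named integer vector `c(outer = ..., inner = ...)`; required
#'   only for leaflets without explicit counts.
#' @return Named list of data frames (`outer`, `inner`) with columns
#'   `species`, `count`.
#' @export
composition_counts <- function(comp, totals = NULL) {
  stopifnot(inherits(comp, "composition"))
  out <- lapply(names(comp), function(lf) {
    d <- comp[[lf]]
    if (all(!is.na(d$count))) {
      data.frame(species = d$species, count = d$count)
    } else {
      if (is.null(totals) || is.na(totals[lf]))
        stop("no explicit counts for ", lf, " leaflet and no total supplied")
      data.frame(species = d$species,
                 count = build_counts(d$fraction, totals[[lf]]))
    }
  })
  names(out) <- names(comp)
  out
}
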