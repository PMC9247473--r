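# Small fixtures shared across tests. Everything is built in code.

# Two-species minimal registry: 4-bead lipids with a single 3-bead tail.
tiny_registry <- function() {
  specs <- list(
    lipid_spec("LIPA", c("PO4", "GL1", "C1A", "C2A", "C3A"), "PO4",
               tails = list(c("C1A", "C2A", "C3A")), n_unsaturated_bonds = 1L),
    lipid_spec("LIPB", c("PO4", "GL1", "C1B", "C2B", "C3B"), "PO4",
               tails = list(c("C1B", "C2B", "C3B")), n_unsaturated_bonds = 0L)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

tiny_composition <- function(n_out = 60, n_in = 60, fa = 0.5) {
  composition(
    outer = data.frame(species = c("LIPA", "LIPB"), fraction = c(fa, 1 - fa),
                       count = c(round(fa * n_out), n_out - round(fa * n_out))),
    inner = data.frame(species = c("LIPA", "LIPB"), fraction = c(fa, 1 - fa),
                       count = c(round(fa * n_in), n_in - round(fa * n_in))))
}

# A flat bilayer frame built by hand: headgroups at z = z0 +/- gap/2.
flat_frame <- function(n_per_leaflet = 40, Lx = 20, Ly = 10, Lz = 20,
                       gap = 4, z0 = 10, species = "LIPA", seed = 1) {
  set.seed(seed)
  mk <- function(resid0, z) {
    data.frame(resid = as.integer(resid0 + seq_len(n_per_leaflet)), species = species,
               bead = "PO4", x = runif(n_per_leaflet, 0, Lx),
               y = runif(n_per_leaflet, 0, Ly), z = z)
  }
  membrane_frame(rbind(mk(0L, z0 + gap / 2), mk(n_per_leaflet, z0 - gap / 2)),
                 box = c(Lx, Ly, Lz))
}

# Synthetic curvature table with fully controlled bin counts.
hand_table <- function(curvatures, species, leaflet = "inner", frame = 1L) {
  tab <- data.frame(frame = frame, resid = seq_along(curvatures),
                    species = species, leaflet = leaflet,
                    x = seq_along(curvatures) * 0.01, curvature = curvatures,
                    stringsAsFactors = FALSE)
  class(tab) <- c("curvature_table", "data.frame")
  tab
}

expect_silent_warning_free <- function(expr) {
  expect_silent(suppressMessages(expr))
}

# Independent maximum-likelihood oracle for one imposed slope: given the
# generator's own placement probabilities p(sp | C) = f_sp (1 + s C) /
# (1 + f_sp s C) (single nonzero slope), estimate s from (species, C) pairs
# of one leaflet by direct likelihood maximization. Works from ground-truth
# curvature, with no binning, no spline and no enrichment normalization.
ml_slope_oracle <- function(species, C, target, frac_target) {
  is_t <- species == target
  nll <- function(s) {
    -(sum(log(pmax(1 + s * C[is_t], 1e-12))) -
        sum(log(pmax(1 + frac_target * s * C, 1e-12))))
  }
  optimize(nll, c(-5, 5))$minimum
}
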