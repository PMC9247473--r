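#' Define a curvature-sorting model for the synthetic generator
#'
#' Per (species, leaflet), a linear enrichment slope `s` (nm): at leaflet
#' curvature `C` (nm^-1, signed, outer-inverted convention) a lipid of
#' species `s` is placed with probability proportional to
#' `fraction_s * max(0, 1 + s * C)`. Slopes default to 0 (no sorting).
#'
#' @param slopes Data frame with columns `species`, `leaflet`, `slope`, or
#'   `NULL` for the all-zero model.
#' @param d2 Leaflet offset `d/2` from the midplane along the local normal
#'   (nm). Typical coarse-grained half-thickness.
#' @param sigma_z Gaussian z-noise of the placed headgroup bead (nm).
#' @param bead_spacing Spacing of the remaining beads laid along the inward
#'   local normal (nm).
#' @return Object of class `sorting_model`.
#' @export
sorting_model <- function(slopes = NULL, d2 = 2.0, sigma_z = 0.3,
                          bead_spacing = 0.3) {
  if (is.null(slopes)) {
    slopes <- data.frame(species = character(), leaflet = character(),
                         slope = numeric())
  } else {
    slopes <- as.data.frame(slopes)
    stopifnot(all(c("species", "leaflet", "slope") %in% names(slopes)))
    stopifnot(all(slopes$leaflet %in% c("outer", "inner")))
  }
  if (sigma_z < 0) stop("sigma_z must be >= 0")
  if (d2 <= 0) stop("d2 must be positive")
  structure(list(slopes = slopes, d2 = d2, sigma_z = sigma_z,
                 bead_spacing = bead_spacing),
            class = "sorting_model")
}

#' Per-species slopes for one leaflet, aligned to a species vector
#' @noRd
model_slopes_for <- function(model, species, leaflet) {
  s <- stats::setNames(rep(0, length(species)), species)
  sel <- model$slopes$leaflet == leaflet
  hit <- intersect(model$slopes$species[sel], species)
  if (length(hit)) {
    rows <- model$slopes[sel, ]
    s[hit] <- rows$slope[match(hit, rows$species)]
  }
  s
}

#' Sample one synthetic buckled-membrane frame
#'
#' Places the composition's lipids on the two leaflet surfaces of a buckled
#' midplane with known, analytic geometry and known curvature-dependent
#' sorting, producing both the coordinate frame and the generator's ground
#' truth (the oracle for recovery tests).
#'
#' Placement, per leaflet: the leaflet surface is the midplane offset by
#' `d/2` along the local unit normal; lipid positions are drawn uniformly in
#' arc length along that surface; species are assigned by a categorical draw
#' with probability proportional to `fraction * max(0, 1 + slope * C(x))`
#' (renormalized at each x), where `C` is the analytic signed leaflet
#' curvature; the headgroup bead sits on the surface with Gaussian z-noise
#' `sigma_z`, the remaining beads are laid along the inward normal at fixed
#' spacing; y is uniform in `[0, Ly)`. When every slope of a leaflet is
#' exactly 0, the composition's integer counts drive the assignment exactly
#' (a random permutation of the count vector), not a multinomial draw.
#' Deterministic given `seed`.
#'
#' @param profile A [make_buckle_profile()] object.
#' @param comp A [composition()] with explicit counts (or supply `totals`).
#' @param model A [sorting_model()].
#' @param seed Integer seed.
#' @param registry Species registry.
#' @param Ly,Lz Box lengths in y and z (nm); the membrane is centered at
#'   `Lz / 2`.
#' @param headgroup_only If `TRUE`, only the surface bead of each lipid is
#'   generated (sufficient for the curvature/sorting pipeline; much faster).
#' @param totals Leaflet totals for apportionment when counts are absent.
#' @return List with `frame` (a [membrane_frame()]) and `truth` (data frame
#'   `resid`, `species`, `leaflet`, `x`, `x_mid`, `curvature_true`), where
#'   `curvature_true` is the signed leaflet-surface curvature at the
#'   placement point (the sorting covariate the pipeline estimates) and `x`
#'   is the headgroup x coordinate.
#' @export
sample_frame <- function(profile, comp, model = sorting_model(), seed = 1L,
                         registry = plasma_registry(), Ly = 20, Lz = 20,
                         headgroup_only = FALSE, totals = NULL) {
  stopifnot(inherits(profile, "buckle_profile"), inherits(model, "sorting_model"))
  counts <- composition_counts(comp, totals)
  kmax <- profile$A * profile$k^2
  if (model$d2 * kmax >= 0.995)
    stop(sprintf("model inconsistency: leaflet offset d/2=%.2f self-intersects at gamma=%.2f (d2*max|curvature|=%.3f)",
                 model$d2, profile$gamma, model$d2 * kmax))
  set.seed(as.integer(seed))
  Xi <- profile$Xi
  # dense grid for arc-length CDF inversion and local geometry
  nx <- 4096L
  xg <- seq(0, Xi, length.out = nx + 1L)
  zg <- profile_height(profile, xg)
  dzg <- profile_dz(profile, xg)
  spd <- sqrt(1 + dzg^2)
  kap <- profile_curvature(profile, xg)

  res0 <- 0L
  beads_list <- list()
  truth_list <- list()
  for (lf in c("outer", "inner")) {
    sgn <- if (lf == "outer") 1 else -1
    cnt <- counts[[lf]]
    N <- sum(cnt$count)
    if (N <= 0) stop("leaflet ", lf, " has no lipids")
    h <- sgn * model$d2
    # offset-curve speed: |p'(x)| = speed_mid * (1 - h * kappa)
    w <- spd * (1 - h * kap)
    cdf <- cumsum((w[-1] + w[-length(w)]) / 2)
    cdf <- c(0, cdf / cdf[length(cdf)])
    u <- stats::runif(N)
    xm <- stats::approx(cdf, xg, xout = u, ties = "ordered")$y
    zm <- profile_height(profile, xm)
    dz <- profile_dz(profile, xm)
    sp1 <- sqrt(1 + dz^2)
    km <- profile_curvature(profile, xm)
    # signed leaflet curvature (outer sign inverted per the package convention)
    Ct <- if (lf == "outer") -km / (1 - model$d2 * km) else km / (1 + model$d2 * km)
    # unit upward normal (-z', 1)/speed; leaflet surface at +/- d/2
    nxv <- -dz / sp1
    nzv <- 1 / sp1
    xh <- xm + h * nxv
    zh <- zm + h * nzv

    slopes <- model_slopes_for(model, cnt$species, lf)
    frac <- cnt$count / N
    if (all(slopes == 0)) {
      species <- sample(rep.int(cnt$species, cnt$count))
    } else {
      P <- outer(Ct, slopes) + 1
      P[P < 0] <- 0
      P <- sweep(P, 2, frac, "*")
      rs <- rowSums(P)
      if (any(rs <= 0))
        stop("model inconsistency: all species probabilities 0 at some x (clipping)")
      P <- P / rs
      cp <- P
      for (j in 2:ncol(cp)) cp[, j] <- cp[, j] + cp[, j - 1]
      idx <- rowSums(stats::runif(N) > cp) + 1L
      species <- cnt$species[idx]
    }
    resid <- res0 + seq_len(N)
    yv <- stats::runif(N, 0, Ly)
    znoise <- if (model$sigma_z > 0) stats::rnorm(N, 0, model$sigma_z) else 0
    zhead <- zh + znoise

    if (headgroup_only) {
      hb <- headgroup_beads(registry)[species]
      beads_list[[lf]] <- data.frame(
        resid = resid, species = species, bead = unname(hb),
        x = xh %% Xi, y = yv, z = zhead + Lz / 2, stringsAsFactors = FALSE)
    } else {
      # beads laid inward from the surface: headgroup bead first, then the
      # remaining inventory at fixed spacing along -sgn * normal
      per_sp <- split(seq_len(N), species)
      sub <- lapply(names(per_sp), function(sp) {
        ii <- per_sp[[sp]]
        spec <- registry[[sp]]
        if (is.null(spec)) stop("species missing from registry: ", sp)
        bn <- c(spec$headgroup_bead, setdiff(spec$bead_names, spec$headgroup_bead))
        nb <- length(bn)
        depth <- (seq_len(nb) - 1L) * model$bead_spacing
        data.frame(
          resid = rep(resid[ii], each = nb),
          species = sp,
          bead = rep(bn, times = length(ii)),
          x = (rep(xh[ii], each = nb) - sgn * rep(nxv[ii], each = nb) * rep(depth, length(ii))) %% Xi,
          y = rep(yv[ii], each = nb),
          z = rep(zhead[ii], each = nb) - sgn * rep(nzv[ii], each = nb) * rep(depth, length(ii)) + Lz / 2,
          stringsAsFactors = FALSE)
      })
      beads_list[[lf]] <- do.call(rbind, sub)
    }
    truth_list[[lf]] <- data.frame(
      resid = resid, species = species, leaflet = lf,
      x = xh %% Xi, x_mid = xm %% Xi, curvature_true = Ct,
      stringsAsFactors = FALSE)
    res0 <- res0 + N
  }
  beads <- do.call(rbind, beads_list)
  rownames(beads) <- NULL
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(frame = membrane_frame(beads, box = c(Xi, Ly, Lz)), truth = truth)
}

#' Generate a synthetic trajectory of independent frames
#'
#' `n_frames` statistically independent [sample_frame()] draws. Per-frame
#' seeds are derived from the master seed by drawing them from the base RNG
#' seeded with `seed` (a fixed, documented splitting rule), so the whole
#' trajectory is reproducible bit-for-bit given the master seed.
#'
#' @inheritParams sample_frame
#' @param n_frames Number of frames, >= 1.
#' @param seed Master seed.
#' @return List with `frames` (list of [membrane_frame()]) and `truth` (one
#'   data frame with a leading `frame` column).
#' @export
generate_trajectory <- function(profile, comp, model = sorting_model(),
                                n_frames, seed = 1L,
                                registry = plasma_registry(), Ly = 20, Lz = 20,
                                headgroup_only = FALSE, totals = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  fseeds <- derive_frame_seeds(seed, n_frames)
  frames <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    smp <- sample_frame(profile, comp, model, seed = fseeds[i],
                        registry = registry, Ly = Ly, Lz = Lz,
                        headgroup_only = headgroup_only, totals = totals)
    frames[[i]] <- smp$frame
    truths[[i]] <- cbind(frame = i, smp$truth)
  }
  list(frames = frames, truth = do.call(rbind, truths))
}

#' Per-frame seeds derived from a master seed
#' @noRd
derive_frame_seeds <- function(seed, n_frames) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n_frames)
}

#' Write a trajectory to a directory of GRO files plus a ground-truth CSV
#'
#' One `frame_%04d.gro` per frame and `ground_truth.csv` with columns
#' `frame`, `resid`, `species`, `leaflet`, `x`, `x_mid`, `curvature_true`.
#'
#' @param traj Result of [generate_trajectory()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory_gro <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(traj$frames)) {
    write_gro(traj$frames[[i]], file.path(dir, sprintf("frame_%04d.gro", i)),
              title = sprintf("curvsort synthetic frame %d", i))
  }
  utils::write.csv(traj$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a directory of GRO frames as a trajectory
#' @param dir Directory containing `*.gro` files (sorted by name).
#' @return List of [membrane_frame()].
#' @export
read_trajectory_gro <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.gro$", full.names = TRUE))
  if (!length(files)) stop("no .gro files in ", dir)
  lapply(files, read_gro)
}
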