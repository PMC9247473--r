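#' Default pipeline configuration
#'
#' All analysis constants in one nested list: the geometry of the synthetic
#' system, the sorting-model parameters, and the fixed analysis constants
#' (curvature bin width 0.05 nm^-1, 5% occupancy mask, 4 blocks, 1.0 nm
#' contact cutoff, 0.1 nm^-1 extreme-curvature threshold, 1 nm localization
#' bin). Values can be overridden by a YAML config file
#' ([read_pipeline_config()]) or by function arguments.
#'
#' @param ... Named overrides of the form `section$key`, e.g.
#'   `analysis = list(bin_width = 0.1)`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    geometry = list(X0 = 40, Ly = 20, Lz = 20, gamma = 0.1,
                    d2 = 2.0, sigma_z = 0.3, bead_spacing = 0.3),
    analysis = list(bin_width = 0.05, occupancy_frac = 0.05, n_blocks = 4,
                    contact_cutoff = 1.0, extreme_threshold = 0.1,
                    x_bin = 1.0, leaflet_bin_width = 2.0, roughness = 0.5),
    generate = list(n_frames = 400, seed = 1, headgroup_only = FALSE),
    io = list(out_dir = "curvsort_out")
  )
  cfg <- merge_config(cfg, list(...), "")
  structure(cfg, class = "pipeline_config")
}

#' @noRd
merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    full <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[nm]])) {
      if (!is.list(over[[nm]])) stop("config key ", full, " must be a section")
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], full)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Generate frames and compute their curvature table in one streaming pass
#'
#' Equivalent to [generate_trajectory()] followed by
#' [per_lipid_curvature()], but frames are generated, analysed (leaflet
#' assignment from coordinates, spline fit, per-lipid signed curvature) and
#' discarded one at a time, so long trajectories do not need to be held in
#' memory. The generator's ground truth is returned alongside for recovery
#' comparisons.
#'
#' @inheritParams generate_trajectory
#' @param reuse_sp,k,roughness Passed to the curvature fit (see
#'   [per_lipid_curvature()]).
#' @return List with `curvature` (a curvature table) and `truth`.
#' @export
simulate_curvature_table <- function(profile, comp, model = sorting_model(),
                                     n_frames, seed = 1L,
                                     registry = plasma_registry(),
                                     Ly = 20, Lz = 20, reuse_sp = TRUE,
                                     k = NULL, roughness = 0.5) {
  fseeds <- derive_frame_seeds(seed, n_frames)
  tabs <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  sp_use <- list(outer = NULL, inner = NULL)
  for (i in seq_len(n_frames)) {
    smp <- sample_frame(profile, comp, model, seed = fseeds[i],
                        registry = registry, Ly = Ly, Lz = Lz,
                        headgroup_only = TRUE)
    fr <- assign_leaflets(smp$frame, registry)
    h <- headgroup_positions(fr, registry)
    lf <- unname(fr$leaflets[as.character(h$resid)])
    sides <- lapply(c("outer", "inner"), function(side) {
      cv <- fit_leaflet_spline(fr, side, registry, k = k,
                               sp = sp_use[[side]], roughness = roughness)
      if (reuse_sp && is.null(sp_use[[side]])) sp_use[[side]] <<- cv$sp
      sel <- lf == side
      C <- pointwise_curvature(cv, h$x[sel])
      if (side == "outer") C <- -C
      data.frame(frame = i, resid = h$resid[sel], species = h$species[sel],
                 leaflet = side, x = h$x[sel], curvature = C,
                 stringsAsFactors = FALSE)
    })
    tabs[[i]] <- do.call(rbind, sides)
    truths[[i]] <- cbind(frame = i, smp$truth)
  }
  curv <- do.call(rbind, tabs)
  class(curv) <- c("curvature_table", "data.frame")
  list(curvature = curv, truth = do.call(rbind, truths))
}

#' Run the full sorting analysis on a set of frames
#'
#' Orchestrates leaflet assignment, spline curvature, sorting statistics and
#' (optionally) contacts/descriptors, writing tidy CSV tables to a
#' directory: `curvature_table.csv`, `distributions.csv`, `enrichment.csv`,
#' `slopes.csv`, `means.csv`, `extreme_fractions.csv`, `localization.csv`
#' and, when `contacts = TRUE`, `contacts_<leaflet>.csv` and
#' `descriptors.csv`.
#'
#' @param frames List of [membrane_frame()], or a directory of `.gro` files.
#' @param out_dir Output directory.
#' @param registry Species registry.
#' @param cfg A [pipeline_config()].
#' @param contacts Also compute contact matrices and dynamic descriptors
#'   (requires full-bead frames).
#' @return Invisibly, a list with the in-memory results.
#' @export
analyze_frames <- function(frames, out_dir, registry = plasma_registry(),
                           cfg = pipeline_config(), contacts = FALSE) {
  if (is.character(frames)) frames <- read_trajectory_gro(frames)
  an <- cfg$analysis
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- per_lipid_curvature(frames, registry, k = NULL,
                             roughness = an$roughness,
                             leaflet_bin_width = an$leaflet_bin_width)
  write_curvature_table(tab, file.path(out_dir, "curvature_table.csv"))
  dist <- leaflet_curvature_distribution(tab, an$bin_width, an$n_blocks)
  utils::write.csv(dist, file.path(out_dir, "distributions.csv"), row.names = FALSE)
  enr <- list(); slp <- list()
  for (lf in intersect(c("outer", "inner"), unique(tab$leaflet))) {
    pr <- enrichment_profile(tab, lf, an$bin_width, an$occupancy_frac, an$n_blocks)
    enr[[lf]] <- pr
    s <- partition_slope(pr)
    s$leaflet <- lf
    slp[[lf]] <- s
  }
  enr_tidy <- do.call(rbind, lapply(enr, function(pr) {
    data.frame(leaflet = pr$leaflet,
               species = rep(pr$species, times = length(pr$centers)),
               bin_center = rep(pr$centers, each = length(pr$species)),
               enrichment = as.vector(pr$F),
               masked = rep(!pr$mask, each = length(pr$species)))
  }))
  utils::write.csv(enr_tidy, file.path(out_dir, "enrichment.csv"), row.names = FALSE)
  slopes <- do.call(rbind, slp)
  utils::write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)
  means <- mean_curvature_per_species(tab, an$n_blocks)
  utils::write.csv(means, file.path(out_dir, "means.csv"), row.names = FALSE)
  extr <- extreme_fraction(tab, an$extreme_threshold, an$n_blocks)
  utils::write.csv(extr, file.path(out_dir, "extreme_fractions.csv"), row.names = FALSE)
  loc <- localization_profile(tab, Lx = frames[[1]]$box[1], x_bin = an$x_bin)
  utils::write.csv(loc, file.path(out_dir, "localization.csv"), row.names = FALSE)
  res <- list(curvature = tab, distributions = dist, enrichment = enr,
              slopes = slopes, means = means, extreme = extr,
              localization = loc)
  if (contacts) {
    cm <- lapply(c("outer", "inner"), function(lf)
      contact_matrix(frames, lf, registry, an$contact_cutoff, an$n_blocks))
    names(cm) <- c("outer", "inner")
    for (lf in names(cm))
      utils::write.csv(as.data.frame(cm[[lf]]$normalized),
                       file.path(out_dir, paste0("contacts_", lf, ".csv")))
    desc <- descriptor_table(registry, frames, n_blocks = an$n_blocks)
    utils::write.csv(desc, file.path(out_dir, "descriptors.csv"), row.names = FALSE)
    res$contacts <- cm
    res$descriptors <- desc
  }
  invisible(res)
}

#' Impose known partition slopes, run the pipeline, report the recovery
#'
#' One-shot generate + analyze + compare: synthetic frames are generated
#' with the given enrichment slopes as ground truth, the full pipeline
#' (leaflet assignment, spline curvature, binned enrichment with occupancy
#' mask, per-block OLS) recovers the slopes, and a per-species report of
#' imposed vs recovered slope, block SD and bias is returned.
#'
#' @param imposed Data frame `species`, `leaflet`, `slope`.
#' @param gamma Compressional strain of the synthetic system.
#' @param n_frames Number of independent frames.
#' @param seed Master seed.
#' @param comp Composition (defaults to the bundled asymmetric plasma
#'   membrane).
#' @param registry Species registry.
#' @param cfg A [pipeline_config()] (geometry and analysis constants).
#' @return Data frame `species`, `leaflet`, `imposed`, `recovered`, `sd`,
#'   `bias`, with attribute `"curvature"` carrying the curvature table.
#' @export
recover_slopes <- function(imposed, gamma = 0.1, n_frames = 400, seed = 1L,
                           comp = plasma_composition(),
                           registry = plasma_registry(),
                           cfg = pipeline_config()) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  imposed <- as.data.frame(imposed)
  stopifnot(all(c("species", "leaflet", "slope") %in% names(imposed)))
  geo <- cfg$geometry; an <- cfg$analysis
  profile <- make_buckle_profile(geo$X0, gamma)
  model <- sorting_model(imposed, d2 = geo$d2, sigma_z = geo$sigma_z,
                         bead_spacing = geo$bead_spacing)
  sim <- simulate_curvature_table(profile, comp, model, n_frames, seed,
                                  registry, Ly = geo$Ly, Lz = geo$Lz,
                                  roughness = an$roughness)
  res <- lapply(seq_len(nrow(imposed)), function(i) {
    lf <- imposed$leaflet[i]
    pr <- enrichment_profile(sim$curvature, lf, an$bin_width,
                             an$occupancy_frac, an$n_blocks)
    s <- partition_slope(pr, imposed$species[i])
    data.frame(species = imposed$species[i], leaflet = lf,
               imposed = imposed$slope[i], recovered = s$slope, sd = s$sd,
               bias = s$slope - imposed$slope[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "curvature") <- sim$curvature
  attr(out, "truth") <- sim$truth
  out
}
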