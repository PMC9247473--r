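#' Intra-leaflet lipid-lipid contact matrix
#'
#' An unordered pair of distinct lipids of the same leaflet is in contact in
#' a frame if ANY bead-bead distance between them is below the cutoff
#' (minimum-image convention in x and y). Raw per-species-pair contact
#' counts are averaged over frames and normalized by the random-mixing
#' expectation `E(i,j) = T * f_i * f_j * (2 - delta_ij)`, where `T` is the
#' total mean contact count and `f` the leaflet composition fractions, so
#' ideal mixing gives 1 in every cell.
#'
#' @param frames List of [membrane_frame()] (leaflets are assigned if
#'   missing).
#' @param leaflet `"outer"` or `"inner"`.
#' @param registry Species registry.
#' @param cutoff Contact cutoff (nm, default 1.0); must be below half the
#'   smallest lateral box edge.
#' @param n_blocks Number of blocks for the across-block SD (default 4; use
#'   1 for a single estimate).
#' @return Object of class `contact_matrix`: `species`, `raw` (mean contacts
#'   per frame), `normalized`, `sd` (block SD of the normalized values),
#'   `total` (mean total contacts), `fractions`.
#' @export
contact_matrix <- function(frames, leaflet = c("outer", "inner"),
                           registry = plasma_registry(), cutoff = 1.0,
                           n_blocks = 4L) {
  leaflet <- match.arg(leaflet)
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  if (cutoff <= 0) stop("cutoff must be positive")
  species <- NULL
  per_frame <- vector("list", length(frames))
  frac_acc <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.null(fr$leaflets)) fr <- assign_leaflets(fr, registry)
    if (cutoff > min(fr$box[1:2]) / 2)
      stop("cutoff larger than half the smallest lateral box edge (minimum-image violation)")
    lf <- bead_leaflets(fr)
    b <- fr$beads[lf == leaflet, ]
    if (!nrow(b)) stop("leaflet '", leaflet, "' is empty")
    sp_of_res <- tapply(b$species, b$resid, `[`, 1)
    if (is.null(species)) species <- sort(unique(unname(sp_of_res)))
    pairs <- contact_pairs(b, fr$box, cutoff)
    M <- matrix(0, length(species), length(species),
                dimnames = list(species, species))
    if (nrow(pairs)) {
      si <- unname(sp_of_res[as.character(pairs$ri)])
      sj <- unname(sp_of_res[as.character(pairs$rj)])
      a <- pmin(si, sj); bb <- pmax(si, sj)
      tt <- table(factor(a, levels = species), factor(bb, levels = species))
      M <- unclass(tt)
      M <- M + t(M) - diag(diag(M))   # symmetric; self-pairs counted once
    }
    per_frame[[i]] <- M
    fr_frac <- tabulate(factor(unname(sp_of_res), levels = species),
                        nbins = length(species)) / length(sp_of_res)
    frac_acc <- if (is.null(frac_acc)) fr_frac else frac_acc + fr_frac
  }
  f <- frac_acc / length(frames)
  names(f) <- species
  raw <- Reduce(`+`, per_frame) / length(frames)
  norm_of <- function(M) {
    Tt <- (sum(M) + sum(diag(M))) / 2  # total over unordered pairs
    E <- Tt * outer(f, f) * (2 - diag(length(species)))
    out <- M / E
    out[E == 0] <- NA
    out
  }
  normalized <- norm_of(raw)
  sdm <- matrix(NA_real_, length(species), length(species),
                dimnames = list(species, species))
  if (n_blocks > 1 && length(frames) >= n_blocks) {
    nper <- length(frames) %/% n_blocks
    bn <- lapply(seq_len(n_blocks), function(bk) {
      idx <- ((bk - 1) * nper + 1):(bk * nper)
      norm_of(Reduce(`+`, per_frame[idx]) / nper)
    })
    arr <- simplify2array(bn)
    sdm <- apply(arr, c(1, 2), stats::sd)
  }
  structure(list(leaflet = leaflet, species = species, raw = raw,
                 normalized = normalized, sd = sdm, fractions = f,
                 total = (sum(raw) + sum(diag(raw))) / 2, cutoff = cutoff),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s leaflet, cutoff %.1f nm, %.1f mean contacts/frame\n",
              x$leaflet, x$cutoff, x$total))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Lipid pairs with any bead-bead distance below cutoff (one leaflet)
#'
#' Cell-list neighbour search in x,y with periodic minimum image laterally;
#' z is treated as open.
#' @noRd
contact_pairs <- function(beads, box, cutoff) {
  n <- nrow(beads)
  Lx <- box[1]; Ly <- box[2]
  x <- beads$x %% Lx; y <- beads$y %% Ly; z <- beads$z
  ncx <- max(1L, floor(Lx / cutoff)); ncy <- max(1L, floor(Ly / cutoff))
  pair_hits <- function(ii, jj, same) {
    if (!length(ii) || !length(jj)) return(NULL)
    g <- expand.grid(i = ii, j = jj)
    if (same) g <- g[g$i < g$j, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    dx <- x[g$i] - x[g$j]; dx <- dx - Lx * round(dx / Lx)
    dy <- y[g$i] - y[g$j]; dy <- dy - Ly * round(dy / Ly)
    dz <- z[g$i] - z[g$j]
    hit <- dx * dx + dy * dy + dz * dz < cutoff^2
    hit <- hit & beads$resid[g$i] != beads$resid[g$j]
    if (!any(hit)) return(NULL)
    data.frame(ri = beads$resid[g$i[hit]], rj = beads$resid[g$j[hit]])
  }
  if (ncx < 3L || ncy < 3L) {
    hits <- pair_hits(seq_len(n), seq_len(n), same = TRUE)
  } else {
    cx <- pmin(floor(x / (Lx / ncx)), ncx - 1L)
    cy <- pmin(floor(y / (Ly / ncy)), ncy - 1L)
    cell <- cx + ncx * cy
    members <- split(seq_len(n), cell)
    keys <- as.integer(names(members))
    # half-shell of neighbour offsets avoids double counting across cells
    offs <- cbind(dx = c(0, 1, 1, 0, 1), dy = c(0, 0, 1, 1, -1))
    acc <- list()
    for (ci in seq_along(members)) {
      kx <- keys[ci] %% ncx; ky <- keys[ci] %/% ncx
      for (o in seq_len(nrow(offs))) {
        nkx <- (kx + offs[o, 1]) %% ncx
        nky <- (ky + offs[o, 2]) %% ncy
        nkey <- nkx + ncx * nky
        same <- nkey == keys[ci]
        jj <- members[[as.character(nkey)]]
        if (is.null(jj)) next
        h <- pair_hits(members[[ci]], jj, same = same)
        if (!is.null(h)) acc[[length(acc) + 1L]] <- h
      }
    }
    hits <- if (length(acc)) do.call(rbind, acc) else NULL
  }
  if (is.null(hits)) return(data.frame(ri = integer(), rj = integer()))
  a <- pmin(hits$ri, hits$rj); b <- pmax(hits$ri, hits$rj)
  unique(data.frame(ri = a, rj = b))
}

#' Acyl-tail P2 order parameter per species
#'
#' `P2 = <(3 cos^2 theta - 1) / 2>` over all consecutive tail-bead bonds,
#' with theta measured against the membrane normal, averaged over lipids and
#' frames, block-averaged. By default the normal is the local leaflet normal
#' obtained from the fitted leaflet spline (the tangent rotated 90 degrees
#' in the XZ plane); on a flat membrane this reduces to the global z axis.
#'
#' @param frames List of [membrane_frame()].
#' @param registry Species registry.
#' @param species Species to include (default: all with >= 1 tail of >= 2
#'   beads).
#' @param normal `"local"` (spline normal) or `"z"` (global z axis).
#' @param n_blocks Number of blocks (default 4; 1 for a single estimate).
#' @return Data frame `species`, `p2`, `sd`, `n_blocks`.
#' @export
tail_order_parameter <- function(frames, registry = plasma_registry(),
                                 species = NULL, normal = c("local", "z"),
                                 n_blocks = 4L) {
  normal <- match.arg(normal)
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  if (is.null(species)) {
    ok <- vapply(registry, function(s)
      length(s$tails) >= 1 && any(lengths(s$tails) >= 2), TRUE)
    species <- names(registry)[ok]
  }
  per_frame <- lapply(frames, function(fr) {
    if (is.null(fr$leaflets)) fr <- assign_leaflets(fr, registry)
    nrm <- lipid_normals(fr, registry, normal)
    vapply(species, function(sp) {
      bonds <- tail_bond_vectors(fr, registry, sp)
      if (is.null(bonds)) return(NA_real_)
      nmat <- nrm[match(bonds$resid, nrm$resid), c("nx", "ny", "nz")]
      blen <- sqrt(bonds$bx^2 + bonds$by^2 + bonds$bz^2)
      keep <- blen > 1e-12
      if (!all(keep)) warning("zero-length bond vector(s) skipped")
      ct <- (bonds$bx * nmat$nx + bonds$by * nmat$ny + bonds$bz * nmat$nz)[keep] /
        blen[keep]
      mean((3 * ct^2 - 1) / 2)
    }, numeric(1))
  })
  mat <- do.call(rbind, per_frame)
  summarize_per_frame(mat, species, "p2", n_blocks)
}

#' Mean splay angle between the two acyl tails per species
#'
#' Per lipid and frame, the angle (degrees) between the two tail end-to-end
#' vectors (first tail bead to last tail bead of each tail), averaged over
#' lipids and frames with block statistics. Species without exactly two
#' tails (e.g. cholesterol) get `NA` with `applicable = FALSE`.
#'
#' @inheritParams tail_order_parameter
#' @return Data frame `species`, `splay_deg`, `sd`, `n_blocks`,
#'   `applicable`.
#' @export
splay_angle <- function(frames, registry = plasma_registry(), species = NULL,
                        n_blocks = 4L) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  if (is.null(species)) species <- names(registry)
  two_tailed <- vapply(species, function(sp)
    length(registry[[sp]]$tails) == 2, TRUE)
  per_frame <- lapply(frames, function(fr) {
    vapply(species, function(sp) {
      if (!two_tailed[sp]) return(NA_real_)
      v <- tail_end_vectors(fr, registry, sp)
      if (is.null(v)) return(NA_real_)
      dot <- rowSums(v$t1 * v$t2)
      cosang <- dot / (sqrt(rowSums(v$t1^2)) * sqrt(rowSums(v$t2^2)))
      mean(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
    }, numeric(1))
  })
  mat <- do.call(rbind, per_frame)
  out <- summarize_per_frame(mat, species, "splay_deg", n_blocks)
  out$applicable <- unname(two_tailed[out$species])
  out
}

#' @noRd
summarize_per_frame <- function(mat, species, value_name, n_blocks) {
  res <- lapply(seq_along(species), function(j) {
    v <- mat[, j]
    if (all(is.na(v))) {
      d <- data.frame(species = species[j], value = NA_real_, sd = NA_real_,
                      n_blocks = 0L)
    } else if (length(v) >= n_blocks && n_blocks > 1) {
      bs <- block_average(v, n_blocks)
      d <- data.frame(species = species[j], value = bs$mean, sd = bs$sd,
                      n_blocks = n_blocks)
    } else {
      d <- data.frame(species = species[j], value = mean(v, na.rm = TRUE),
                      sd = NA_real_, n_blocks = 1L)
    }
    d
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "value"] <- value_name
  rownames(out) <- NULL
  out
}

#' Local leaflet normal at each lipid's headgroup position
#' @noRd
lipid_normals <- function(frame, registry, normal = "local") {
  h <- headgroup_positions(frame, registry)
  if (normal == "z") {
    return(data.frame(resid = h$resid, nx = 0, ny = 0, nz = 1))
  }
  lf <- unname(frame$leaflets[as.character(h$resid)])
  out <- h[, "resid", drop = FALSE]
  out$nx <- 0; out$ny <- 0; out$nz <- 1
  for (side in unique(lf)) {
    cv <- fit_leaflet_spline(frame, side, registry)
    sel <- lf == side
    d <- curve_eval(cv, h$x[sel])
    nn <- sqrt(1 + d$f1^2)
    out$nx[sel] <- -d$f1 / nn
    out$nz[sel] <- 1 / nn
  }
  out
}

#' Consecutive tail-bond vectors for all lipids of one species
#' @noRd
tail_bond_vectors <- function(frame, registry, sp) {
  spec <- registry[[sp]]
  if (is.null(spec)) stop("species missing from registry: ", sp)
  b <- frame$beads[frame$beads$species == sp, ]
  if (!nrow(b)) return(NULL)
  pos <- stats::setNames(seq_len(nrow(b)), paste(b$resid, b$bead))
  acc <- list()
  for (tl in spec$tails) {
    if (length(tl) < 2) next
    for (q in seq_len(length(tl) - 1L)) {
      rids <- unique(b$resid)
      i1 <- pos[paste(rids, tl[q])]
      i2 <- pos[paste(rids, tl[q + 1L])]
      ok <- !is.na(i1) & !is.na(i2)
      if (!any(ok)) next
      acc[[length(acc) + 1L]] <- data.frame(
        resid = rids[ok],
        bx = b$x[i2[ok]] - b$x[i1[ok]],
        by = b$y[i2[ok]] - b$y[i1[ok]],
        bz = b$z[i2[ok]] - b$z[i1[ok]])
    }
  }
  if (!length(acc)) return(NULL)
  do.call(rbind, acc)
}

#' Tail end-to-end vectors (two-tailed species)
#' @noRd
tail_end_vectors <- function(frame, registry, sp) {
  spec <- registry[[sp]]
  b <- frame$beads[frame$beads$species == sp, ]
  if (!nrow(b)) return(NULL)
  pos <- stats::setNames(seq_len(nrow(b)), paste(b$resid, b$bead))
  rids <- unique(b$resid)
  vecs <- lapply(spec$tails, function(tl) {
    i1 <- pos[paste(rids, tl[1])]
    i2 <- pos[paste(rids, tl[length(tl)])]
    cbind(b$x[i2] - b$x[i1], b$y[i2] - b$y[i1], b$z[i2] - b$z[i1])
  })
  ok <- stats::complete.cases(vecs[[1]]) & stats::complete.cases(vecs[[2]])
  if (!any(ok)) return(NULL)
  list(t1 = vecs[[1]][ok, , drop = FALSE], t2 = vecs[[2]][ok, , drop = FALSE])
}

#' Static (and optionally dynamic) per-species descriptor table
#'
#' Static descriptors from the registry: bead count (a molecular-volume
#' proxy), head:tail bead ratio, and unsaturation fraction (unsaturated tail
#' bonds / tail bonds). When frames are supplied, the dynamic descriptors
#' (P2 tail order parameter and mean splay angle) are attached.
#'
#' @param registry Species registry.
#' @param frames Optional list of [membrane_frame()].
#' @param ... Passed to [tail_order_parameter()] / [splay_angle()].
#' @return Data frame, one row per species.
#' @export
descriptor_table <- function(registry, frames = NULL, ...) {
  out <- do.call(rbind, lapply(registry, function(s) {
    if (s$n_tail_beads == 0)
      stop("missing head/tail partition for species ", s$name)
    data.frame(
      species = s$name,
      n_beads = length(s$bead_names),
      n_head_beads = s$n_head_beads,
      n_tail_beads = s$n_tail_beads,
      head_tail_ratio = s$n_head_beads / s$n_tail_beads,
      unsaturation_fraction = if (s$n_tail_bonds > 0)
        s$n_unsaturated_bonds / s$n_tail_bonds else 0)
  }))
  rownames(out) <- NULL
  if (!is.null(frames)) {
    p2 <- tail_order_parameter(frames, registry, ...)
    sa <- splay_angle(frames, registry, ...)
    out$p2 <- p2$p2[match(out$species, p2$species)]
    out$splay_deg <- sa$splay_deg[match(out$species, sa$species)]
  }
  out
}

#' Pearson correlation between per-species mean curvature and a descriptor
#'
#' Values are matched by species name; species in `exclude` are removed
#' before computing. At least 3 paired values are required and both vectors
#' must have nonzero variance.
#'
#' @param mean_curvatures Named numeric vector (species -> mean curvature).
#' @param descriptor Named numeric vector (species -> descriptor value).
#' @param exclude Character vector of species to exclude (e.g. `"CHOL"`).
#' @return Pearson correlation coefficient.
#' @export
curvature_descriptor_correlation <- function(mean_curvatures, descriptor,
                                             exclude = character()) {
  common <- setdiff(intersect(names(mean_curvatures), names(descriptor)),
                    exclude)
  if (length(common) < 3)
    stop("fewer than 3 paired species after exclusion")
  x <- mean_curvatures[common]; y <- descriptor[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}
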