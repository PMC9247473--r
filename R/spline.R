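#' Fit a periodic smoothing spline to a leaflet's headgroup positions
#'
#' All headgroup (x, z) pairs of one leaflet (y collapsed; the buckle is
#' uniaxial) are fitted by a penalized cyclic cubic regression spline
#' (`mgcv`, basis `"cc"`), giving a C2-continuous periodic height function
#' f(x) on `[0, Lx)`. The smoothing parameter is chosen by GCV unless given;
#' duplicate or near-duplicate x values are handled by the penalized solver
#' without special treatment. A residual RMS much larger than the expected
#' surface roughness (`> 5 * roughness`) flags the frame with a warning but
#' does not drop it.
#'
#' @param frame A [membrane_frame()] with leaflets assigned (see
#'   [assign_leaflets()]), or a data frame with columns `x`, `z` (then
#'   `leaflet`/`registry` are ignored and `Lx` is required).
#' @param leaflet `"outer"` or `"inner"`.
#' @param registry Species registry (for the surface bead of each species).
#' @param k Spline basis dimension; default one knot per 1.5 nm, clamped to
#'   `[10, 40]`.
#' @param sp Smoothing parameter; `NULL` for GCV selection.
#' @param periodic Fit with periodic end conditions (the default; set
#'   `FALSE` to fit an open curve, e.g. an arc segment).
#' @param roughness Expected residual scale (nm) used only for the QC
#'   warning threshold.
#' @param Lx Domain length when `frame` is a raw data frame.
#' @return Object of class `leaflet_curve`: the fit plus diagnostics
#'   (`rms`, `k`, `sp`, `n`).
#' @export
fit_leaflet_spline <- function(frame, leaflet = c("outer", "inner"),
                               registry = plasma_registry(), k = NULL,
                               sp = NULL, periodic = TRUE, roughness = 0.5,
                               Lx = NULL) {
  if (inherits(frame, "membrane_frame")) {
    leaflet <- match.arg(leaflet)
    h <- headgroup_positions(frame, registry)
    lf <- frame$leaflets
    if (is.null(lf)) stop("leaflets not assigned; call assign_leaflets()")
    h <- h[unname(lf[as.character(h$resid)]) == leaflet, ]
    Lx <- frame$box[1]
    pts <- data.frame(x = h$x, z = h$z)
  } else {
    pts <- as.data.frame(frame)[, c("x", "z")]
    leaflet <- if (is.character(leaflet)) leaflet[1] else NA_character_
    if (is.null(Lx)) stop("Lx required when fitting raw points")
  }
  if (nrow(pts) < 20) stop("too few headgroup beads to fit a leaflet spline (need >= 20)")
  pts$x <- pts$x %% Lx
  if (is.null(k)) k <- max(10L, min(40L, as.integer(round(Lx / 1.5))))
  bs <- if (periodic) "cc" else "cr"
  knots <- if (periodic) list(x = seq(0, Lx, length.out = k)) else NULL
  fit <- mgcv::gam(z ~ s(x, bs = bs, k = k), data = pts, knots = knots,
                   sp = sp, method = "GCV.Cp")
  rms <- sqrt(mean(stats::residuals(fit)^2))
  if (rms > 5 * roughness)
    warning(sprintf("leaflet spline residual RMS %.3f nm exceeds 5 x roughness scale (%.2f nm); frame flagged",
                    rms, roughness))
  structure(list(fit = fit, Lx = Lx, leaflet = leaflet, periodic = periodic,
                 k = k, sp = fit$sp, rms = rms, n = nrow(pts)),
            class = "leaflet_curve")
}

#' @export
print.leaflet_curve <- function(x, ...) {
  cat(sprintf("<leaflet_curve> %s: n=%d, k=%d, sp=%.3g, residual RMS=%.3f nm%s\n",
              x$leaflet, x$n, x$k, x$sp, x$rms,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Evaluate a fitted leaflet curve and its derivatives
#'
#' Returns f, f' and f'' at the requested x (wrapped into the periodic
#' domain). Derivatives are computed exactly on the spline basis by central
#' differencing of the linear-predictor matrix with a small step.
#'
#' @param curve A [fit_leaflet_spline()] object.
#' @param x Positions (nm).
#' @param h Differencing step (nm).
#' @return List with numeric vectors `f`, `f1`, `f2`.
#' @export
curve_eval <- function(curve, x, h = 1e-3) {
  wrap <- function(v) if (curve$periodic) v %% curve$Lx else v
  n <- length(x)
  xx <- wrap(c(x, x + h, x - h))
  b <- stats::coef(curve$fit)
  v <- as.numeric(mgcv::predict.gam(curve$fit, newdata = data.frame(x = xx),
                                    type = "lpmatrix") %*% b)
  f <- v[seq_len(n)]; fp <- v[n + seq_len(n)]; fm <- v[2 * n + seq_len(n)]
  list(f = f, f1 = (fp - fm) / (2 * h), f2 = (fp - 2 * f + fm) / h^2)
}

#' Pointwise curvature of a fitted leaflet curve
#'
#' The raw (not leaflet-sign-adjusted) pointwise curvature
#' `C(x) = f''(x) / (1 + f'(x)^2)^(3/2)` in nm^-1.
#'
#' @inheritParams curve_eval
#' @return Numeric vector of curvatures (nm^-1).
#' @export
pointwise_curvature <- function(curve, x, h = 1e-3) {
  d <- curve_eval(curve, x, h = h)
  d$f2 / (1 + d$f1^2)^1.5
}

#' Per-lipid signed curvature table for a trajectory
#'
#' For every lipid in every frame: fit the two leaflet splines, evaluate the
#' pointwise curvature at the lipid's own headgroup x on its own leaflet's
#' curve, and invert the sign for outer-leaflet lipids so that concave and
#' convex regions (seen from each leaflet's side) are negative and positive
#' respectively. Unfittable frames are skipped with a warning; more than 10%
#' skipped frames is an error.
#'
#' @param frames A list of [membrane_frame()] (or a single frame).
#' @param registry Species registry.
#' @param sp Smoothing parameters, numeric length-2 `(outer, inner)` or
#'   `NULL`.
#' @param reuse_sp If `TRUE` (default) and `sp` is `NULL`, the smoothing
#'   parameter is selected by GCV on the first frame and held fixed for the
#'   remaining frames (stabilizes the fit across frames and is much faster);
#'   `FALSE` reselects per frame.
#' @param k,roughness Passed to [fit_leaflet_spline()].
#' @param leaflet_bin_width Passed to [assign_leaflets()] for frames without
#'   labels.
#' @return A `curvature_table`: data frame `frame`, `resid`, `species`,
#'   `leaflet`, `x`, `curvature` (signed, nm^-1), one row per lipid per
#'   retained frame.
#' @export
per_lipid_curvature <- function(frames, registry = plasma_registry(),
                                sp = NULL, reuse_sp = TRUE, k = NULL,
                                roughness = 0.5, leaflet_bin_width = 2.0) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  n <- length(frames)
  sp_use <- if (!is.null(sp)) stats::setNames(as.list(sp), c("outer", "inner"))
            else list(outer = NULL, inner = NULL)
  out <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    res <- tryCatch({
      if (is.null(fr$leaflets))
        fr <- assign_leaflets(fr, registry, bin_width = leaflet_bin_width)
      h <- headgroup_positions(fr, registry)
      lf <- unname(fr$leaflets[as.character(h$resid)])
      tabs <- lapply(c("outer", "inner"), function(side) {
        cv <- fit_leaflet_spline(fr, side, registry, k = k,
                                 sp = sp_use[[side]], roughness = roughness)
        if (reuse_sp && is.null(sp_use[[side]]))
          sp_use[[side]] <<- cv$sp
        sel <- lf == side
        C <- pointwise_curvature(cv, h$x[sel])
        if (side == "outer") C <- -C
        data.frame(frame = i, resid = h$resid[sel], species = h$species[sel],
                   leaflet = side, x = h$x[sel], curvature = C,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, tabs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(res)))
      out[[i]] <- NULL
    } else out[[i]] <- res
  }
  if (skipped > 0.1 * n)
    stop(sprintf("%d of %d frames unfittable (> 10%%)", skipped, n))
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("curvature_table", "data.frame")
  tab
}

#' Write / read a curvature table as CSV
#' @param tab A curvature table from [per_lipid_curvature()].
#' @param path CSV path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_curvature_table <- function(tab, path) {
  out <- data.frame(frame = tab$frame, residue_id = tab$resid,
                    species = tab$species, leaflet = tab$leaflet,
                    x_nm = tab$x, curvature_per_nm = tab$curvature)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curvature_table
#' @export
read_curvature_table <- function(path) {
  d <- utils::read.csv(path)
  tab <- data.frame(frame = d$frame, resid = d$residue_id, species = d$species,
                    leaflet = d$leaflet, x = d$x_nm, curvature = d$curvature_per_nm,
                    stringsAsFactors = FALSE)
  class(tab) <- c("curvature_table", "data.frame")
  tab
}
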