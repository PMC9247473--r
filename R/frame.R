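#' Construct a membrane frame
#'
#' One coarse-grained configuration: a bead table with residue (lipid)
#' identity and 3D positions in nm, plus an orthorhombic box. Leaflet labels
#' (outer/inner per residue) are attached by [assign_leaflets()].
#'
#' @param beads Data frame with columns `resid` (integer), `species`,
#'   `bead`, `x`, `y`, `z` (nm).
#' @param box Numeric length-3, `(Lx, Ly, Lz)` in nm, all > 0.
#' @param time Optional time stamp in ns (metadata only).
#' @param leaflets Optional named character vector residue id -> `"outer"` /
#'   `"inner"`.
#' @return Object of class `membrane_frame`.
#' @export
membrane_frame <- function(beads, box, time = NA_real_, leaflets = NULL) {
  beads <- as.data.frame(beads)
  req <- c("resid", "species", "bead", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("beads must have columns ", paste(req, collapse = ", "))
  if (!all(is.finite(beads$x) & is.finite(beads$y) & is.finite(beads$z)))
    stop("non-finite bead position")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (nm)")
  sp_per_res <- tapply(beads$species, beads$resid, function(s) length(unique(s)))
  if (any(sp_per_res > 1))
    stop("residue with inconsistent species labels: ",
         names(sp_per_res)[which(sp_per_res > 1)[1]])
  structure(list(beads = beads, box = box, time = time, leaflets = leaflets),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> %d beads, %d residues, box %.2f x %.2f x %.2f nm%s\n",
              nrow(x$beads), length(unique(x$beads$resid)),
              x$box[1], x$box[2], x$box[3],
              if (is.null(x$leaflets)) "" else ", leaflets assigned"))
  invisible(x)
}

#' Extract headgroup bead records of a frame
#'
#' One row per lipid: the bead designated as that species' surface bead in
#' the registry, with x wrapped into `[0, Lx)`.
#'
#' @param frame A [membrane_frame()].
#' @param registry Species registry (named list of [lipid_spec()]).
#' @return Data frame `resid`, `species`, `x`, `y`, `z`.
#' @export
headgroup_positions <- function(frame, registry) {
  b <- frame$beads
  hb <- headgroup_beads(registry)
  unknown <- setdiff(unique(b$species), names(hb))
  if (length(unknown))
    stop("species missing from registry: ", paste(unknown, collapse = ", "))
  keep <- b$bead == unname(hb[b$species])
  h <- b[keep, c("resid", "species", "x", "y", "z")]
  if (anyDuplicated(h$resid))
    stop("residue with more than one surface bead")
  h$x <- h$x %% frame$box[1]
  h
}

#' Assign lipids to leaflets on a (possibly buckled) membrane
#'
#' Labels every residue `outer` or `inner` by comparing its headgroup bead
#' height to a local midplane. Because a buckled membrane's leaflets
#' interleave in global z, the midplane is local: headgroup z values are
#' averaged in x bins (default 2 nm wide, periodic) and the per-bin means are
#' interpolated at each lipid's x. Labels are recomputed per frame; species
#' such as cholesterol may change leaflets between frames.
#'
#' @param frame A [membrane_frame()].
#' @param registry Species registry.
#' @param bin_width Width of the x bins used for the local midplane (nm).
#' @return The frame with `$leaflets` set (named character vector,
#'   residue id -> `"outer"`/`"inner"`).
#' @export
assign_leaflets <- function(frame, registry, bin_width = 2.0) {
  h <- headgroup_positions(frame, registry)
  if (nrow(h) < 2) stop("need at least 2 residues with headgroup beads")
  Lx <- frame$box[1]
  nb <- max(3L, as.integer(round(Lx / bin_width)))
  w <- Lx / nb
  bin <- pmin(floor(h$x / w), nb - 1L)
  mid <- tapply(h$z, factor(bin, levels = 0:(nb - 1L)), mean)
  centers <- (0:(nb - 1L) + 0.5) * w
  ok <- !is.na(mid)
  if (sum(ok) < 2) stop("degenerate membrane: too few occupied x bins")
  # periodic linear interpolation of the binned midplane at each lipid x
  cx <- c(centers[ok] - Lx, centers[ok], centers[ok] + Lx)
  cz <- rep(mid[ok], 3)
  zmid <- stats::approx(cx, cz, xout = h$x, rule = 2)$y
  lf <- ifelse(h$z > zmid, "outer", "inner")
  if (length(unique(lf)) < 2)
    stop("degenerate membrane: all lipids assigned to one leaflet")
  names(lf) <- as.character(h$resid)
  frame$leaflets <- lf
  frame
}

#' Leaflet label lookup for each bead row of a frame
#' @noRd
bead_leaflets <- function(frame) {
  if (is.null(frame$leaflets)) stop("leaflets not assigned; call assign_leaflets()")
  unname(frame$leaflets[as.character(frame$beads$resid)])
}
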