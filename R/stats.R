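#' Map frame ids onto contiguous equal blocks
#'
#' Splits the ordered unique frame ids into `n_blocks` contiguous equal
#' blocks; trailing remainder frames are dropped with a warning.
#'
#' @param frame_ids Vector of frame ids (one per record).
#' @param n_blocks Number of blocks (default 4).
#' @return Integer vector of block indices aligned to `frame_ids`, `NA` for
#'   dropped frames.
#' @export
frame_blocks <- function(frame_ids, n_blocks = 4L) {
  uf <- sort(unique(frame_ids))
  if (length(uf) < n_blocks)
    stop("fewer frames (", length(uf), ") than blocks (", n_blocks, ")")
  nper <- length(uf) %/% n_blocks
  dropped <- length(uf) - nper * n_blocks
  if (dropped > 0)
    warning(sprintf("%d trailing frame(s) dropped to form %d equal blocks",
                    dropped, n_blocks))
  blk <- rep(NA_integer_, length(uf))
  blk[seq_len(nper * n_blocks)] <- rep(seq_len(n_blocks), each = nper)
  blk[match(frame_ids, uf)]
}

#' Block average of a per-frame statistic
#'
#' The trajectory is split into `n_blocks` contiguous equal intervals, the
#' statistic is averaged within each block, and the mean and SD across
#' blocks are reported (the "block average +/- SD" convention).
#'
#' @param values Numeric vector, one value per frame (in frame order).
#' @param n_blocks Number of blocks (default 4).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List of class `block_stat`: `mean`, `sd`, `n_blocks`,
#'   `block_means`.
#' @export
block_average <- function(values, n_blocks = 4L, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(values)
  if (n < n_blocks) stop("fewer values (", n, ") than blocks (", n_blocks, ")")
  nper <- n %/% n_blocks
  if (n %% n_blocks > 0)
    warning(sprintf("%d trailing value(s) dropped to form %d equal blocks",
                    n %% n_blocks, n_blocks))
  v <- values[seq_len(nper * n_blocks)]
  bm <- as.numeric(tapply(v, rep(seq_len(n_blocks), each = nper), mean))
  s <- stats::sd(bm)
  if (sd_type == "population") s <- s * sqrt((n_blocks - 1) / n_blocks)
  structure(list(mean = mean(bm), sd = unname(s), n_blocks = n_blocks,
                 block_means = bm),
            class = "block_stat")
}

#' @export
print.block_stat <- function(x, ...) {
  cat(sprintf("<block_stat> %.4g +/- %.4g (%d blocks)\n", x$mean, x$sd, x$n_blocks))
  invisible(x)
}

#' Per-leaflet curvature distribution with block statistics
#'
#' Density-normalized histogram of all lipids' signed curvature per leaflet,
#' with per-block replicate densities and the across-block mean +/- SD per
#' bin. Supports leaflet-asymmetry comparisons and extreme-curvature tail
#' inspection.
#'
#' @param tab A curvature table from [per_lipid_curvature()].
#' @param bin_width Histogram bin width in nm^-1 (default 0.05).
#' @param n_blocks Number of blocks (default 4).
#' @return Data frame `leaflet`, `bin_center`, `density`, `sd`, `count`.
#' @export
leaflet_curvature_distribution <- function(tab, bin_width = 0.05, n_blocks = 4L) {
  stopifnot(nrow(tab) > 0)
  edges <- curvature_bin_edges(tab$curvature, bin_width)
  blk <- frame_blocks(tab$frame, n_blocks)
  keep <- !is.na(blk)
  res <- lapply(unique(tab$leaflet), function(lf) {
    sel <- keep & tab$leaflet == lf
    dens <- vapply(seq_len(n_blocks), function(b) {
      cv <- tab$curvature[sel & blk == b]
      h <- hist_counts(cv, edges)
      h / (sum(h) * bin_width)
    }, numeric(length(edges) - 1L))
    dens <- matrix(dens, nrow = length(edges) - 1L)
    cnt <- hist_counts(tab$curvature[sel], edges)
    data.frame(leaflet = lf,
               bin_center = (edges[-1] + edges[-length(edges)]) / 2,
               density = rowMeans(dens),
               sd = apply(dens, 1, stats::sd),
               count = cnt)
  })
  do.call(rbind, res)
}

#' Uniform bin edges covering a curvature range
#' @noRd
curvature_bin_edges <- function(C, bin_width) {
  lo <- floor(min(C) / bin_width) * bin_width
  hi <- ceiling(max(C) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi, by = bin_width)
}

#' @noRd
hist_counts <- function(v, edges) {
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1 | idx >= length(edges) + 1L] <- NA
  idx[idx == length(edges)] <- length(edges) - 1L
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Normalized per-species enrichment profile vs curvature
#'
#' For each curvature bin b and species s, the enrichment
#' `F_s(b) = (n_s(b) / n_all(b)) / (N_s / N_all)`: the species' share of the
#' lipids in the bin divided by its overall leaflet share, so `F = 1` means
#' no sorting. Bins whose mean per-frame occupancy is below
#' `occupancy_frac` of the mean per-frame leaflet lipid count are masked and
#' excluded from all downstream fits. Computed per block (shares and bin
#' fractions from the same block, so the normalization identity
#' `sum_s (N_s/N_all) F_s(b) = 1` holds exactly per block and bin).
#'
#' @param tab A curvature table.
#' @param leaflet `"outer"` or `"inner"`.
#' @param bin_width Curvature bin width (nm^-1, default 0.05).
#' @param occupancy_frac Occupancy mask threshold (default 0.05).
#' @param n_blocks Number of blocks (default 4).
#' @return Object of class `enrichment_profile`: bin edges/centers, species,
#'   `F` (pooled species x bin matrix), `F_blocks` (blocks x species x bins
#'   array), `shares` (pooled leaflet shares), `occupancy` (mean per-frame
#'   count per bin), `mask` (TRUE = bin kept).
#' @export
enrichment_profile <- function(tab, leaflet, bin_width = 0.05,
                               occupancy_frac = 0.05, n_blocks = 4L) {
  sub <- tab[tab$leaflet == leaflet, ]
  if (!nrow(sub)) stop("leaflet '", leaflet, "' not present in table")
  absent <- setdiff(unique(tab$species), unique(sub$species))
  if (length(absent))
    warning("species absent from ", leaflet, " leaflet excluded: ",
            paste(absent, collapse = ", "))
  blk <- frame_blocks(sub$frame, n_blocks)
  keep <- !is.na(blk)
  sub <- sub[keep, ]; blk <- blk[keep]
  edges <- curvature_bin_edges(sub$curvature, bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nbin <- length(centers)
  bin <- findInterval(sub$curvature, edges, rightmost.closed = TRUE)
  bin[bin == nbin + 1L] <- nbin
  species <- sort(unique(sub$species))
  nf <- length(unique(sub$frame))
  occ <- tabulate(bin, nbins = nbin) / nf
  per_frame_leaflet <- nrow(sub) / nf
  mask <- occ >= occupancy_frac * per_frame_leaflet

  spf <- factor(sub$species, levels = species)
  bf <- factor(bin, levels = seq_len(nbin))
  F_blocks <- array(NA_real_, dim = c(n_blocks, length(species), nbin),
                    dimnames = list(NULL, species, NULL))
  for (b in seq_len(n_blocks)) {
    sel <- blk == b
    nb_all <- tabulate(bf[sel], nbins = nbin)
    n_sb <- table(spf[sel], bf[sel])
    share <- tabulate(spf[sel], nbins = length(species)) / sum(sel)
    Fm <- sweep(sweep(unclass(n_sb), 2, nb_all, "/"), 1, share, "/")
    Fm[, nb_all == 0] <- NA
    F_blocks[b, , ] <- Fm
  }
  nb_all <- tabulate(bf, nbins = nbin)
  n_sb <- table(spf, bf)
  shares <- tabulate(spf, nbins = length(species)) / nrow(sub)
  names(shares) <- species
  Fp <- sweep(sweep(unclass(n_sb), 2, nb_all, "/"), 1, shares, "/")
  Fp[, nb_all == 0] <- NA
  structure(list(leaflet = leaflet, edges = edges, centers = centers,
                 species = species, F = Fp, F_blocks = F_blocks,
                 shares = shares, occupancy = occ, mask = mask,
                 bin_width = bin_width, occupancy_frac = occupancy_frac,
                 n_blocks = n_blocks),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("<enrichment_profile> %s leaflet: %d species, %d bins (%d masked), bin width %.2f nm^-1\n",
              x$leaflet, length(x$species), length(x$centers),
              sum(!x$mask), x$bin_width))
  invisible(x)
}

#' Curvature-partitioning slope of a species
#'
#' Ordinary least-squares slope of the enrichment `F_s` versus bin-center
#' curvature over the unmasked bins, fitted independently within each block;
#' the across-block mean +/- SD is reported. The magnitude of the deviation
#' from zero reflects the extent of curvature partitioning (units nm, since
#' F is dimensionless and curvature is nm^-1).
#'
#' @param profile An [enrichment_profile()].
#' @param species Species to fit (default: all in the profile).
#' @return Data frame `species`, `slope`, `sd`, `n_blocks`.
#' @export
partition_slope <- function(profile, species = NULL) {
  stopifnot(inherits(profile, "enrichment_profile"))
  if (is.null(species)) species <- profile$species
  missing_sp <- setdiff(species, profile$species)
  if (length(missing_sp))
    stop("species not in profile: ", paste(missing_sp, collapse = ", "))
  if (sum(profile$mask) < 3)
    stop("fewer than 3 unmasked bins; cannot fit a partition slope")
  cx <- profile$centers
  res <- lapply(species, function(sp) {
    sl <- vapply(seq_len(profile$n_blocks), function(b) {
      Fv <- profile$F_blocks[b, sp, ]
      ok <- profile$mask & is.finite(Fv)
      if (sum(ok) < 3) return(NA_real_)
      unname(stats::coef(stats::lm(Fv[ok] ~ cx[ok]))[2])
    }, numeric(1))
    if (anyNA(sl))
      stop("fewer than 3 unmasked bins in some block for species ", sp)
    data.frame(species = sp, slope = mean(sl), sd = stats::sd(sl),
               n_blocks = profile$n_blocks)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-species, per-leaflet statistic with block averaging
#' @noRd
per_species_block_stat <- function(tab, n_blocks, fun) {
  blk <- frame_blocks(tab$frame, n_blocks)
  keep <- !is.na(blk)
  tab <- tab[keep, ]; blk <- blk[keep]
  key <- interaction(tab$species, tab$leaflet, drop = TRUE)
  res <- lapply(levels(key), function(kk) {
    sel <- key == kk
    bm <- vapply(seq_len(n_blocks), function(b) {
      v <- tab$curvature[sel & blk == b]
      if (!length(v)) NA_real_ else fun(v)
    }, numeric(1))
    parts <- strsplit(kk, ".", fixed = TRUE)[[1]]
    data.frame(species = parts[1], leaflet = parts[2],
               value = mean(bm, na.rm = TRUE),
               sd = stats::sd(bm[!is.na(bm)]),
               n_blocks = sum(!is.na(bm)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mean signed curvature per species and leaflet
#'
#' Arithmetic mean of the signed per-lipid curvature over all records of
#' each (species, leaflet), block-averaged.
#'
#' @param tab A curvature table.
#' @param n_blocks Number of blocks (default 4).
#' @return Data frame `species`, `leaflet`, `mean_curvature`, `sd`,
#'   `n_blocks`.
#' @export
mean_curvature_per_species <- function(tab, n_blocks = 4L) {
  out <- per_species_block_stat(tab, n_blocks, mean)
  names(out)[names(out) == "value"] <- "mean_curvature"
  out
}

#' Fraction of extreme curvature values per species and leaflet
#'
#' Fraction of records with `|C| > threshold`, block-averaged.
#'
#' @param tab A curvature table.
#' @param threshold Absolute-curvature threshold (nm^-1, default 0.1).
#' @param n_blocks Number of blocks (default 4).
#' @return Data frame `species`, `leaflet`, `fraction`, `sd`, `n_blocks`.
#' @export
extreme_fraction <- function(tab, threshold = 0.1, n_blocks = 4L) {
  out <- per_species_block_stat(tab, n_blocks,
                                function(v) mean(abs(v) > threshold))
  names(out)[names(out) == "value"] <- "fraction"
  out
}

#' Lipid localization probability along the buckle
#'
#' Per (species, leaflet), the normalized occupancy along the wrapped buckle
#' coordinate x: each row of the returned profile sums to 1 over the x bins.
#' Species present in the table but absent from a leaflet get an all-zero
#' row flagged `absent`.
#'
#' @param tab A curvature table.
#' @param Lx Box length along x (nm).
#' @param x_bin Bin width along x (nm, default 1).
#' @return Data frame `species`, `leaflet`, `x_center`, `prob`, `absent`.
#' @export
localization_profile <- function(tab, Lx, x_bin = 1.0) {
  nb <- max(1L, as.integer(round(Lx / x_bin)))
  w <- Lx / nb
  centers <- (seq_len(nb) - 0.5) * w
  species <- sort(unique(tab$species))
  res <- lapply(c("outer", "inner"), function(lf) {
    sub <- tab[tab$leaflet == lf, ]
    do.call(rbind, lapply(species, function(sp) {
      xs <- sub$x[sub$species == sp] %% Lx
      if (!length(xs)) {
        data.frame(species = sp, leaflet = lf, x_center = centers,
                   prob = 0, absent = TRUE)
      } else {
        cnt <- tabulate(pmin(floor(xs / w), nb - 1L) + 1L, nbins = nb)
        data.frame(species = sp, leaflet = lf, x_center = centers,
                   prob = cnt / sum(cnt), absent = FALSE)
      }
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
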