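#' Compressional strain of a buckled box
#'
#' gamma = (X0 - Xi) / X0, the fractional reduction of the box length along
#' the buckling axis.
#'
#' @param X0 Unbuckled box length along x (nm), > 0.
#' @param Xi Buckled box length along x (nm), 0 < Xi <= X0.
#' @return Dimensionless strain in `[0, 1)`.
#' @export
strain <- function(X0, Xi) {
  if (X0 <= 0) stop("X0 must be positive")
  if (Xi <= 0) stop("Xi must be positive")
  if (Xi > X0) stop("negative strain: Xi > X0 (extension is not modeled)")
  (X0 - Xi) / X0
}

#' Construct a buckled midplane profile
#'
#' The buckled midplane is modeled as a single-period cosine
#' `z_mid(x) = A cos(2 pi x / Xi)` with `Xi = (1 - gamma) X0`. The amplitude
#' `A` is solved by bisection so that the arc length of the curve over one
#' period equals the unbuckled length `X0` (the membrane area is conserved
#' under buckling). `gamma = 0` gives `A = 0` exactly. The cosine is a
#' geometric stand-in for the equilibrium shape of a compressed sheet chosen
#' for its analytic derivatives and curvature.
#'
#' @param X0 Unbuckled box length along x (nm).
#' @param gamma Compressional strain, `0 <= gamma < 0.5`.
#' @param tol Bisection tolerance on A (nm).
#' @return Object of class `buckle_profile` with fields `X0`, `Xi`, `gamma`,
#'   `A`, `k` (angular wavenumber `2 pi / Xi`).
#' @export
make_buckle_profile <- function(X0, gamma, tol = 1e-6) {
  if (X0 <= 0) stop("X0 must be positive")
  if (gamma < 0 || gamma >= 0.5) stop("gamma must be in [0, 0.5)")
  Xi <- (1 - gamma) * X0
  k <- 2 * pi / Xi
  A <- 0
  if (gamma > 0) {
    arc <- function(A)
      stats::integrate(function(x) sqrt(1 + (A * k * sin(k * x))^2),
                       0, Xi, rel.tol = 1e-10)$value
    lo <- 0; hi <- X0
    if (arc(hi) < X0)
      stop("amplitude solver failure: arc(A=X0)=", arc(hi), " < X0=", X0)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (arc(mid) < X0) lo <- mid else hi <- mid
    }
    A <- (lo + hi) / 2
  }
  structure(list(X0 = X0, Xi = Xi, gamma = gamma, A = A, k = k),
            class = "buckle_profile")
}

#' @export
print.buckle_profile <- function(x, ...) {
  cat(sprintf("<buckle_profile> gamma=%.2f: X0=%.2f nm, Xi=%.2f nm, A=%.4f nm, max |curvature|=%.4f nm^-1\n",
              x$gamma, x$X0, x$Xi, x$A, x$A * x$k^2))
  invisible(x)
}

#' Midplane height, derivatives and curvature of a buckle profile
#'
#' `profile_height`, `profile_dz` and `profile_d2z` evaluate
#' `z_mid(x) = A cos(kx)` and its first two derivatives;
#' `profile_curvature` evaluates the raw signed midplane curvature
#' `z'' / (1 + z'^2)^(3/2)` (positive where the curve bends toward +z).
#'
#' @param profile A [make_buckle_profile()] object.
#' @param x Positions along the buckle (nm), wrapped into the period.
#' @return Numeric vector.
#' @export
profile_height <- function(profile, x) profile$A * cos(profile$k * x)

#' @rdname profile_height
#' @export
profile_dz <- function(profile, x) -profile$A * profile$k * sin(profile$k * x)

#' @rdname profile_height
#' @export
profile_d2z <- function(profile, x) -profile$A * profile$k^2 * cos(profile$k * x)

#' @rdname profile_height
#' @export
profile_curvature <- function(profile, x) {
  profile_d2z(profile, x) / (1 + profile_dz(profile, x)^2)^1.5
}

#' Signed leaflet-surface curvature of a buckle profile
#'
#' The leaflet surface is the midplane offset by `d2` nm along the local unit
#' normal (+ for outer, - for inner). The curvature of an offset curve is
#' `kappa / (1 -+ d2 * kappa)` (parallel-curve formula), and the outer-leaflet
#' sign is inverted so that, for both leaflets, concave regions (as seen from
#' that leaflet's own side) are negative and convex regions positive.
#'
#' The offset surface is regular only while `d2 * max|kappa| < 1`; larger
#' offsets self-intersect and are rejected.
#'
#' @param profile A [make_buckle_profile()] object.
#' @param x Midplane x parameter (nm).
#' @param leaflet `"outer"` or `"inner"`.
#' @param d2 Leaflet offset `d/2` from the midplane (nm).
#' @return Signed curvature in nm^-1.
#' @export
leaflet_curvature <- function(profile, x, leaflet = c("outer", "inner"), d2 = 2.0) {
  leaflet <- match.arg(leaflet)
  kap <- profile_curvature(profile, x)
  kmax <- profile$A * profile$k^2
  if (d2 * kmax >= 1)
    stop(sprintf("leaflet offset d/2=%.2f nm self-intersects: d2 * max|curvature| = %.3f >= 1; reduce d2 or gamma",
                 d2, d2 * kmax))
  if (leaflet == "outer") -kap / (1 - d2 * kap) else kap / (1 + d2 * kap)
}

#' Arc length of the midplane over one period
#' @param profile A [make_buckle_profile()] object.
#' @return Arc length in nm (equals `X0` by construction, within solver tolerance).
#' @export
profile_arc_length <- function(profile) {
  stats::integrate(function(x) sqrt(1 + profile_dz(profile, x)^2),
                   0, profile$Xi, rel.tol = 1e-10)$value
}
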