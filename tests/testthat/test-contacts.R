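# helper: frame of single-bead "lipids" at given coordinates, one leaflet
point_frame <- function(xyz, species, Lx = 20, Ly = 20, Lz = 20,
                        bead = "PO4") {
  n <- nrow(xyz)
  beads <- data.frame(resid = seq_len(n), species = species, bead = bead,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  fr <- membrane_frame(beads, c(Lx, Ly, Lz))
  fr$leaflets <- setNames(rep("inner", n), as.character(seq_len(n)))
  fr
}

test_that("the contact cutoff is a strict distance threshold with minimum image", {
  near <- point_frame(rbind(c(1, 1, 5), c(1.9, 1, 5)), c("A", "B"))
  cm <- contact_matrix(near, "inner", cutoff = 1.0, n_blocks = 1)
  expect_equal(cm$raw["A", "B"], 1)
  far <- point_frame(rbind(c(1, 1, 5), c(2.1, 1, 5)), c("A", "B"))
  expect_equal(contact_matrix(far, "inner", n_blocks = 1)$raw["A", "B"], 0)
  # neighbours across the periodic x boundary are found
  wrap <- point_frame(rbind(c(0.2, 1, 5), c(19.9, 1, 5)), c("A", "B"))
  expect_equal(contact_matrix(wrap, "inner", n_blocks = 1)$raw["A", "B"], 1)
  # a lipid pair with several close bead pairs still counts once
  multi <- point_frame(rbind(c(1, 1, 5), c(1.5, 1, 5), c(1, 1.2, 5)),
                       c("A", "A", "B"))
  multi$beads$resid <- c(1L, 1L, 2L)
  multi$leaflets <- setNames(c("inner", "inner"), c("1", "2"))
  expect_equal(contact_matrix(multi, "inner", n_blocks = 1)$raw["A", "B"], 1)
  expect_error(contact_matrix(near, "inner", cutoff = 15, n_blocks = 1),
               "minimum-image")
})

test_that("random mixing normalizes to 1 and label permutation is a null", {
  set.seed(12)
  frames <- lapply(1:8, function(i) {
    n <- 400
    point_frame(cbind(runif(n, 0, 20), runif(n, 0, 20), rnorm(n, 5, 0.2)),
                sample(c("A", "B"), n, TRUE))
  })
  cm <- contact_matrix(frames, "inner", cutoff = 1.0, n_blocks = 4)
  expect_equal(cm$normalized, t(cm$normalized))
  # every cell within ~3 block SD of the ideal-mixing value 1
  dev <- abs(cm$normalized - 1)
  expect_true(all(dev < pmax(3 * cm$sd, 0.1)))
  # permutation oracle: shuffling species labels keeps normalized ~ 1
  perm <- lapply(frames, function(fr) {
    per_res <- unique(fr$beads$resid)
    relab <- sample(c("A", "B"), length(per_res), TRUE)
    fr$beads$species <- relab[match(fr$beads$resid, per_res)]
    fr
  })
  cp <- contact_matrix(perm, "inner", cutoff = 1.0, n_blocks = 4)
  expect_true(all(abs(cp$normalized - 1) < pmax(3 * cp$sd, 0.1)))
})

test_that("imposed self-clustering makes the self cell the matrix maximum", {
  set.seed(13)
  frames <- lapply(1:4, function(i) {
    # species C clustered in a 3x3 patch; A/B uniform
    nC <- 60; nAB <- 300
    xyz <- rbind(cbind(runif(nC, 9, 11), runif(nC, 9, 11), rnorm(nC, 5, 0.1)),
                 cbind(runif(nAB, 0, 20), runif(nAB, 0, 20), rnorm(nAB, 5, 0.1)))
    point_frame(xyz, c(rep("C", nC), sample(c("A", "B"), nAB, TRUE)))
  })
  cm <- contact_matrix(frames, "inner", n_blocks = 1)
  expect_equal(cm$normalized["C", "C"], max(cm$normalized))
  expect_gt(cm$normalized["C", "C"], max(cm$normalized["A", ]))
})

test_that("P2 order parameter hits its closed-form limits", {
  reg <- tiny_registry()
  mk <- function(dx, dz) {
    # 20 lipids per leaflet, flat membrane, tails along (dx, 0, dz)
    rows <- list()
    for (r in 1:40) {
      z0 <- if (r <= 20) 12 else 8
      sgn <- if (r <= 20) -1 else 1
      x0 <- (r %% 20) + 0.5
      depth <- (0:4) * 0.3
      rows[[r]] <- data.frame(
        resid = r, species = "LIPA",
        bead = c("PO4", "GL1", "C1A", "C2A", "C3A"),
        x = x0 + sgn * dx * depth, y = 5, z = z0 + sgn * dz * depth)
    }
    membrane_frame(do.call(rbind, rows), c(20, 10, 20))
  }
  # bonds parallel to the normal
  p2_par <- tail_order_parameter(mk(0, 1), reg, "LIPA", normal = "z",
                                 n_blocks = 1)
  expect_equal(p2_par$p2, 1, tolerance = 1e-12)
  # bonds perpendicular
  p2_perp <- tail_order_parameter(mk(1, 0), reg, "LIPA", normal = "z",
                                  n_blocks = 1)
  expect_equal(p2_perp$p2, -0.5, tolerance = 1e-12)
  # flat membrane: local spline normal reduces to the z axis
  p2_loc <- tail_order_parameter(mk(0, 1), reg, "LIPA", normal = "local",
                                 n_blocks = 1)
  expect_equal(p2_loc$p2, p2_par$p2, tolerance = 1e-10)
})

test_that("isotropic bond orientations give P2 ~ 0", {
  reg <- list(ISO = lipid_spec("ISO", c("PO4", "T1", "T2"), "PO4",
                               tails = list(c("T1", "T2"))))
  set.seed(14)
  n <- 4000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  x0 <- runif(n, 0, 50); y0 <- runif(n, 0, 50)
  z0 <- rep(c(12, 8), length.out = n)
  off <- rep(c(0, 0, 0.3), n)   # PO4 and T1 coincide; T2 one bond away
  rows <- data.frame(
    resid = rep(seq_len(n), each = 3),
    species = "ISO",
    bead = rep(c("PO4", "T1", "T2"), n),
    x = rep(x0, each = 3) + off * rep(u[, 1], each = 3),
    y = rep(y0, each = 3) + off * rep(u[, 2], each = 3),
    z = rep(z0, each = 3) + off * rep(u[, 3], each = 3))
  fr <- membrane_frame(rows, c(50, 50, 20))
  fr$leaflets <- setNames(rep(c("outer", "inner"), length.out = n),
                          as.character(seq_len(n)))
  p2 <- tail_order_parameter(fr, reg, "ISO", normal = "z", n_blocks = 1)
  # Monte-Carlo null: sd of P2 over n bonds ~ 1/sqrt(n)
  expect_lt(abs(p2$p2), 3 / sqrt(n))
})

test_that("splay angles match dot-product arithmetic", {
  two_tail <- list(DT = lipid_spec(
    "DT", c("PO4", "A1", "A2", "B1", "B2"), "PO4",
    tails = list(c("A1", "A2"), c("B1", "B2"))))
  mk <- function(v1, v2) {
    beads <- data.frame(
      resid = 1L, species = "DT", bead = c("PO4", "A1", "A2", "B1", "B2"),
      x = c(5, 5, 5 + v1[1], 5, 5 + v2[1]),
      y = c(5, 5, 5 + v1[2], 5, 5 + v2[2]),
      z = c(10, 10, 10 + v1[3], 10, 10 + v2[3]))
    membrane_frame(beads, c(10, 10, 20))
  }
  expect_equal(splay_angle(mk(c(0, 0, -1), c(0, 0, -1)), two_tail, "DT",
                           n_blocks = 1)$splay_deg, 0, tolerance = 1e-10)
  expect_equal(splay_angle(mk(c(0, 0, -1), c(0, 0, 1)), two_tail, "DT",
                           n_blocks = 1)$splay_deg, 180, tolerance = 1e-10)
  # 60 degrees by construction
  v1 <- c(0, 0, -1); v2 <- c(sin(pi / 3), 0, -cos(pi / 3))
  expect_equal(splay_angle(mk(v1, v2), two_tail, "DT", n_blocks = 1)$splay_deg,
               60, tolerance = 1e-6)
  # cholesterol-like single-tail species is flagged not applicable
  sa2 <- splay_angle(list(mk(v1, v2)), plasma_registry(), "CHOL", n_blocks = 1)
  expect_true(is.na(sa2$splay_deg))
  expect_false(sa2$applicable)
})

test_that("static descriptors follow from the registry arithmetic", {
  reg <- plasma_registry()
  d <- descriptor_table(reg)
  expect_equal(d$head_tail_ratio[d$species == "POPC"], 4 / 8)
  expect_equal(d$n_beads[d$species == "CHOL"], 8)
  expect_equal(d$unsaturation_fraction[d$species == "CHOL"], 0)
  expect_equal(d$unsaturation_fraction[d$species == "PAPC"], 4 / 7)
  # a species with 2 head and 8 tail beads has ratio 0.25
  reg2 <- list(X = lipid_spec("X", c("H1", paste0("T", 1:8), "H2"), "H1",
                              tails = list(paste0("T", 1:4), paste0("T", 5:8))))
  expect_equal(descriptor_table(reg2)$head_tail_ratio, 0.25)
})

test_that("descriptor correlations behave like Pearson's r", {
  mc <- c(A = -0.1, B = -0.05, C = 0.0, D = 0.05)
  desc <- c(A = 4, B = 3, C = 2, D = 1)     # exact negative linear relation
  expect_equal(curvature_descriptor_correlation(mc, desc), -1)
  # affine rescaling of the descriptor leaves r unchanged
  expect_equal(curvature_descriptor_correlation(mc, 3 * desc + 7), -1)
  # exclusion applies before the n >= 3 check
  expect_error(curvature_descriptor_correlation(mc[1:3], desc[1:3],
                                                exclude = "A"),
               "fewer than 3")
  expect_error(curvature_descriptor_correlation(mc, c(A = 1, B = 1, C = 1, D = 1)),
               "zero variance")
  # permutation null: mean r over label shuffles ~ 0
  set.seed(15)
  rs <- replicate(500, {
    curvature_descriptor_correlation(mc, setNames(sample(desc), names(desc)))
  })
  expect_lt(abs(mean(rs)), 0.05)
})
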