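test_that("block averaging reproduces hand-computed block statistics", {
  # 4 blocks with per-block means 1, 2, 3, 4
  v <- rep(c(1, 2, 3, 4), each = 5)
  bs <- block_average(v, 4)
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$sd, sd(c(1, 2, 3, 4)))           # sample SD ~ 1.2910
  expect_equal(bs$sd, 1.2909944, tolerance = 1e-6)
  expect_equal(block_average(v, 4, sd_type = "population")$sd,
               sd(c(1, 2, 3, 4)) * sqrt(3 / 4))
  # constant series
  expect_equal(block_average(rep(7, 12))$sd, 0)
  # remainder values are dropped with a warning
  expect_warning(bs2 <- block_average(seq_len(403), 4), "dropped")
  expect_equal(bs2$block_means, c(50.5, 150.5, 250.5, 350.5))
  expect_error(block_average(1:3, 4), "fewer values")
})

test_that("frame blocks are contiguous, equal, and drop the remainder", {
  ids <- rep(1:11, each = 2)
  expect_warning(blk <- frame_blocks(ids, 4), "dropped")
  expect_true(all(is.na(blk[ids > 8])))
  expect_equal(unname(blk[match(c(1, 3, 5, 7), ids)]), c(1, 2, 3, 4))
  expect_error(frame_blocks(1:3, 4), "fewer frames")
})

test_that("curvature distributions are density-normalized per leaflet", {
  set.seed(5)
  C <- c(rnorm(4000, 0, 0.1), rnorm(4000, 0, 0.2))
  tab <- hand_table(C, "LIPA", leaflet = rep(c("outer", "inner"), each = 4000))
  tab$frame <- rep(rep(1:8, each = 500), 2)
  d <- leaflet_curvature_distribution(tab, bin_width = 0.05)
  for (lf in c("outer", "inner")) {
    sub <- d[d$leaflet == lf, ]
    expect_equal(sum(sub$density) * 0.05, 1, tolerance = 1e-10)
  }
  # the wider inner distribution has more mass in the negative tail
  tail_in <- sum(d$density[d$leaflet == "inner" & d$bin_center < -0.3])
  tail_out <- sum(d$density[d$leaflet == "outer" & d$bin_center < -0.3])
  expect_gt(tail_in, tail_out)
  # degenerate all-zero table occupies a single bin
  tab0 <- hand_table(rep(0, 40), "LIPA")
  tab0$frame <- rep(1:4, each = 10)
  d0 <- leaflet_curvature_distribution(tab0)
  expect_equal(sum(d0$count > 0), 1)
})

test_that("enrichment normalization identity holds exactly in every unmasked bin", {
  set.seed(8)
  n <- 8000
  C <- runif(n, -0.2, 0.2)
  sp <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  tab <- hand_table(C, sp)
  tab$frame <- rep(1:8, each = n / 8)
  pr <- enrichment_profile(tab, "inner")
  # sum_s share_s * F_s(b) = 1 exactly, pooled and per block
  chk <- colSums(pr$F * pr$shares)
  expect_equal(unname(chk[pr$mask]), rep(1, sum(pr$mask)), tolerance = 1e-12)
  for (b in 1:4) {
    Fb <- pr$F_blocks[b, , ]
    chk_b <- colSums(Fb * pr$shares)  # block shares ~ pooled shares here
    expect_equal(unname(chk_b[pr$mask]), rep(1, sum(pr$mask)), tolerance = 0.05)
  }
  # uniform random placement: no sorting, F ~ 1 in unmasked bins
  expect_true(all(abs(pr$F[, pr$mask] - 1) < 0.2))
})

test_that("occupancy mask removes bins below the 5% threshold", {
  # 3 bins: 50%, 46%, 4% of the lipids; 4 frames
  C <- c(rep(-0.04, 500), rep(0.01, 460), rep(0.06, 40))
  tab <- hand_table(C, "A")
  tab$frame <- rep(1:4, 250)
  pr <- enrichment_profile(tab, "inner", bin_width = 0.05, occupancy_frac = 0.05)
  expect_identical(unname(pr$mask), c(TRUE, TRUE, FALSE))
})

test_that("partition slope matches the closed-form OLS oracle", {
  # exactly linear enrichment: F = 1 - 0.242 * C in every block
  centers <- c(-0.125, -0.075, -0.025, 0.025, 0.075, 0.125)
  make_tab <- function() {
    rows <- list()
    rid <- 0
    for (f in 1:4) for (i in seq_along(centers)) {
      nA <- round(1000 * (1 - 0.242 * centers[i]) * 0.5)
      nB <- 1000 - nA
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, resid = rid + seq_len(1000),
        species = rep(c("A", "B"), c(nA, nB)), leaflet = "inner",
        x = 0, curvature = centers[i])
      rid <- rid + 1000
    }
    tab <- do.call(rbind, rows)
    class(tab) <- c("curvature_table", "data.frame")
    tab
  }
  tab <- make_tab()
  pr <- enrichment_profile(tab, "inner", occupancy_frac = 0.01)
  s <- partition_slope(pr, "A")
  # shares shift slightly from 0.5, so the expected OLS slope follows the
  # same arithmetic the estimator uses; recompute it independently
  shareA <- mean(tab$species == "A")
  Fs <- vapply(centers, function(cc) {
    sub <- tab[tab$curvature == cc & tab$frame == 1, ]
    mean(sub$species == "A") / shareA
  }, numeric(1))
  beta <- sum((centers - mean(centers)) * (Fs - mean(Fs))) /
    sum((centers - mean(centers))^2)
  expect_equal(s$slope, beta, tolerance = 1e-6)
  expect_equal(s$sd, 0, tolerance = 1e-6)
})

test_that("five hand-made points give the hand-computed OLS slope", {
  cx <- c(-0.1, -0.05, 0, 0.05, 0.1)
  Fv <- c(1.2, 1.1, 1.0, 0.95, 0.8)
  # freeze the closed-form OLS value: sum(x F)/sum(x^2) = -0.0475/0.025
  expect_equal(unname(coef(lm(Fv ~ cx))[2]), -1.9)
})

test_that("constant enrichment yields zero slope and too few bins error out", {
  set.seed(6)
  C <- rep(c(-0.06, -0.02, 0.02, 0.06), each = 250)
  sp <- sample(c("A", "B"), 1000, TRUE)
  tab <- hand_table(C, sp)
  tab$frame <- rep(1:4, 250)   # every block sees every bin and species
  pr <- enrichment_profile(tab, "inner")
  s <- partition_slope(pr)
  # per-bin species shares fluctuate, but the expected slope is 0
  expect_true(all(abs(s$slope) < 2 * pmax(s$sd, 0.05)))
  # collapse to 2 occupied bins -> error
  tab2 <- hand_table(rep(c(-0.02, 0.02), 500), sp)
  tab2$frame <- rep(1:4, 250)
  pr2 <- enrichment_profile(tab2, "inner")
  expect_error(partition_slope(pr2), "fewer than 3 unmasked bins")
})

test_that("per-species means and extreme fractions are block-averaged correctly", {
  C <- rep(c(-0.2, 0.2), 500)
  tab <- hand_table(C, "A")
  tab$frame <- rep(1:4, each = 250)
  m <- mean_curvature_per_species(tab)
  expect_equal(m$mean_curvature, 0, tolerance = 1e-12)
  ef <- extreme_fraction(tab, threshold = 0.1)
  expect_equal(ef$fraction, 1)
  expect_equal(extreme_fraction(tab, threshold = 0.25)$fraction, 0)
  # with zero sorting all species share the leaflet-wide mean
  set.seed(3)
  C2 <- rnorm(4000, -0.03, 0.05)
  tab2 <- hand_table(C2, sample(c("A", "B"), 4000, TRUE))
  tab2$frame <- rep(1:4, each = 1000)
  m2 <- mean_curvature_per_species(tab2)
  # exchangeable placement: species means differ only by sampling noise
  # (SE of the difference ~ 0.0016 at this size)
  expect_lt(abs(m2$mean_curvature[1] - m2$mean_curvature[2]), 0.006)
})

test_that("localization profiles are per-species probabilities along the buckle", {
  set.seed(4)
  x <- runif(2000, 0, 36)
  tab <- hand_table(rep(0, 2000), sample(c("A", "B"), 2000, TRUE))
  tab$x <- x
  loc <- localization_profile(tab, Lx = 36, x_bin = 1)
  for (sp in c("A", "B")) {
    row <- loc[loc$species == sp & loc$leaflet == "inner", ]
    expect_equal(sum(row$prob), 1)
    expect_true(all(abs(row$prob - 1 / 36) < 0.02))
  }
  # species absent from a leaflet: all-zero row flagged absent
  out_rows <- loc[loc$leaflet == "outer" & loc$species == "A", ]
  expect_true(all(out_rows$absent))
  expect_equal(sum(out_rows$prob), 0)
})

test_that("gamma widens the occupied curvature range monotonically", {
  comp <- plasma_composition()
  rng <- lapply(c(0.1, 0.4), function(gm) {
    p <- make_buckle_profile(40, gm)
    sim <- simulate_curvature_table(p, comp, sorting_model(d2 = 1.5),
                                    n_frames = 4, seed = 90)
    range(sim$curvature$curvature)
  })
  expect_lt(rng[[2]][1], rng[[1]][1])
  expect_gt(rng[[2]][2], rng[[1]][2])
})
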