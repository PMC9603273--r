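test_that("trace construction and resampling follow the arc-length contract", {
  straight <- membrane_trace("t", "OM", cbind(c(0, 100), c(0, 0)))
  pts <- resample_trace(straight, 0.1)
  expect_equal(nrow(pts), 1001L)
  expect_equal(pts[2, 1], 0.1)
  # step larger than the trace keeps both ends
  expect_equal(nrow(resample_trace(straight, 500)), 2L)
  expect_error(resample_trace(straight, 0), "step")
  expect_error(membrane_trace("t", "OM", cbind(1, 1)), "at least 2")
  expect_error(membrane_trace("t", "OM", cbind(c(1, 1), c(2, 2))),
               "distinct")
})

test_that("parallel traces give a constant profile equal to the gap", {
  om <- membrane_trace("t", "OM", cbind(c(0, 100), c(0, 0)))
  im <- membrane_trace("t", "IM", cbind(c(0, 100), c(-32.7, -32.7)))
  p <- distance_profile(om, im)
  expect_equal(p$mean, 327)
  expect_equal(p$sem, 0)
  expect_true(all(p$distances == 327))
  # symmetric limit: the two directions agree exactly for parallel traces
  q <- distance_profile(im, om)
  expect_equal(q$mean, p$mean)
  expect_error(distance_profile(om, membrane_trace("other", "IM",
                                                   cbind(c(0, 1), c(0, 1)))),
               "different tomograms")
})

test_that("an L-shaped target measures to the corner vertex, not an extension", {
  src <- membrane_trace("t", "OM", cbind(c(-4, -2.9), c(4, 4)))
  tgt <- membrane_trace("t", "IM", cbind(c(0, 0, 5), c(5, 0, 0)))
  p <- distance_profile(src, tgt, step = 10)  # samples only the two ends
  # nearest target feature for (-4, 4) is the segment x=0; for the corner
  # geometry the source start measures to the vertical segment
  expect_equal(p$distances[1], 40, tolerance = 1e-9)
  src2 <- membrane_trace("t", "OM", cbind(c(-3, -3.001), c(-4, -4)))
  p2 <- distance_profile(src2, tgt, step = 10)
  # below-left of the corner (0,0): closest point is the vertex itself
  expect_equal(p2$distances[1], 10 * sqrt(3^2 + 4^2), tolerance = 1e-9)
})

test_that("segment-mode distances match a dense brute-force oracle", {
  set.seed(123)
  for (i in 1:100) {
    src <- membrane_trace("t", "OM", random_polyline(sample(3:7, 1)))
    shift <- c(0, runif(1, 4, 7)) + rnorm(2, 0, 0.2)
    tgt <- membrane_trace("t", "IM",
                          random_polyline(sample(3:7, 1), origin = shift))
    p <- distance_profile(src, tgt, step = 0.25)
    oracle <- brute_force_profile(src, tgt, step = 0.25)
    expect_lt(max(abs(p$distances - oracle)), 1e-6)
  }
})

test_that("distances are invariant under translation and rotation", {
  set.seed(5)
  src_pts <- random_polyline(5)
  tgt_pts <- random_polyline(5, origin = c(0, 4))
  ref <- distance_profile(membrane_trace("t", "OM", src_pts),
                          membrane_trace("t", "IM", tgt_pts), step = 0.5)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- rnorm(2, 0, 10)
    tr <- function(p) sweep(p %*% R, 2, shift, "+")
    moved <- distance_profile(membrane_trace("t", "OM", tr(src_pts)),
                              membrane_trace("t", "IM", tr(tgt_pts)),
                              step = 0.5)
    expect_equal(moved$distances, ref$distances, tolerance = 1e-9)
  }
})

test_that("generated trace pairs recover the planted gap", {
  # zero noise, zero curvature: exact recovery
  tp <- gen_membrane_pair(327, 100, noise_sd = 0, curvature_amplitude = 0,
                          seed = 1)
  expect_equal(distance_profile(tp$om, tp$im)$mean, 327)
  # noisy traces: within 3 * noise_sd / sqrt(n model points)
  tp2 <- gen_membrane_pair(327, 100, noise_sd = 10, seed = 1)
  n_pts <- nrow(tp2$om$points)
  expect_lt(abs(distance_profile(tp2$om, tp2$im)$mean - 327),
            3 * 10 / sqrt(n_pts))
  # curvature alone does not bias the measurement appreciably
  tp3 <- gen_membrane_pair(327, 100, noise_sd = 0, curvature_amplitude = 30,
                           seed = 2)
  expect_lt(abs(distance_profile(tp3$om, tp3$im)$mean - 327), 0.5)
})

test_that("traces round-trip through the TSV format", {
  tp <- gen_membrane_pair(327, 50, noise_sd = 5, seed = 9, tomogram_id = "tA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(list(tp$om, tp$im), path)
  back <- read_traces(path)
  expect_equal(back$tA.OM$points, tp$om$points, tolerance = 1e-12)
  expect_equal(back$tA.IM$membrane, "IM")
})

test_that("species thickness summaries aggregate tomogram means with SEM", {
  mk_prof <- function(m) structure(list(tomogram_id = "x", mean = m),
                                   class = "periplasm_profile")
  s <- thickness_summary(lapply(c(320, 327, 334), mk_prof),
                         rep("M_xanthus", 3))
  expect_equal(s$grand_mean_A, 327)
  expect_equal(s$sem_A, sd(c(320, 327, 334)) / sqrt(3))
  expect_equal(s$sem_A, 4.0414519, tolerance = 1e-6)
  one <- thickness_summary(list(mk_prof(300)), "X")
  expect_equal(one$sem_A, 0)
  expect_true(one$single_tomogram)
  eq <- thickness_summary(lapply(c(300, 300), mk_prof), rep("Y", 2))
  expect_equal(eq$sem_A, 0)
  expect_error(thickness_summary(list(), character()), "no profiles")
})

test_that("correlation handles exact, monotone and degenerate inputs", {
  x <- 1:10
  lin <- data.frame(thickness_A = x, length_aa = 2 * x)
  r <- correlate_thickness(lin)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$n_pairs, 10L)
  # decreasing monotone nonlinear map: rho = -1, r > -1
  mono <- data.frame(thickness_A = x, length_aa = exp(-x))
  m <- correlate_thickness(mono)
  expect_equal(m$spearman_rho, -1)
  expect_gt(m$pearson_r, -1)
  expect_error(correlate_thickness(data.frame(thickness_A = rep(1, 5),
                                              length_aa = 1:5)),
               "constant")
  expect_error(correlate_thickness(lin[1, ]), "at least 2")
})

test_that("planted correlations are recovered within the sampling bound", {
  for (r in c(-0.5, 0, 0.5, 1)) {
    p <- gen_correlated_pairs(r, 1000, seed = 17)
    est <- correlate_thickness(p)
    expect_lt(abs(est$pearson_r - r), 2 / sqrt(1000))
  }
})

test_that("hydrophobic thickness follows the 40% rule", {
  h <- hydrophobic_thickness(69.8)
  expect_equal(as.numeric(h), 27.92)
  expect_equal(attr(h, "reported"), 28)
  expect_equal(as.numeric(hydrophobic_thickness(0)), 0)
  expect_equal(as.numeric(hydrophobic_thickness(100)), 40)
  expect_error(hydrophobic_thickness(100, fraction = 1.2), "fraction")
  expect_error(hydrophobic_thickness(-1), "thickness")
})
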