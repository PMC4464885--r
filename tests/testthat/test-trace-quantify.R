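test_that("trace extraction recovers planted signal over background", {
  # one 5x5 colony at value bg + s in every channel; global background
  # subtraction must leave exactly s
  col <- list(rows = 11:15, cols = 11:15,
              dd = rep(50, 6), da = rep(80, 6), aa = rep(120, 6))
  st <- build_stack(colonies = list(col))
  lab <- matrix(0L, 40, 40); lab[11:15, 11:15] <- 1L
  cmap <- structure(list(
    label_image = lab,
    records = data.frame(colony_id = 1L, row = 12, col = 12,
                         area_px = 25L, radius_px = sqrt(25 / pi),
                         touches_border = FALSE)), class = "colony_map")
  tr <- extract_traces(st, cmap, background = "global")
  expect_equal(unname(tr$intensity[1, "donor_ex_donor_em", ]), rep(50, 6))
  expect_equal(unname(tr$intensity[1, "donor_ex_acceptor_em", ]),
               rep(80, 6))
  expect_equal(unname(tr$ratio[1, ]), rep(80 / 50, 6))

  # local-annulus background gives the same answer on a flat background
  tr2 <- extract_traces(st, cmap, background = "local")
  expect_equal(tr2$ratio, tr$ratio)

  # dimension mismatch errors
  bad <- cmap; bad$label_image <- matrix(0L, 20, 20)
  expect_error(extract_traces(st, bad), "mismatch")
})

test_that("noise-free extraction matches the simulator forward model", {
  sim <- small_plate(seed = 13, noise = noise_off())
  cm <- detect_colonies(sim$stack)
  tr <- extract_traces(sim$stack, cm)
  m <- join_truth(data.frame(colony_id = cm$records$colony_id), cm,
                  sim$manifest)
  i <- match(m$colony_id, tr$colony_ids)
  # baseline ratio equals R0_true to near machine precision
  base_ratio <- rowMeans(tr$ratio[i, 1:2, drop = FALSE])
  expect_equal(base_ratio, m$R0_true, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("R0 is the baseline-window mean with strict preconditions", {
  expect_equal(compute_R0(rep(0.95, 8), 4), 0.95)
  expect_equal(compute_R0(c(1.0, 1.2, 9, 9), 2), 1.1)
  # window must precede application
  expect_error(compute_R0(rep(1, 8), 4, c(4, 6)), "application")
  expect_error(compute_R0(rep(1, 8), 4, c(2, 2)), "window")
  expect_error(compute_R0(c(1, -0.5, 9, 9), 2), "onpositive")
})

test_that("dRR modes compute the documented response statistics", {
  trace <- c(1, 1, 1, 2, 4, 5, 5, 5)   # R0 = 1, plateau 5
  expect_equal(compute_dRR(trace, 1, 2, "mean-window", c(5, 8)), 4.0)
  expect_equal(compute_dRR(trace, 1, 2, "max"), 4.0)
  expect_equal(compute_dRR(trace, 1, 2, "endpoint"), 4.0)
  # Twitch-3-like arithmetic: R0 1.30, plateau 10.4 -> 700%
  tw <- c(1.30, 1.30, 1.30, 8, 10.4, 10.4, 10.4, 10.4)
  expect_equal(compute_dRR(tw, 1.30, 2, "mean-window", c(4, 8)), 7.0)
  # null response
  expect_equal(compute_dRR(rep(2, 8), 2, 2), 0)
  expect_error(compute_dRR(trace, 0, 2), "R0")
  expect_error(compute_dRR(trace, 1, 2, "mean-window", c(1, 3)),
               "after the application")
})

test_that("acceptor-brightening artifacts are flagged from the direct channel", {
  # constant direct-acceptor trace: no flag; x1.5 step: flag
  mk <- function(aa_post) {
    aa <- c(rep(100, 3), rep(aa_post, 3))
    col <- list(rows = 5:9, cols = 5:9, dd = rep(50, 6),
                da = rep(60, 6), aa = aa)
    st <- build_stack(dim = c(20, 20), colonies = list(col))
    lab <- matrix(0L, 20, 20); lab[5:9, 5:9] <- 1L
    cmap <- structure(list(
      label_image = lab,
      records = data.frame(colony_id = 1L, row = 6, col = 6,
                           area_px = 25L, radius_px = sqrt(25 / pi),
                           touches_border = FALSE)), class = "colony_map")
    extract_traces(st, cmap, background = "global")
  }
  expect_false(flag_artifact(mk(100)))
  expect_true(flag_artifact(mk(150)))

  # simulator truth: artifact gain on -> all colonies flagged; off -> none
  art <- small_plate(seed = 17, n = 20,
                     optics = optics_params(artifact_gain = 0.5))
  cm <- detect_colonies(art$stack)
  tab <- quantify_colonies(art$stack, cm)
  expect_true(all(tab$artifact_flag))
  clean <- small_plate(seed = 17, n = 20)
  cm2 <- detect_colonies(clean$stack)
  tab2 <- quantify_colonies(clean$stack, cm2)
  expect_false(any(tab2$artifact_flag))
})

test_that("ratios are invariant to a global intensity scaling", {
  sim <- small_plate(seed = 19, n = 30)
  cm <- detect_colonies(sim$stack)
  tab1 <- quantify_colonies(sim$stack, cm)
  scaled <- sim$stack
  for (ch in names(scaled$images))
    scaled$images[[ch]] <- scaled$images[[ch]] * 3
  tab2 <- quantify_colonies(scaled, cm)
  expect_equal(tab2$R0, tab1$R0, tolerance = 1e-12)
  expect_equal(tab2$dRR, tab1$dRR, tolerance = 1e-12)
})

test_that("noise-free estimates recover truth and respect deposition order", {
  sim <- small_plate(seed = 23, n = 40, spray_model = "gun",
                     noise = noise_off(),
                     sensor = sensor_params(R0_sdlog = 0, dRR_sdlog = 0,
                                            brightness_sdlog = 0))
  cm <- detect_colonies(sim$stack)
  tab <- quantify_colonies(sim$stack, cm)
  m <- join_truth(tab, cm, sim$manifest)
  expect_equal(nrow(m), 40)
  err_R0 <- abs(m$R0 - m$R0_true) / m$R0_true
  err_dRR <- abs(m$dRR - m$realized_dRR) / pmax(m$realized_dRR, 0.1)
  expect_lt(max(err_R0), 0.001)
  expect_lt(max(err_dRR), 0.001)
})

test_that("raising a colony's deposition never lowers its noise-free dRR", {
  # re-render the identical plate under increasingly steep gun fields:
  # per colony the deposition falls monotonically with the gradient, so
  # the estimated dRR must fall too (everything else held fixed)
  lay <- sample_colony_layout(10, plate_radius = 90, min_separation = 25,
                              seed = 29)
  tr <- data.frame(colony_id = 1:10, R0_true = rep(1, 10),
                   dRR_max_true = rep(2, 10), brightness = rep(300, 10))
  frames <- frames_spec(8, 60, 2)
  est <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(g) {
    spray <- make_spray_field("gun", dim = lay$img_dim, plate_radius = 90,
                              params = list(gradient = g))
    out <- render_experiment(lay, tr, spray, noise = noise_off(),
                             frames = frames)
    cm <- detect_colonies(out$stack)
    tab <- quantify_colonies(out$stack, cm)
    ev <- evaluate_detection(cm, out$manifest)
    tab$dRR[match(ev$matches$colony_id[order(ev$matches$truth_id)],
                  tab$colony_id)]
  })
  # each row: one colony across rising gradients (falling deposition)
  expect_true(all(apply(est, 1, function(v) all(diff(v) <= 1e-9))))
})

test_that("colonies with nonpositive donor baseline are excluded, not fatal", {
  col_ok <- list(rows = 5:9, cols = 5:9, dd = rep(50, 6),
                 da = rep(60, 6), aa = rep(100, 6))
  col_dark <- list(rows = 20:24, cols = 20:24, dd = rep(0, 6),
                   da = rep(60, 6), aa = rep(100, 6))
  st <- build_stack(colonies = list(col_ok, col_dark))
  lab <- matrix(0L, 40, 40)
  lab[5:9, 5:9] <- 1L; lab[20:24, 20:24] <- 2L
  cmap <- structure(list(
    label_image = lab,
    records = data.frame(colony_id = 1:2, row = c(6, 21), col = c(6, 21),
                         area_px = c(25L, 25L),
                         radius_px = rep(sqrt(25 / pi), 2),
                         touches_border = c(FALSE, FALSE))),
    class = "colony_map")
  expect_message(tab <- quantify_colonies(st, cmap, background = "global"),
                 "excluded")
  expect_equal(tab$colony_id, 1L)
  expect_equal(attr(tab, "excluded"), 2L)
})
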