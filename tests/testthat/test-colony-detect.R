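test_that("threshold estimation matches direct statistics", {
  const <- matrix(10, 5, 5)
  expect_equal(estimate_threshold(const, "plain"), 10)
  expect_warning(thr <- estimate_threshold(const, "robust"), "MAD")
  expect_equal(thr, 10)

  # sparse bright tail: plain mode against an independent two-pass
  # mean/SD computation
  x <- c(rep(0, 990), rep(1000, 10))
  img <- matrix(x, 10, 100)
  mu <- sum(x) / length(x)
  s <- sqrt(sum((x - mu)^2) / (length(x) - 1))
  expect_equal(estimate_threshold(img, "plain"), mu + 3 * s)

  # robust mode is insensitive to a 1% bright tail, plain mode is not
  x2 <- c(rep(0:9, 99), rep(1000, 10))
  img2 <- matrix(x2, 10, 100)
  expect_lt(estimate_threshold(img2, "robust"),
            9 + 3 * 1.4826 * mad(0:9))
  expect_gt(estimate_threshold(img2, "plain"), 100)

  expect_error(estimate_threshold(matrix(numeric(0), 0, 0)), "empty")
})

test_that("plain 3-sigma threshold cuts the expected Gaussian tail", {
  withr::with_seed(99, {
    img <- matrix(rnorm(500 * 500, 100, 10), 500, 500)
    thr <- estimate_threshold(img, "plain")
    frac <- mean(img > thr)
    p <- pnorm(-3)  # 0.00135
    se <- sqrt(p * (1 - p) / length(img))
    expect_lt(abs(frac - p), 5 * se)
  })
})

test_that("mask cleaning matches brute-force disk morphology", {
  expect_equal(sum(clean_mask(matrix(FALSE, 10, 10))), 0)
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(sum(clean_mask(single, erosion_radius = 1)), 0)

  # solid disk radius 10: erosion 2 then opening 2 leaves (up to grid
  # discretization of the disk boundary) a disk of radius 8
  m <- disk_mask(c(31, 31), c(16, 16), 10)
  got <- clean_mask(m, erosion_radius = 2, opening_radius = 2)
  want_er <- brute_erode(m, 2)
  want <- brute_dilate(brute_erode(want_er, 2), 2) & want_er
  expect_equal(got, want)
  inner <- disk_mask(c(31, 31), c(16, 16), 8)
  outer <- disk_mask(c(31, 31), c(16, 16), 8.5)
  expect_true(all(got[inner]))       # contains the radius-8 disk
  expect_true(all(outer[got]))       # contained in the radius-8.5 disk

  # random masks against the brute-force oracle
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- matrix(runif(20 * 20) < 0.45, 20, 20)
      got <- clean_mask(m, 1, 1)
      want_e <- brute_erode(m, 1)
      want <- brute_dilate(brute_erode(want_e, 1), 1) & want_e
      expect_equal(got, want)
    }
  })
  expect_error(clean_mask(single, erosion_radius = -1), ">= 0")
})

test_that("cleaning is anti-extensive", {
  withr::with_seed(8, {
    for (i in 1:10) {
      m <- matrix(runif(30 * 30) < 0.5, 30, 30)
      cleaned <- clean_mask(m, 1, 2)
      expect_true(all(m[cleaned]))
    }
  })
})

test_that("component labeling and filters behave as specified", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE
  m[12:16, 12:16] <- TRUE
  cm <- label_colonies(m, min_area = 1, border_margin = 0)
  expect_equal(nrow(cm$records), 2)
  expect_equal(cm$records$area_px, c(25L, 25L))
  # tie on area: first colony is the one with the smaller centroid row
  expect_equal(cm$records$row[1], 3)   # 0-based centroid of rows 2:6
  expect_equal(cm$records$col[1], 3)

  # labels are contiguous 1..n and bijective with records
  labs <- sort(unique(as.vector(cm$label_image)))
  expect_equal(labs, 0:2)
  expect_equal(tabulate(cm$label_image[cm$label_image > 0]),
               cm$records$area_px)

  # min_area filter removes small components
  s <- matrix(FALSE, 12, 12); s[4, 4:6] <- TRUE
  expect_equal(nrow(label_colonies(s, min_area = 10)$records), 0)

  # border flag
  e <- matrix(FALSE, 30, 30); e[2:5, 10:13] <- TRUE; e[15:18, 15:18] <- TRUE
  cm2 <- label_colonies(e, min_area = 1, border_margin = 5)
  expect_equal(sum(cm2$records$touches_border), 1)

  # empty mask yields an empty map, not an error
  expect_equal(nrow(label_colonies(matrix(FALSE, 4, 4))$records), 0)
})

test_that("labeling agrees with an independent flood fill", {
  withr::with_seed(21, {
    for (conn in c(4, 8)) {
      for (i in 1:20) {
        m <- matrix(runif(12 * 12) < 0.4, 12, 12)
        ours <- fretscreen:::label_components(m, conn)
        oracle <- flood_fill_label(m, conn)
        expect_equal(canonical_labels(ours), canonical_labels(oracle))
      }
    }
  })
})

test_that("planted colonies are detected with sub-pixel centroids", {
  tr <- data.frame(colony_id = 1:10,
                   R0_true = rep(1, 10), dRR_max_true = rep(1, 10),
                   brightness = rep(400, 10))
  lay <- sample_colony_layout(10, plate_radius = 80, min_separation = 30,
                              radius_range = c(4, 5), seed = 3)
  spray <- make_spray_field("uniform", dim = lay$img_dim,
                            plate_radius = 80)
  out <- render_experiment(lay, tr, spray, frames = frames_spec(4, 30, 1),
                           seed = 3)
  cm <- detect_colonies(out$stack)
  expect_equal(nrow(cm$records), 10)
  ev <- evaluate_detection(cm, out$manifest)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_true(all(ev$matches$dist <= 1))
})

test_that("detection handles noise-only stacks and border colonies", {
  lay0 <- sample_colony_layout(0, plate_radius = 40, min_separation = 0)
  spray0 <- make_spray_field("uniform", dim = lay0$img_dim,
                             plate_radius = 40)
  tr0 <- data.frame(colony_id = integer(0), R0_true = numeric(0),
                    dRR_max_true = numeric(0), brightness = numeric(0))
  out0 <- render_experiment(lay0, tr0, spray0,
                            frames = frames_spec(2, 30, 0), seed = 5)
  expect_equal(nrow(detect_colonies(out0$stack)$records), 0)

  # a colony centered within the border margin is kept but flagged
  img <- matrix(0, 60, 60)
  img[disk_mask(c(60, 60), c(4, 30), 6)] <- 500
  img <- img + matrix(rpois(3600, 20), 60, 60)
  arr <- array(img, c(60, 60, 2))
  st <- plate_stack(list(donor_ex_donor_em = arr,
                         donor_ex_acceptor_em = arr,
                         acceptor_ex_acceptor_em = arr),
                    frame_times = c(0, 30), application_frame = 0)
  cm <- detect_colonies(st)
  expect_gte(nrow(cm$records), 1)
  expect_true(cm$records$touches_border[1])
  expect_error(detect_colonies(st, detect_params(channel = "nope")),
               "channel")
})

test_that("translating the image translates all centroids equally", {
  img <- matrix(5, 80, 80)
  for (ctr in list(c(20, 22), c(45, 50), c(60, 30)))
    img[disk_mask(c(80, 80), ctr, 5)] <- 600
  shift <- function(m, dr, dc) {
    out <- matrix(5, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  as_stack <- function(m) {
    arr <- array(m, c(dim(m), 2))
    plate_stack(list(donor_ex_donor_em = arr, donor_ex_acceptor_em = arr,
                     acceptor_ex_acceptor_em = arr),
                frame_times = c(0, 30), application_frame = 0)
  }
  # constant background has zero MAD, so the threshold falls back to
  # plain mode (warning expected and irrelevant here)
  cm1 <- suppressWarnings(detect_colonies(as_stack(img)))
  cm2 <- suppressWarnings(detect_colonies(as_stack(shift(img, 7, 3))))
  expect_equal(nrow(cm2$records), nrow(cm1$records))
  expect_equal(cm2$records$row, cm1$records$row + 7)
  expect_equal(cm2$records$col, cm1$records$col + 3)
})
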