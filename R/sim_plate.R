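# Synthetic screening-plate generator.
#
# Emulates a wide-field CCD screen of bacterial colonies expressing FRET
# biosensors: a dense random colony layout, per-colony sensor truth
# (basal ratio, maximal relative ratio change, brightness), a spray
# deposition field that scales the realized response, three imaging
# channels with background, vignetting and photon noise, and saturating
# response kinetics after ligand application. Every render returns the
# image stack together with a ground-truth manifest, so downstream
# detection/quantification/ranking can be benchmarked exactly.

#' Sample a random non-overlapping colony layout
#'
#' Places `n` colony centers uniformly inside a circular plate by dart
#' throwing, rejecting candidates closer than `min_separation` to an
#' accepted center. Colony radii are drawn uniformly from `radius_range`.
#' All colonies lie fully inside the plate.
#'
#' @param n number of colonies (>= 0).
#' @param plate_radius plate radius in pixels.
#' @param min_separation minimum center-to-center distance in pixels.
#' @param radius_range length-2 numeric, colony radius range in pixels.
#' @param img_dim image side length in pixels; default leaves a 25 px
#'   margin around the plate.
#' @param seed optional integer seed; fixed seed gives an identical layout.
#' @param max_tries total dart-throw budget; exhausting it signals an
#'   overcrowded request.
#' @return an object of class `colony_layout`: list with `positions`
#'   (data.frame `row`, `col`, `radius`; 0-based pixel coordinates, origin
#'   top-left), `plate_center`, `plate_radius`, `img_dim`.
#' @export
sample_colony_layout <- function(n, plate_radius, min_separation,
                                 radius_range = c(3.5, 5),
                                 img_dim = NULL, seed = NULL,
                                 max_tries = max(10000, 400 * n)) {
  stopifnot_scalar(n, "n")
  if (n < 0) stop("n must be >= 0")
  stopifnot_scalar(plate_radius, "plate_radius", positive = TRUE)
  stopifnot_scalar(min_separation, "min_separation")
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (length(radius_range) != 2L || any(radius_range <= 0))
    stop("radius_range must be two positive numbers")
  if (is.null(img_dim)) img_dim <- ceiling(2 * (plate_radius + 25))
  center <- rep((img_dim - 1) / 2, 2)

  pos <- with_seed_if(seed, {
    rows <- numeric(n); cols <- numeric(n); radii <- numeric(n)
    placed <- 0L; tries <- 0L
    while (placed < n) {
      if (tries >= max_tries)
        stop("colony placement infeasible: ", placed, "/", n,
             " placed after ", tries, " tries; reduce n or min_separation")
      tries <- tries + 1L
      rad <- runif(1, radius_range[1], radius_range[2])
      rmax <- plate_radius - rad
      u <- sqrt(runif(1)) * rmax
      th <- runif(1, 0, 2 * pi)
      r0 <- center[1] + u * sin(th)
      c0 <- center[2] + u * cos(th)
      if (placed > 0L) {
        d2 <- (rows[seq_len(placed)] - r0)^2 + (cols[seq_len(placed)] - c0)^2
        if (min(d2) < min_separation^2) next
      }
      placed <- placed + 1L
      rows[placed] <- r0; cols[placed] <- c0; radii[placed] <- rad
    }
    data.frame(row = rows, col = cols, radius = radii)
  })

  structure(list(positions = pos, plate_center = center,
                 plate_radius = plate_radius, img_dim = img_dim),
            class = "colony_layout")
}

#' Default sensor-library distribution parameters
#'
#' Log-normal library draws centered on a TN-XXL-like prototype: basal
#' ratio around 0.95, maximal relative ratio change around 1.0 (100%)
#' with moderate diversity, and a baseline donor-channel brightness of
#' ~300 expected photons per pixel at the colony center. Setting an
#' `sdlog` to 0 gives a replicate plate of a single sensor.
#'
#' @param R0_meanlog,R0_sdlog log-normal parameters of the true basal ratio.
#' @param dRR_meanlog,dRR_sdlog log-normal parameters of the true maximal
#'   relative ratio change (1.0 = 100%).
#' @param brightness_meanlog,brightness_sdlog log-normal parameters of the
#'   expected donor-channel photon count per pixel at the colony center.
#' @return a list of class `sensor_params`.
#' @export
sensor_params <- function(R0_meanlog = log(0.95), R0_sdlog = 0.2,
                          dRR_meanlog = log(1.0), dRR_sdlog = 0.30,
                          brightness_meanlog = log(300),
                          brightness_sdlog = 0.2) {
  structure(list(R0_meanlog = R0_meanlog, R0_sdlog = R0_sdlog,
                 dRR_meanlog = dRR_meanlog, dRR_sdlog = dRR_sdlog,
                 brightness_meanlog = brightness_meanlog,
                 brightness_sdlog = brightness_sdlog),
            class = "sensor_params")
}

#' Draw per-colony sensor ground truth
#'
#' @param n number of colonies.
#' @param sensor a [sensor_params()] list.
#' @param seed optional integer seed.
#' @return data.frame with `colony_id`, `R0_true`, `dRR_max_true`,
#'   `brightness`.
#' @export
sample_sensor_truths <- function(n, sensor = sensor_params(), seed = NULL) {
  with_seed_if(seed, data.frame(
    colony_id = seq_len(n),
    R0_true = rlnorm(n, sensor$R0_meanlog, sensor$R0_sdlog),
    dRR_max_true = rlnorm(n, sensor$dRR_meanlog, sensor$dRR_sdlog),
    brightness = rlnorm(n, sensor$brightness_meanlog, sensor$brightness_sdlog)
  ))
}

#' Plant high-performing winner colonies into a sensor-truth table
#'
#' Overwrites the maximal response of `n_winners` randomly chosen colonies
#' with `factor` times the library median, emulating rare strong variants
#' whose recovery a screen should be judged on.
#'
#' @param truths data.frame from [sample_sensor_truths()].
#' @param n_winners number of winners to plant.
#' @param factor multiple of the library median response.
#' @param seed optional integer seed.
#' @return list with `truths` (modified table) and `winner_ids`.
#' @export
plant_winners <- function(truths, n_winners = 5, factor = 3, seed = NULL) {
  if (n_winners > nrow(truths)) stop("n_winners exceeds number of colonies")
  ids <- with_seed_if(seed, sample(nrow(truths), n_winners))
  truths$dRR_max_true[ids] <- factor * median(truths$dRR_max_true)
  list(truths = truths, winner_ids = sort(truths$colony_id[ids]))
}

#' Build a spray deposition field
#'
#' The deposition field d(x, y) in \[0, 1\] scales each colony's realized
#' response. Three models: `uniform` (d = 1 everywhere, ideal delivery);
#' `gun` (smooth radial decline d(r) = 1 - g (r / plate_radius)^p, the
#' improved spray-gun protocol aimed at the plate center); `bottle`
#' (radial decline multiplied by a patchy log-normal random field,
#' emulating uneven hand spraying).
#'
#' @param model `"uniform"`, `"gun"` or `"bottle"`.
#' @param dim image dimensions, scalar or `c(nrow, ncol)`.
#' @param plate_radius plate radius in pixels.
#' @param center spray center `(row, col)`, 0-based; default image center.
#' @param params model parameters: `gradient` (g, default 0.5 gun / 0.3
#'   bottle), `power` (p, default 1), `patch_sdlog` (bottle patch
#'   log-amplitude, default 0.5), `patch_scale` (bottle patch correlation
#'   length in px, default 30).
#' @param seed optional integer seed (bottle patches).
#' @return object of class `spray_field`: list with `model`, `deposition`
#'   matrix, `center`, `plate_radius`, `params`.
#' @export
make_spray_field <- function(model = c("uniform", "gun", "bottle"),
                             dim, plate_radius, center = NULL,
                             params = list(), seed = NULL) {
  model <- match.arg(model)
  if (length(dim) == 1L) dim <- c(dim, dim)
  if (is.null(center)) center <- (dim - 1) / 2
  defaults <- list(gradient = if (model == "bottle") 0.3 else 0.5,
                   power = 1, patch_sdlog = 0.5, patch_scale = 30)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown spray params: ",
                            paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)

  r <- radial_distance(dim[1], dim[2], center)
  dep <- switch(model,
    uniform = matrix(1, dim[1], dim[2]),
    gun = 1 - p$gradient * (r / plate_radius)^p$power,
    bottle = {
      radial <- pmin(pmax(1 - p$gradient * (r / plate_radius)^p$power, 0), 1)
      z <- with_seed_if(seed, matrix(rnorm(prod(dim)), dim[1], dim[2]))
      z <- smooth_field(z, p$patch_scale)
      z <- (z - mean(z)) / sd(z)
      patch <- exp(p$patch_sdlog * z)
      patch <- patch / max(patch[r <= plate_radius])
      radial * patch
    })
  dep <- pmin(pmax(dep, 0), 1)
  structure(list(model = model, deposition = dep, center = center,
                 plate_radius = plate_radius, params = p),
            class = "spray_field")
}

#' Look up deposition at (possibly fractional) 0-based positions
#' @param field a `spray_field`.
#' @param row,col 0-based pixel coordinates (vectors).
#' @return deposition values in \[0, 1\].
#' @export
deposition_at <- function(field, row, col) {
  field$deposition[cbind(round(row) + 1L, round(col) + 1L)]
}

#' Acquisition frame specification
#'
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param application_frame 0-based index of the frame at which the ligand
#'   is applied (response kinetics start there).
#' @return list of class `frames_spec`.
#' @export
frames_spec <- function(n_frames = 16, frame_interval = 30,
                        application_frame = 4) {
  if (application_frame < 0 || application_frame >= n_frames)
    stop("application_frame must lie within the frame range")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 application_frame = as.integer(application_frame),
                 frame_times = (seq_len(n_frames) - 1) * frame_interval),
            class = "frames_spec")
}

#' Optical / background rendering parameters
#'
#' Background is a constant autofluorescence level (higher on agar than on
#' white blotting paper; agar additionally carries low-frequency mottle).
#' Vignetting is a radially symmetric multiplicative field, mild by
#' default (>= 0.92 at the image corners). `artifact_gain` > 0 enables a
#' FRET-independent acceptor-brightening artifact: both acceptor-emission
#' channels gain a factor (1 + artifact_gain * s(t)) after application,
#' emulating pH-driven brightening of the acceptor fluorophore.
#'
#' @param background_mode `"paper"` or `"agar"`.
#' @param background_level expected background photons per pixel; default
#'   20 (paper) or 60 (agar).
#' @param mottle_amplitude relative amplitude of agar background mottle.
#' @param mottle_scale mottle correlation length in pixels.
#' @param vignette_strength relative fall-off at the image corner.
#' @param acceptor_direct_gain direct-acceptor brightness relative to the
#'   donor-channel brightness.
#' @param artifact_gain FRET-independent acceptor gain amplitude (0 = off).
#' @return list of class `optics_params`.
#' @export
optics_params <- function(background_mode = c("paper", "agar"),
                          background_level = NULL,
                          mottle_amplitude = 0.25, mottle_scale = 40,
                          vignette_strength = 0.08,
                          acceptor_direct_gain = 2.0,
                          artifact_gain = 0) {
  background_mode <- match.arg(background_mode)
  if (is.null(background_level))
    background_level <- if (background_mode == "paper") 20 else 60
  if (artifact_gain < -1) stop("artifact_gain must be >= -1")
  structure(list(background_mode = background_mode,
                 background_level = background_level,
                 mottle_amplitude = mottle_amplitude,
                 mottle_scale = mottle_scale,
                 vignette_strength = vignette_strength,
                 acceptor_direct_gain = acceptor_direct_gain,
                 artifact_gain = artifact_gain),
            class = "optics_params")
}

#' Camera noise parameters
#'
#' Shot noise is Poisson in the expected photon count; read noise is
#' additive Gaussian; `quantize` rounds to integer counts and clips at 0
#' (CCD analog-to-digital conversion). [noise_off()] disables everything,
#' giving the exact noise-free expectation.
#'
#' @param shot_noise logical, Poisson photon noise.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param quantize round to nonnegative integer counts.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(shot_noise = TRUE, read_noise_sd = 3,
                         quantize = TRUE) {
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(shot_noise = shot_noise, read_noise_sd = read_noise_sd,
                 quantize = quantize), class = "noise_params")
}

#' @rdname noise_params
#' @export
noise_off <- function() noise_params(FALSE, 0, FALSE)

#' Response kinetics parameters
#'
#' After ligand application the sensor response rises as a saturating
#' exponential s(t) = 1 - exp(-(t - t_app) / tau); s = 0 before and at
#' application.
#'
#' @param tau time constant in seconds.
#' @return list of class `kinetics_params`.
#' @export
kinetics_params <- function(tau = 30) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  structure(list(tau = tau), class = "kinetics_params")
}

# Gaussian smoothing of a random field, with the kernel radius capped so
# the filter never exceeds the image (gblur requires filter <= image).
smooth_field <- function(z, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(z))
  if (rmax %% 2 == 0) rmax <- rmax - 1
  as.matrix(EBImage::gblur(z, sigma = sigma, radius = min(r, rmax)))
}

# Saturating-exponential response time course, s(t) in [0, 1].
response_s <- function(frame_times, application_frame, tau) {
  t_app <- frame_times[application_frame + 1L]
  s <- 1 - exp(-pmax(frame_times - t_app, 0) / tau)
  s[frame_times <= t_app] <- 0
  s
}

#' Render a synthetic screening experiment
#'
#' Produces the three-channel time-lapse image stack and the matching
#' ground-truth manifest. For every colony the expected (noise-free)
#' channel means obey
#' `R(t) = donor_ex_acceptor_em / donor_ex_donor_em
#'       = R0_true * (1 + dRR_max_true * d * s(t))`,
#' with `d` the spray deposition at the colony center and `s(t)` the
#' response time course; the direct-acceptor channel is independent of
#' `R(t)` except under the optional acceptor-brightening artifact.
#' Colonies are rendered as flat-top disks with a Gaussian-smoothed rim.
#'
#' @param layout a `colony_layout`.
#' @param truths sensor-truth data.frame (one row per colony, in layout
#'   order).
#' @param spray_field a `spray_field` whose grid defines the image size.
#' @param optics an [optics_params()] list.
#' @param noise a [noise_params()] list.
#' @param kinetics a [kinetics_params()] list.
#' @param frames a [frames_spec()] list.
#' @param rim_sigma Gaussian rim width of the colony profile, pixels.
#' @param seed optional integer seed; identical seeds and configs give
#'   bit-identical stacks.
#' @return list with `stack` (class `plate_stack`: named list of
#'   `nrow x ncol x n_frames` arrays per channel plus acquisition
#'   metadata) and `manifest` (data.frame: `colony_id`, `row`, `col`,
#'   `radius`, `R0_true`, `dRR_max_true`, `brightness`, `deposition`,
#'   `realized_dRR`).
#' @export
render_experiment <- function(layout, truths, spray_field,
                              optics = optics_params(),
                              noise = noise_params(),
                              kinetics = kinetics_params(),
                              frames = frames_spec(),
                              rim_sigma = 1.0, seed = NULL) {
  n <- nrow(layout$positions)
  if (nrow(truths) != n)
    stop("dimension mismatch: ", n, " colonies in layout but ",
         nrow(truths), " sensor truths")
  dims <- dim(spray_field$deposition)
  nr <- dims[1]; nc <- dims[2]
  if (!is.null(layout$img_dim) && any(layout$img_dim != dims))
    stop("dimension mismatch: layout img_dim ", layout$img_dim,
         " vs spray field grid ", nr, "x", nc)

  pos <- layout$positions
  dep <- if (n > 0) deposition_at(spray_field, pos$row, pos$col) else numeric(0)
  s_t <- response_s(frames$frame_times, frames$application_frame,
                    kinetics$tau)
  art_t <- 1 + optics$artifact_gain * s_t

  # Per-pixel colony index and profile weight (colonies do not overlap at
  # the layout's minimum separation; ties keep the heavier weight).
  wmap <- matrix(0, nr, nc)
  imap <- matrix(0L, nr, nc)
  extent <- ceiling(pos$radius + rim_sigma * sqrt(-2 * log(0.01)))
  for (i in seq_len(n)) {
    r0 <- pos$row[i]; c0 <- pos$col[i]; e <- extent[i]
    ri <- max(0, floor(r0 - e)):min(nr - 1, ceiling(r0 + e))
    ci <- max(0, floor(c0 - e)):min(nc - 1, ceiling(c0 + e))
    dd <- sqrt(outer((ri - r0)^2, (ci - c0)^2, "+"))
    w <- exp(-pmax(dd - pos$radius[i], 0)^2 / (2 * rim_sigma^2))
    w[w < 0.01] <- 0
    sub_r <- ri + 1L; sub_c <- ci + 1L
    old_w <- wmap[sub_r, sub_c]
    old_i <- imap[sub_r, sub_c]
    take <- w > old_w
    old_w[take] <- w[take]
    old_i[take] <- i
    wmap[sub_r, sub_c] <- old_w
    imap[sub_r, sub_c] <- old_i
  }

  vr <- radial_distance(nr, nc, c((nr - 1) / 2, (nc - 1) / 2))
  vign <- 1 - optics$vignette_strength * (vr / max(vr))^2

  out <- with_seed_if(seed, {
    bg <- matrix(optics$background_level, nr, nc)
    if (optics$background_mode == "agar" && optics$mottle_amplitude > 0) {
      z <- matrix(rnorm(nr * nc), nr, nc)
      z <- smooth_field(z, optics$mottle_scale)
      z <- (z - mean(z)) / sd(z)
      bg <- bg * pmax(1 + optics$mottle_amplitude * z, 0.1)
    }
    nt <- frames$n_frames
    images <- lapply(CHANNELS, function(ch) array(0, c(nr, nc, nt)))
    names(images) <- CHANNELS
    idx1 <- as.vector(imap) + 1L
    wvec <- as.vector(wmap)
    vv <- as.vector(vign)
    bgv <- as.vector(bg)
    for (ch in CHANNELS) {
      for (f in seq_len(nt)) {
        amp <- switch(ch,
          donor_ex_donor_em = truths$brightness,
          donor_ex_acceptor_em = truths$brightness * truths$R0_true *
            (1 + truths$dRR_max_true * dep * s_t[f]) * art_t[f],
          acceptor_ex_acceptor_em = truths$brightness *
            optics$acceptor_direct_gain * art_t[f])
        av <- c(0, amp)[idx1]
        expected <- vv * (bgv + wvec * av)
        if (any(expected < 0)) stop("negative expected intensity")
        x <- if (noise$shot_noise) rpois(length(expected), expected)
             else expected
        if (noise$read_noise_sd > 0)
          x <- x + rnorm(length(x), 0, noise$read_noise_sd)
        if (noise$quantize) x <- round(x)
        if (noise$read_noise_sd > 0 || noise$quantize) x <- pmax(x, 0)
        images[[ch]][, , f] <- x
      }
    }
    images
  })

  stack <- structure(list(images = out, channels = CHANNELS,
                          frame_times = frames$frame_times,
                          application_frame = frames$application_frame,
                          background_mode = optics$background_mode),
                     class = "plate_stack")
  manifest <- data.frame(colony_id = seq_len(n),
                         row = pos$row, col = pos$col, radius = pos$radius,
                         R0_true = truths$R0_true,
                         dRR_max_true = truths$dRR_max_true,
                         brightness = truths$brightness,
                         deposition = dep,
                         realized_dRR = truths$dRR_max_true * dep)
  list(stack = stack, manifest = manifest)
}

#' @export
print.plate_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("plate_stack:", d[1], "x", d[2], "px,", d[3], "frames,",
      length(x$images), "channels\n")
  cat("  application frame:", x$application_frame,
      " background:", x$background_mode, "\n")
  invisible(x)
}

#' Simulate a complete screening plate
#'
#' Convenience wrapper: layout + sensor truths + spray field + render,
#' with per-stage sub-seeds derived from one master seed.
#'
#' @param n_colonies colonies per plate.
#' @param plate_radius plate radius in pixels (image side is
#'   `2 * (plate_radius + 25)` px).
#' @param min_separation minimum colony center separation, pixels.
#' @param radius_range colony radius range, pixels.
#' @param spray_model `"uniform"`, `"gun"` or `"bottle"`.
#' @param spray_params spray model parameters, see [make_spray_field()].
#' @param sensor sensor-library distribution, see [sensor_params()].
#' @param truths optional explicit sensor-truth table overriding `sensor`.
#' @param optics,noise,kinetics,frames rendering parameter lists.
#' @param seed master seed.
#' @return list with `stack`, `manifest`, `layout`, `spray_field`.
#' @export
simulate_plate <- function(n_colonies = 750, plate_radius = 395,
                           min_separation = 18, radius_range = c(3.5, 5),
                           spray_model = "uniform", spray_params = list(),
                           sensor = sensor_params(), truths = NULL,
                           optics = optics_params(),
                           noise = noise_params(),
                           kinetics = kinetics_params(),
                           frames = frames_spec(), seed = NULL) {
  layout <- sample_colony_layout(n_colonies, plate_radius, min_separation,
                                 radius_range,
                                 seed = derive_seed(seed, "layout"))
  if (is.null(truths))
    truths <- sample_sensor_truths(n_colonies, sensor,
                                   seed = derive_seed(seed, "sensors"))
  spray <- make_spray_field(spray_model, dim = layout$img_dim,
                            plate_radius = plate_radius,
                            params = spray_params,
                            seed = derive_seed(seed, "spray"))
  res <- render_experiment(layout, truths, spray, optics = optics,
                           noise = noise, kinetics = kinetics,
                           frames = frames,
                           seed = derive_seed(seed, "noise"))
  c(res, list(layout = layout, spray_field = spray))
}

#' Degenerate-codon library diversity arithmetic
#'
#' Enumerates all codons of a degenerate scheme, translates them with the
#' standard genetic code, and reports the distinct non-stop amino acids,
#' the number of stop codons, and the amino-acid sequence space for a
#' given number of randomized positions. The NNB scheme (N = A/C/G/T,
#' B = C/G/T) encodes all 20 amino acids while reducing stop-codon
#' frequency, which is why it is the usual choice for linker
#' randomization.
#'
#' @param n_random_positions number of randomized codon positions (>= 0).
#' @param codon_scheme `"NNB"`, `"NNK"` or `"NNN"`.
#' @return list with `codon_count`, `aa_alphabet_size`,
#'   `stop_codon_count`, `aa_sequence_space`.
#' @export
library_diversity <- function(n_random_positions,
                              codon_scheme = c("NNB", "NNK", "NNN")) {
  codon_scheme <- match.arg(codon_scheme)
  stopifnot_scalar(n_random_positions, "n_random_positions")
  if (n_random_positions < 0) stop("n_random_positions must be >= 0")
  N <- c("A", "C", "G", "T")
  third <- switch(codon_scheme, NNB = c("C", "G", "T"),
                  NNK = c("G", "T"), NNN = N)
  codons <- as.vector(outer(as.vector(outer(N, N, paste0)), third, paste0))
  aa <- Biostrings::GENETIC_CODE[codons]
  aas <- unique(aa[aa != "*"])
  list(codon_count = length(codons),
       aa_alphabet_size = length(aas),
       stop_codon_count = sum(aa == "*"),
       aa_sequence_space = length(aas)^n_random_positions)
}
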