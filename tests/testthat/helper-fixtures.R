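# Shared fixtures and independent oracles, all built in code.

# A minimal hand-built stack: constant background `bg`, one or more
# square "colonies" whose per-channel, per-frame amplitudes are given
# explicitly. Rows of `colonies`: list(rows, cols, dd, da, aa) where
# dd/da/aa are length-n_frames amplitude vectors added on top of bg.
build_stack <- function(dim = c(40, 40), n_frames = 6, bg = 10,
                        colonies = list(), frame_interval = 30,
                        application_frame = 2) {
  mk <- function(which) {
    arr <- array(bg, c(dim, n_frames))
    for (col in colonies) {
      amp <- col[[which]]
      for (f in seq_len(n_frames))
        arr[col$rows, col$cols, f] <- bg + amp[f]
    }
    arr
  }
  plate_stack(list(donor_ex_donor_em = mk("dd"),
                   donor_ex_acceptor_em = mk("da"),
                   acceptor_ex_acceptor_em = mk("aa")),
              frame_times = (seq_len(n_frames) - 1) * frame_interval,
              application_frame = application_frame)
}

# Independent flood-fill connected-component oracle (stack-based DFS).
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    todo <- start
    lab[start] <- cur
    while (length(todo)) {
      p <- todo[length(todo)]; todo <- todo[-length(todo)]
      pr <- ((p - 1L) %% nr) + 1L; pc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(nbr))) {
        r2 <- pr + nbr[k, 1]; c2 <- pc + nbr[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; todo <- c(todo, q) }
      }
    }
  }
  lab
}

# Canonical form of a labeling: relabel components by first occurrence
# in column-major order, so two labelings can be compared directly.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# Brute-force binary morphology with a Euclidean disk: direct min/max
# over the neighborhood, padding outside the image as foreground for
# erosion and background for dilation.
brute_erode <- function(mask, radius) {
  offs <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (k in seq_len(nrow(offs))) {
      r2 <- i + offs[k, 1]; c2 <- j + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r2, c2]) { out[i, j] <- FALSE; break }
    }
  }
  out
}

brute_dilate <- function(mask, radius) {
  offs <- disk_offsets(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j]) next
    for (k in seq_len(nrow(offs))) {
      r2 <- i + offs[k, 1]; c2 <- j + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r2, c2]) { out[i, j] <- TRUE; break }
    }
  }
  out
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, ])
}

disk_mask <- function(dim, center, radius) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# A small, fast simulated plate used across test files.
small_plate <- function(seed = 42, n = 60, spray_model = "uniform",
                        noise = noise_params(), sensor = sensor_params(),
                        truths = NULL, optics = optics_params(),
                        frames = frames_spec(8, 60, 2)) {
  simulate_plate(n_colonies = n, plate_radius = 110,
                 spray_model = spray_model, sensor = sensor,
                 truths = truths, optics = optics, noise = noise,
                 frames = frames, seed = seed)
}

# Join detected colony table to manifest truth via centroid matching.
join_truth <- function(tab, colony_map, manifest) {
  ev <- evaluate_detection(colony_map, manifest)
  m <- merge(ev$matches, manifest, by.x = "truth_id", by.y = "colony_id")
  merge(m, tab, by = "colony_id")
}
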