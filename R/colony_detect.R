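# Colony identification on the direct-acceptor-excitation image:
# k-sigma intensity threshold -> binary erosion + opening with Euclidean
# disk structuring elements -> connected-component labeling -> area and
# border filters. The direct-acceptor channel is used because it is
# FRET-independent: colony visibility there does not depend on the
# sensor's ratio state.

#' Estimate the colony-identification intensity threshold
#'
#' Threshold = center + k * spread of the pixel intensity distribution.
#' `"plain"` uses mean and SD of all pixels; `"robust"` (default) uses
#' median and the normal-consistent MAD (1.4826 * MAD), which is
#' insensitive to the bright-colony tail on densely covered plates. A
#' constant image makes the robust spread 0; the estimator then falls
#' back to plain mode with a warning.
#'
#' @param image numeric matrix.
#' @param stat_mode `"robust"` or `"plain"`.
#' @param k spread multiplier (the classical choice is 3).
#' @return scalar intensity threshold.
#' @export
estimate_threshold <- function(image, stat_mode = c("robust", "plain"),
                               k = 3) {
  stat_mode <- match.arg(stat_mode)
  if (length(image) == 0) stop("image is empty")
  x <- as.numeric(image)
  if (stat_mode == "robust") {
    spread <- mad(x)  # already scaled by 1.4826
    if (spread == 0) {
      warning("robust spread (MAD) is zero; falling back to plain mode")
      return(estimate_threshold(image, "plain", k))
    }
    median(x) + k * spread
  } else {
    mean(x) + k * sd0(x)
  }
}

# SD with a 0 for length-1/constant degenerate input (sd() returns NA
# for n = 1, which would poison the threshold).
sd0 <- function(x) {
  s <- sd(x)
  if (is.na(s)) 0 else s
}

# Exact Euclidean-disk morphology via the distance transform:
# erosion keeps a foreground pixel iff its distance to the nearest
# background pixel exceeds the radius; dilation is the dual on the
# complement. Pixels outside the image border are treated as foreground
# for erosion (background for dilation), the usual padding convention.
erode_disk <- function(mask, radius) {
  if (radius == 0) return(mask)
  d <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  mask & (d > radius)
}

dilate_disk <- function(mask, radius) {
  if (radius == 0) return(mask)
  d <- as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
  mask | (d <= radius)
}

#' Clean a binary colony mask
#'
#' Applies binary erosion, then morphological opening (erosion followed
#' by dilation), with Euclidean disk structuring elements. Both
#' operations are anti-extensive, so the output is always a subset of the
#' input; the erosion trims rim glow and severs one-pixel bridges, the
#' opening removes remaining specks smaller than its disk.
#'
#' @param mask logical matrix.
#' @param erosion_radius disk radius of the initial erosion, pixels.
#' @param opening_radius disk radius of the opening, pixels.
#' @return logical matrix, subset of `mask`.
#' @export
clean_mask <- function(mask, erosion_radius = 1, opening_radius = 2) {
  if (erosion_radius < 0 || opening_radius < 0)
    stop("structuring-element radii must be >= 0")
  mask <- mask > 0
  storage.mode(mask) <- "logical"
  m <- erode_disk(mask, erosion_radius)
  dilate_disk(erode_disk(m, opening_radius), opening_radius) & m
}

# Connected-component labeling of a binary mask. Adjacency edges between
# foreground pixels (4- or 8-neighborhood) are handed to igraph's
# component search; labels are then 1..n_components in arbitrary order.
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  vid <- match(seq_len(nr * nc), idx)  # pixel -> vertex id (NA if bg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- NULL
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- row_i + o[1]; c2 <- col_i + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(vid[nb])
    if (any(keep))
      edges <- rbind(edges, cbind(vid[idx[ok]][keep], vid[nb][keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Label colonies in a cleaned binary mask
#'
#' Connected components of the mask become colony candidates; components
#' smaller than `min_area`, larger than `max_area`, are dropped
#' (mis-identified particles and merged clumps). Components intersecting
#' the `border_margin`-pixel frame around the image are kept but flagged
#' `touches_border` (paper-edge artifacts; excluded from ranking by
#' default downstream). Labels are renumbered contiguously by descending
#' area, ties by centroid row then column.
#'
#' @param mask logical matrix (cleaned colony mask).
#' @param connectivity 4 or 8 (default 8).
#' @param min_area minimum component area in pixels.
#' @param max_area maximum area; `NULL` means 10x the median component
#'   area (computed after the `min_area` filter).
#' @param border_margin width of the border frame in pixels.
#' @return object of class `colony_map`: list with `label_image`
#'   (integer matrix, 0 = background) and `records` (data.frame:
#'   `colony_id`, `row`, `col` (0-based centroid), `area_px`,
#'   `radius_px` (equivalent-disk radius), `touches_border`).
#' @export
label_colonies <- function(mask, connectivity = 8, min_area = 20,
                           max_area = NULL, border_margin = 5) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- label_components(mask, connectivity)
  ncomp <- max(lab)
  empty <- list(
    label_image = matrix(0L, nr, nc),
    records = data.frame(colony_id = integer(0), row = numeric(0),
                         col = numeric(0), area_px = integer(0),
                         radius_px = numeric(0),
                         touches_border = logical(0)))
  class(empty) <- "colony_map"
  if (ncomp == 0) return(empty)

  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- areas >= min_area
  if (is.null(max_area)) {
    med <- median(areas[keep])
    max_area <- if (is.na(med)) Inf else 10 * med
  }
  keep <- keep & areas <= max_area
  if (!any(keep)) return(empty)

  idx <- which(lab > 0)
  comp <- lab[idx]
  row0 <- ((idx - 1L) %% nr)        # 0-based
  col0 <- ((idx - 1L) %/% nr)
  cent_r <- rowsum(row0, comp)[, 1] / areas
  cent_c <- rowsum(col0, comp)[, 1] / areas
  m <- border_margin
  on_border <- row0 < m | row0 >= nr - m | col0 < m | col0 >= nc - m
  border_flag <- rowsum(as.numeric(on_border), comp)[, 1] > 0

  kept <- which(keep)
  ord <- kept[order(-areas[kept], cent_r[kept], cent_c[kept])]
  relabel <- integer(ncomp)
  relabel[ord] <- seq_along(ord)
  new_lab <- matrix(0L, nr, nc)
  new_lab[idx] <- relabel[comp]

  records <- data.frame(colony_id = seq_along(ord),
                        row = cent_r[ord], col = cent_c[ord],
                        area_px = as.integer(areas[ord]),
                        radius_px = sqrt(areas[ord] / pi),
                        touches_border = border_flag[ord])
  rownames(records) <- NULL
  structure(list(label_image = new_lab, records = records),
            class = "colony_map")
}

#' @export
print.colony_map <- function(x, ...) {
  cat("colony_map:", nrow(x$records), "colonies,",
      sum(x$records$touches_border), "touching border\n")
  invisible(x)
}

#' Detection parameters
#'
#' @param stat_mode threshold statistic mode, `"robust"` or `"plain"`.
#' @param k_sigma threshold spread multiplier.
#' @param erosion_radius,opening_radius mask-cleaning disk radii, px.
#' @param connectivity component connectivity, 4 or 8.
#' @param min_area,max_area component area filter, px (`NULL` max = 10x
#'   median).
#' @param border_margin border frame width, px.
#' @param channel detection channel (default direct acceptor).
#' @param frame 0-based detection frame index.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(stat_mode = "robust", k_sigma = 3,
                          erosion_radius = 1, opening_radius = 2,
                          connectivity = 8, min_area = 20,
                          max_area = NULL, border_margin = 5,
                          channel = "acceptor_ex_acceptor_em", frame = 0) {
  structure(list(stat_mode = stat_mode, k_sigma = k_sigma,
                 erosion_radius = erosion_radius,
                 opening_radius = opening_radius,
                 connectivity = connectivity, min_area = min_area,
                 max_area = max_area, border_margin = border_margin,
                 channel = channel, frame = frame),
            class = "detect_params")
}

#' Detect colonies in a plate image stack
#'
#' Thresholds the configured detection frame (by default the first
#' direct-acceptor-excitation frame), cleans the binary mask with erosion
#' and opening, and labels the surviving components.
#'
#' @param stack a `plate_stack`.
#' @param params a [detect_params()] list.
#' @return a `colony_map`, see [label_colonies()].
#' @export
detect_colonies <- function(stack, params = detect_params()) {
  if (!params$channel %in% names(stack$images))
    stop("stack has no channel '", params$channel, "'")
  img <- stack$images[[params$channel]][, , params$frame + 1L]
  thr <- estimate_threshold(img, params$stat_mode, params$k_sigma)
  mask <- clean_mask(img > thr, params$erosion_radius,
                     params$opening_radius)
  label_colonies(mask, params$connectivity, params$min_area,
                 params$max_area, params$border_margin)
}

#' Match detected colonies to a ground-truth manifest
#'
#' Greedy nearest-centroid assignment: detections are matched to the
#' closest unmatched truth colony within one true colony radius.
#'
#' @param colony_map a `colony_map`.
#' @param manifest a ground-truth manifest from [render_experiment()].
#' @return list with `recall`, `precision`, `n_matched`, and `matches`
#'   (data.frame `colony_id` (detected), `truth_id`, `dist`).
#' @export
evaluate_detection <- function(colony_map, manifest) {
  det <- colony_map$records
  nd <- nrow(det); nt <- nrow(manifest)
  if (nd == 0 || nt == 0)
    return(list(recall = 0, precision = if (nd == 0) NA_real_ else 0,
                n_matched = 0L,
                matches = data.frame(colony_id = integer(0),
                                     truth_id = integer(0),
                                     dist = numeric(0))))
  d2 <- outer(det$row, manifest$row, "-")^2 +
        outer(det$col, manifest$col, "-")^2
  within <- sqrt(d2) <= matrix(manifest$radius, nd, nt, byrow = TRUE)
  cand <- which(within, arr.ind = TRUE)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  out <- vector("list", min(nd, nt)); k <- 0L
  for (i in seq_len(nrow(cand))) {
    di <- cand[i, 1]; ti <- cand[i, 2]
    if (used_d[di] || used_t[ti]) next
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    k <- k + 1L
    out[[k]] <- data.frame(colony_id = det$colony_id[di],
                           truth_id = manifest$colony_id[ti],
                           dist = sqrt(d2[di, ti]))
  }
  matches <- if (k > 0) do.call(rbind, out[seq_len(k)])
             else data.frame(colony_id = integer(0), truth_id = integer(0),
                             dist = numeric(0))
  list(recall = k / nt, precision = k / nd, n_matched = k,
       matches = matches)
}
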