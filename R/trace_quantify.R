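# Per-colony intensity time series and FRET ratio quantification.
#
# The ratio estimator is the ratio of background-corrected mean
# intensities over the colony's labeled pixels (not the mean of
# pixelwise ratios), which is far better behaved at low photon counts.
# Background can be estimated globally (per-frame median of unlabeled
# pixels) or locally (median of an annulus around each colony); the
# local annulus is the default because it also tracks slow multiplicative
# fields such as vignetting.

#' Extract per-colony channel intensity and ratio traces
#'
#' For every colony and frame, the mean intensity over the colony's
#' labeled pixels is computed per channel and a background estimate is
#' subtracted. The FRET ratio trace is
#' `R(t) = donor_ex_acceptor_em(t) / donor_ex_donor_em(t)`, set to `NA`
#' wherever the corrected donor intensity is not positive.
#'
#' @param stack a `plate_stack`.
#' @param colony_map a `colony_map` matching the stack dimensions.
#' @param background `"local"` (annulus median, default), `"global"`
#'   (per-frame median of all unlabeled pixels) or `"none"`.
#' @param annulus_gap gap between colony radius and annulus, pixels.
#' @param annulus_width annulus width, pixels.
#' @return object of class `colony_traces`: list with `intensity`
#'   (array `n_colonies x n_channels x n_frames`, background-corrected),
#'   `ratio` (matrix `n_colonies x n_frames`), `colony_ids`,
#'   `frame_times`, `application_frame`.
#' @export
extract_traces <- function(stack, colony_map,
                           background = c("local", "global", "none"),
                           annulus_gap = 1, annulus_width = 4) {
  background <- match.arg(background)
  lab <- colony_map$label_image
  d <- dim(stack$images[[1]])
  if (!all(dim(lab) == d[1:2]))
    stop("dimension mismatch: label map ", nrow(lab), "x", ncol(lab),
         " vs stack ", d[1], "x", d[2])
  rec <- colony_map$records
  n <- nrow(rec)
  nt <- d[3]
  nch <- length(stack$channels)
  if (n > 0 && any(rec$area_px == 0)) stop("colony with zero pixels")

  intensity <- array(NA_real_, c(n, nch, nt),
                     dimnames = list(NULL, stack$channels, NULL))
  if (n > 0) {
    fg_idx <- which(lab > 0)
    fg_lab <- lab[fg_idx]
    # annulus pixel indices per colony (unlabeled pixels only, nearest
    # colony wins where annuli overlap)
    ann_idx <- NULL
    if (background == "local") {
      nr <- d[1]; nc2 <- d[2]
      ann_list <- vector("list", n)
      for (i in seq_len(n)) {
        r0 <- rec$row[i]; c0 <- rec$col[i]
        rin <- rec$radius_px[i] + annulus_gap
        rout <- rin + annulus_width
        ri <- max(0, floor(r0 - rout)):min(nr - 1, ceiling(r0 + rout))
        ci <- max(0, floor(c0 - rout)):min(nc2 - 1, ceiling(c0 + rout))
        dd <- sqrt(outer((ri - r0)^2, (ci - c0)^2, "+"))
        sel <- dd > rin & dd <= rout
        pix <- as.vector(outer(ri + 1L, (ci) * nr, "+"))[as.vector(sel)]
        pix <- pix[lab[pix] == 0L]
        if (length(pix) < 8)
          stop("annulus of colony ", rec$colony_id[i],
               " has too few background pixels")
        ann_list[[i]] <- pix
      }
      ann_idx <- ann_list
    }
    for (ch in seq_len(nch)) {
      arr <- stack$images[[ch]]
      for (f in seq_len(nt)) {
        frame <- arr[, , f]
        sums <- rowsum(frame[fg_idx], fg_lab)[, 1]
        means <- sums / rec$area_px
        bg <- switch(background,
          none = 0,
          global = median(frame[lab == 0L]),
          local = vapply(ann_idx, function(p) median(frame[p]),
                         numeric(1)))
        intensity[, ch, f] <- means - bg
      }
    }
  }
  donor <- intensity[, "donor_ex_donor_em", , drop = FALSE]
  fret <- intensity[, "donor_ex_acceptor_em", , drop = FALSE]
  ratio <- matrix(NA_real_, n, nt)
  ok <- !is.na(donor) & donor > 0
  ratio[ok[, 1, ]] <- fret[ok] / donor[ok]
  structure(list(intensity = intensity, ratio = ratio,
                 colony_ids = rec$colony_id,
                 frame_times = stack$frame_times,
                 application_frame = stack$application_frame),
            class = "colony_traces")
}

#' @export
print.colony_traces <- function(x, ...) {
  cat("colony_traces:", length(x$colony_ids), "colonies,",
      length(x$frame_times), "frames\n")
  invisible(x)
}

# Normalize a frame window: `window` is 0-based half-open [start, end).
check_window <- function(window, n_frames, what) {
  if (length(window) != 2L || window[1] < 0 || window[2] > n_frames ||
      window[2] <= window[1])
    stop(what, " must be a nonempty 0-based half-open [start, end) ",
         "window within the frame range")
  seq.int(window[1] + 1L, window[2])
}

#' Compute the basal ratio R0
#'
#' Mean of the ratio trace over a baseline window that must lie entirely
#' before the application frame.
#'
#' @param ratio_trace numeric ratio trace (one colony).
#' @param application_frame 0-based application frame index.
#' @param baseline_window 0-based half-open `c(start, end)`; default all
#'   frames before application.
#' @return scalar R0.
#' @export
compute_R0 <- function(ratio_trace, application_frame,
                       baseline_window = NULL) {
  if (is.null(baseline_window)) baseline_window <- c(0, application_frame)
  idx <- check_window(baseline_window, length(ratio_trace),
                      "baseline_window")
  if (baseline_window[2] > application_frame)
    stop("baseline_window must end at or before the application frame")
  vals <- ratio_trace[idx]
  if (any(is.na(vals) | vals <= 0))
    stop("nonpositive or undefined ratio in baseline window ",
         "(nonpositive donor intensity)")
  mean(vals)
}

#' Compute the relative ratio change dRR
#'
#' `dRR = (R_resp - R0) / R0`, where `R_resp` is the mean ratio over the
#' response window (`"mean-window"`, default), the maximum
#' post-application ratio (`"max"`), or the final frame (`"endpoint"`,
#' for slow multi-hour responses).
#'
#' @param ratio_trace numeric ratio trace (one colony).
#' @param R0 basal ratio (> 0).
#' @param application_frame 0-based application frame index.
#' @param response_mode `"mean-window"`, `"max"` or `"endpoint"`.
#' @param response_window 0-based half-open `c(start, end)`, strictly
#'   after the application frame; default the last 3 frames.
#' @return scalar dRR (1.0 = 100%).
#' @export
compute_dRR <- function(ratio_trace, R0, application_frame,
                        response_mode = c("mean-window", "max", "endpoint"),
                        response_window = NULL) {
  response_mode <- match.arg(response_mode)
  if (is.na(R0) || R0 <= 0) stop("R0 must be > 0")
  nt <- length(ratio_trace)
  R_resp <- switch(response_mode,
    "mean-window" = {
      if (is.null(response_window)) response_window <- c(nt - 3, nt)
      idx <- check_window(response_window, nt, "response_window")
      if (response_window[1] <= application_frame)
        stop("response_window must start after the application frame")
      mean(ratio_trace[idx])
    },
    "max" = {
      if (application_frame + 2L > nt)
        stop("no post-application frames")
      max(ratio_trace[seq.int(application_frame + 2L, nt)])
    },
    "endpoint" = ratio_trace[nt])
  (R_resp - R0) / R0
}

#' Flag FRET-independent acceptor-intensity artifacts
#'
#' An acceptor-brightening artifact (e.g. pH-driven) changes the
#' direct-acceptor intensity after application even though that channel
#' is FRET-independent. A colony is flagged when
#' `|post / pre - 1|` of its direct-acceptor intensity exceeds
#' `artifact_threshold`.
#'
#' @param traces a `colony_traces`.
#' @param artifact_threshold relative change threshold (default 0.15).
#' @param baseline_window,response_window 0-based half-open windows;
#'   defaults as in [compute_R0()] / [compute_dRR()].
#' @return logical vector, one flag per colony.
#' @export
flag_artifact <- function(traces, artifact_threshold = 0.15,
                          baseline_window = NULL, response_window = NULL) {
  if (!"acceptor_ex_acceptor_em" %in% dimnames(traces$intensity)[[2]])
    stop("direct-acceptor channel missing from traces")
  nt <- length(traces$frame_times)
  app <- traces$application_frame
  if (is.null(baseline_window)) baseline_window <- c(0, app)
  if (is.null(response_window)) response_window <- c(nt - 3, nt)
  bi <- check_window(baseline_window, nt, "baseline_window")
  ri <- check_window(response_window, nt, "response_window")
  aa <- traces$intensity[, "acceptor_ex_acceptor_em", , drop = FALSE]
  pre <- apply(aa[, 1, bi, drop = FALSE], 1, mean)
  post <- apply(aa[, 1, ri, drop = FALSE], 1, mean)
  abs(post / pre - 1) > artifact_threshold
}

#' Quantify all colonies of a stack into a colony table
#'
#' Runs [extract_traces()], [compute_R0()], [compute_dRR()] and
#' [flag_artifact()] over every detected colony. Colonies whose baseline
#' donor signal is not positive cannot be ratioed and are excluded from
#' the table (ids recorded in the `excluded` attribute) rather than
#' failing the run.
#'
#' @param stack a `plate_stack`.
#' @param colony_map a `colony_map`.
#' @param background background mode, see [extract_traces()].
#' @param baseline_window,response_window 0-based half-open windows.
#' @param response_mode see [compute_dRR()].
#' @param artifact_threshold see [flag_artifact()].
#' @return data.frame (the colony table): `colony_id`, `row`, `col`,
#'   `area_px`, `touches_border`, `R0`, `dRR`, `yfp_intensity` (mean
#'   baseline direct-acceptor intensity), `artifact_flag`; attribute
#'   `excluded` lists colony ids dropped for nonpositive baseline donor
#'   signal, attribute `traces` keeps the `colony_traces`.
#' @export
quantify_colonies <- function(stack, colony_map,
                              background = c("local", "global", "none"),
                              baseline_window = NULL,
                              response_window = NULL,
                              response_mode = "mean-window",
                              artifact_threshold = 0.15) {
  traces <- extract_traces(stack, colony_map, background)
  rec <- colony_map$records
  n <- nrow(rec)
  nt <- length(stack$frame_times)
  app <- stack$application_frame
  bw <- if (is.null(baseline_window)) c(0, app) else baseline_window
  rw <- if (is.null(response_window)) c(nt - 3, nt) else response_window
  bi <- check_window(bw, nt, "baseline_window")

  R0 <- dRR <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- traces$ratio[i, ]
    ok <- !anyNA(tr[bi]) && all(tr[bi] > 0)
    if (!ok) next
    valid[i] <- TRUE
    R0[i] <- compute_R0(tr, app, bw)
    dRR[i] <- compute_dRR(tr, R0[i], app, response_mode, rw)
  }
  art <- flag_artifact(traces, artifact_threshold, bw, rw)
  yfp <- apply(traces$intensity[, "acceptor_ex_acceptor_em", bi,
                                drop = FALSE], 1, mean)
  tab <- data.frame(colony_id = rec$colony_id, row = rec$row,
                    col = rec$col, area_px = rec$area_px,
                    touches_border = rec$touches_border,
                    R0 = R0, dRR = dRR, yfp_intensity = yfp,
                    artifact_flag = art)
  excluded <- tab$colony_id[!valid]
  if (length(excluded))
    message(length(excluded),
            " colonies excluded (nonpositive baseline donor signal)")
  tab <- tab[valid, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "excluded") <- excluded
  attr(tab, "traces") <- traces
  tab
}
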