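# Colony scoring, ranking and pick selection.
#
# The screening score is S = dRR / sqrt(R0): colonies are selected for
# their relative ratio change, with a bias towards large changes rather
# than merely low starting ratios (dividing by the square root of R0
# rather than R0 itself tempers the reward for dim baselines).

#' Screening score of a colony
#'
#' `S = dRR / sqrt(R0)`; vectorized.
#'
#' @param R0 basal ratio(s), > 0.
#' @param dRR relative ratio change(s).
#' @return numeric score(s).
#' @export
score_colony <- function(R0, dRR) {
  if (any(is.na(R0)) || any(R0 <= 0)) stop("R0 must be > 0")
  dRR / sqrt(R0)
}

#' Rank colonies by screening score
#'
#' Adds `score` and `rank` columns, ordered by descending score; ties are
#' broken by higher dRR, then lower R0, then lower colony id.
#' Border-touching and artifact-flagged colonies are excluded from the
#' ranking by default.
#'
#' @param table a colony table (needs `colony_id`, `R0`, `dRR`;
#'   `touches_border` / `artifact_flag` are honored when present).
#' @param exclude_border,exclude_artifact drop flagged colonies before
#'   ranking.
#' @return the ranked table (scored colonies only, ordered by rank);
#'   attribute `excluded` holds the dropped rows.
#' @export
rank_colonies <- function(table, exclude_border = TRUE,
                          exclude_artifact = TRUE) {
  drop <- rep(FALSE, nrow(table))
  if (exclude_border && "touches_border" %in% names(table))
    drop <- drop | table$touches_border
  if (exclude_artifact && "artifact_flag" %in% names(table))
    drop <- drop | table$artifact_flag
  excluded <- table[drop, , drop = FALSE]
  tab <- table[!drop, , drop = FALSE]
  if (nrow(tab) == 0) {
    warning("no scored colonies to rank")
    tab$score <- numeric(0); tab$rank <- integer(0)
    attr(tab, "excluded") <- excluded
    return(tab)
  }
  tab$score <- score_colony(tab$R0, tab$dRR)
  ord <- order(-tab$score, -tab$dRR, tab$R0, tab$colony_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "excluded") <- excluded
  tab
}

#' Select the top-ranked colonies for picking
#'
#' Exactly one of `fraction` / `count` must be given. In fraction mode
#' the pick count is `max(1, round(fraction * n))`, so a nonempty ranking
#' always yields at least one pick.
#'
#' @param ranked a ranked colony table from [rank_colonies()].
#' @param fraction top fraction in (0, 1] (the screening default is
#'   0.02, i.e. the best ~2% of colonies).
#' @param count explicit number of picks.
#' @return object of class `ranking_result`: list with `table` (ranked),
#'   `selection` (ordered picked colony ids), `k`, `selection_params`.
#' @export
select_top <- function(ranked, fraction = NULL, count = NULL) {
  if (is.null(fraction) == is.null(count))
    stop("give exactly one of fraction or count")
  n <- nrow(ranked)
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    k <- if (n == 0) 0L else max(1L, as.integer(round(fraction * n)))
  } else {
    if (count > n) stop("count exceeds number of ranked colonies")
    k <- as.integer(count)
  }
  structure(list(table = ranked,
                 selection = head(ranked$colony_id, k), k = k,
                 selection_params = list(fraction = fraction,
                                         count = count)),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("ranking_result:", nrow(x$table), "scored colonies,",
      x$k, "selected\n")
  invisible(x)
}

#' Select colonies relative to positive-control colonies
#'
#' Control-referenced mode for screens where the assay itself shifts the
#' apparent ratio (e.g. induced-ligand screens): picks every non-control
#' colony whose `R0` is strictly below and whose `dRR` is strictly above
#' the mean of the positive-control colonies. Negative controls are
#' reported for context only.
#'
#' @param table a colony table.
#' @param positive_control_ids colony ids of the positive controls
#'   (parental sensor plus induced ligand); at least one required.
#' @param negative_control_ids optional colony ids of negative controls.
#' @return list with `selection` (picked ids, score order),
#'   `control_means` (`R0`, `dRR`), `negative_controls`.
#' @export
select_vs_controls <- function(table, positive_control_ids,
                               negative_control_ids = integer(0)) {
  if (length(positive_control_ids) < 1)
    stop("at least one positive control id required")
  miss <- setdiff(c(positive_control_ids, negative_control_ids),
                  table$colony_id)
  if (length(miss))
    stop("control ids missing from table: ", paste(miss, collapse = ", "))
  pos <- table[table$colony_id %in% positive_control_ids, ]
  ctrl <- c(R0 = mean(pos$R0), dRR = mean(pos$dRR))
  cand <- table[!table$colony_id %in%
                  c(positive_control_ids, negative_control_ids), ]
  hits <- cand[cand$R0 < ctrl[["R0"]] & cand$dRR > ctrl[["dRR"]], ]
  if (nrow(hits) > 0)
    hits <- hits[order(-score_colony(hits$R0, hits$dRR)), ]
  list(selection = hits$colony_id, control_means = ctrl,
       negative_controls = negative_control_ids)
}

#' Write the three screening report figures and the picks CSV
#'
#' Emits the classic post-experiment report: (1) the sensor landscape,
#' R0 against dRR for every scored colony with the picks highlighted and
#' numbered by rank; (2) the ratio traces of the picked colonies; (3) the
#' plate pick map with numbered pick positions; plus `picks.csv`
#' (`rank,colony_id,row,col,R0,dRR,score`).
#'
#' @param result a `ranking_result`.
#' @param out_dir output directory (created if missing).
#' @param traces optional `colony_traces` for the trace figure (skipped
#'   with a warning when absent).
#' @param img_dim optional image dimensions for the pick map frame.
#' @return named character vector of written file paths.
#' @export
make_reports <- function(result, out_dir, traces = NULL, img_dim = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  tab <- result$table
  sel <- result$selection
  if (length(sel) == 0) warning("empty selection; reports show no picks")
  picks <- tab[match(sel, tab$colony_id), , drop = FALSE]
  paths <- c(landscape = file.path(out_dir, "landscape.png"),
             traces = file.path(out_dir, "selected_traces.png"),
             pick_map = file.path(out_dir, "pick_map.png"),
             picks_csv = file.path(out_dir, "picks.csv"))

  p1 <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$R0, y = .data$dRR)) +
    ggplot2::geom_point(color = "grey40", size = 0.8) +
    ggplot2::labs(x = "basal ratio R0", y = "ratio change ΔR/R",
                  title = "Sensor landscape") +
    ggplot2::theme_minimal()
  if (nrow(picks) > 0)
    p1 <- p1 +
      ggplot2::geom_point(data = picks, color = "gold", size = 2) +
      ggplot2::geom_text(data = cbind(picks, lab = seq_len(nrow(picks))),
                         ggplot2::aes(label = .data$lab),
                         vjust = -0.8, size = 3)
  ggplot2::ggsave(paths[["landscape"]], p1, width = 5, height = 4,
                  dpi = 120)

  if (!is.null(traces) && length(sel) > 0) {
    ids <- match(sel, traces$colony_ids)
    df <- do.call(rbind, lapply(seq_along(sel), function(i) {
      data.frame(colony = factor(sel[i]), time = traces$frame_times,
                 ratio = traces$ratio[ids[i], ])
    }))
    p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                           y = .data$ratio,
                                           color = .data$colony)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(
        xintercept = traces$frame_times[traces$application_frame + 1],
        linetype = "dashed") +
      ggplot2::labs(x = "time (s)", y = "FRET ratio R",
                    title = "Selected colony traces") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(paths[["traces"]], p2, width = 5, height = 4,
                    dpi = 120)
  } else {
    if (is.null(traces)) warning("no traces supplied; trace figure skipped")
    paths <- paths[names(paths) != "traces"]
  }

  p3 <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_point(color = "grey70", size = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Plate pick map") +
    ggplot2::theme_minimal()
  if (nrow(picks) > 0)
    p3 <- p3 +
      ggplot2::geom_point(data = picks, color = "red", size = 2) +
      ggplot2::geom_text(data = cbind(picks, lab = seq_len(nrow(picks))),
                         ggplot2::aes(label = .data$lab),
                         vjust = -0.8, size = 3, color = "red")
  ggplot2::ggsave(paths[["pick_map"]], p3, width = 5, height = 5,
                  dpi = 120)

  picks_out <- data.frame(rank = seq_len(nrow(picks)),
                          colony_id = picks$colony_id,
                          row = picks$row, col = picks$col,
                          R0 = picks$R0, dRR = picks$dRR,
                          score = picks$score)
  write.csv(picks_out, paths[["picks_csv"]], row.names = FALSE)
  paths
}

#' @importFrom ggplot2 .data
NULL
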