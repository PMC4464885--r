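# Spatial quality control: plate-wide variability summaries, the radial
# spray-gradient model and its correction, and plate-vs-reference
# comparison.
#
# Uneven spray deposition is the dominant source of dRR variability on a
# plate: the spray-gun protocol leaves a predictable radial decline of
# dRR from the spray center to the periphery, which can be modelled and
# divided out; hand-bottle spraying leaves patchy, less predictable
# fields that correction cannot fully remove.

#' Coefficient of variation, in percent
#'
#' `100 * SD / mean` with the sample SD (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * sd(values) / m
}

#' Fit the radial spray-gradient model
#'
#' Least-squares fit of `dRR ~ a + b * (r / r_max)^p`, with `r` the
#' colony distance from the spray center and `r_max` the largest colony
#' distance. The center is either supplied, taken as the image center, or
#' fitted by a coarse-to-fine grid search minimizing the residual sum of
#' squares (`"auto"`).
#'
#' @param table colony table with `row`, `col`, `dRR`.
#' @param center `"image-center"`, `"auto"`, or a numeric `(row, col)`.
#' @param exponent_p radial exponent p (default 1, linear decline).
#' @param img_dim image dimensions for the `"image-center"` mode; default
#'   twice the colony extent.
#' @return object of class `radial_model`: `center`, `a` (fitted center
#'   value), `b` (fitted decline over `r_max`), `p`, `r_max`, `rss`,
#'   `sigma` (residual SD), `n`.
#' @export
fit_radial_model <- function(table, center = "image-center",
                             exponent_p = 1, img_dim = NULL) {
  tab <- table[!is.na(table$dRR), , drop = FALSE]
  if (nrow(tab) < 10)
    stop("radial model needs at least 10 scored colonies")
  fit_at <- function(ctr) {
    r <- sqrt((tab$row - ctr[1])^2 + (tab$col - ctr[2])^2)
    r_max <- max(r)
    x <- (r / r_max)^exponent_p
    fit <- lm(tab$dRR ~ x)
    list(ctr = ctr, a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         r_max = r_max, rss = sum(fit$residuals^2),
         sigma = sd(fit$residuals))
  }
  default_ctr <- if (is.null(img_dim)) {
    c(mean(range(tab$row)), mean(range(tab$col)))
  } else rep((img_dim - 1) / 2, 2)[1:2]

  best <- if (is.numeric(center)) {
    fit_at(center)
  } else if (identical(center, "image-center")) {
    fit_at(default_ctr)
  } else if (identical(center, "auto")) {
    span <- max(diff(range(tab$row)), diff(range(tab$col))) / 4
    ctr <- default_ctr
    res <- fit_at(ctr)
    while (span > 2) {
      grid <- expand.grid(dr = seq(-span, span, length.out = 5),
                          dc = seq(-span, span, length.out = 5))
      for (i in seq_len(nrow(grid))) {
        cand <- fit_at(ctr + c(grid$dr[i], grid$dc[i]))
        if (cand$rss < res$rss) res <- cand
      }
      ctr <- res$ctr
      span <- span / 2
    }
    res
  } else stop("center must be 'image-center', 'auto' or a (row, col) pair")

  structure(list(center = best$ctr, a = best$a, b = best$b,
                 p = exponent_p, r_max = best$r_max, rss = best$rss,
                 sigma = best$sigma, n = nrow(tab)),
            class = "radial_model")
}

#' @export
print.radial_model <- function(x, ...) {
  cat("radial_model: dRR ~", signif(x$a, 4), "+", signif(x$b, 4),
      "* (r/r_max)^", x$p, " [n =", x$n, "]\n")
  invisible(x)
}

# Model prediction at colony positions.
predict_radial <- function(model, row, col) {
  r <- sqrt((row - model$center[1])^2 + (col - model$center[2])^2)
  model$a + model$b * (r / model$r_max)^model$p
}

#' Correct colony responses for the radial spray gradient
#'
#' Multiplicative correction `dRR_corrected = dRR * d_hat(0) / d_hat(r)`:
#' the deposition field scales the response amplitude in the forward
#' model, so dividing by the fitted relative deposition inverts it.
#' Scores and ranks are recomputed on the corrected values; the original
#' columns are preserved with an `_uncorrected` suffix.
#'
#' @param table colony table with `row`, `col`, `R0`, `dRR`.
#' @param model a fitted `radial_model`.
#' @param eps minimum admissible predicted relative deposition; a
#'   prediction at or below `eps` signals extrapolation risk and errors.
#' @return the corrected colony table (ranked).
#' @export
correct_radial <- function(table, model, eps = 0.1) {
  dhat <- predict_radial(model, table$row, table$col)
  if (any(dhat <= eps * model$a))
    stop("radial model predicts near-zero deposition for some colonies; ",
         "refusing to extrapolate")
  tab <- table
  tab$dRR_uncorrected <- tab$dRR
  tab$dRR <- tab$dRR * model$a / dhat
  rank_colonies(tab, exclude_border = FALSE, exclude_artifact = FALSE)
}

#' Per-quantity plate variability summary
#'
#' @param table colony table.
#' @param quantities columns to summarize.
#' @return data.frame with `quantity`, `n`, `mean`, `sd`, `cv_pct`.
#' @export
qc_summary <- function(table,
                       quantities = c("R0", "dRR", "yfp_intensity")) {
  quantities <- intersect(quantities, names(table))
  do.call(rbind, lapply(quantities, function(q) {
    v <- table[[q]]
    v <- v[!is.na(v)]
    data.frame(quantity = q, n = length(v), mean = mean(v), sd = sd(v),
               cv_pct = if (length(v) >= 2 && mean(v) != 0)
                 compute_cv(v) else NA_real_)
  }))
}

#' Position-dependence bubble plot
#'
#' Each colony is drawn at its plate position with the marker area
#' proportional to the chosen quantity, exposing spatial bias at a
#' glance.
#'
#' @param table colony table.
#' @param quantity column name to visualize (e.g. `"dRR"`).
#' @return a ggplot object.
#' @export
plot_bubble <- function(table, quantity = "dRR") {
  if (!quantity %in% names(table)) stop("no column ", quantity)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$col, y = -.data$row,
                                      size = .data[[quantity]])) +
    ggplot2::geom_point(alpha = 0.5, color = "steelblue") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", size = quantity,
                  title = paste("Position dependence of", quantity)) +
    ggplot2::theme_minimal()
}

#' Compare plate measurements to a reference (in vitro) table
#'
#' Matches colonies by `colony_id`, reports Pearson correlations of `R0`
#' and `dRR` over the matched subset, and the top-k enrichment: how many
#' of the reference's top-m colonies (by screening score) appear in the
#' plate's top-k.
#'
#' @param table plate colony table (`colony_id`, `R0`, `dRR`).
#' @param reference reference table with the same columns.
#' @param top_k plate pick-list size (default 15).
#' @param top_m reference best-performer count (default 5).
#' @return list with `pearson_R0`, `pearson_dRR`, `enrichment`,
#'   `n_matched`.
#' @export
compare_to_reference <- function(table, reference, top_k = 15, top_m = 5) {
  m <- merge(table[, c("colony_id", "R0", "dRR")],
             reference[, c("colony_id", "R0", "dRR")],
             by = "colony_id", suffixes = c("_plate", "_ref"))
  if (nrow(m) < 3) stop("fewer than 3 matched colonies")
  if (sd(m$R0_plate) == 0 || sd(m$R0_ref) == 0 ||
      sd(m$dRR_plate) == 0 || sd(m$dRR_ref) == 0)
    stop("zero variance in a compared variable")
  sc_plate <- score_colony(m$R0_plate, m$dRR_plate)
  sc_ref <- score_colony(m$R0_ref, m$dRR_ref)
  top_plate <- m$colony_id[order(-sc_plate)][seq_len(min(top_k, nrow(m)))]
  top_ref <- m$colony_id[order(-sc_ref)][seq_len(min(top_m, nrow(m)))]
  list(pearson_R0 = cor(m$R0_plate, m$R0_ref),
       pearson_dRR = cor(m$dRR_plate, m$dRR_ref),
       enrichment = length(intersect(top_plate, top_ref)),
       n_matched = nrow(m))
}

#' Simulate a reference table correlated with a plate table
#'
#' Builds a synthetic in-vitro reference whose `R0` and `dRR` have a
#' planted Pearson correlation with the plate values:
#' `ref = mean + sd * (rho * z(x) + sqrt(1 - rho^2) * eps)` with `z(x)`
#' the standardized plate values. At `rho = 1` the reference reproduces
#' the plate values (and their ranking) exactly.
#'
#' @param table plate colony table.
#' @param rho_R0,rho_dRR planted correlations in \[0, 1\].
#' @param seed optional integer seed.
#' @return a reference table (`colony_id`, `R0`, `dRR`).
#' @export
simulate_reference <- function(table, rho_R0 = 0.6, rho_dRR = 0.3,
                               seed = NULL) {
  mix <- function(x, rho) {
    z <- (x - mean(x)) / sd(x)
    y <- rho * z + sqrt(1 - rho^2) * rnorm(length(x))
    mean(x) + sd(x) * y
  }
  with_seed_if(seed, data.frame(
    colony_id = table$colony_id,
    R0 = pmax(mix(table$R0, rho_R0), 0.05),
    dRR = pmax(mix(table$dRR, rho_dRR), -0.99)))
}

#' Planted-correlation enrichment study
#'
#' Monte-Carlo harness around [compare_to_reference()]: draws plate/
#' reference pairs at a planted correlation and reports the mean top-k
#' enrichment.
#'
#' @param rho planted correlation for both R0 and dRR.
#' @param n_pairs matched colonies per draw.
#' @param n_draws Monte-Carlo draws.
#' @param top_k,top_m enrichment rule.
#' @param sensor sensor-library distribution for the plate draws.
#' @param seed master seed.
#' @return mean enrichment over draws.
#' @export
enrichment_study <- function(rho, n_pairs = 180, n_draws = 200,
                             top_k = 15, top_m = 5,
                             sensor = sensor_params(), seed = NULL) {
  with_seed_if(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      plate <- sample_sensor_truths(n_pairs, sensor)
      tab <- data.frame(colony_id = plate$colony_id,
                        R0 = plate$R0_true, dRR = plate$dRR_max_true)
      ref <- simulate_reference(tab, rho, rho)
      compare_to_reference(tab, ref, top_k, top_m)$enrichment
    }, numeric(1)))
  })
}
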