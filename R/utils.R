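#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad sd rnorm rpois rlnorm runif coef lm cor
#'   complete.cases quantile
#' @importFrom utils write.csv read.csv head packageVersion
#' @importFrom grDevices png dev.off
NULL

# Canonical channel names, in fixed order: donor excitation / donor emission,
# donor excitation / acceptor emission (the FRET channel), acceptor
# excitation / acceptor emission (direct acceptor, FRET-independent).
CHANNELS <- c("donor_ex_donor_em", "donor_ex_acceptor_em",
              "acceptor_ex_acceptor_em")

#' Derive a per-stage sub-seed from a master seed
#'
#' One master seed drives a whole run; each stage (layout, sensors, spray,
#' noise, ...) gets its own deterministic sub-seed so that changing one
#' stage's parameters does not perturb the random draws of another.
#'
#' @param seed master seed (integer) or `NULL`.
#' @param stage stage name, one of the known pipeline stages.
#' @return an integer seed, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stages <- c(layout = 1, sensors = 2, spray = 3, noise = 4, mottle = 5,
              reference = 6, study = 7)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + stages[[stage]] * 104729) %% 2147483647)
}

# Run `expr` under `seed` if non-NULL (preserving the caller's RNG state),
# else run it as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}

# Squared-distance grids used by the simulator and the radial QC model.
# `center` is 0-based (row, col); returned matrix is nrow x ncol.
radial_distance <- function(nrow, ncol, center) {
  rr <- matrix(0:(nrow - 1), nrow, ncol)
  cc <- matrix(0:(ncol - 1), nrow, ncol, byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}
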