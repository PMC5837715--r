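#' Scan the smoothed ratio-estimate density across bandwidth multipliers
#'
#' Multimodality triage for the mode-based estimate: evaluates the weighted
#' empirical density of the per-variant ratio estimates on a shared grid for
#' each bandwidth multiplier `phi`. Sharpening the bandwidth (smaller `phi`)
#' can reveal secondary peaks -- clusters of invalid instruments sharing a
#' pleiotropic bias -- that the default bandwidth smooths over; examining
#' the curves guides the choice of `phi` for the final analysis.
#'
#' The grid is shared across all `phi` values (padding set by the widest
#' bandwidth) so the curves overlay directly.
#'
#' @param data an [mr_summary] dataset with at least 3 instruments.
#' @param phis positive bandwidth multipliers, e.g. `c(1, 0.5, 0.25)`.
#' @param weighting,nome weight options as in [standardized_weights()].
#' @param grid_points number of shared grid points.
#' @return list of class `mbe_density_scan`; one element per `phi`, each a
#'   `density_curve` list with `phi`, `x`, `f`, `mode_x` and a
#'   `local_maxima` data frame (grid points strictly exceeding both
#'   neighbours; plateaus report their leftmost point, sorted by x).
#' @examples
#' set.seed(2)
#' d <- mr_summary(beta_exposure = runif(20, 0.1, 0.3),
#'                 se_exposure   = rep(0.01, 20),
#'                 beta_outcome  = runif(20, 0.1, 0.3) * 0.2,
#'                 se_outcome    = rep(0.01, 20))
#' sc <- density_scan(d, phis = c(1, 0.5, 0.25))
#' sapply(sc, function(cu) nrow(cu$local_maxima))
#' @export
density_scan <- function(data, phis = c(1, 0.5, 0.25),
                         weighting = c("weighted", "simple"), nome = FALSE,
                         grid_points = 2048) {
  weighting <- match.arg(weighting)
  stopifnot(length(phis) >= 1L, all(phis > 0), grid_points >= 100)
  if (nrow(data) < 3L) stop("density scan requires at least 3 instruments")
  ratios <- compute_ratios(data)
  w <- standardized_weights(ratios, weighting, nome)
  s <- modified_silverman_bandwidth(ratios$ratio, phi = 1)
  h_max <- max(phis) * s
  grid <- seq(min(ratios$ratio) - 3 * h_max, max(ratios$ratio) + 3 * h_max,
              length.out = grid_points)
  curves <- lapply(phis, function(phi) {
    f <- ratio_density(grid, ratios$ratio, phi * s, w)
    lm_idx <- .local_maxima(f)
    structure(list(phi = phi, x = grid, f = f,
                   mode_x = grid[which.max(f)],
                   local_maxima = data.frame(x = grid[lm_idx],
                                             f = f[lm_idx])),
              class = "density_curve")
  })
  structure(curves, class = "mbe_density_scan",
            weighting = weighting, nome = nome,
            grid = c(min(grid), max(grid), grid_points))
}

# interior indices whose value strictly exceeds both neighbours;
# a flat plateau flanked by lower values reports its leftmost index
.local_maxima <- function(f) {
  n <- length(f)
  if (n < 3L) return(integer())
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (f[i] > f[i - 1L]) {
      j <- i
      while (j < n && f[j + 1L] == f[j]) j <- j + 1L
      if (j < n && f[j + 1L] < f[j]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

#' @export
as.data.frame.mbe_density_scan <- function(x, ...) {
  do.call(rbind, lapply(x, function(cu) {
    data.frame(phi = cu$phi, x = cu$x, f = cu$f)
  }))
}

#' Plot a density scan
#'
#' Overlays the density curves for all scanned bandwidth multipliers, with a
#' dashed reference line at zero causal effect.
#'
#' @param x an `mbe_density_scan`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mbe_density_scan <- function(x, ...) {
  fs <- sapply(x, `[[`, "f")
  graphics::matplot(x[[1]]$x, fs, type = "l", lty = 1,
                    col = seq_along(x),
                    xlab = "ratio estimate", ylab = "density", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topright", legend = paste0("phi = ",
                                               sapply(x, `[[`, "phi")),
                   col = seq_along(x), lty = 1, bty = "n")
  invisible(x)
}
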