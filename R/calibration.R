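# ---------------------------------------------------------------------------
# Posterior calibration: invert the fitted monotone device-bias spline,
# draw by draw, to map a noisy device reading (plus covariates) back to a
# posterior distribution over the latent truth.
# ---------------------------------------------------------------------------

#' Calibrate a device reading to the latent scale
#'
#' For every retained posterior draw r the covariate effect is removed,
#' \code{y* = y - gamma^(r)' z}, and the draw's monotone spline
#' \code{s^(r)} is inverted numerically by bounded scalar minimisation of
#' \code{|s^(r)(x) - y*|} over the draw's latent range padded by 10\%.
#' The collected minimisers form the calibration posterior. Readings whose
#' bias-corrected value lies beyond the spline's attainable range produce a
#' boundary minimiser and are flagged rather than dropped.
#'
#' @param y device reading, kcal/day (scalar).
#' @param z covariates: named vector or one-row data.frame with
#'   \code{gender}, \code{bmi}, \code{age}.
#' @param draws an \code{eb_draws} object from \code{\link{rjmcmc_fit}}.
#' @param attribute \code{"ee"} or \code{"es"}.
#' @param tol inversion tolerance, kcal.
#' @param max_draws cap on posterior draws inverted (evenly thinned);
#'   inversion cost is linear in the number of draws.
#' @return Object of class \code{eb_calibration}: \code{draws} (calibrated
#'   posterior draws), \code{estimate} (posterior median), \code{lower},
#'   \code{upper} (95\% credible interval), \code{boundary_frac} (share of
#'   draws hitting a search bound), and the inputs echoed.
#' @export
calibrate <- function(y, z, draws, attribute = c("ee", "es"), tol = 1e-6,
                      max_draws = 1000L) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(draws, "eb_draws"))
  if (!draws$kind %in% c("smemn", "smem"))
    stop("calibration requires a spline model fit (smemn or smem)",
         call. = FALSE)
  if (!is.finite(y)) stop("y must be finite", call. = FALSE)
  if (is.data.frame(z)) z <- unlist(z[1, ])
  zv <- as.numeric(z[c("gender", "bmi", "age")])
  if (any(is.na(zv)))
    stop("z must provide gender, bmi and age", call. = FALSE)

  boundary <- if (attribute == "ee") draws$boundary_ee else draws$boundary_es
  sdraws <- do.call(c, draws$spline)
  if (length(sdraws) > max_draws)
    sdraws <- sdraws[round(seq(1, length(sdraws), length.out = max_draws))]
  R <- length(sdraws)
  cal <- numeric(R); at_bound <- logical(R)
  kf <- paste0("knots_", attribute); bf <- paste0("beta_", attribute)
  gf <- paste0("gamma_", attribute); xf <- paste0("xr_", attribute)
  for (r in seq_len(R)) {
    d <- sdraws[[r]]
    ystar <- y - sum(d[[gf]] * zv)
    ks <- knot_set(d[[kf]], boundary)
    xr <- d[[xf]]
    pad <- 0.1 * diff(xr)
    lo <- max(xr[1] - pad, boundary[1]); hi <- min(xr[2] + pad, boundary[2])
    # bracket on the knot grid (one vectorised evaluation), then root-find
    # within the bracketing segment; monotonicity makes the root unique up
    # to flat regions
    grid <- c(lo, d[[kf]][d[[kf]] > lo & d[[kf]] < hi], hi)
    vals <- evaluate_spline(grid, ks, d[[bf]])
    if (ystar <= vals[1]) { cal[r] <- lo; at_bound[r] <- TRUE; next }
    if (ystar >= vals[length(vals)]) {
      cal[r] <- hi; at_bound[r] <- TRUE; next
    }
    seg <- findInterval(ystar, vals, rightmost.closed = TRUE)
    root <- uniroot(function(x) evaluate_spline(x, ks, d[[bf]]) - ystar,
                    lower = grid[seg], upper = grid[seg + 1],
                    f.lower = vals[seg] - ystar,
                    f.upper = vals[seg + 1] - ystar, tol = tol)
    cal[r] <- root$root
  }
  structure(list(draws = cal,
                 estimate = median(cal),
                 lower = unname(quantile(cal, 0.025)),
                 upper = unname(quantile(cal, 0.975)),
                 boundary_frac = mean(at_bound),
                 y = y, z = zv, attribute = attribute),
            class = "eb_calibration")
}

#' @export
print.eb_calibration <- function(x, ...) {
  cat(sprintf(
    "<eb_calibration> %s: y = %.2f -> %.2f [%.2f, %.2f] (%d draws%s)\n",
    x$attribute, x$y, x$estimate, x$lower, x$upper, length(x$draws),
    if (x$boundary_frac > 0)
      sprintf(", %.1f%% at search bound", 100 * x$boundary_frac) else ""))
  invisible(x)
}

#' Credible interval for a calibration result
#'
#' Empirical quantile interval of the calibrated draws, using the default
#' type-7 quantile rule.
#'
#' @param result an \code{eb_calibration}.
#' @param level interval mass (default 0.95).
#' @return \code{c(lower, upper)}.
#' @export
credible_interval <- function(result, level = 0.95) {
  stopifnot(inherits(result, "eb_calibration"), level > 0, level < 1)
  if (length(result$draws) < 100)
    stop("need at least 100 calibrated draws for a credible interval",
         call. = FALSE)
  a <- (1 - level) / 2
  unname(quantile(result$draws, c(a, 1 - a)))
}

#' Calibrate a table of device readings
#'
#' Applies \code{\link{calibrate}} to each row of a data.frame holding
#' device readings and covariates, for whichever of the \code{y_ee} /
#' \code{y_es} columns are present.
#'
#' @param newdata data.frame with \code{gender}, \code{bmi}, \code{age} and
#'   at least one of \code{y_ee}, \code{y_es}.
#' @param draws an \code{eb_draws} from a spline model fit.
#' @return Long-format data.frame: row, attribute, y, median, lower, upper,
#'   boundary_frac.
#' @export
calibrate_table <- function(newdata, draws) {
  attrs <- intersect(c("ee", "es"), sub("^y_", "",
                     intersect(c("y_ee", "y_es"), names(newdata))))
  if (!length(attrs))
    stop("newdata must contain a y_ee or y_es column", call. = FALSE)
  out <- list()
  for (a in attrs) {
    for (i in seq_len(nrow(newdata))) {
      r <- calibrate(newdata[[paste0("y_", a)]][i], newdata[i, ], draws, a)
      out[[length(out) + 1]] <- data.frame(
        row = i, attribute = a, y = r$y, median = r$estimate,
        lower = r$lower, upper = r$upper, boundary_frac = r$boundary_frac)
    }
  }
  do.call(rbind, out)
}
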