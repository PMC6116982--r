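#' Energy density constants for body-composition conversion
#'
#' Energy densities used to convert changes in fat mass and fat-free mass
#' into kilocalories. Defaults are the standard two-compartment values
#' (9500 kcal/kg fat mass, 1100 kcal/kg fat-free mass); they are injectable
#' because a single value cannot capture biological variation between
#' subjects.
#'
#' @param c_fm energy density of fat mass, kcal/kg.
#' @param c_ffm energy density of fat-free mass, kcal/kg.
#' @return An object of class \code{energy_constants}.
#' @export
energy_constants <- function(c_fm = 9500, c_ffm = 1100) {
  if (!is.numeric(c_fm) || !is.numeric(c_ffm) || c_fm <= 0 || c_ffm <= 0)
    stop("energy densities must be strictly positive numbers", call. = FALSE)
  if (c_fm <= c_ffm)
    stop("fat mass energy density must exceed fat-free mass energy density",
         call. = FALSE)
  structure(list(c_fm = c_fm, c_ffm = c_ffm), class = "energy_constants")
}

#' Convert DXA body-composition change to energy storage rate
#'
#' Converts a change in fat mass and fat-free mass over an elapsed period
#' into an average daily change in energy stores (dES, kcal/day):
#' \deqn{\Delta ES = C_{FM}\,\Delta FM/\Delta T + C_{FFM}\,\Delta FFM/\Delta T.}
#' Positive values indicate net energy storage.
#'
#' @param delta_fm change in fat mass, kg (vectorised).
#' @param delta_ffm change in fat-free mass, kg.
#' @param delta_t elapsed time, days; must be strictly positive.
#' @param constants an \code{\link{energy_constants}} object.
#' @return dES in kcal/day.
#' @examples
#' delta_es_from_dxa(1, 0, 14)       # 9500/14
#' delta_es_from_dxa(-0.5, 0.7, 14)  # net loss
#' @export
delta_es_from_dxa <- function(delta_fm, delta_ffm, delta_t,
                              constants = energy_constants()) {
  stopifnot(inherits(constants, "energy_constants"))
  if (any(!is.finite(delta_t)) || any(delta_t <= 0))
    stop("delta_t must be a strictly positive number of days", call. = FALSE)
  (constants$c_fm * delta_fm + constants$c_ffm * delta_ffm) / delta_t
}

#' Back-calculate energy intake from the energy balance identity
#'
#' The first-law identity dES = EI - EE rearranged as EI = EE + dES.
#'
#' @param ee energy expenditure, kcal/day.
#' @param delta_es change in energy stores, kcal/day.
#' @return Energy intake, kcal/day.
#' @export
energy_intake <- function(ee, delta_es) ee + delta_es
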