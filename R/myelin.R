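#' Myelin sheath thickness from the g-ratio
#'
#' The g-ratio is the inner axonal diameter over the outer fiber diameter,
#' g = r_ax / (r_ax + t_p + t_my), so the sheath thickness is
#' t_my = r_ax * (1/g - 1) - t_p.
#'
#' @param g g-ratio, strictly between 0 and 1
#' @param r_ax axon radius (um)
#' @param t_p periaxonal space thickness (um), default 0.0123 (12.3 nm)
#' @return sheath thickness t_my (um)
#' @export
myelin_thickness <- function(g, r_ax, t_p = 0.0123) {
  stopifnot(is.numeric(g), is.numeric(r_ax), is.numeric(t_p))
  if (any(g <= 0) || any(g >= 1)) {
    stop("g-ratio must lie strictly between 0 and 1")
  }
  if (any(r_ax <= 0) || any(t_p < 0)) stop("r_ax must be > 0 and t_p >= 0")
  t_my <- r_ax * (1 / g - 1) - t_p
  if (any(t_my < 0)) {
    stop("negative sheath thickness: geometry impossible for these g, r_ax, t_p")
  }
  t_my
}

#' Number of myelin wraps in a sheath
#'
#' One wrap is two glial plasma membranes, so a sheath of thickness
#' \code{t_my} holds t_my / (2 * t_mem) wraps.
#'
#' @param t_my sheath thickness (um), >= 0
#' @param t_mem single plasma-membrane thickness (um), default 0.0075 (7.5 nm)
#' @return wrap count (possibly fractional)
#' @export
wraps_from_thickness <- function(t_my, t_mem = 0.0075) {
  if (any(t_my < 0)) stop("t_my must be >= 0")
  if (any(t_mem <= 0)) stop("t_mem must be > 0")
  t_my / (2 * t_mem)
}

#' Sheath conductance and capacitance from the wrap count
#'
#' n wraps = 2n membranes in series, each with the axolemma's specific leak
#' conductance G_ax and capacitance C_ax, so G_my = G_ax / (2n) and
#' C_my = C_ax / (2n). With n = 0 there is no sheath and the internode is
#' bare membrane.
#'
#' @param n integer wrap count, >= 0
#' @param G_ax axolemma leak conductance density (pS/um^2), default 0.333
#' @param C_ax axolemma specific capacitance (uF/cm^2), default 1
#' @return list with \code{G_my}, \code{C_my} (same units as inputs) and
#'   \code{has_sheath}; for n = 0 the conductances are NA and
#'   \code{has_sheath} is FALSE
#' @export
sheath_rc <- function(n, G_ax = 0.333, C_ax = 1) {
  if (length(n) != 1 || n < 0 || n != round(n)) {
    stop("wrap count n must be a single non-negative integer")
  }
  if (n == 0) {
    return(list(G_my = NA_real_, C_my = NA_real_, has_sheath = FALSE, n = 0L))
  }
  list(G_my = G_ax / (2 * n), C_my = C_ax / (2 * n), has_sheath = TRUE, n = as.integer(n))
}

#' Full myelin sheath description for the default fiber
#'
#' Convenience constructor tying together the geometric chain
#' g-ratio -> sheath thickness -> wrap count -> sheath RC, with the default
#' periaxonal space parameters.
#'
#' @param n integer wrap count actually applied (the geometric estimate from
#'   the default fiber is 15.6; the main model rounds to 15)
#' @param g g-ratio used for the geometric estimate
#' @param r_ax axon radius (um)
#' @param t_p periaxonal thickness (um)
#' @param t_mem membrane thickness (um)
#' @param rho_peri periaxonal resistivity (Ohm cm)
#' @param G_ax,C_ax axolemma leak density (pS/um^2) and capacitance (uF/cm^2)
#' @return object of class \code{myelin_sheath}
#' @export
myelin_sheath <- function(n = 15, g = 0.698, r_ax = 0.57, t_p = 0.0123,
                          t_mem = 0.0075, rho_peri = 53.7,
                          G_ax = 0.333, C_ax = 1) {
  rc <- sheath_rc(n, G_ax, C_ax)
  t_my <- myelin_thickness(g, r_ax, t_p)
  structure(
    list(
      n = rc$n, G_my = rc$G_my, C_my = rc$C_my, has_sheath = rc$has_sheath,
      g = g, r_ax = r_ax, t_p = t_p, t_mem = t_mem, t_my = t_my,
      wraps_geometric = wraps_from_thickness(t_my, t_mem),
      rho_peri = rho_peri, G_ax = G_ax, C_ax = C_ax
    ),
    class = "myelin_sheath"
  )
}
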