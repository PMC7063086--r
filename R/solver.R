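#' Advance the model state by time stepping
#'
#' Runs the compiled implicit (backward-Euler) stepper for \code{t_ms}
#' milliseconds at step \code{dt}. The scheme solves the branched voltage
#' system exactly each step (Hines elimination, with the myelin double-cable
#' layer eliminated locally) and advances gating variables by exact
#' exponential relaxation; it is unconditionally stable, so the subthreshold
#' conditioning phases can run at a coarser step than the spike windows.
#'
#' @param model \code{cable_model}
#' @param state state list as returned by \code{\link{rest_state}} or a
#'   previous \code{run_sim} call
#' @param dt time step (ms); the spike-window default is 6.25e-3 (6.25 us)
#' @param t_ms duration (ms)
#' @param inj data frame of constant injections over this call: columns
#'   \code{comp} (1-based compartment index) and \code{amp} (nA)
#' @param record 1-based compartment indices whose V(t) to record
#' @param record_ca 1-based compartment indices whose Ca current to record
#'   (nA, inward negative)
#' @param rec_stride record every \code{rec_stride}-th step
#' @return list with the final \code{state}, and \code{t} (ms), \code{V}
#'   (matrix, rows = recorded compartments), \code{ICa}
#' @export
run_sim <- function(model, state, dt, t_ms,
                    inj = NULL, record = integer(0),
                    record_ca = integer(0), rec_stride = 1L) {
  nsteps <- max(1L, round(t_ms / dt))
  if (abs(nsteps * dt - t_ms) > 1e-6 * max(1, t_ms)) {
    warning("t_ms is not a multiple of dt; running ", nsteps, " steps")
  }
  # the periaxonal axial current is advanced explicitly; its relaxation time
  # bounds the usable step for sheathed models
  sh <- model$is_sheath == 1L
  if (any(sh)) {
    gp <- model$g_peri_prev + c(model$g_peri_prev[-1], 0) + model$g_peri_ground
    tau <- (model$cm[sh] + model$cm_sheath[sh]) / pmax(gp[sh], 1e-300)
    dt_max <- 0.8 * min(tau)
    if (dt > dt_max) {
      stop(sprintf(
        "dt = %g ms exceeds the periaxonal stability bound (%.3g ms) for this mesh; reduce dt or coarsen the internode segmentation",
        dt, dt_max
      ))
    }
  }
  if (is.null(inj)) inj <- data.frame(comp = integer(0), amp = numeric(0))
  out <- .cable_step_run(
    model, state, dt, as.integer(nsteps),
    as.integer(inj$comp - 1L), as.numeric(inj$amp),
    as.integer(record - 1L), as.integer(rec_stride),
    as.integer(record_ca - 1L)
  )
  state <- out[c(
    "V", "W", "m12", "h12", "m16", "h16", "n_kdr", "m_kv1", "h_kv1", "m_ca"
  )]
  list(
    state = state,
    t = out$rec_t + if (!is.null(attr(state, "t0"))) attr(state, "t0") else 0,
    V = out$rec_V, ICa = out$rec_ICa
  )
}

## constant sparse part of the system: axial couplings + sheath couplings
.steady_matrix_parts <- function(model) {
  n <- model$n
  par <- model$parent + 1L # 1-based, root 0
  has_p <- par > 0
  i_ax <- which(has_p)
  # W unknowns appended after the n voltages
  wi <- which(model$is_sheath == 1L)
  nw <- length(wi)
  w_of <- integer(n)
  w_of[wi] <- n + seq_len(nw)
  gl <- model$G[, "leak"]

  ii <- c(i_ax, par[i_ax], i_ax, par[i_ax])
  jj <- c(par[i_ax], i_ax, i_ax, par[i_ax])
  xx <- c(-model$g_ax[i_ax], -model$g_ax[i_ax], model$g_ax[i_ax], model$g_ax[i_ax])

  if (nw) {
    # V row: +gl on diag (V), -gl to W ; W row: -gl to V, +gl+Gm+ground on diag
    ii <- c(ii, wi, wi, w_of[wi], w_of[wi])
    jj <- c(jj, wi, w_of[wi], wi, w_of[wi])
    xx <- c(
      xx, gl[wi], -gl[wi], -gl[wi],
      gl[wi] + model$gm_sheath[wi] + model$g_peri_ground[wi]
    )
    # periaxonal axial links
    pp <- which(model$g_peri_prev > 0)
    if (length(pp)) {
      a <- w_of[pp]
      b <- w_of[pp - 1L]
      g <- model$g_peri_prev[pp]
      ii <- c(ii, a, b, a, b)
      jj <- c(jj, b, a, a, b)
      xx <- c(xx, -g, -g, g, g)
    }
  }
  A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + nw, n + nw))
  list(A0 = A0, wi = wi, nw = nw, w_of = w_of)
}

## steady-state channel conductance and driving term at voltage v
.steady_channel_terms <- function(model, v) {
  kin <- model$kinetics
  G <- model$G
  n <- model$n
  gtot <- numeric(n)
  ge <- numeric(n)
  sheath <- model$is_sheath == 1L
  add <- function(col, kinent, gtot, ge) {
    sel <- which(G[, col] > 0 & !sheath)
    if (length(sel)) {
      go <- G[sel, col] * open_fraction_steady(kinent, v[sel])
      gtot[sel] <- gtot[sel] + go
      ge[sel] <- ge[sel] + go * kinent$erev
    }
    list(gtot, ge)
  }
  r <- add("na12", kin$nav12, gtot, ge)
  r <- add("na16", kin$nav16, r[[1]], r[[2]])
  r <- add("kdr", kin$kdr, r[[1]], r[[2]])
  r <- add("kv1", kin$kv1, r[[1]], r[[2]])
  r <- add("ca", kin$capq, r[[1]], r[[2]])
  gtot <- r[[1]]
  ge <- r[[2]]
  # leak of unsheathed compartments (sheathed leak lives in the A0 couplings)
  gl <- model$G[, "leak"]
  gtot[!sheath] <- gtot[!sheath] + gl[!sheath]
  ge[!sheath] <- ge[!sheath] + gl[!sheath] * model$eleak[!sheath]
  list(gtot = gtot, ge = ge)
}

#' Self-consistent steady-state voltage profile
#'
#' Fast path for long subthreshold protocols: gating variables are held at
#' their steady state for the local voltage and the resulting nonlinear DC
#' system is solved by damped Newton iteration (sparse direct solve per
#' step, numerical channel-slope Jacobian, residual backtracking). The
#' persistent-Na region makes plain fixed-point iteration diverge even where
#' a stable subthreshold solution exists; Newton handles it. Fails with an
#' explicit error advising the time-domain path when no nearby solution is
#' found (e.g. the injection initiates spiking).
#'
#' @param model \code{cable_model}
#' @param inj data frame with \code{comp}, \code{amp} (nA)
#' @param v0 initial voltage guess (scalar or per-compartment)
#' @param tol convergence tolerance on the membrane-current residual (nA)
#' @param max_iter Newton iteration cap
#' @return state list (as \code{\link{rest_state}}) with converged V and W
#' @export
steady_state <- function(model, inj = NULL, v0 = -70, tol = 1e-7,
                         max_iter = 200) {
  n <- model$n
  parts <- .steady_matrix_parts(model)
  nw <- parts$nw
  wi <- parts$wi
  rhs <- numeric(n + nw)
  if (!is.null(inj) && nrow(inj)) {
    rhs[inj$comp] <- rhs[inj$comp] + inj$amp
  }
  # sheathed internode leak needs its E_leak driving split across V and W rows
  gl <- model$G[, "leak"]
  if (nw) {
    rhs[wi] <- rhs[wi] + gl[wi] * model$eleak[wi]
    rhs[parts$w_of[wi]] <- rhs[parts$w_of[wi]] - gl[wi] * model$eleak[wi]
  }
  ich <- function(v) {
    ch <- .steady_channel_terms(model, v)
    ch$gtot * v - ch$ge
  }
  resid <- function(x) {
    as.numeric(parts$A0 %*% x) + c(ich(x[seq_len(n)]), numeric(nw)) - rhs
  }
  x <- c(rep_len(v0, n), if (nw) rep(-20, nw) else numeric(0))
  f <- resid(x)
  h <- 0.05
  # pseudo-transient continuation: Newton damped by a capacitance-scaled
  # diagonal M/dtp (equivalent to implicit-Euler pseudo-time steps); dtp
  # grows as the residual falls, recovering full Newton near the solution
  mcap <- c(model$cm, model$cm_sheath[wi] + model$cm[wi])
  dtp <- 1e5 # start at (essentially) full Newton; damp only on divergence
  nrm <- function(g) sqrt(sum(g^2))
  for (iter in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    v <- x[seq_len(n)]
    didv <- (ich(v + h) - ich(v - h)) / (2 * h)
    J <- parts$A0 + Matrix::Diagonal(n + nw, c(didv, numeric(nw)) + mcap / dtp)
    xn <- x + as.numeric(Matrix::solve(J, -f))
    fn <- resid(xn)
    if (nrm(fn) <= nrm(f) * (1 + 1e-3)) {
      dtp <- min(dtp * min(10, max(1.05, nrm(f) / max(nrm(fn), 1e-300))), 1e7)
      x <- xn
      f <- fn
    } else {
      dtp <- dtp / 10
      if (dtp < 1e-4) {
        stop(
          "steady-state continuation stalled (residual ",
          signif(max(abs(f)), 3),
          " nA); the injection may initiate spiking - use run_sim"
        )
      }
    }
  }
  if (max(abs(f)) >= tol) {
    stop(
      "steady-state continuation did not converge (residual ",
      signif(max(abs(f)), 3),
      " nA); the injection may initiate spiking - use run_sim"
    )
  }
  v <- x[seq_len(n)]
  wfull <- numeric(n)
  if (nw) wfull[wi] <- x[n + seq_len(nw)]
  g <- init_steady_state(v, model$kinetics)
  list(
    V = v, W = wfull,
    m12 = g$m12, h12 = g$h12, m16 = g$m16, h16 = g$h16,
    n_kdr = g$n_kdr, m_kv1 = g$m_kv1, h_kv1 = g$h_kv1, m_ca = g$m_ca
  )
}

#' Resting state of a model
#'
#' Zero-current steady state (gates at steady state, periaxonal potentials
#' self-consistent). With the calibrated leak reversals this sits at
#' -70 mV throughout.
#'
#' @param model \code{cable_model}
#' @return state list
#' @export
rest_state <- function(model) steady_state(model, inj = NULL, v0 = -70)

#' Conduction velocity between two recorded locations
#'
#' Distance over spike-peak time difference. Both traces must contain a
#' propagated spike (upward crossing of 0 mV); identical peak times are an
#' error rather than an infinite velocity.
#'
#' @param t time base (ms)
#' @param v1,v2 voltage traces (mV) at the two locations
#' @param dist_um path distance between the locations (um)
#' @return velocity (m/s)
#' @export
conduction_velocity <- function(t, v1, v2, dist_um) {
  pk <- function(v) {
    if (max(v) < 0) stop("no spike (no 0 mV crossing) in trace")
    t[which.max(v)]
  }
  t1 <- pk(v1)
  t2 <- pk(v2)
  if (t1 == t2) stop("identical spike peak times; velocity undefined")
  abs(dist_um / (t2 - t1)) * 1e-3 # um/ms -> m/s
}
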