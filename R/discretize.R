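#' Discretize a morphology into a compartmental cable model
#'
#' Splits every section into compartments no longer than the per-role maximum
#' segment length, assigns membrane capacitance, channel conductances (with
#' the AIS Nav gradients as linear ramps) and axial conductances, and equips
#' sheathed internodes with the double-cable layer: axolemma RC in series
#' with a periaxonal space (12.3 nm annulus of 53.7 Ohm cm fluid, axially
#' resistive) under the myelin RC to ground. Periaxonal ends are sealed by
#' default (escape only through the sheath; see the methods vignette), or can
#' be grounded at the flanking nodes with \code{periaxonal_ends = "grounded"}.
#'
#' Collaterals are cut into one compartment per presynaptic-site spacing so
#' every site sits exactly at a compartment center; nodal compartments carry
#' the preset's nodal densities plus 1 pS/um^2 of P/Q Ca, presynaptic-site
#' compartments add the same weak P/Q density.
#'
#' @param morph \code{morphology}
#' @param preset \code{membrane_preset}
#' @param max_seg named list of per-role maximum compartment lengths (um);
#'   entries: soma, dendrite, hillock, ais, internode, node, collateral
#' @param kinetics kinetics set
#' @param periaxonal_ends "sealed" or "grounded"
#' @param eleaks optionally precomputed region E_leak list (from
#'   \code{\link{calibrate_preset_eleaks}}); computed when NULL
#' @return object of class \code{cable_model}
#' @export
discretize <- function(morph, preset,
                       max_seg = list(
                         soma = 35, dendrite = 100, hillock = 5, ais = 5,
                         internode = 25, node = 1.5, collateral = NA
                       ),
                       kinetics = default_kinetics(),
                       periaxonal_ends = c("sealed", "grounded"),
                       eleaks = NULL) {
  periaxonal_ends <- match.arg(periaxonal_ends)
  s <- morph$sections
  if (any(s$length <= 0)) stop("zero- or negative-length section in morphology")
  cfg <- morph$config
  if (is.null(eleaks)) {
    node_frac <- {
      nl <- sum(s$length[s$role == "main_axon_node"])
      il <- sum(s$length[s$role == "main_axon_internode"])
      if (nl + il > 0) nl / (nl + il) else 1.5 / 101.1
    }
    eleaks <- calibrate_preset_eleaks(preset, -70, node_frac, kinetics)
  }
  sheath <- preset$sheath
  has_sheath <- !is.null(sheath) && sheath$has_sheath

  seg_len_for <- function(role, length) {
    key <- switch(role,
      main_axon_node = "node", main_axon_internode = "internode", role
    )
    m <- max_seg[[key]]
    if (key == "collateral" && (is.null(m) || is.na(m))) m <- cfg$site_spacing
    max(1L, ceiling(length / m))
  }

  ns <- nrow(s)
  sec_first <- integer(ns) # first comp index (1-based) per section
  sec_n <- integer(ns)
  # accumulators
  acc <- list()
  n_total <- 0L
  for (i in seq_len(ns)) {
    role <- s$role[i]
    if (role == "collateral") {
      # one comp per site spacing + distal remainder
      nfull <- floor(s$length[i] / cfg$site_spacing)
      rem <- s$length[i] - nfull * cfg$site_spacing
      lens <- c(rep(cfg$site_spacing, nfull), if (rem > 1e-9) rem)
      if (!length(lens)) lens <- s$length[i]
    } else {
      k <- seg_len_for(role, s$length[i])
      lens <- rep(s$length[i] / k, k)
    }
    sec_first[i] <- n_total + 1L
    sec_n[i] <- length(lens)
    acc[[i]] <- lens
    n_total <- n_total + length(lens)
  }

  n <- n_total
  parent <- integer(n)
  comp_sec <- integer(n)
  comp_len <- numeric(n)
  comp_diam <- numeric(n)
  comp_pos <- numeric(n) # center position within section (um)
  for (i in seq_len(ns)) {
    idx <- sec_first[i] + seq_len(sec_n[i]) - 1L
    lens <- acc[[i]]
    comp_sec[idx] <- i
    comp_len[idx] <- lens
    comp_diam[idx] <- s$diam[i]
    comp_pos[idx] <- cumsum(lens) - lens / 2
    parent[idx] <- c(0L, idx[-length(idx)])
    # first comp's parent: comp of the parent section at parent_pos
    if (is.na(s$parent[i])) {
      parent[idx[1]] <- 0L # root (becomes -1 in the 0-based export)
    } else {
      p <- match(s$parent[i], s$id)
      pp <- s$parent_pos[i]
      off <- pmin(sec_n[p], pmax(1L, ceiling(pp * sec_n[p])))
      parent[idx[1]] <- sec_first[p] + off - 1L
    }
  }

  area <- pi * comp_diam * comp_len # um^2
  cm <- area * 1e-5 * cfg$c_m # nF

  # axial conductance to parent (uS): series of the two half-cylinders
  half_res <- function(idx) {
    # Ohm: R_i [Ohm cm -> Ohm um] * (L/2) / (pi r^2)
    (cfg$r_i * 1e4) * (comp_len[idx] / 2) / (pi * (comp_diam[idx] / 2)^2)
  }
  g_ax <- numeric(n)
  has_parent <- parent > 0
  g_ax[has_parent] <- 1e6 / (half_res(which(has_parent)) + half_res(parent[has_parent]))

  # channel densities (pS/um^2) per compartment
  dens <- matrix(0, n, 6, dimnames = list(NULL, c("na12", "na16", "kdr", "kv1", "ca", "leak")))
  eleak <- numeric(n)
  sd <- preset$somatodendritic
  ax <- preset$axon
  is_sheath_comp <- logical(n)
  role_of <- s$role[comp_sec]
  for (i in seq_len(ns)) {
    idx <- sec_first[i] + seq_len(sec_n[i]) - 1L
    role <- s$role[i]
    if (role %in% c("soma", "dendrite", "hillock")) {
      d <- sd[[if (role == "hillock") "hillock" else role]]
      dens[idx, "na12"] <- d$nav12
      dens[idx, "kdr"] <- d$kdr
      dens[idx, "leak"] <- d$leak
      eleak[idx] <- eleaks$somatodendritic
    } else if (role == "ais") {
      d <- sd$ais
      f <- comp_pos[idx] / s$length[i]
      dens[idx, "na12"] <- d$nav12_from + f * (d$nav12_to - d$nav12_from)
      dens[idx, "na16"] <- d$nav16_from + f * (d$nav16_to - d$nav16_from)
      dens[idx, "kdr"] <- d$kdr
      dens[idx, "leak"] <- d$leak
      eleak[idx] <- eleaks$somatodendritic
    } else if (role == "main_axon_node") {
      dens[idx, "na16"] <- ax$node$nav16
      dens[idx, "kv1"] <- ax$node$kv1
      dens[idx, "ca"] <- ax$node$capq
      dens[idx, "leak"] <- ax$leak
      eleak[idx] <- eleaks$axon
    } else if (role == "main_axon_internode") {
      dens[idx, "na16"] <- ax$internode$nav16
      dens[idx, "kv1"] <- ax$internode$kv1
      dens[idx, "leak"] <- ax$leak
      eleak[idx] <- eleaks$axon
      if (has_sheath) is_sheath_comp[idx] <- TRUE
    } else if (role == "collateral") {
      dens[idx, "na16"] <- ax$collateral$nav16
      dens[idx, "kv1"] <- ax$collateral$kv1
      dens[idx, "leak"] <- ax$leak
      eleak[idx] <- eleaks$collateral
    }
  }
  if (has_sheath && any(is_sheath_comp) &&
    any(dens[is_sheath_comp, c("na12", "na16", "kdr", "kv1", "ca")] != 0)) {
    stop("sheathed internodes must carry no voltage-gated conductance")
  }

  # presynaptic sites: weak P/Q density at the site compartments
  site_comp <- integer(0)
  if (!is.null(morph$sites) && nrow(morph$sites)) {
    site_comp <- integer(nrow(morph$sites))
    for (k in seq_len(nrow(morph$sites))) {
      ci <- match(morph$sites$collateral_id[k], s$id)
      j <- which.min(abs(comp_pos[sec_first[ci] + seq_len(sec_n[ci]) - 1L] -
        morph$sites$pos_on_collateral[k]))
      site_comp[k] <- sec_first[ci] + j - 1L
    }
    dens[site_comp, "ca"] <- dens[site_comp, "ca"] + ax$site_capq
  }

  G <- dens * area * 1e-6 # uS

  # double-cable layer for sheathed internode compartments
  gm_sheath <- numeric(n)
  cm_sheath <- numeric(n)
  g_peri_prev <- numeric(n)
  g_peri_ground <- numeric(n)
  if (has_sheath) {
    gm_sheath[is_sheath_comp] <- sheath$G_my * area[is_sheath_comp] * 1e-6 # uS
    cm_sheath[is_sheath_comp] <- sheath$C_my * area[is_sheath_comp] * 1e-5 # nF
    ann <- 2 * pi * (comp_diam / 2) * sheath$t_p # periaxonal annulus, um^2
    r_per_um <- (sheath$rho_peri * 1e4) / ann # Ohm/um
    for (i in which(s$role == "main_axon_internode")) {
      idx <- sec_first[i] + seq_len(sec_n[i]) - 1L
      if (length(idx) > 1) {
        pr <- (r_per_um[idx[-length(idx)]] * comp_len[idx[-length(idx)]] / 2 +
          r_per_um[idx[-1]] * comp_len[idx[-1]] / 2)
        g_peri_prev[idx[-1]] <- 1e6 / pr # uS
      }
      if (periaxonal_ends == "grounded") {
        g_peri_ground[idx[1]] <- g_peri_ground[idx[1]] +
          1e6 / (r_per_um[idx[1]] * comp_len[idx[1]] / 2)
        last <- idx[length(idx)]
        g_peri_ground[last] <- g_peri_ground[last] +
          1e6 / (r_per_um[last] * comp_len[last] / 2)
      }
    }
  }

  # bookkeeping for measurements
  soma_comp <- sec_first[which(s$role == "soma")]
  axon_start_comp <- {
    ai <- which(s$role %in% c("main_axon_internode", "main_axon_node"))
    if (length(ai)) sec_first[min(ai)] else NA_integer_
  }
  node_comp <- integer(0)
  node_dist <- numeric(0)
  for (i in which(s$role == "main_axon_node")) {
    idx <- sec_first[i] + seq_len(sec_n[i]) - 1L
    mid <- idx[ceiling(length(idx) / 2)]
    node_comp <- c(node_comp, mid)
    node_dist <- c(node_dist, s$path_start[i] + comp_pos[mid])
  }
  comp_path <- rep(NA_real_, n)
  on_path <- !is.na(s$path_start[comp_sec])
  comp_path[on_path] <- s$path_start[comp_sec][on_path] + comp_pos[on_path]

  structure(
    list(
      n = n, parent = parent - 1L, # 0-based; root is -1
      g_ax = g_ax, cm = cm, area = area,
      G = G, eleak = eleak,
      is_sheath = as.integer(is_sheath_comp),
      gm_sheath = gm_sheath, cm_sheath = cm_sheath,
      g_peri_prev = g_peri_prev, g_peri_ground = g_peri_ground,
      soma_comp = soma_comp, axon_start_comp = axon_start_comp,
      node_comp = node_comp, node_dist = node_dist,
      site_comp = site_comp,
      comp_path = comp_path, comp_len = comp_len, comp_diam = comp_diam,
      comp_role = role_of, comp_sec = comp_sec,
      kinetics = kinetics, kin_packed = kinetics_pack(kinetics),
      preset = preset$name, eleaks = eleaks,
      periaxonal_ends = periaxonal_ends,
      morph = morph
    ),
    class = "cable_model"
  )
}

#' @export
print.cable_model <- function(x, ...) {
  cat(
    "<cable_model>", x$n, "compartments; preset", x$preset, ";",
    sum(x$is_sheath), "sheathed internode compartments;",
    length(x$site_comp), "presynaptic sites\n"
  )
  invisible(x)
}
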