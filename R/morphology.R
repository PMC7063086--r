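#' Default morphology configuration
#'
#' Geometry of the synthetic L5 pyramidal cell: a soma, an equivalent-cylinder
#' dendritic load (its diameter is set by \code{\link{calibrate_dendritic_load}}
#' so that 322 pA depolarizes the soma by 15 mV), an axon hillock, an AIS, a
#' 20 mm main axon of 1.14 um diameter and ten 0.23 um collaterals at the
#' reference branch distances. Axonal path distances are measured in um from
#' the soma exit (soma-hillock junction). The six proximal collaterals default
#' to 1,980 um and the four distal ones to 1,000 um, which yields the
#' reference total of 1,982 presynaptic sites at 8 um spacing.
#'
#' @param axon_length total main-axon length incl. hillock+AIS span (um)
#' @param collateral_distances branch distances from the soma (um)
#' @param collateral_lengths per-collateral lengths (um), recycled
#' @param site_spacing presynaptic site spacing on collaterals (um)
#' @param expected_sites if non-NULL, \code{\link{build_default_morphology}}
#'   asserts the realized site total equals this (config assertion, not
#'   silent trimming)
#' @param dend_length,dend_diam dendritic equivalent cylinder (um)
#' @param soma_length,soma_diam soma cylinder (um)
#' @param hillock_length,hillock_diam,ais_length,ais_diam initial segment
#'   geometry (um); unprinted in the source description, config defaults
#' @param node_length node of Ranvier length (um)
#' @param r_i axial resistivity (Ohm cm)
#' @param c_m specific capacitance (uF/cm^2)
#' @return list of class \code{morph_config}
#' @export
morph_config <- function(axon_length = 20000,
                         collateral_distances = c(
                           128.5, 129.6, 300.9, 301.5, 810.1, 993.9,
                           1907.4, 2922.4, 3937.4, 4952.4
                         ),
                         collateral_lengths = c(rep(1980, 6), rep(1000, 4)),
                         site_spacing = 8,
                         expected_sites = NULL,
                         dend_length = 3000, dend_diam = 8.8,
                         soma_length = 35, soma_diam = 23,
                         hillock_length = 10, hillock_diam = 2,
                         ais_length = 50, ais_diam = 1.2,
                         node_length = 1.5,
                         r_i = 150, c_m = 1) {
  nc <- length(collateral_distances)
  cl <- rep_len(collateral_lengths, max(nc, 1L))
  structure(
    list(
      axon_length = axon_length,
      collateral_distances = collateral_distances,
      collateral_lengths = if (nc) cl else numeric(0),
      site_spacing = site_spacing,
      expected_sites = expected_sites,
      dend_length = dend_length, dend_diam = dend_diam,
      soma_length = soma_length, soma_diam = soma_diam,
      hillock_length = hillock_length, hillock_diam = hillock_diam,
      ais_length = ais_length, ais_diam = ais_diam,
      node_length = node_length,
      main_axon_diam = 1.14, collateral_diam = 0.23,
      r_i = r_i, c_m = c_m
    ),
    class = "morph_config"
  )
}

#' Configuration matching the reference model
#' @rdname morph_config
#' @export
default_morph_config <- function() morph_config(expected_sites = 1982L)

.new_section <- function(id, role, length, diam, parent, parent_pos, path_start) {
  data.frame(
    id = id, role = role, length = length, diam = diam,
    parent = parent, parent_pos = parent_pos, path_start = path_start,
    stringsAsFactors = FALSE
  )
}

#' Build the synthetic morphology
#'
#' Assembles the section tree (soma, dendritic cylinder, hillock, AIS, main
#' axon, collaterals), lays out nodes of Ranvier and internodes on the main
#' axon via \code{\link{layout_internodes}}, and places presynaptic sites via
#' \code{\link{place_presynaptic_sites}}.
#'
#' @param config a \code{\link{morph_config}}
#' @param internode_target mean internode length target (um)
#' @return object of class \code{morphology}: \code{$sections} (data frame),
#'   \code{$sites}, \code{$nodes} (measurement node center distances),
#'   \code{$config}
#' @export
build_default_morphology <- function(config = default_morph_config(),
                                     internode_target = 100) {
  cfg <- config
  if (any(cfg$collateral_distances >= cfg$axon_length)) {
    stop(
      "collateral branch distance (",
      max(cfg$collateral_distances), " um) exceeds the main axon length (",
      cfg$axon_length, " um)"
    )
  }
  if (length(cfg$collateral_distances) &&
    any(cfg$collateral_distances <= cfg$hillock_length + cfg$ais_length)) {
    stop("collateral branch distances must lie beyond the AIS")
  }
  sec <- rbind(
    .new_section(1L, "soma", cfg$soma_length, cfg$soma_diam, NA_integer_, NA_real_, NA_real_),
    .new_section(2L, "dendrite", cfg$dend_length, cfg$dend_diam, 1L, 0, NA_real_),
    .new_section(3L, "hillock", cfg$hillock_length, cfg$hillock_diam, 1L, 1, 0),
    .new_section(4L, "ais", cfg$ais_length, cfg$ais_diam, 3L, 1, cfg$hillock_length)
  )
  morph <- structure(
    list(sections = sec, sites = NULL, nodes = numeric(0), config = cfg,
         internode_target = internode_target),
    class = "morphology"
  )
  morph <- layout_internodes(morph, internode_target)
  morph <- place_presynaptic_sites(morph, cfg$site_spacing)
  if (!is.null(cfg$expected_sites) && nrow(morph$sites) != cfg$expected_sites) {
    stop(
      "morphology realizes ", nrow(morph$sites),
      " presynaptic sites but the configuration asserts ", cfg$expected_sites
    )
  }
  morph
}

## node intervals around branch distances, merged when closer than node_length
.node_intervals <- function(branches, node_len) {
  if (!length(branches)) {
    return(matrix(numeric(0), ncol = 2))
  }
  b <- sort(branches)
  lo <- b - node_len / 2
  hi <- b + node_len / 2
  out <- list()
  cur <- c(lo[1], hi[1])
  for (i in seq_along(b)[-1]) {
    if (lo[i] <= cur[2]) {
      cur[2] <- hi[i]
    } else {
      out[[length(out) + 1]] <- cur
      cur <- c(lo[i], hi[i])
    }
  }
  out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

#' Lay out nodes of Ranvier and internodes on the main axon
#'
#' Places a 1.5 um node of Ranvier at every collateral branch point (nodes of
#' branch points closer than one node length merge), then cuts each stretch
#' between nodes into internodes: stretches longer than twice the target are
#' subdivided with interior nodes so internode lengths land near the target
#' (the default 100 um target reproduces the reference 99-180 um internodes,
#' mean about 101 um). Branch-point distances are never moved, so scaled
#' layouts (half/quarter target) keep collateral positions fixed.
#'
#' @param morph \code{morphology} whose main axon has not yet been segmented
#'   (or whose segmentation is to be replaced)
#' @param mean_target internode length target (um)
#' @return \code{morphology} with main-axon node/internode sections appended
#' @export
layout_internodes <- function(morph, mean_target = 100) {
  cfg <- morph$config
  node_len <- cfg$node_length
  if (mean_target <= node_len) {
    stop("mean_target (", mean_target, " um) must exceed the node length (",
         node_len, " um)")
  }
  sec <- morph$sections[!(morph$sections$role %in%
    c("main_axon_node", "main_axon_internode", "collateral")), ]
  next_id <- max(sec$id) + 1L
  ax_start <- cfg$hillock_length + cfg$ais_length
  ax_end <- cfg$axon_length
  nodes <- .node_intervals(cfg$collateral_distances, node_len)
  # clamp to the axon span
  if (nrow(nodes)) {
    nodes[, 1] <- pmax(nodes[, 1], ax_start)
    nodes[, 2] <- pmin(nodes[, 2], ax_end)
  }
  bounds <- rbind(c(NA, ax_start), nodes, c(ax_end, NA))
  prev_id <- 4L # AIS
  rows <- list()
  node_centers <- numeric(0)
  add <- function(role, from, to) {
    r <- .new_section(next_id, role, to - from, cfg$main_axon_diam,
                      prev_id, 1, from)
    next_id <<- next_id + 1L
    prev_id <<- r$id
    rows[[length(rows) + 1]] <<- r
  }
  for (i in seq_len(nrow(bounds) - 1)) {
    from <- bounds[i, 2]
    to <- bounds[i + 1, 1]
    s <- to - from
    if (s > 2 * mean_target) {
      n <- max(1L, floor((s + node_len) / (mean_target + node_len)))
      il <- (s - (n - 1) * node_len) / n
      pos <- from
      for (k in seq_len(n)) {
        add("main_axon_internode", pos, pos + il)
        pos <- pos + il
        if (k < n) {
          add("main_axon_node", pos, pos + node_len)
          node_centers <- c(node_centers, pos + node_len / 2)
          pos <- pos + node_len
        }
      }
    } else if (s > 1e-9) {
      add("main_axon_internode", from, to)
    }
    if (i < nrow(bounds) - 1) {
      add("main_axon_node", bounds[i + 1, 1], bounds[i + 1, 2])
      node_centers <- c(node_centers, mean(bounds[i + 1, ]))
    }
  }
  ax <- do.call(rbind, rows)
  # attach collaterals to the node section containing each branch distance
  coll_rows <- list()
  for (j in seq_along(cfg$collateral_distances)) {
    b <- cfg$collateral_distances[j]
    host <- ax[ax$role == "main_axon_node" &
      ax$path_start - 1e-9 <= b &
      ax$path_start + ax$length + 1e-9 >= b, , drop = FALSE]
    stopifnot(nrow(host) >= 1)
    host <- host[1, ]
    coll_rows[[j]] <- .new_section(
      next_id, "collateral", cfg$collateral_lengths[j], cfg$collateral_diam,
      host$id, (b - host$path_start) / host$length, b
    )
    next_id <- next_id + 1L
  }
  morph$sections <- rbind(sec, ax, do.call(rbind, coll_rows))
  morph$nodes <- sort(node_centers)
  morph$internode_target <- mean_target
  if (!is.null(morph$sites)) {
    morph <- place_presynaptic_sites(morph, morph$config$site_spacing)
  }
  morph
}

#' Mean length of the main-axon internodes
#' @param morph \code{morphology}
#' @return mean internode length (um)
#' @export
mean_internode_length <- function(morph) {
  s <- morph$sections
  mean(s$length[s$role == "main_axon_internode"])
}

#' Place presynaptic sites along the collaterals
#'
#' Sites are placed every \code{spacing} um at segment midpoints,
#' \code{floor(length / spacing)} per collateral; each stores its axonal path
#' distance from the soma (branch distance plus position on the collateral).
#'
#' @param morph \code{morphology} with collaterals
#' @param spacing site spacing (um), > 0
#' @return \code{morphology} with \code{$sites} data frame (site_id,
#'   collateral_id, pos_on_collateral, path_distance)
#' @export
place_presynaptic_sites <- function(morph, spacing = 8) {
  if (spacing <= 0) stop("site spacing must be > 0")
  s <- morph$sections
  colls <- s[s$role == "collateral", , drop = FALSE]
  out <- list()
  sid <- 0L
  for (i in seq_len(nrow(colls))) {
    n <- floor(colls$length[i] / spacing)
    if (n < 1) next
    pos <- (seq_len(n) - 0.5) * spacing
    out[[length(out) + 1]] <- data.frame(
      site_id = sid + seq_len(n),
      collateral_id = colls$id[i],
      pos_on_collateral = pos,
      path_distance = colls$path_start[i] + pos
    )
    sid <- sid + n
  }
  morph$sites <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      site_id = integer(0), collateral_id = integer(0),
      pos_on_collateral = numeric(0), path_distance = numeric(0)
    )
  }
  rownames(morph$sites) <- NULL
  morph
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$sections
  cat(
    "<morphology>", nrow(s), "sections;",
    sum(s$role == "collateral"), "collaterals;",
    sum(s$role == "main_axon_node"), "main-axon node sections;",
    if (is.null(x$sites)) 0 else nrow(x$sites), "presynaptic sites\n"
  )
  cat(sprintf(
    "  main axon %g um; mean internode %.1f um (target %g)\n",
    x$config$axon_length, mean_internode_length(x), x$internode_target
  ))
  invisible(x)
}

#' Axonal path distance between two points
#'
#' Distances are additive along the tree; this resolves the path distance of
#' a position on any axonal section from the soma exit.
#'
#' @param morph \code{morphology}
#' @param section_id section id
#' @param pos relative position on the section in [0, 1]
#' @return path distance (um)
#' @export
path_distance <- function(morph, section_id, pos = 0.5) {
  s <- morph$sections
  i <- match(section_id, s$id)
  if (is.na(i)) stop("unknown section id ", section_id)
  if (is.na(s$path_start[i])) stop("section ", section_id, " is not on the axonal path")
  s$path_start[i] + pos * s$length[i]
}
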