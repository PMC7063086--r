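#' Write a morphology to SWC
#'
#' Standard 7-column SWC (index, type, x, y, z, radius, parent) with type
#' codes 1 = soma, 2 = axon, 3 = dendrite. The synthetic cell has no
#' reconstructed 3-D shape, so coordinates are laid out schematically: the
#' axonal path along +x, the dendritic cylinder along -x, and each collateral
#' along +/-y from its branch point. Presynaptic sites have no SWC concept
#' and go to a sidecar CSV (\code{\link{write_sites_csv}}).
#'
#' @param morph \code{morphology}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_swc <- function(morph, path) {
  s <- morph$sections
  ns <- nrow(s)
  rows <- vector("list", 4 * ns)
  idx <- 0L
  origin <- c(0, 0, 0)
  add_sample <- function(type, xyz, radius, parent) {
    idx <<- idx + 1L
    rows[[idx]] <<- c(idx, type, xyz, radius, parent)
    idx
  }
  soma_i <- which(s$role == "soma")
  soma_idx <- add_sample(1L, origin, s$diam[soma_i] / 2, -1L)
  dirs <- list(
    dendrite = c(-1, 0, 0), hillock = c(1, 0, 0), ais = c(1, 0, 0),
    main_axon_node = c(1, 0, 0), main_axon_internode = c(1, 0, 0)
  )
  coll_sign <- 1
  # per-section sample indices at breakpoints (children attachment points
  # and the distal end), so mid-section branches parent onto a real sample
  # and read-back lengths are exact
  sample_at <- vector("list", ns) # each: data.frame(pos, idx)
  start_xyz <- matrix(0, ns, 3)
  end_xyz <- matrix(0, ns, 3)
  ord <- order(s$id)
  for (i in ord) {
    if (s$role[i] == "soma") next
    p <- match(s$parent[i], s$id)
    parent_is_soma <- s$role[p] == "soma"
    base <- if (parent_is_soma) {
      origin
    } else {
      start_xyz[p, ] + s$parent_pos[i] * (end_xyz[p, ] - start_xyz[p, ])
    }
    if (s$role[i] == "collateral") {
      d <- c(0, coll_sign, 0)
      coll_sign <- -coll_sign
      type <- 2L
    } else {
      d <- dirs[[s$role[i]]]
      type <- if (s$role[i] == "dendrite") 3L else 2L
    }
    start_xyz[i, ] <- base
    end_xyz[i, ] <- base + d * s$length[i]
    parent_idx <- if (parent_is_soma) {
      soma_idx
    } else {
      tab <- sample_at[[p]]
      j <- which.min(abs(tab$pos - s$parent_pos[i]))
      tab$idx[j]
    }
    # breakpoints: children attachment positions on this section, then the end
    kids <- which(!is.na(s$parent) & s$parent == s$id[i])
    pos <- sort(unique(c(s$parent_pos[kids][s$parent_pos[kids] < 1 - 1e-9], 1)))
    tab <- data.frame(pos = pos, idx = NA_integer_)
    prev <- parent_idx
    for (k in seq_along(pos)) {
      prev <- add_sample(type, base + d * s$length[i] * pos[k], s$diam[i] / 2, prev)
      tab$idx[k] <- prev
    }
    sample_at[[i]] <- tab
  }
  df <- as.data.frame(do.call(rbind, rows[seq_len(idx)]))
  names(df) <- c("n", "type", "x", "y", "z", "r", "parent")
  header <- c(
    "# SWC export (schematic coordinates; path lengths and radii are exact)",
    "# columns: n type x y z radius parent"
  )
  writeLines(
    c(header, sprintf(
      "%d %d %.6f %.6f %.6f %.6f %d",
      df$n, df$type, df$x, df$y, df$z, df$r, df$parent
    )),
    path
  )
  invisible(path)
}

#' Read an SWC file
#'
#' Parses a 7-column SWC into a section table: every sample becomes a section
#' spanning from its parent sample, with length the Euclidean sample distance
#' and diameter twice the sample radius. Role information beyond the SWC type
#' codes (soma/axon/dendrite) is not recoverable from SWC.
#'
#' @param path SWC file
#' @return data frame with columns id, type, role, length, diam, parent
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
    col.names = c("n", "type", "x", "y", "z", "r", "parent")
  )
  role <- c("soma", "axon", "dendrite")[pmin(raw$type, 3)]
  pl <- match(raw$parent, raw$n)
  len <- ifelse(is.na(pl), 0,
    sqrt((raw$x - raw$x[pl])^2 + (raw$y - raw$y[pl])^2 + (raw$z - raw$z[pl])^2)
  )
  data.frame(
    id = raw$n, type = raw$type, role = role,
    length = len, diam = 2 * raw$r, parent = raw$parent
  )
}

#' Write / read the presynaptic-site sidecar table
#'
#' @param morph \code{morphology} with sites
#' @param path CSV file
#' @return the path (write) or the site data frame (read)
#' @export
write_sites_csv <- function(morph, path) {
  df <- morph$sites
  names(df) <- c("site_id", "collateral_id", "pos_on_collateral_um", "path_distance_um")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- c("site_id", "collateral_id", "pos_on_collateral", "path_distance")
  df
}
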