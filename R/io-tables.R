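#' Column schema for spot morphometry tables
#'
#' @return character vector of the canonical SpotTable column names.
#' @keywords internal
spot_table_columns <- function() {
  c("id", "volume_um3", "surface_um2", "centroid_z_um", "centroid_y_um",
    "centroid_x_um", "bbox_z0", "bbox_z1", "bbox_y0", "bbox_y1",
    "bbox_x0", "bbox_x1", "mean_intensity", "flag_small")
}

empty_spot_table <- function() {
  df <- data.frame(id = integer(), volume_um3 = numeric(),
                   surface_um2 = numeric(), centroid_z_um = numeric(),
                   centroid_y_um = numeric(), centroid_x_um = numeric(),
                   bbox_z0 = integer(), bbox_z1 = integer(),
                   bbox_y0 = integer(), bbox_y1 = integer(),
                   bbox_x0 = integer(), bbox_x1 = integer(),
                   mean_intensity = numeric(), flag_small = logical())
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write a spot table as CSV
#'
#' Writes the per-spot morphometry table with its documented header; an
#' empty table produces a header-only file.
#'
#' @param table a spot table as returned by [extract_spots()].
#' @param path output CSV path.
#' @export
write_spot_table <- function(table, path) {
  stopifnot(all(spot_table_columns() %in% names(table)))
  write.csv(as.data.frame(table)[spot_table_columns()], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a spot table CSV
#' @param path CSV written by [write_spot_table()].
#' @export
read_spot_table <- function(path) {
  df <- read.csv(path)
  class(df) <- c("spot_table", "data.frame")
  df
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf(paste0("<vessel_graph> %d nodes, %d segments, ",
                     "%d junction(s), mask volume %.1f um^3\n"),
              nrow(x$nodes), nrow(x$segments),
              sum(x$nodes$degree >= 3), x$mask_volume_um3))
  invisible(x)
}

#' Write a vessel graph
#'
#' GraphML keeps the full attribute set (node positions, per-segment length,
#' chord, tortuosity, mean diameter, and the polylines/radii as JSON) and
#' round-trips losslessly through [read_vessel_graph()]. The SWC-like format
#' writes one point per line (`id type x y z radius parent`), with each
#' segment emitted as an independent parent chain.
#'
#' @param graph a `vessel_graph`.
#' @param path output path.
#' @param format `"graphml"` or `"swc"`.
#' @export
write_vessel_graph <- function(graph, path, format = c("graphml", "swc")) {
  format <- match.arg(format)
  if (format == "graphml") {
    nseg <- nrow(graph$segments)
    g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
    igraph::V(g)$name <- as.character(graph$nodes$id)
    igraph::V(g)$z_um <- graph$nodes$z_um
    igraph::V(g)$y_um <- graph$nodes$y_um
    igraph::V(g)$x_um <- graph$nodes$x_um
    igraph::V(g)$degree <- graph$nodes$degree
    if (nseg > 0) {
      ep <- rbind(match(graph$segments$from, graph$nodes$id),
                  match(graph$segments$to, graph$nodes$id))
      g <- igraph::add_edges(g, as.vector(ep))
      igraph::E(g)$seg_id <- graph$segments$id
      igraph::E(g)$length_um <- graph$segments$length_um
      igraph::E(g)$chord_um <- graph$segments$chord_um
      igraph::E(g)$tortuosity <- graph$segments$tortuosity
      igraph::E(g)$mean_diameter_um <- graph$segments$mean_diameter_um
      igraph::E(g)$points_json <- vapply(graph$polylines, function(p)
        as.character(jsonlite::toJSON(unname(p), digits = NA)), character(1))
      igraph::E(g)$radii_json <- vapply(graph$radii, function(r)
        as.character(jsonlite::toJSON(unname(r), digits = NA)), character(1))
    }
    g <- igraph::set_graph_attr(g, "mask_volume_um3", graph$mask_volume_um3)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c("# SWC-like vessel centerlines (um)",
               "# id type x y z radius parent")
    nid <- 0
    for (i in seq_len(nrow(graph$segments))) {
      p <- graph$polylines[[i]]
      r <- graph$radii[[i]]
      for (j in seq_len(nrow(p))) {
        nid <- nid + 1
        parent <- if (j == 1) -1 else nid - 1
        lines <- c(lines, sprintf("%d 2 %.4f %.4f %.4f %.4f %d", nid,
                                  p[j, 3], p[j, 2], p[j, 1], r[j], parent))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a vessel graph from GraphML
#' @param path file written by [write_vessel_graph()] with
#'   `format = "graphml"`.
#' @return a `vessel_graph`.
#' @export
read_vessel_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = as.integer(igraph::V(g)$name),
                      z_um = igraph::V(g)$z_um, y_um = igraph::V(g)$y_um,
                      x_um = igraph::V(g)$x_um,
                      degree = as.integer(igraph::V(g)$degree))
  ne <- igraph::ecount(g)
  if (ne > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    segments <- data.frame(
      id = as.integer(igraph::E(g)$seg_id),
      from = nodes$id[el[, 1]], to = nodes$id[el[, 2]],
      length_um = igraph::E(g)$length_um,
      chord_um = igraph::E(g)$chord_um,
      tortuosity = igraph::E(g)$tortuosity,
      mean_diameter_um = igraph::E(g)$mean_diameter_um)
    polylines <- lapply(igraph::E(g)$points_json, function(s) {
      m <- jsonlite::fromJSON(s)
      if (is.null(dim(m))) m <- matrix(m, ncol = 3)
      colnames(m) <- c("z_um", "y_um", "x_um")
      m
    })
    radii <- lapply(igraph::E(g)$radii_json, function(s)
      as.numeric(jsonlite::fromJSON(s)))
    segments$n_points <- vapply(polylines, nrow, integer(1))
    ord <- order(segments$id)
    segments <- segments[ord, , drop = FALSE]
    polylines <- polylines[ord]
    radii <- radii[ord]
    rownames(segments) <- NULL
  } else {
    segments <- data.frame(id = integer(), from = integer(), to = integer(),
                           length_um = numeric(), chord_um = numeric(),
                           tortuosity = numeric(),
                           mean_diameter_um = numeric(),
                           n_points = integer())
    polylines <- list()
    radii <- list()
  }
  mv <- igraph::graph_attr(g, "mask_volume_um3")
  structure(list(nodes = nodes, segments = segments, polylines = polylines,
                 radii = radii, mask_volume_um3 = as.numeric(mv %||% NA)),
            class = "vessel_graph")
}
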