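#' 3D image stack container
#'
#' A minimal container for a single-channel confocal Z-stack: a numeric 3D
#' array in (z, y, x) axis order plus the physical voxel spacing. The
#' physical coordinate of voxel (iz, iy, ix) (1-based) is taken at its
#' centre, ((ix - 0.5) dx, (iy - 0.5) dy, (iz - 0.5) dz) micrometres; every
#' micrometre-valued output of the package uses this convention.
#'
#' @param voxels numeric 3D array, dim = c(nz, ny, nx), non-negative finite.
#' @param spacing numeric length-3, (dz, dy, dx) in um, all positive.
#' @param source_path optional provenance string.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, source_path = NA_character_) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array (z, y, x)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (dz, dy, dx) in um")
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 source_path = source_path),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".json")

#' Read a multi-page grayscale TIFF into an image_stack
#'
#' Pages become the z axis. Voxel spacing is resolved, in order of
#' precedence: the `spacing` argument, a sidecar JSON written by
#' [write_stack()], TIFF resolution tags (in-plane only, assumed um), then
#' the configured default; the chosen source is reported via [message()].
#' Multi-channel (RGB) files are rejected rather than silently collapsed.
#'
#' @param path TIFF file path.
#' @param spacing optional explicit (dz, dy, dx) um.
#' @param config optional [pipeline_config()] supplying the fallback spacing;
#'   if no source yields a spacing the function errors.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2L)
    stop("unsupported format: multi-channel TIFF (expected single-channel grayscale): ", path)
  nz <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) {
    if (!identical(dim(pages[[i]]), c(ny, nx))) stop("inconsistent page sizes in ", path)
    vox[i, , ] <- pages[[i]]
  }
  src <- NULL
  sc <- sidecar_path(path)
  tag_spacing <- NULL
  info <- try(suppressWarnings(tiff::readTIFF(path, payload = FALSE)), silent = TRUE)
  if (!inherits(info, "try-error")) {
    a <- attributes(if (is.list(info)) info[[1]] else info)
    if (!is.null(a$x.resolution) && is.finite(a$x.resolution) && a$x.resolution > 0) {
      dxy <- 1 / a$x.resolution
      tag_spacing <- c(1, dxy, dxy)
    }
  }
  if (!is.null(spacing)) {
    src <- "argument"
  } else if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    spacing <- as.numeric(meta$spacing_um)
    src <- "sidecar"
    if (!is.null(tag_spacing) && any(abs(tag_spacing[2:3] - spacing[2:3]) > 1e-9))
      message("read_stack: sidecar spacing overrides conflicting TIFF resolution tags for ", path)
  } else if (!is.null(tag_spacing)) {
    spacing <- tag_spacing
    src <- "tiff_tags"
    message("read_stack: z spacing not stored in TIFF tags; using 1 um for ", path)
  } else if (!is.null(config)) {
    spacing <- config$voxel_spacing
    src <- "config_default"
  } else {
    stop("no voxel spacing available for ", path,
         " (no argument, sidecar, TIFF tags or config default)")
  }
  message(sprintf("read_stack: spacing (%g, %g, %g) um from %s",
                  spacing[1], spacing[2], spacing[3], src))
  st <- image_stack(vox, spacing, source_path = path)
  attr(st, "spacing_source") <- src
  st
}

#' Write an image_stack (or integer label array) as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned integers; values outside
#' `[0, 65535]` are clipped. The voxel spacing is written to a sidecar JSON
#' next to the file so that [read_stack()] round-trips it exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- round(stack$voxels)
  v[v < 0] <- 0; v[v > 65535] <- 65535
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(spacing_um = stack$spacing, axis_order = "zyx"),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write an integer label map as 16-bit TIFF (0 = background)
#' @param labels integer 3D array (z, y, x) of instance ids.
#' @param spacing (dz, dy, dx) um.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, spacing, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored as 16-bit")
  write_stack(image_stack(labels + 0.0, spacing), path)
}

# ---- SWC ------------------------------------------------------------------

#' Write a skeleton graph or phantom cell tree as SWC
#'
#' SWC rows are `id type x y z radius parent` in physical um. Each connected
#' component is rooted (parent -1): at the soma node when one is flagged,
#' otherwise at the component's first node. The root carries type 1 (soma),
#' every other node type 3 (process/dendrite-like).
#'
#' @param graph a `skeleton_graph` (see [build_graph()]) or `cell_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton_swc <- function(graph, path) {
  if (inherits(graph, "cell_tree")) graph <- as_skeleton_graph(graph)
  stopifnot(inherits(graph, "skeleton_graph"))
  rows <- list(); nid <- 0L
  g <- graph$igraph
  comp <- igraph::components(g)
  node_swc <- integer(igraph::vcount(g))
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    root <- members[1]
    soma_here <- members[graph$nodes$class[members] == "soma"]
    if (length(soma_here)) root <- soma_here[1]
    order <- as.integer(igraph::bfs(g, root = root, unreachable = FALSE)$order)
    order <- order[!is.na(order)]
    parent_swc <- integer(0)
    visited <- integer(0)
    for (v in order) {
      nid <- nid + 1L
      node_swc[v] <- nid
      # find an already-visited neighbour = BFS parent
      nb <- as.integer(igraph::neighbors(g, v))
      pv <- nb[nb %in% visited]
      if (length(pv) == 0) {
        rows[[length(rows) + 1L]] <- c(nid, 1L, graph$nodes$x[v], graph$nodes$y[v],
                                       graph$nodes$z[v], graph$nodes$radius[v], -1L)
      } else {
        # emit the edge polyline between parent and v as chained type-3 nodes
        pvx <- pv[1]
        eid <- igraph::get_edge_ids(g, c(pvx, v))
        poly <- graph$edges$polyline[[eid]]
        # orient polyline from parent to v
        pc <- c(graph$nodes$x[pvx], graph$nodes$y[pvx], graph$nodes$z[pvx])
        d_first <- sum((poly[1, ] - pc)^2); d_last <- sum((poly[nrow(poly), ] - pc)^2)
        if (d_last < d_first) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
        prev <- node_swc[pvx]
        if (nrow(poly) > 2) for (k in 2:(nrow(poly) - 1)) {
          nid <- nid + 1L
          rows[[length(rows) + 1L]] <- c(nid, 3L, poly[k, 1], poly[k, 2], poly[k, 3], 0.5, prev)
          prev <- nid
        }
        nid_v <- nid + 1L; nid <- nid_v
        node_swc[v] <- nid_v
        rows[[length(rows) + 1L]] <- c(nid_v, 3L, graph$nodes$x[v], graph$nodes$y[v],
                                       graph$nodes$z[v], graph$nodes$radius[v], prev)
      }
      visited <- c(visited, v)
    }
  }
  m <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC skeleton (um); columns: id type x y z radius parent", con)
  if (!is.null(m)) {
    m[, 6][!is.finite(m[, 6])] <- 1.0
    write.table(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                           x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                           parent = as.integer(m[, 7])),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an SWC file
#' @param path SWC file.
#' @return data.frame with columns id, type, x, y, z, radius, parent.
#' @export
read_swc <- function(path) {
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  df
}

# ---- tables and provenance ------------------------------------------------

#' Write per-cell morphometrics to CSV with a stable column order
#' @param records data.frame of per-cell morphometrics (possibly 0 rows).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_morphometrics_csv <- function(records, path) {
  lead <- intersect(c("cell_id", "sample_id", "condition", "field_id",
                      "soma_volume", "segment_count", "endpoint_count",
                      "junction_count", "component_count", "longest_path",
                      "sholl_auc", "max_branches", "critical_radius",
                      "spheroid_count", "activated", "dystrophic",
                      "dystrophy_reasons"), names(records))
  records <- records[, c(lead, setdiff(names(records), lead)), drop = FALSE]
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON provenance record for a pipeline run
#' @param path output JSON path.
#' @param config the [pipeline_config()] used.
#' @param seed master seed of the run.
#' @param stages optional named numeric vector of per-stage timings (s).
#' @param inputs optional character vector of input paths.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, stages = NULL, inputs = NULL) {
  rec <- list(
    package = "migmorph",
    version = as.character(utils::packageVersion("migmorph")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    config = unclass(config),
    seed = seed,
    stage_timings_s = as.list(stages),
    inputs = inputs
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
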