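#' Conformational Sholl profile of a skeleton graph
#'
#' For each radius r = step, 2 step, ... counts the crossings of the sphere
#' of radius r about the soma centre by the edge polylines: strict sign
#' changes of (radial distance - r) along each polyline, so a polyline
#' crossing several times contributes each crossing, a vertex exactly on
#' the sphere does not interrupt a crossing, and a tangency that does not
#' pass through counts zero. When the graph carries voxel classes, per-class densities
#' (slab, junction, endpoint counts per annulus [r_i, r_i+1) divided by the
#' annulus volume) are emitted alongside.
#'
#' @param graph a `skeleton_graph`.
#' @param soma_center (x, y, z) um; defaults to the graph's soma node.
#' @param step radial step, um (default 1, the standard envelope spacing).
#' @param r_max maximal radius (default: radial extent + one step).
#' @return object of class `sholl_profile`: data.frame `profile` (radius,
#'   intersections, and density columns when available), `soma_center`,
#'   `step`.
#' @export
sholl_profile <- function(graph, soma_center = NULL, step = 1, r_max = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"), step > 0)
  if (is.null(soma_center)) {
    si <- which(graph$nodes$class == "soma")
    if (length(si) != 1L) stop("soma_center required (graph has no unique soma node)")
    soma_center <- c(graph$nodes$x[si], graph$nodes$y[si], graph$nodes$z[si])
  }
  if (!nrow(graph$edges)) {
    warning("empty graph; returning all-zero profile")
    prof <- data.frame(radius = step, intersections = 0L)
    return(structure(list(profile = prof, soma_center = soma_center, step = step),
                     class = "sholl_profile"))
  }
  seg_rads <- lapply(graph$edges$polyline, function(p)
    sqrt(rowSums(sweep(p, 2, soma_center, "-")^2)))
  max_r <- max(vapply(seg_rads, max, numeric(1)))
  if (is.null(r_max)) r_max <- max_r + step
  radii <- seq(step, r_max, by = step)
  counts <- integer(length(radii))
  for (rads in seg_rads) {
    for (k in seq_along(radii)) {
      s <- sign(rads - radii[k])
      s <- s[s != 0]
      if (length(s) > 1) counts[k] <- counts[k] + sum(diff(s) != 0)
    }
  }
  prof <- data.frame(radius = radii, intersections = as.integer(counts))
  if (!is.null(graph$voxel_classes)) {
    vc <- graph$voxel_classes
    vr <- sqrt((vc$x - soma_center[1])^2 + (vc$y - soma_center[2])^2 +
               (vc$z - soma_center[3])^2)
    shell <- findInterval(vr, radii)  # 0 = inside first sphere
    annvol <- (4 / 3) * pi * ((radii + step)^3 - radii^3)
    for (cl in c("slab", "junction", "endpoint")) {
      cnt <- tabulate(shell[vc$class == cl], nbins = length(radii))
      prof[[paste0(cl, "_density")]] <- cnt / annvol
    }
  }
  structure(list(profile = prof, soma_center = soma_center, step = step),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  s <- sholl_auc(x)
  cat(sprintf("sholl_profile: step %g um, %d radii, max %d branches at %g um, AUC %.1f\n",
              x$step, nrow(x$profile), s$max_branches, s$critical_radius, s$auc))
  invisible(x)
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$profile$radius, x$profile$intersections, type = "s",
                 xlab = "distance from soma (um)", ylab = "branches", ...)
  invisible(x)
}

#' Sholl summary: AUC, maximum and critical radius
#'
#' Trapezoidal integral of the branch-count curve over radius, from r = 0
#' (count defined as 0) to one step past the last non-zero radius, plus the
#' curve maximum and the radius at which it first occurs.
#'
#' @param profile a `sholl_profile`.
#' @return list of class `sholl_summary`: `auc` (branches um),
#'   `max_branches`, `critical_radius` (um).
#' @export
sholl_auc <- function(profile) {
  stopifnot(inherits(profile, "sholl_profile"))
  r <- profile$profile$radius
  cnt <- profile$profile$intersections
  if (!length(cnt) || all(cnt == 0))
    return(structure(list(auc = 0, max_branches = 0L, critical_radius = NA_real_),
                     class = "sholl_summary"))
  last <- max(which(cnt > 0))
  rr <- c(0, r[seq_len(last)], r[last] + profile$step)
  cc <- c(0, cnt[seq_len(last)], 0)
  auc <- sum(diff(rr) * (cc[-1] + cc[-length(cc)]) / 2)
  mx <- max(cnt)
  structure(list(auc = auc, max_branches = as.integer(mx),
                 critical_radius = r[which.max(cnt)]),
            class = "sholl_summary")
}

#' Pool per-cell summaries across samples of each condition
#'
#' Builds the long-format per-cell table (3-7 cells per sample pooled under
#' their condition) consumed by the group statistics. Rows are sorted by
#' (condition, sample, cell), so pooling is order-invariant.
#'
#' @param cells data.frame with at least cell_id, sample_id, condition and
#'   the per-cell metrics (sholl_auc, max_branches, segment_count,
#'   longest_path, ...).
#' @return the sorted pooled data.frame.
#' @export
pool_cells <- function(cells) {
  need <- c("cell_id", "sample_id", "condition")
  if (!all(need %in% names(cells)))
    stop("cells must have columns ", paste(need, collapse = ", "))
  tab <- table(cells$condition)
  empty <- names(tab)[tab == 0]
  if (length(empty)) stop("condition with zero cells: ", paste(empty, collapse = ", "))
  if (!nrow(cells)) stop("no cells to pool")
  cells[order(cells$condition, cells$sample_id, cells$cell_id), , drop = FALSE]
}
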