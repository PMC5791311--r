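#' Phantom specification for synthetic microglia
#'
#' Describes one morphological regime of the synthetic branching-cell
#' generator. Two presets emulate the morphologies of interest:
#' `young_like` (highly ramified, surveillant-like) and `aged_like`
#' (deramified, with stochastic process fragmentation as a dystrophy
#' surrogate). Branching probabilities are calibrated at construction time
#' (via the expected-tip recursion, see [expected_tip_count()]) so that the
#' mean tip count per cell equals `tip_target`; the preset targets are 13.1
#' tips for `young_like` and 5.6 for `aged_like`, the magnitudes reported
#' for naive young and aged microglia.
#'
#' @param regime "young_like" or "aged_like".
#' @param tip_target mean number of process tips per cell the branching
#'   probabilities are calibrated to (default 13.1 young / 5.6 aged).
#' @param n_primary number of primary processes leaving the soma
#'   (default 4 young / 3 aged).
#' @param segment_length_mean,segment_length_sd segment length distribution,
#'   um (default 6 +- 1.5 young, 4.5 +- 1.2 aged).
#' @param taper per-branch-order radius taper factor (default 0.85).
#' @param initial_radius,min_radius process radius at order 1 and floor, um.
#' @param soma_radius_range soma radius range, um (default 2.5-3.5).
#' @param fragmentation_prob probability that a distal (order >= 2) segment
#'   is rendered disconnected (default 0 young, 0.5 aged).
#' @param cells_per_field cells per simulated field (default 1).
#' @param field_shape (nz, ny, nx) voxels of a full field (default
#'   c(25, 512, 512)); single-cell renders crop to the cell's bounding box.
#' @param voxel_spacing (dz, dy, dx) um, default c(1.0, 0.3, 0.3).
#' @param psf_sigma Gaussian PSF sigma (z, y, x) um, default c(0.6, 0.15, 0.15).
#' @param snr (soma peak - background) over Gaussian read-noise sd;
#'   `Inf` disables both shot and read noise (noiseless limit). Default 12.
#' @param background_level,signal_amplitude counts: background offset and
#'   soma-peak amplitude above background (default 100 and 2000).
#' @param z_half_extent half-thickness of the slab the processes are kept in,
#'   um (default 9, matching a 25-slice stack at 1 um).
#' @param min_soma_separation minimum distance between somata in a
#'   multi-cell field, um (default 18).
#' @param seed default seed used when none is passed to the generators.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(regime = c("young_like", "aged_like"),
                         tip_target = NULL,
                         n_primary = NULL,
                         segment_length_mean = NULL,
                         segment_length_sd = NULL,
                         taper = 0.85,
                         initial_radius = 0.8,
                         min_radius = 0.6,
                         soma_radius_range = c(2.5, 3.5),
                         fragmentation_prob = NULL,
                         cells_per_field = 1L,
                         field_shape = c(25L, 512L, 512L),
                         voxel_spacing = c(1.0, 0.3, 0.3),
                         psf_sigma = c(0.6, 0.15, 0.15),
                         snr = 12,
                         background_level = 100,
                         signal_amplitude = 2000,
                         z_half_extent = 9,
                         min_soma_separation = 18,
                         seed = 1L) {
  regime <- match.arg(regime)
  young <- regime == "young_like"
  if (is.null(tip_target)) tip_target <- if (young) 13.1 else 5.6
  if (is.null(n_primary)) n_primary <- if (young) 4L else 3L
  if (is.null(segment_length_mean)) segment_length_mean <- if (young) 6 else 4.5
  if (is.null(segment_length_sd)) segment_length_sd <- if (young) 1.5 else 1.2
  if (is.null(fragmentation_prob)) fragmentation_prob <- if (young) 0 else 0.5
  stopifnot(all(voxel_spacing > 0), snr > 0, tip_target >= n_primary,
            fragmentation_prob >= 0, fragmentation_prob <= 1,
            segment_length_mean > 0, initial_radius > 0, min_radius > 0)
  base <- if (young) c(0.75, 0.55, 0.35, 0.15, 0.05) else c(0.50, 0.30, 0.12, 0.05, 0.02)
  probs <- calibrate_branch_probs(base, n_primary, tip_target)
  structure(list(
    regime = regime, tip_target = tip_target, n_primary = as.integer(n_primary),
    branch_probs = probs,
    segment_length_mean = segment_length_mean, segment_length_sd = segment_length_sd,
    taper = taper, initial_radius = initial_radius, min_radius = min_radius,
    soma_radius_range = soma_radius_range, fragmentation_prob = fragmentation_prob,
    cells_per_field = as.integer(cells_per_field), field_shape = as.integer(field_shape),
    voxel_spacing = as.numeric(voxel_spacing), psf_sigma = as.numeric(psf_sigma),
    snr = snr, background_level = background_level, signal_amplitude = signal_amplitude,
    z_half_extent = z_half_extent, min_soma_separation = min_soma_separation,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec [%s]: %d primaries, tip target %.1f, branch probs %s\n",
              x$regime, x$n_primary, x$tip_target,
              paste(round(x$branch_probs, 3), collapse = " ")))
  cat(sprintf("  fragmentation %.2f, snr %g, spacing %s um\n", x$fragmentation_prob,
              x$snr, paste(x$voxel_spacing, collapse = "x")))
  invisible(x)
}

#' Expected tip count of the recursive bifurcation model
#'
#' For branch probability p_o at order o, a segment either terminates
#' (probability 1 - p_o) or bifurcates; the expected number of tips of a
#' subtree rooted at order o is E_o = (1 - p_o) + 2 p_o E_{o+1}, with E = 1
#' beyond the last order. A cell with k primaries has expectation k E_1.
#'
#' @param branch_probs per-order bifurcation probabilities.
#' @param n_primary number of primary processes.
#' @return expected tips per cell.
#' @export
expected_tip_count <- function(branch_probs, n_primary) {
  e <- 1
  for (p in rev(branch_probs)) e <- (1 - p) + 2 * p * e
  n_primary * e
}

calibrate_branch_probs <- function(base, n_primary, tip_target) {
  if (tip_target <= n_primary + 1e-9) return(rep(0, length(base)))
  f <- function(s) expected_tip_count(pmin(1, base * s), n_primary) - tip_target
  hi <- 1
  while (f(hi) < 0 && hi < 64) hi <- hi * 2
  s <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  pmin(1, base * s)
}

norm3 <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) c(1, 0, 0) else v / n }

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one ground-truth branching cell
#'
#' Stochastic recursive bifurcation: `n_primary` processes leave the soma in
#' mostly-lateral directions; each segment has random length, a meandering
#' polyline, and a radius tapering with branch order; at its end it
#' bifurcates with the order-specific calibrated probability. In `aged_like`
#' regimes, distal segments (order >= 2) are flagged as fragmented with
#' probability `fragmentation_prob`; fragmented segments are rendered with a
#' proximal gap, so every fragmentation event adds one connected component.
#' Output is a pure function of `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param soma_center (x, y, z) um; defaults to the field centre.
#' @return object of class `cell_tree`: soma geometry, a node table, a list
#'   of segments (polyline points and radii in um), `tip_count`,
#'   `junction_count`, and `n_fragmented`.
#' @export
generate_cell_tree <- function(spec, seed = spec$seed, soma_center = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(soma_center)) {
    fs <- spec$field_shape; sp <- spec$voxel_spacing
    soma_center <- c(fs[3] * sp[3] / 2, fs[2] * sp[2] / 2, fs[1] * sp[1] / 2)
  }
  with_seed(seed, {
    soma_radius <- runif(1, spec$soma_radius_range[1], spec$soma_radius_range[2])
    nodes <- list(list(id = 1L, xyz = soma_center, parent = 0L, order = 0L))
    segments <- list()
    n_nodes <- 1L
    zlim <- c(soma_center[3] - spec$z_half_extent, soma_center[3] + spec$z_half_extent)
    # cloud of already-drawn points, for self-avoidance: a growing process
    # steers away from (or stops before) capsule-merging distance of another
    # process; points of the parent and sibling segments are exempt near the
    # shared branch point
    cloud <- matrix(numeric(0), 0, 3)
    cloud_pn <- integer(0)  # parent node of the segment each point belongs to
    cloud_cn <- integer(0)  # child node of that segment
    cloud_tip <- numeric(0) # extra clearance of each point (terminal bulbs)
    avoid_dist <- 2.0
    bulb_margin <- 0.6      # tip clearance supplement (bulbs fuse sooner)
    grow <- function(start, dir, order, parent_node) {
      len <- max(2.5, rnorm(1, spec$segment_length_mean * 0.97^(order - 1),
                            spec$segment_length_sd))
      r0 <- max(spec$min_radius, spec$initial_radius * spec$taper^(order - 1))
      r1 <- max(spec$min_radius, spec$initial_radius * spec$taper^order)
      npts <- max(2L, as.integer(ceiling(len / 1.5)) + 1L)
      step <- len / (npts - 1)
      pts <- matrix(0, npts, 3)
      pts[1, ] <- start
      d <- dir
      truncated <- FALSE
      k_eff <- npts
      dstart2 <- if (nrow(cloud)) rowSums(sweep(cloud, 2, start, "-")^2) else numeric(0)
      kin <- cloud_cn == parent_node | cloud_pn == parent_node
      # z-differences are down-weighted: axial voxelization inflates the
      # rendered tube, so capsules fuse at larger axial separations; points
      # that may carry a terminal bulb demand extra clearance, as does the
      # candidate point itself when it could become a tip
      blocked <- function(nxt, self_margin = 0) {
        if (!nrow(cloud)) return(FALSE)
        dd2 <- (cloud[, 1] - nxt[1])^2 + (cloud[, 2] - nxt[2])^2 +
               (0.75 * (cloud[, 3] - nxt[3]))^2
        any(dd2 < (avoid_dist + cloud_tip + self_margin)^2 &
            !(kin & dstart2 < 2.2^2))
      }
      for (k in 2:npts) {
        ok <- FALSE
        for (try in 1:14) {
          d_try <- norm3(d + rnorm(3, 0, if (try == 1) 0.12 else 0.35) * c(1, 1, 0.5))
          nxt <- pts[k - 1, ] + d_try * step
          if (nxt[3] < zlim[1] || nxt[3] > zlim[2]) {
            d_try[3] <- -d_try[3]; nxt <- pts[k - 1, ] + d_try * step
          }
          mid <- (pts[k - 1, ] + nxt) / 2
          sm <- if (k == npts) bulb_margin else 0
          if (!blocked(nxt, sm) && !blocked(mid)) { ok <- TRUE; d <- d_try; break }
        }
        if (!ok) { truncated <- TRUE; k_eff <- k - 1L; break }
        pts[k, ] <- nxt
      }
      # a branch that cannot reach a renderable length is not drawn at all:
      # its sibling is spliced through the branch point afterwards
      if (truncated && (k_eff - 1) * step < 2.0) return(FALSE)
      pts <- pts[seq_len(k_eff), , drop = FALSE]
      n_nodes <<- n_nodes + 1L
      nid <- n_nodes
      nodes[[nid]] <<- list(id = nid, xyz = pts[k_eff, ], parent = parent_node, order = order)
      segments[[length(segments) + 1L]] <<- list(
        parent_node = parent_node, child_node = nid, pts = pts,
        radii = seq(r0, r1, length.out = k_eff), order = order, fragmented = FALSE)
      # densify to ~0.5 um so the avoidance test cannot miss inter-sample
      # closest approaches
      dense <- pts
      if (k_eff >= 2) {
        segs <- lapply(seq_len(k_eff - 1L), function(j) {
          a <- pts[j, ]; b <- pts[j + 1L, ]
          nsub <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 0.5) + 1L)
          tt <- seq(0, 1, length.out = nsub)
          cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                a[3] + tt * (b[3] - a[3]))
        })
        dense <- do.call(rbind, segs)
      }
      cloud <<- rbind(cloud, dense)
      cloud_pn <<- c(cloud_pn, rep(parent_node, nrow(dense)))
      cloud_cn <<- c(cloud_cn, rep(nid, nrow(dense)))
      tipm <- numeric(nrow(dense))
      # the segment end may become a terminal bulb; demand clearance there
      dend2 <- rowSums(sweep(dense, 2, pts[k_eff, ], "-")^2)
      tipm[dend2 < bulb_margin^2] <- bulb_margin
      cloud_tip <<- c(cloud_tip, tipm)
      p_branch <- if (order <= length(spec$branch_probs)) spec$branch_probs[order] else 0
      if (!truncated && runif(1) < p_branch) {
        d_end <- norm3(pts[k_eff, ] - pts[k_eff - 1, ])
        perp <- norm3(pracma_cross(d_end, rnorm(3)))
        # near-symmetric bifurcation keeps siblings resolvable on the grid
        th1 <- runif(1, 0.45, 0.85); th2 <- runif(1, 0.45, 0.85)
        # a child that cannot be placed resolvably is retried in fresh
        # directions before being given up
        grow_retry <- function(dir0) {
          if (grow(pts[k_eff, ], dir0, order + 1L, nid)) return(TRUE)
          for (r in 1:3) {
            perp_r <- norm3(pracma_cross(d_end, rnorm(3)))
            th_r <- runif(1, 0.45, 0.85) * sample(c(-1, 1), 1)
            if (grow(pts[k_eff, ], norm3(d_end * cos(th_r) + perp_r * sin(th_r)),
                     order + 1L, nid)) return(TRUE)
          }
          FALSE
        }
        grow_retry(norm3(d_end * cos(th1) + perp * sin(th1)))
        grow_retry(norm3(d_end * cos(th2) - perp * sin(th2)))
      }
      TRUE
    }
    az0 <- runif(1, 0, 2 * pi)
    for (i in seq_len(spec$n_primary)) {
      az <- az0 + 2 * pi * (i - 1) / spec$n_primary + runif(1, -0.3, 0.3)
      dir <- norm3(c(cos(az), sin(az), runif(1, -0.25, 0.25)))
      grow(soma_center, dir, 1L, 1L)
    }
    # splice pass-through nodes left where one sibling of a bifurcation was
    # not drawable: parent and surviving child become one segment
    repeat {
      pn <- vapply(segments, function(s) s$parent_node, integer(1))
      cn <- vapply(segments, function(s) s$child_node, integer(1))
      pass <- cn[cn %in% pn & vapply(cn, function(n) sum(pn == n) == 1L, logical(1))]
      if (!length(pass)) break
      n0 <- pass[1]
      i_par <- which(cn == n0); i_ch <- which(pn == n0)
      segments[[i_par]]$pts <- rbind(segments[[i_par]]$pts,
                                     segments[[i_ch]]$pts[-1, , drop = FALSE])
      segments[[i_par]]$radii <- c(segments[[i_par]]$radii,
                                   segments[[i_ch]]$radii[-1])
      segments[[i_par]]$child_node <- segments[[i_ch]]$child_node
      segments <- segments[-i_ch]
    }
    # rebuild the node table from the surviving segments
    pn <- vapply(segments, function(s) s$parent_node, integer(1))
    cn <- vapply(segments, function(s) s$child_node, integer(1))
    ids <- c(1L, cn)
    xyz <- rbind(soma_center,
                 t(vapply(segments, function(s) s$pts[nrow(s$pts), ], numeric(3))))
    parents <- pn
    has_child <- ids %in% pn
    tip_count <- sum(!has_child[-1])
    junction_count <- sum(has_child[-1])
    n_frag <- 0L
    if (spec$fragmentation_prob > 0) {
      for (si in seq_along(segments)) {
        if (segments[[si]]$order >= 2 && runif(1) < spec$fragmentation_prob) {
          segments[[si]]$fragmented <- TRUE
          n_frag <- n_frag + 1L
        }
      }
    }
    nd <- data.frame(
      id = ids,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      parent = c(0L, parents),
      order = c(0L, vapply(segments, function(s) s$order, integer(1))))
    rownames(nd) <- NULL
    structure(list(soma_center = soma_center, soma_radius = soma_radius,
                   nodes = nd, segments = segments,
                   tip_count = tip_count, junction_count = junction_count,
                   segment_count = length(segments), n_fragmented = n_frag,
                   spec_regime = spec$regime, seed = seed),
              class = "cell_tree")
  })
}

pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

#' @export
print.cell_tree <- function(x, ...) {
  cat(sprintf("cell_tree [%s]: %d segments, %d tips, %d junctions, soma r %.2f um%s\n",
              x$spec_regime, x$segment_count, x$tip_count, x$junction_count,
              x$soma_radius,
              if (x$n_fragmented > 0) sprintf(", %d fragmented", x$n_fragmented) else ""))
  invisible(x)
}

shift_tree <- function(tree, offset) {
  tree$soma_center <- tree$soma_center + offset
  tree$nodes$x <- tree$nodes$x + offset[1]
  tree$nodes$y <- tree$nodes$y + offset[2]
  tree$nodes$z <- tree$nodes$z + offset[3]
  tree$segments <- lapply(tree$segments, function(s) {
    s$pts <- sweep(s$pts, 2, offset, "+"); s
  })
  tree
}

#' Analytic Sholl profile of a ground-truth tree
#'
#' Exact sphere-crossing counts: for every radius r = step, 2 step, ... the
#' number of strict sign changes of (radial distance - r) along each
#' segment's polyline, summed over segments. A polyline that crosses a
#' sphere several times contributes each crossing; a vertex lying exactly
#' on the sphere does not interrupt a crossing, and a tangency that touches
#' without passing counts zero. This is the independent geometric oracle
#' for the skeleton-based Sholl profile.
#'
#' @param tree a [generate_cell_tree()] result.
#' @param step radial step, um (default 1).
#' @param r_max maximal radius; defaults to the tree's radial extent + step.
#' @return data.frame (radius, intersections).
#' @export
analytic_sholl <- function(tree, step = 1, r_max = NULL) {
  stopifnot(step > 0)
  ctr <- tree$soma_center
  seg_rads <- lapply(tree$segments, function(s)
    sqrt(rowSums(sweep(s$pts, 2, ctr, "-")^2)))
  max_r <- max(vapply(seg_rads, max, numeric(1)), 0)
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
  data.frame(radius = radii, intersections = as.integer(counts))
}

#' Convert a ground-truth tree to a skeleton graph
#'
#' Nodes are the tree's soma, junctions and tips; edges carry the segment
#' polylines and their physical lengths. Fragmented segments are kept (the
#' tree is the pre-fragmentation truth). Used to run graph-level analyses
#' (Sholl, longest path) directly on ground truth.
#'
#' @param tree a `cell_tree`.
#' @return a `skeleton_graph`.
#' @export
as_skeleton_graph <- function(tree) {
  nd <- tree$nodes
  parents <- nd$parent
  is_leaf <- !(nd$id %in% parents)
  cls <- ifelse(nd$id == 1L, "soma", ifelse(is_leaf, "endpoint", "junction"))
  nodes <- data.frame(id = nd$id, x = nd$x, y = nd$y, z = nd$z, class = cls,
                      radius = c(tree$soma_radius, rep(0.5, nrow(nd) - 1L)),
                      stringsAsFactors = FALSE)
  polys <- lapply(tree$segments, function(s) s$pts)
  lens <- vapply(polys, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  edges <- data.frame(
    from = vapply(tree$segments, function(s) s$parent_node, integer(1)),
    to = vapply(tree$segments, function(s) s$child_node, integer(1)),
    length = lens)
  edges$polyline <- polys
  skeleton_graph(nodes, edges, spacing = NULL, voxel_classes = NULL)
}

#' Rasterize one cell into a confocal-like stack
#'
#' Processes are drawn as tapered capsules and the soma as a bright
#' ellipsoid (slightly flattened in z), in a stack cropped to the cell's
#' bounding box plus a margin. The clean render is blurred with the
#' anisotropic Gaussian PSF, then Poisson shot noise and Gaussian read noise
#' are added (`snr = Inf` disables both, giving the exact noiseless render).
#' Fragmented segments are drawn with their proximal 40% omitted.
#'
#' @param tree a `cell_tree`.
#' @param spec the [phantom_spec()] (noise/optics/grid parameters).
#' @param seed seed for the noise draw (default `spec$seed`).
#' @param margin bounding-box margin, um.
#' @return list: `stack` (an [image_stack()], counts), `mask` (logical
#'   ground-truth array before blur/noise), `tree` (the tree shifted into
#'   stack coordinates), `origin` (um offset applied).
#' @export
rasterize_cell <- function(tree, spec, seed = spec$seed, margin = 2.5) {
  pts <- do.call(rbind, lapply(tree$segments, function(s) s$pts))
  rmax <- max(vapply(tree$segments, function(s) max(s$radii), numeric(1)), tree$soma_radius)
  lo <- pmin(apply(pts, 2, min), tree$soma_center - tree$soma_radius) - rmax - margin
  hi <- pmax(apply(pts, 2, max), tree$soma_center + tree$soma_radius) + rmax + margin
  sp <- spec$voxel_spacing  # (dz, dy, dx)
  dims <- as.integer(ceiling((hi - lo) / c(sp[3], sp[2], sp[1])))[c(3, 2, 1)]  # (nz,ny,nx)
  tree2 <- shift_tree(tree, -lo)
  out <- render_cells(list(tree2), spec, dims, seed = seed)
  list(stack = out$stack, mask = out$mask, labels = out$labels,
       tree = tree2, origin = lo)
}

# Draw a list of trees into a field of given dims; returns stack+mask+labels.
render_cells <- function(trees, spec, dims, seed) {
  sp <- spec$voxel_spacing
  n <- prod(dims)
  vol <- numeric(n); dim(vol) <- dims
  lab <- numeric(n); dim(lab) <- dims
  for (ci in seq_along(trees)) {
    tree <- trees[[ci]]
    leaf_ids <- tree$nodes$id[!(tree$nodes$id %in% tree$nodes$parent)]
    for (s in tree$segments) {
      # terminal bulb: tips are drawn with a >= 1 um cap so the tip is at
      # least one z-slice thick and thinning always forms an endpoint there
      if (s$child_node %in% leaf_ids) {
        tippt <- s$pts[nrow(s$pts), ]
        br <- max(s$radii[length(s$radii)], 1.0)
        cpp_draw_ellipsoid(vol, dims, sp, tippt, rep(br, 3), 0.7)
        cpp_draw_ellipsoid(lab, dims, sp, tippt, rep(br, 3), ci)
      }
    }
    for (s in tree$segments) {
      pts <- s$pts; radii <- s$radii
      if (isTRUE(s$fragmented)) {
        # the rendered gap must exceed twice the capsule radius plus the
        # axial voxel size, or the pieces stay bridged on the grid
        cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
        gap <- max(0.4 * cum[length(cum)], 2.4)
        keep <- cum >= gap
        if (sum(keep) < 2) next
        pts <- pts[keep, , drop = FALSE]; radii <- radii[keep]
      }
      cpp_draw_polyline(vol, dims, sp, pts, radii, 0.7)
      cpp_draw_polyline(lab, dims, sp, pts, radii, ci)
    }
    semi <- c(tree$soma_radius, tree$soma_radius, tree$soma_radius * 0.8)
    cpp_draw_ellipsoid(vol, dims, sp, tree$soma_center, semi, 1.0)
    cpp_draw_ellipsoid(lab, dims, sp, tree$soma_center, semi, ci)
  }
  mask <- vol > 0
  dim(mask) <- dims
  img <- vol
  if (any(spec$psf_sigma > 0)) {
    sig_vox <- spec$psf_sigma / sp
    img <- cpp_gaussian_blur3d(img, dims, sig_vox)
    dim(img) <- dims
  }
  img <- spec$background_level + spec$signal_amplitude * img
  if (is.finite(spec$snr)) {
    img <- with_seed(seed, {
      shot <- rpois(n, lambda = as.numeric(img))
      read_sd <- spec$signal_amplitude / spec$snr
      pmax(0, shot + rnorm(n, 0, read_sd))
    })
    dim(img) <- dims
  }
  labi <- array(as.integer(round(lab)), dims)
  list(stack = image_stack(img, sp), mask = mask, labels = labi)
}

#' Rasterize a multi-cell field with ground truth
#'
#' Places `spec$cells_per_field` cells at soma positions sampled uniformly
#' in the field interior subject to a minimum soma separation (rejection
#' sampling, bounded retries), generates a tree per cell, and renders them
#' into one stack. The ground-truth instance label volume is produced before
#' blur and noise.
#'
#' @param spec a [phantom_spec()].
#' @param seed master seed for placement, trees and noise.
#' @return list: `stack`, `ground_truth` (trees, soma centre matrix, label
#'   volume, per-cell truth table), `mask`.
#' @export
rasterize_field <- function(spec, seed = spec$seed) {
  fs <- spec$field_shape; sp <- spec$voxel_spacing
  ext <- c(fs[3] * sp[3], fs[2] * sp[2], fs[1] * sp[1])  # (x, y, z) um
  ncell <- spec$cells_per_field
  centers <- with_seed(seed, {
    m <- matrix(NA_real_, ncell, 3)
    margin <- 12
    for (i in seq_len(ncell)) {
      ok <- FALSE
      for (try in 1:200) {
        cand <- c(runif(1, margin, ext[1] - margin), runif(1, margin, ext[2] - margin),
                  ext[3] / 2 + runif(1, -1, 1))
        if (i == 1 || all(sqrt(rowSums(sweep(m[seq_len(i - 1), , drop = FALSE], 2,
                                             cand, "-")^2)) >= spec$min_soma_separation)) {
          m[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", ncell, " somata with separation ",
                    spec$min_soma_separation, " um after 200 tries")
    }
    m
  })
  trees <- lapply(seq_len(ncell), function(i)
    generate_cell_tree(spec, seed = derive_seed(seed, i), soma_center = centers[i, ]))
  out <- render_cells(trees, spec, fs, seed = derive_seed(seed, ncell + 1L))
  truth <- data.frame(
    cell = seq_len(ncell),
    tip_count = vapply(trees, function(t) t$tip_count, integer(1)),
    segment_count = vapply(trees, function(t) t$segment_count, integer(1)),
    junction_count = vapply(trees, function(t) t$junction_count, integer(1)),
    n_fragmented = vapply(trees, function(t) t$n_fragmented, integer(1)),
    soma_x = centers[, 1], soma_y = centers[, 2], soma_z = centers[, 3])
  list(stack = out$stack, mask = out$mask,
       ground_truth = list(trees = trees, soma_centers = centers,
                           labels = out$labels, table = truth))
}

# Master-seed -> per-item seed splitting rule (documented, stays < 2^31).
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Default cohort conditions
#'
#' Four condition presets mirroring a young/aged x naive/inflamed design,
#' with branching calibrated to mean tips of 13.1, 8.4, 5.6 and 4.9 per
#' cell respectively.
#' @return named list of [phantom_spec()]s.
#' @export
cohort_conditions <- function() {
  list(
    young_naive = phantom_spec("young_like", tip_target = 13.1),
    young_si    = phantom_spec("young_like", tip_target = 8.4),
    aged_naive  = phantom_spec("aged_like", tip_target = 5.6),
    aged_si     = phantom_spec("aged_like", tip_target = 4.9)
  )
}

#' Generate a phantom cohort on disk
#'
#' Renders `n_cells` single-cell fields per condition (each cell in its own
#' cropped stack), writes the stacks, ground-truth label volumes, SWC trees
#' and analytic Sholl profiles, and a manifest CSV. Cells are assigned to
#' samples in blocks of `cells_per_sample` so that pooled analyses retain a
#' sample id. Fully reproducible from `master_seed` via the per-cell seed
#' derivation `(master + 7919 i) mod (2^31 - 1)`.
#'
#' @param conditions named list of [phantom_spec()]s (default
#'   [cohort_conditions()]).
#' @param n_cells cells per condition (>= 3).
#' @param out_dir output directory (created).
#' @param master_seed integer master seed.
#' @param cells_per_sample cells pooled under one sample id (default 5).
#' @param write_stacks set FALSE to skip TIFF/SWC output and return
#'   everything in memory (manifest plus per-cell objects).
#' @return manifest data.frame (invisibly when writing); with
#'   `write_stacks = FALSE`, a list with `manifest` and `cells`.
#' @export
generate_cohort <- function(conditions = cohort_conditions(), n_cells = 5,
                            out_dir = NULL, master_seed = 1L,
                            cells_per_sample = 5L, write_stacks = !is.null(out_dir)) {
  stopifnot(n_cells >= 3, length(conditions) >= 1, !is.null(names(conditions)))
  if (write_stacks) {
    if (is.null(out_dir)) stop("out_dir required when write_stacks = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list(); cells <- list()
  i_global <- 0L
  for (cond in names(conditions)) {
    spec <- conditions[[cond]]
    for (i in seq_len(n_cells)) {
      i_global <- i_global + 1L
      seed_i <- derive_seed(master_seed, i_global)
      tree <- generate_cell_tree(spec, seed = seed_i)
      ras <- rasterize_cell(tree, spec, seed = derive_seed(seed_i, 1L))
      truth_sholl <- analytic_sholl(ras$tree, step = 1)
      lp <- true_longest_path(ras$tree)
      stack_path <- label_path <- swc_path <- sholl_path <- NA_character_
      if (write_stacks) {
        base <- file.path(out_dir, sprintf("%s_cell%03d", cond, i))
        stack_path <- paste0(base, ".tif")
        label_path <- paste0(base, "_labels.tif")
        swc_path <- paste0(base, ".swc")
        sholl_path <- paste0(base, "_true_sholl.csv")
        write_stack(ras$stack, stack_path)
        write_label_map(ras$labels, spec$voxel_spacing, label_path)
        write_skeleton_swc(ras$tree, swc_path)
        write.csv(truth_sholl, sholl_path, row.names = FALSE)
      }
      rows[[i_global]] <- data.frame(
        condition = cond, sample_id = paste0(cond, "_s", ceiling(i / cells_per_sample)),
        cell_id = sprintf("%s_c%03d", cond, i), seed = seed_i,
        stack = stack_path, labels = label_path, swc = swc_path,
        true_sholl = sholl_path,
        true_tip_count = tree$tip_count, true_segment_count = tree$segment_count,
        true_junction_count = tree$junction_count,
        true_longest_path = lp, true_soma_radius = tree$soma_radius,
        n_fragmented = tree$n_fragmented, stringsAsFactors = FALSE)
      if (!write_stacks)
        cells[[i_global]] <- list(tree = ras$tree, stack = ras$stack,
                                  mask = ras$mask, labels = ras$labels,
                                  true_sholl = truth_sholl)
    }
  }
  manifest <- do.call(rbind, rows)
  if (write_stacks) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    invisible(manifest)
  } else list(manifest = manifest, cells = cells)
}

#' Ground-truth longest path of a tree (um)
#'
#' Weighted diameter over the tree graph with polyline arc lengths as edge
#' weights.
#' @param tree a `cell_tree`.
#' @return length in um.
#' @export
true_longest_path <- function(tree) {
  g <- as_skeleton_graph(tree)
  longest_path(g)
}
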