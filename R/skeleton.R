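#' Skeletonize one cell mask
#'
#' Topology-preserving 3D curve thinning on the voxel grid: simple,
#' non-endpoint border voxels are removed in six directional sub-iterations
#' until stable (simple-point test after Bertrand & Malandain: one
#' foreground 26-component in the 26-neighbourhood and one background
#' 6-component in the 18-neighbourhood adjacent to the centre). Thinning is
#' grid-based and ignores anisotropy; physical lengths are computed
#' afterwards on the skeleton. The skeleton is a subset of the mask and has
#' exactly the mask's connected components.
#'
#' @param mask logical 3D array (z, y, x) of one cell's voxels.
#' @param spacing (dz, dy, dx) um.
#' @return object of class `skeleton_voxels`: `mask` (logical skeleton
#'   array), `class` (filled by [classify_voxels()]), `spacing`.
#' @export
skeletonize_cell <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask cannot be skeletonized")
  dims <- dim(mask)
  skel <- cpp_thin3d(as.logical(mask), dims)
  dim(skel) <- dims
  structure(list(mask = skel, class = NULL, spacing = as.numeric(spacing)),
            class = "skeleton_voxels")
}

#' Classify skeleton voxels by 26-neighbourhood degree
#'
#' 0 foreground neighbours: isolated; 1: endpoint; 2: slab; 3 or more:
#' junction.
#'
#' @param skel a `skeleton_voxels` object.
#' @return the object with `class` filled: integer array coded 0 background,
#'   1 endpoint, 2 slab, 3 junction, 4 isolated.
#' @export
classify_voxels <- function(skel) {
  stopifnot(inherits(skel, "skeleton_voxels"))
  dims <- dim(skel$mask)
  deg <- cpp_neighbor_count26(as.logical(skel$mask), dims)
  cls <- integer(length(deg))
  fg <- !is.na(deg)
  cls[fg & deg == 0] <- 4L
  cls[fg & deg == 1] <- 1L
  cls[fg & deg == 2] <- 2L
  cls[fg & deg >= 3] <- 3L
  dim(cls) <- dims
  skel$class <- cls
  skel
}

#' @export
print.skeleton_voxels <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("skeleton_voxels: %d voxels", n))
  if (!is.null(x$class)) {
    cat(sprintf(" (%d endpoints, %d slabs, %d junctions, %d isolated)",
                sum(x$class == 1L), sum(x$class == 2L),
                sum(x$class == 3L), sum(x$class == 4L)))
  }
  cat("\n")
  invisible(x)
}

# physical (x, y, z) um of 1-based (iz, iy, ix) voxel indices
vox_phys <- function(iz, iy, ix, spacing) {
  cbind(x = (ix - 0.5) * spacing[3], y = (iy - 0.5) * spacing[2],
        z = (iz - 0.5) * spacing[1])
}

#' Skeleton graph constructor
#'
#' @param nodes data.frame: id, x, y, z (um), class
#'   ("soma"/"junction"/"endpoint"/"isolated"), radius.
#' @param edges data.frame: from, to (node ids), length (um), and a
#'   `polyline` list-column of k x 3 coordinate matrices.
#' @param spacing voxel spacing or NULL for analytic graphs.
#' @param voxel_classes optional data.frame (x, y, z, class) of all skeleton
#'   voxels, used for class densities in Sholl shells.
#' @return object of class `skeleton_graph` with fields `nodes`, `edges`,
#'   `igraph`, `segment_count`, `component_count`, `longest_path_um`,
#'   `max_branch_order`.
#' @export
skeleton_graph <- function(nodes, edges, spacing = NULL, voxel_classes = NULL) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) data.frame(from = match(edges$from, nodes$id),
                                    to = match(edges$to, nodes$id))
        else data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes))))
  obj <- structure(list(nodes = nodes, edges = edges, igraph = g,
                        spacing = spacing, voxel_classes = voxel_classes,
                        segment_count = nrow(edges),
                        component_count = igraph::components(g)$no,
                        longest_path_um = NA_real_,
                        max_branch_order = NA_integer_),
                   class = "skeleton_graph")
  obj$longest_path_um <- longest_path(obj)
  soma_idx <- which(nodes$class == "soma")
  if (length(soma_idx) == 1L && nrow(edges)) {
    d <- igraph::distances(g, v = soma_idx, weights = NA)[1, ]
    ends <- cbind(match(edges$from, nodes$id), match(edges$to, nodes$id))
    eo <- pmax(d[ends[, 1]], d[ends[, 2]])
    eo <- eo[is.finite(eo)]
    if (length(eo)) obj$max_branch_order <- as.integer(max(eo))
  }
  obj
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d nodes, %d segments, %d component(s), longest path %.2f um\n",
              nrow(x$nodes), x$segment_count, x$component_count, x$longest_path_um))
  invisible(x)
}

#' Build the physical-unit skeleton graph from classified voxels
#'
#' Adjacent junction voxels are merged into one junction node (cluster
#' centroid as its coordinate); when a soma is supplied, every skeleton
#' voxel within the soma radius of its centre collapses into a single soma
#' node, so the soma's thinning residue does not inflate the segment count.
#' Edges are traced between node voxels through runs of slab voxels; edge
#' length is the sum of voxel-centre steps in um under the anisotropic
#' spacing. Pure-cycle components (no junction or endpoint voxel) are
#' anchored at their first voxel in scan order for determinism.
#'
#' @param skel a classified `skeleton_voxels` (see [classify_voxels()]).
#' @param soma_center optional (x, y, z) um.
#' @param soma_radius optional soma radius, um.
#' @param prune_terminal_um remove terminal spur edges shorter than this
#'   (um, default 1): thinning a tube of finite radius leaves grid-scale
#'   spurs at junction and soma bulges that are artifacts of voxelization,
#'   not branches.
#' @param merge_junction_um contract junction-junction edges shorter than
#'   this (um, default 1.2): one anatomical branch point can thin into two
#'   junction clusters a voxel or two apart.
#' @return a [skeleton_graph()].
#' @export
build_graph <- function(skel, soma_center = NULL, soma_radius = NULL,
                        prune_terminal_um = 1.0, merge_junction_um = 1.2) {
  stopifnot(inherits(skel, "skeleton_voxels"))
  if (is.null(skel$class)) skel <- classify_voxels(skel)
  dims <- dim(skel$mask)
  sp <- skel$spacing
  lin <- which(skel$mask)
  if (!length(lin)) stop("empty skeleton")
  nz <- dims[1]; ny <- dims[2]
  iz <- ((lin - 1L) %% nz) + 1L
  iy <- (((lin - 1L) %/% nz) %% ny) + 1L
  ix <- ((lin - 1L) %/% (nz * ny)) + 1L
  phys <- vox_phys(iz, iy, ix, sp)
  cls <- skel$class[lin]
  nvox <- length(lin)
  pos_of <- new.env() # not used; lookup table below
  lut <- integer(prod(dims)); lut[lin] <- seq_len(nvox)

  in_soma <- rep(FALSE, nvox)
  if (!is.null(soma_center) && !is.null(soma_radius)) {
    d2 <- (phys[, 1] - soma_center[1])^2 + (phys[, 2] - soma_center[2])^2 +
          (phys[, 3] - soma_center[3])^2
    in_soma <- d2 <= soma_radius^2
  }

  # group ids: 0 = slab (ungrouped); soma voxels all share group 1
  grp <- integer(nvox)
  next_grp <- 0L
  grp_class <- character(0)
  if (any(in_soma)) {
    next_grp <- 1L
    grp[in_soma] <- 1L
    grp_class <- "soma"
  }
  # junction clusters (26-CC over junction voxels not already in soma)
  jmask <- rep(FALSE, prod(dims)); jmask[lin[cls == 3L & !in_soma]] <- TRUE
  if (any(jmask)) {
    jlab <- cpp_label3d(jmask, dims, 26L)
    jl <- jlab[lin]
    for (jc in seq_len(max(jl))) {
      next_grp <- next_grp + 1L
      grp[jl == jc] <- next_grp
      grp_class <- c(grp_class, "junction")
    }
  }
  # endpoints and isolated voxels: singleton groups
  for (k in which(cls %in% c(1L, 4L) & !in_soma & grp == 0L)) {
    next_grp <- next_grp + 1L
    grp[k] <- next_grp
    grp_class <- c(grp_class, if (cls[k] == 1L) "endpoint" else "isolated")
  }

  neigh <- function(k) {
    zz <- iz[k]; yy <- iy[k]; xx <- ix[k]
    out <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      jz <- zz + dz; jy <- yy + dy; jx <- xx + dx
      if (jz < 1 || jz > dims[1] || jy < 1 || jy > dims[2] || jx < 1 || jx > dims[3]) next
      l <- jz + nz * (jy - 1L) + nz * ny * (jx - 1L)
      p <- lut[l]
      if (p > 0L) out <- c(out, p)
    }
    out
  }

  # pure-cycle / all-slab components: anchor at first voxel in scan order
  comp_all <- cpp_label3d(as.logical(skel$mask), dims, 26L)[lin]
  for (cc in unique(comp_all)) {
    members <- which(comp_all == cc)
    if (all(grp[members] == 0L)) {
      k <- members[which.min(lin[members])]
      next_grp <- next_grp + 1L
      grp[k] <- next_grp
      grp_class <- c(grp_class, "slab_anchor")
    }
  }

  visited <- rep(FALSE, nvox)       # slab voxels consumed by a trace
  edge_from <- integer(0); edge_to <- integer(0)
  polylines <- list(); elen <- numeric(0)
  direct_seen <- character(0)

  add_edge <- function(a, b, poly) {
    edge_from <<- c(edge_from, a); edge_to <<- c(edge_to, b)
    polylines[[length(polylines) + 1L]] <<- poly
    elen <<- c(elen, sum(sqrt(rowSums(diff(poly)^2))))
  }

  for (v in order(lin)) {
    if (grp[v] == 0L) next
    for (u in neigh(v)) {
      if (grp[u] != 0L) {
        if (grp[u] == grp[v]) next
        key <- paste(min(lin[v], lin[u]), max(lin[v], lin[u]))
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        add_edge(grp[v], grp[u], rbind(phys[v, ], phys[u, ]))
      } else if (!visited[u]) {
        poly <- rbind(phys[v, ], phys[u, ])
        prev <- v; cur <- u; visited[cur] <- TRUE
        repeat {
          nb <- neigh(cur)
          nb <- nb[nb != prev]
          nodes_nb <- nb[grp[nb] != 0L]
          # avoid immediately re-entering the source cluster via a diagonal
          nodes_nb <- nodes_nb[!(grp[nodes_nb] == grp[v] & nrow(poly) <= 2)]
          if (length(nodes_nb)) {
            w <- nodes_nb[which.min(lin[nodes_nb])]
            poly <- rbind(poly, phys[w, ])
            add_edge(grp[v], grp[w], poly)
            break
          }
          slab_nb <- nb[grp[nb] == 0L & !visited[nb]]
          if (!length(slab_nb)) { # dead end or closed loop back to visited slab
            add_edge(grp[v], grp[v], poly)
            break
          }
          w <- slab_nb[which.min(lin[slab_nb])]
          poly <- rbind(poly, phys[w, ])
          prev <- cur; cur <- w; visited[cur] <- TRUE
        }
      }
    }
  }

  # node table: centroids of member voxels
  nid <- seq_len(next_grp)
  cx <- tapply(phys[, 1], grp, mean)[as.character(nid)]
  cy <- tapply(phys[, 2], grp, mean)[as.character(nid)]
  cz <- tapply(phys[, 3], grp, mean)[as.character(nid)]
  nodes <- data.frame(id = nid, x = as.numeric(cx), y = as.numeric(cy),
                      z = as.numeric(cz),
                      class = ifelse(grp_class == "slab_anchor", "slab", grp_class),
                      radius = 0.5, stringsAsFactors = FALSE)
  if (!is.null(soma_center) && any(nodes$class == "soma")) {
    si <- which(nodes$class == "soma")
    nodes$x[si] <- soma_center[1]; nodes$y[si] <- soma_center[2]; nodes$z[si] <- soma_center[3]
    if (!is.null(soma_radius)) nodes$radius[si] <- soma_radius
  }
  edges <- data.frame(from = edge_from, to = edge_to, length = elen)
  edges$polyline <- polylines

  simp <- simplify_skeleton_edges(nodes, edges, prune_terminal_um, merge_junction_um)
  nodes <- simp$nodes; edges <- simp$edges

  vc <- data.frame(x = phys[, 1], y = phys[, 2], z = phys[, 3],
                   class = c("background", "endpoint", "slab", "junction",
                             "isolated")[cls + 1L],
                   stringsAsFactors = FALSE)
  skeleton_graph(nodes, edges, spacing = sp, voxel_classes = vc)
}

# Graph-level cleanup of voxelization artifacts:
#   1. prune terminal spur edges shorter than prune_um (never a whole
#      component, never an edge ending at the soma's far side... the spur tip
#      node is dropped with the edge);
#   2. drop self-loops shorter than merge_um (thick-junction artifacts);
#   3. contract junction-junction edges shorter than merge_um;
#   4. splice the two edges of any degree-2 junction node left behind.
# Repeats until stable. Classes endpoint/soma are never contracted away.
simplify_skeleton_edges <- function(nodes, edges, prune_um, merge_um) {
  repeat {
    changed <- FALSE
    if (!nrow(edges)) break
    deg <- tabulate(c(edges$from, edges$to), nbins = max(nodes$id))
    cls_of <- function(ids) nodes$class[match(ids, nodes$id)]
    # 1. terminal spurs; the anchoring node must keep degree >= 3 so that
    # the second prong of a thinned tip cap ("fishtail") is never consumed
    if (prune_um > 0) {
      f1 <- deg[edges$from] == 1 & cls_of(edges$from) != "soma"
      t1 <- deg[edges$to] == 1 & cls_of(edges$to) != "soma"
      anchor_deg <- ifelse(f1, deg[edges$to], deg[edges$from])
      spur <- xor(f1, t1) & edges$length < prune_um & edges$from != edges$to &
              anchor_deg >= 3
      if (any(spur)) {
        j <- which(spur)[which.min(edges$length[spur])]
        tip <- if (f1[j]) edges$from[j] else edges$to[j]
        edges <- edges[-j, , drop = FALSE]
        nodes <- nodes[nodes$id != tip, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed && merge_um > 0) {
      # 2. short self-loops
      loop <- edges$from == edges$to & edges$length < merge_um
      if (any(loop)) { edges <- edges[!loop, , drop = FALSE]; changed <- TRUE }
    }
    if (!changed && merge_um > 0 && nrow(edges)) {
      # 3. short junction-junction connectors
      jj <- edges$from != edges$to &
            cls_of(edges$from) == "junction" &
            cls_of(edges$to) == "junction" &
            edges$length < merge_um
      if (any(jj)) {
        j <- which(jj)[1]
        a <- edges$from[j]; b <- edges$to[j]
        edges <- edges[-j, , drop = FALSE]
        edges$from[edges$from == b] <- a
        edges$to[edges$to == b] <- a
        nodes <- nodes[nodes$id != b, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed && nrow(edges) >= 2) {
      # 3b. forked tips: two terminal edges from one junction whose tip
      # nodes nearly coincide are one branch end split by thinning; keep
      # the longer prong
      deg <- tabulate(c(edges$from, edges$to), nbins = max(nodes$id))
      tipn <- function(e) if (deg[edges$from[e]] == 1) edges$from[e] else
                          if (deg[edges$to[e]] == 1) edges$to[e] else NA_integer_
      anchn <- function(e, tn) if (edges$from[e] == tn) edges$to[e] else edges$from[e]
      term <- which(vapply(seq_len(nrow(edges)), function(e)
        !is.na(tipn(e)) && cls_of(tipn(e)) == "endpoint", logical(1)))
      done <- FALSE
      if (length(term) >= 2) {
        tt <- vapply(term, tipn, integer(1))
        aa <- vapply(seq_along(term), function(k) anchn(term[k], tt[k]), integer(1))
        for (a in unique(aa[duplicated(aa)])) {
          es <- term[aa == a]
          if (length(es) < 2) next
          tn <- vapply(es, tipn, integer(1))
          co <- nodes[match(tn, nodes$id), c("x", "y", "z")]
          pr <- utils::combn(seq_along(es), 2)
          for (q in seq_len(ncol(pr))) {
            i1 <- pr[1, q]; i2 <- pr[2, q]
            if (sqrt(sum((co[i1, ] - co[i2, ])^2)) < 1.6) {
              drop <- if (edges$length[es[i1]] < edges$length[es[i2]]) i1 else i2
              nodes <- nodes[nodes$id != tn[drop], , drop = FALSE]
              edges <- edges[-es[drop], , drop = FALSE]
              changed <- TRUE; done <- TRUE; break
            }
          }
          if (done) break
        }
      }
    }
    if (!changed && nrow(edges) >= 2) {
      # 3c. parallel edges (thinning ladders): keep the shorter of two edges
      # joining the same node pair
      key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
      dup <- key[duplicated(key) & edges$from != edges$to]
      if (length(dup)) {
        es <- which(key == dup[1])
        drop <- es[which.max(edges$length[es])]
        edges <- edges[-drop, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed && nrow(edges)) {
      # 4. degree-2 junction splice
      deg <- tabulate(c(edges$from, edges$to), nbins = max(nodes$id))
      cand <- nodes$id[nodes$class == "junction" & deg[nodes$id] == 2]
      cand <- cand[!vapply(cand, function(v) any(edges$from == v & edges$to == v),
                           logical(1))]
      if (length(cand)) {
        v <- cand[1]
        ei <- which(edges$from == v | edges$to == v)
        e1 <- ei[1]; e2 <- ei[2]
        other <- function(e) if (edges$from[e] == v) edges$to[e] else edges$from[e]
        orient <- function(e) {
          p <- edges$polyline[[e]]
          # polyline should END at v
          vd <- nodes[match(v, nodes$id), ]
          if (sum((p[1, ] - c(vd$x, vd$y, vd$z))^2) <
              sum((p[nrow(p), ] - c(vd$x, vd$y, vd$z))^2))
            p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
          p
        }
        p1 <- orient(e1); p2 <- orient(e2)
        poly <- rbind(p1, p2[rev(seq_len(nrow(p2))), , drop = FALSE])
        newe <- data.frame(from = other(e1), to = other(e2),
                           length = edges$length[e1] + edges$length[e2])
        newe$polyline <- list(poly)
        edges <- rbind(edges[-ei, , drop = FALSE], newe)
        nodes <- nodes[nodes$id != v, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # relabel ids densely
  if (nrow(nodes)) {
    remap <- setNames(seq_len(nrow(nodes)), nodes$id)
    if (nrow(edges)) {
      edges$from <- as.integer(remap[as.character(edges$from)])
      edges$to <- as.integer(remap[as.character(edges$to)])
    }
    nodes$id <- seq_len(nrow(nodes))
  }
  rownames(nodes) <- NULL
  if (nrow(edges)) rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Longest path of a skeleton graph (um)
#'
#' Weighted graph diameter: the maximum over node pairs of the shortest-path
#' length along edges; for multi-component graphs, the maximum over
#' components.
#'
#' @param graph a `skeleton_graph`.
#' @return length in um (0 for an edgeless graph).
#' @export
longest_path <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (!nrow(graph$edges)) return(0)
  d <- igraph::distances(graph$igraph, weights = graph$edges$length)
  max(d[is.finite(d)])
}
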