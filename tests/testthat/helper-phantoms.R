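# Shared fixtures: noiseless phantom spec and a cached noiseless render.

noiseless_spec <- function(regime = "young_like", ...) {
  phantom_spec(regime, snr = Inf, psf_sigma = c(0, 0, 0), ...)
}

# one noiseless young cell, rendered once per test run
cached_cell <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- noiseless_spec()
      tree <- generate_cell_tree(spec, seed = 42)
      ras <- rasterize_cell(tree, spec, seed = 1)
      cache <<- list(spec = spec, tree = tree, ras = ras)
    }
    cache
  }
})

# independent all-pairs shortest path oracle (Floyd-Warshall on the node
# distance matrix; parallel edges collapsed to their minimum)
fw_diameter <- function(graph) {
  n <- nrow(graph$nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (e in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$from[e], graph$nodes$id)
    j <- match(graph$edges$to[e], graph$nodes$id)
    D[i, j] <- min(D[i, j], graph$edges$length[e])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    upd <- D[i, k] + D[k, ]
    sel <- upd < D[i, ]
    D[i, sel] <- upd[sel]
  }
  max(D[is.finite(D)])
}

# independent oracle: exhaustive scan of the cross-entropy objective over
# integer thresholds
li_scan_oracle <- function(x) {
  y <- x - min(x)
  cands <- 0:ceiling(max(y))
  bestv <- Inf; best <- NA
  for (t in cands) {
    b <- y[y <= t]; f <- y[y > t]
    if (!length(b) || !length(f)) next
    mb <- max(mean(b), 1e-12); mf <- max(mean(f), 1e-12)
    v <- -(sum(b) * log(mb) + sum(f) * log(mf))
    if (v < bestv) { bestv <- v; best <- t }
  }
  best
}

# dense-resampling Sholl oracle: counts strict sign changes of the radial
# distance along polylines sampled every 0.01 um
dense_sholl <- function(tree, step = 1, r_max = NULL) {
  ctr <- tree$soma_center
  dense <- lapply(tree$segments, function(s) {
    pts <- s$pts
    out <- list()
    for (j in seq_len(nrow(pts) - 1)) {
      a <- pts[j, ]; b <- pts[j + 1, ]
      L <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2, ceiling(L / 0.01)))
      out[[j]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                        a[3] + tt * (b[3] - a[3]))
    }
    do.call(rbind, out)
  })
  max_r <- max(vapply(dense, function(p) max(sqrt(rowSums(sweep(p, 2, ctr, "-")^2))),
               numeric(1)))
  if (is.null(r_max)) r_max <- max_r + step
  radii <- seq(step, r_max, by = step)
  counts <- integer(length(radii))
  for (p in dense) {
    rad <- sqrt(rowSums(sweep(p, 2, ctr, "-")^2))
    for (k in seq_along(radii)) {
      s <- sign(rad - radii[k])
      s <- s[s != 0]
      counts[k] <- counts[k] + sum(diff(s) != 0)
    }
  }
  data.frame(radius = radii, intersections = as.integer(counts))
}
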