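#' Morphometrics of one segmented cell
#'
#' Skeletonizes the cell's voxels, classifies skeleton voxels, builds the
#' physical skeleton graph (collapsing the soma region to one node),
#' computes the Sholl profile and its summary, counts detached spheroid-like
#' components, and assembles the per-cell scalar record.
#'
#' @param cell_mask logical 3D array of one cell's voxels.
#' @param soma_row one row of a `soma_set` table (centroid and volume).
#' @param spacing (dz, dy, dx) um.
#' @param config a [pipeline_config()].
#' @return list: `morpho` (one-row data.frame), `graph`, `profile`.
#' @export
measure_cell <- function(cell_mask, soma_row, spacing, config = pipeline_config()) {
  soma_center <- c(soma_row$x, soma_row$y, soma_row$z)
  soma_r <- (3 * soma_row$volume / (4 * pi))^(1 / 3)
  skel <- classify_voxels(skeletonize_cell(cell_mask, spacing))
  graph <- build_graph(skel, soma_center = soma_center,
                       soma_radius = max(soma_r, 1.5),
                       prune_terminal_um = config$prune_terminal_um,
                       merge_junction_um = config$merge_junction_um)
  prof <- sholl_profile(graph, soma_center, step = config$sholl_step)
  summ <- sholl_auc(prof)
  sph <- count_spheroids(cell_mask, spacing, config$spheroid_max_volume,
                         config$spheroid_min_compactness)
  morpho <- data.frame(
    soma_volume = soma_row$volume,
    segment_count = graph$segment_count,
    endpoint_count = sum(graph$nodes$class == "endpoint"),
    junction_count = sum(graph$nodes$class == "junction"),
    component_count = graph$component_count,
    longest_path = graph$longest_path_um,
    sholl_auc = summ$auc,
    max_branches = summ$max_branches,
    critical_radius = summ$critical_radius,
    max_branch_order = graph$max_branch_order,
    spheroid_count = sph)
  list(morpho = morpho, graph = graph, profile = prof)
}

# Detached, compact, small components of the cell mask: candidate
# cytoplasmic spheroids. Compactness = volume over bounding-sphere volume
# (sphericity surrogate that needs no surface mesh).
count_spheroids <- function(cell_mask, spacing, max_volume, min_compactness) {
  dims <- dim(cell_mask)
  lab <- cpp_label3d(as.logical(cell_mask), dims, 26L)
  n <- max(lab)
  if (n <= 1L) return(0L)
  voxvol <- prod(spacing)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  main <- which.max(sizes)
  cnt <- 0L
  nz <- dims[1]; ny <- dims[2]
  for (i in seq_len(n)) {
    if (i == main) next
    vol <- sizes[i] * voxvol
    if (vol > max_volume) next
    vox <- which(lab == i)
    iz <- ((vox - 1L) %% nz) + 1L
    iy <- (((vox - 1L) %/% nz) %% ny) + 1L
    ix <- ((vox - 1L) %/% (nz * ny)) + 1L
    ph <- vox_phys(iz, iy, ix, spacing)
    ctr <- colMeans(ph)
    rmax <- sqrt(max(rowSums(sweep(ph, 2, ctr, "-")^2))) + sqrt(sum(spacing^2)) / 2
    comp <- vol / ((4 / 3) * pi * rmax^3)
    if (comp >= min_compactness) cnt <- cnt + 1L
  }
  cnt
}

#' Activation classification (hypertrophy rule)
#'
#' Operationalizes the visual criterion "enlarged cell body with shortened
#' processes": activated iff soma volume strictly exceeds
#' `soma_volume_threshold` AND the longest path is strictly below
#' `process_length_threshold`. Values exactly at a threshold are not
#' activated. Raising the soma threshold can never increase the activated
#' count (monotone rule).
#'
#' @param cells per-cell morphometrics data.frame (soma_volume,
#'   longest_path).
#' @param soma_volume_threshold um^3 (default 200).
#' @param process_length_threshold um (default 30).
#' @return logical vector.
#' @export
classify_activation <- function(cells, soma_volume_threshold = 200,
                                process_length_threshold = 30) {
  cells$soma_volume > soma_volume_threshold &
    cells$longest_path < process_length_threshold
}

#' Dystrophy classification (at least one feature)
#'
#' Numeric surrogates of the visual dystrophy features: fragmentation iff
#' the cell has more than one connected component; deramification iff the
#' segment count is strictly below `deramification_threshold`; spheroids iff
#' any detached compact spheroid-like component was found. A cell is
#' dystrophic iff at least one feature is present. Gnarling and beading have
#' no measurable surrogate and are not operationalized.
#'
#' @param cells per-cell morphometrics data.frame (component_count,
#'   segment_count, spheroid_count).
#' @param deramification_threshold segment-count cutoff (default 12).
#' @return data.frame: dystrophic flag and comma-separated
#'   `dystrophy_reasons` drawn from fragmentation, deramification,
#'   spheroids.
#' @export
classify_dystrophy <- function(cells, deramification_threshold = 12) {
  frag <- cells$component_count > 1
  deram <- cells$segment_count < deramification_threshold
  sph <- cells$spheroid_count > 0
  reasons <- mapply(function(f, d, s)
    paste(c(if (f) "fragmentation", if (d) "deramification", if (s) "spheroids"),
          collapse = ","),
    frag, deram, sph)
  data.frame(dystrophic = frag | deram | sph, dystrophy_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Percentage of activated microglia per field and per animal
#'
#' Per-field percentage (100 x activated / total) and the per-animal mean
#' over its fields; a warning is raised for animals with fewer than
#' `min_fields` counted fields.
#'
#' @param cells data.frame with columns field_id, animal_id and logical
#'   activated.
#' @param min_fields fields required per animal (default 4).
#' @return list: `fields` (field_id, animal_id, total, activated,
#'   percent_activated), `animals` (animal_id, n_fields, percent_activated).
#' @export
percent_activated <- function(cells, min_fields = 4L) {
  stopifnot(all(c("field_id", "animal_id", "activated") %in% names(cells)))
  if (!nrow(cells)) stop("no cells")
  sp <- split(cells, cells$field_id)
  fields <- do.call(rbind, lapply(sp, function(d) data.frame(
    field_id = d$field_id[1], animal_id = d$animal_id[1],
    total = nrow(d), activated = sum(d$activated),
    percent_activated = 100 * sum(d$activated) / nrow(d),
    stringsAsFactors = FALSE)))
  rownames(fields) <- NULL
  sa <- split(fields, fields$animal_id)
  animals <- do.call(rbind, lapply(sa, function(d) {
    if (nrow(d) < min_fields)
      warning("animal ", d$animal_id[1], " has only ", nrow(d),
              " field(s); at least ", min_fields, " expected")
    data.frame(animal_id = d$animal_id[1], n_fields = nrow(d),
               percent_activated = mean(d$percent_activated),
               stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL
  list(fields = fields, animals = animals)
}
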