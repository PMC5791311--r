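#' Pipeline configuration
#'
#' Builds the full set of tunables for the morphometry pipeline with
#' documented defaults. Unknown names are rejected so typos cannot silently
#' fall back to defaults. All lengths are physical micrometres unless the
#' name says `_px` (pixels of the in-plane grid, as the cited tools take
#' them).
#'
#' @param ... name = value overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{voxel_spacing}{c(dz, dy, dx) um used when a stack carries no
#'     spacing metadata; default c(1.0, 0.3, 0.3).}
#'   \item{clahe_block_radius_px, clahe_max_slope, clahe_bins}{slice-wise
#'     contrast-limited adaptive histogram equalization; radius 63 px,
#'     slope limit 3, 256 bins.}
#'   \item{li_tol, li_max_iter, li_per_slice}{Li minimum-cross-entropy
#'     threshold iteration: convergence tolerance 0.5 gray level, cap 100
#'     iterations, computed once per 3D stack by default.}
#'   \item{opening_radius_px, closing_radius_px}{disk radii (pixels) of the
#'     slice-wise mask simplification; 1 and 1.}
#'   \item{phansalkar_radius_px, phansalkar_k, phansalkar_p, phansalkar_q,
#'     phansalkar_r}{local soma threshold: disk radius 20 px and the
#'     algorithm's published constants k = 0.25, p = 2, q = 10, R = 0.5.}
#'   \item{soma_opening_px}{ball opening applied to the Phansalkar mask
#'     before grouping somata (removes thin processes); 3 px.}
#'   \item{soma_min_volume, soma_max_volume}{soma volume gate, 25-1500 um^3 (brackets the phantom somata after the detection opening).}
#'   \item{cell_min_volume, cell_max_volume}{accepted-cell volume gate,
#'     100-20000 um^3 (brackets the phantom cells, ramified and
#'     deramified).}
#'   \item{fragment_adoption_um}{detached foreground components are assigned
#'     to the nearest watershed basin within this distance, so dystrophic
#'     fragments stay with their cell; 6 um.}
#'   \item{min_object_volume}{foreground components smaller than this
#'     (um^3) are removed as noise specks after mask simplification; 4.}
#'   \item{prune_terminal_um, merge_junction_um}{skeleton-graph cleanup of
#'     voxelization artifacts: terminal spurs shorter than 1 um are pruned
#'     and junction-junction connectors shorter than 1.2 um contracted.}
#'   \item{sholl_step}{radial step of the Sholl envelopes, 1 um.}
#'   \item{soma_volume_threshold, process_length_threshold}{activation rule:
#'     activated iff soma volume > 200 um^3 AND longest path < 30 um
#'     (strict inequalities).}
#'   \item{deramification_threshold}{dystrophy rule: deramified iff segment
#'     count < 12.}
#'   \item{spheroid_max_volume, spheroid_min_compactness}{detached components
#'     count as spheroids when volume <= 65 um^3 and volume over
#'     bounding-sphere volume >= 0.2.}
#'   \item{min_fields_per_animal}{fields required per animal before the
#'     activation percentage is considered complete; 4.}
#'   \item{posthoc}{default multiple-comparison procedure, "holm_sidak"
#'     (alternative "dunn").}
#'   \item{seed}{master seed for every stochastic stage; 1.}
#' }
#'
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    voxel_spacing = c(1.0, 0.3, 0.3),
    clahe_block_radius_px = 63,
    clahe_max_slope = 3,
    clahe_bins = 256,
    li_tol = 0.5,
    li_max_iter = 100L,
    li_per_slice = FALSE,
    opening_radius_px = 1,
    closing_radius_px = 1,
    phansalkar_radius_px = 20L,
    phansalkar_k = 0.25,
    phansalkar_p = 2,
    phansalkar_q = 10,
    phansalkar_r = 0.5,
    soma_opening_px = 3,
    soma_min_volume = 25,
    soma_max_volume = 1500,
    cell_min_volume = 100,
    cell_max_volume = 20000,
    fragment_adoption_um = 6,
    min_object_volume = 4,
    prune_terminal_um = 1.0,
    merge_junction_um = 1.2,
    sholl_step = 1,
    soma_volume_threshold = 200,
    process_length_threshold = 30,
    deramification_threshold = 12,
    spheroid_max_volume = 65,
    spheroid_min_compactness = 0.2,
    min_fields_per_animal = 4L,
    posthoc = "holm_sidak",
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]])) over <- over[[1]]
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("pipeline_config() overrides must be named")
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  stopifnot(all(defaults$voxel_spacing > 0), defaults$sholl_step > 0)
  if (!defaults$posthoc %in% c("holm_sidak", "dunn"))
    stop("posthoc must be 'holm_sidak' or 'dunn'")
  structure(defaults, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("migmorph pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

# Stable hash of a config (md5 of its canonical JSON), used in provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
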