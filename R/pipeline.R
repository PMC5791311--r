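#' Run the full morphometry pipeline on one stack
#'
#' Segmentation chain ([segment_stack()]), then for every accepted cell:
#' skeletonization, graph construction, Sholl analysis and morphometric
#' classification.
#'
#' @param stack an [image_stack()] or TIFF path.
#' @param config a [pipeline_config()].
#' @param field_id identifier attached to the per-cell rows.
#' @return object of class `pipeline_result`: `cells` (per-cell
#'   morphometrics with classification flags), `graphs`, `profiles`,
#'   `segmentation` (the [segment_stack()] output).
#' @export
run_pipeline <- function(stack, config = pipeline_config(), field_id = "field1") {
  if (is.character(stack)) stack <- read_stack(stack, config = config)
  seg <- segment_stack(stack, config)
  cells <- seg$labels$cells
  acc <- cells$id[cells$accepted]
  rows <- list(); graphs <- list(); profiles <- list()
  for (i in seq_along(acc)) {
    id <- acc[i]
    cm <- seg$labels$labels == id
    dim(cm) <- dim(seg$labels$labels)
    soma_id <- which(vapply(seg$somata$voxels,
                            function(sv) any(seg$labels$labels[sv] == id), logical(1)))[1]
    soma_row <- seg$somata$somata[soma_id, ]
    mc <- measure_cell(cm, soma_row, stack$spacing, config)
    mc$morpho$cell_id <- paste0(field_id, "_cell", id)
    mc$morpho$field_id <- field_id
    rows[[i]] <- mc$morpho
    graphs[[i]] <- mc$graph
    profiles[[i]] <- mc$profile
  }
  cells_df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(cells_df)) {
    cells_df$activated <- classify_activation(cells_df,
                                              config$soma_volume_threshold,
                                              config$process_length_threshold)
    dys <- classify_dystrophy(cells_df, config$deramification_threshold)
    cells_df <- cbind(cells_df, dys)
  }
  structure(list(cells = cells_df, graphs = graphs, profiles = profiles,
                 segmentation = seg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  n <- if (is.null(x$cells)) 0L else nrow(x$cells)
  cat(sprintf("pipeline_result: %d accepted cell(s)\n", n))
  if (n) print(x$cells[, c("cell_id", "segment_count", "sholl_auc",
                           "max_branches", "longest_path", "activated",
                           "dystrophic")])
  invisible(x)
}

#' Analyze a phantom (or real) cohort end-to-end
#'
#' Runs [run_pipeline()] on every stack of a manifest (as written by
#' [generate_cohort()]) or an in-memory cohort, pools the accepted cells
#' per condition and computes the group comparison.
#'
#' @param cohort manifest data.frame with columns condition, sample_id,
#'   cell_id, stack (TIFF paths), or the list returned by
#'   `generate_cohort(write_stacks = FALSE)`.
#' @param config a [pipeline_config()].
#' @param metrics metrics forwarded to [group_compare()].
#' @return list: `pooled` (per-cell long table), `stats`
#'   (`group_comparison`), `results` (per-field `pipeline_result`s).
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           metrics = c("segment_count", "sholl_auc",
                                       "max_branches", "longest_path")) {
  in_memory <- is.list(cohort) && !is.data.frame(cohort)
  manifest <- if (in_memory) cohort$manifest else cohort
  rows <- list(); results <- list()
  for (i in seq_len(nrow(manifest))) {
    stack <- if (in_memory) cohort$cells[[i]]$stack
             else suppressMessages(read_stack(manifest$stack[i], config = config))
    res <- run_pipeline(stack, config, field_id = manifest$cell_id[i])
    results[[i]] <- res
    if (is.null(res$cells) || !nrow(res$cells)) next
    # single-cell fields: keep the largest accepted cell for this record
    cell <- res$cells[which.max(res$cells$segment_count), , drop = FALSE]
    cell$condition <- manifest$condition[i]
    cell$sample_id <- manifest$sample_id[i]
    cell$cell_id <- manifest$cell_id[i]
    rows[[length(rows) + 1L]] <- cell
  }
  if (!length(rows)) stop("no accepted cells in the cohort")
  pooled <- pool_cells(do.call(rbind, rows))
  stats <- group_compare(pooled, metrics, posthoc = config$posthoc)
  list(pooled = pooled, stats = stats, results = results)
}
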