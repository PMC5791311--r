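#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group comparison with mid-rank ties and the standard tie
#' correction; the p-value uses the chi-square approximation with k - 1
#' degrees of freedom regardless of group size. When every observation is
#' identical the test is degenerate and returns H = 0, p = 1 with a flag.
#'
#' @param values numeric vector of pooled per-cell values.
#' @param groups factor/character of condition labels (same length).
#' @return list of class `kw_test`: `H`, `df`, `p`, `n` (per-group sizes),
#'   `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  if (length(unique(values)) == 1L) {
    return(structure(list(H = 0, df = nlevels(groups) - 1L, p = 1,
                          n = as.integer(table(groups)), degenerate = TRUE),
                     class = "kw_test"))
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, n = as.integer(table(groups)),
                 degenerate = FALSE),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %s)%s\n",
              x$H, x$df, x$p, paste(x$n, collapse = "/"),
              if (x$degenerate) " [degenerate: all values identical]" else ""))
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m p-values ascending, sets adjusted_(i) = max over j <= i of
#' 1 - (1 - p_(j))^(m - j + 1), clips at 1, and maps the values back to the
#' input order; monotone non-decreasing in the sorted sequence and
#' invariant to input order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in input order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Dunn's pairwise post-hoc comparisons
#'
#' Dunn z-statistics on the pooled mid-ranks with tie correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups; two-sided normal
#' p-values, adjusted per `adjust`: "holm_sidak" (step-down, the default
#' used for the morphometric comparisons), "bonferroni" (classic Dunn
#' correction) or "none".
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param adjust adjustment method.
#' @return data.frame: group1, group2, z, p_raw, p_adj, method.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("holm_sidak", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- switch(adjust,
                  holm_sidak = holm_sidak_adjust(p_raw),
                  bonferroni = pmin(1, p_raw * length(p_raw)),
                  none = p_raw)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_raw = p_raw, p_adj = p_adj,
             method = if (adjust == "none") "dunn" else adjust,
             stringsAsFactors = FALSE)
}

#' Per-group mean and SEM
#'
#' @param values,groups as in [kruskal_wallis()].
#' @return data.frame: group, n, mean, sem (NA with a warning for n = 1).
#' @export
summarize_groups <- function(values, groups) {
  groups <- factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    sem <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else {
      warning("group ", g, " has n = 1; SEM undefined")
      NA_real_
    }
    data.frame(group = g, n = length(v), mean = mean(v), sem = sem,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled nonparametric group comparison of per-cell morphometrics
#'
#' For each metric: per-condition n / mean / SEM, the Kruskal-Wallis
#' omnibus, and the pairwise post-hoc table (Dunn z statistics with
#' Holm-Sidak step-down adjustment by default, or classic Bonferroni-Dunn).
#'
#' @param pooled long-format per-cell table from [pool_cells()].
#' @param metrics metric column names (default segment_count, sholl_auc,
#'   max_branches, longest_path).
#' @param posthoc "holm_sidak" or "dunn".
#' @return object of class `group_comparison`: named list per metric with
#'   `summary`, `omnibus`, `pairwise`.
#' @export
group_compare <- function(pooled,
                          metrics = c("segment_count", "sholl_auc",
                                      "max_branches", "longest_path"),
                          posthoc = c("holm_sidak", "dunn")) {
  posthoc <- match.arg(posthoc)
  metrics <- intersect(metrics, names(pooled))
  if (!length(metrics)) stop("none of the requested metrics are in the table")
  res <- lapply(metrics, function(m) {
    v <- pooled[[m]]
    g <- pooled$condition
    list(metric = m,
         summary = summarize_groups(v, g),
         omnibus = kruskal_wallis(v, g),
         pairwise = dunn_posthoc(v, g, adjust = if (posthoc == "dunn") "bonferroni"
                                               else "holm_sidak"))
  })
  names(res) <- metrics
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (m in names(x)) {
    cat("==", m, "==\n")
    s <- x[[m]]$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-14s n=%2d  %.1f +- %.1f (SEM)\n", s$group[i], s$n[i],
                  s$mean[i], s$sem[i]))
    print(x[[m]]$omnibus)
    pw <- x[[m]]$pairwise
    for (i in seq_len(nrow(pw)))
      cat(sprintf("  %s vs %s: z = %.2f, p = %.4g (adj %.4g, %s)\n",
                  pw$group1[i], pw$group2[i], pw$z[i], pw$p_raw[i], pw$p_adj[i],
                  pw$method[i]))
  }
  invisible(x)
}

#' Write a group comparison as a tidy CSV (one row per metric x pair)
#' @param comparison a `group_comparison`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(comparison, path) {
  rows <- do.call(rbind, lapply(names(comparison), function(m) {
    pw <- comparison[[m]]$pairwise
    pw$metric <- m
    pw$H <- comparison[[m]]$omnibus$H
    pw$omnibus_p <- comparison[[m]]$omnibus$p
    pw
  }))
  rows <- rows[, c("metric", "H", "omnibus_p", "group1", "group2", "z",
                   "p_raw", "p_adj", "method")]
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
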