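#' Significance stars for a p-value
#'
#' Convention: `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05,
#' `NS` otherwise.
#'
#' @param p p-value(s) in [0, 1].
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (!is.finite(x)) return(NA_character_)
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*" else "NS"
  }, character(1))
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-based two-sample comparison used for all per-cell ensemble
#' statistics. The exact null distribution is used when
#' `n_a * n_b <= exact_limit` and no ties are present; otherwise the normal
#' approximation with tie and continuity correction. Groups in which every
#' value is identical across both samples give p = 1.
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @param exact_limit Switch-over product of group sizes (default 1e4).
#' @return List with `U` (the Mann-Whitney statistic for `a` vs `b`),
#'   `p` (two-sided), `stars` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_limit = 1e4) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 finite values")
  }
  if (length(unique(c(a, b))) == 1) {
    return(list(
      U = length(a) * length(b) / 2, p = 1, stars = "NS",
      method = "degenerate (all values tied)"
    ))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= exact_limit
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(
    U = unname(wt$statistic), p = wt$p.value, stars = p_stars(wt$p.value),
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Summarise per-cell measurements into condition-level medians
#'
#' Aggregates a per-cell results table by the grouping keys and reports the
#' median together with two robust dispersions (median absolute deviation
#' and interquartile range) for each value column. Groups smaller than
#' `min_n` are flagged; empty groups are dropped with a warning.
#'
#' @param cells Data frame of per-cell measurements.
#' @param group_keys Character vector of grouping columns present in
#'   `cells` (default condition, compartment, channel).
#' @param value_cols Numeric columns to summarise (default `D` and `c`).
#' @param min_n Groups below this size get `flag_small = TRUE` (default 10).
#' @return Data frame with one row per group: the keys, `n`, and per value
#'   column `median_*`, `mad_*`, `iqr_*`.
#' @export
summarize_cells <- function(cells,
                            group_keys = c("condition", "compartment", "channel"),
                            value_cols = c("D", "c"), min_n = 10) {
  stopifnot(is.data.frame(cells))
  group_keys <- intersect(group_keys, names(cells))
  if (length(group_keys) == 0) stop("no grouping columns found")
  if (nrow(cells) == 0) stop("empty measurement table")
  for (k in group_keys) {
    x <- as.character(cells[[k]])
    x[is.na(x)] <- "unspecified"
    cells[[k]] <- x
  }
  key <- interaction(cells[group_keys], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    sub <- cells[key == lv, , drop = FALSE]
    keep <- rep(TRUE, nrow(sub))
    if ("qc_pass" %in% names(sub)) keep <- sub$qc_pass %in% TRUE
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("group with no usable cells omitted: ", gsub("\r", "/", lv))
      return(NULL)
    }
    out <- sub[1, group_keys, drop = FALSE]
    out$n <- nrow(sub)
    for (v in value_cols) {
      x <- sub[[v]]
      x <- x[is.finite(x)]
      out[[paste0("median_", v)]] <- median(x)
      out[[paste0("mad_", v)]] <- if (length(x) > 1) mad(x) else 0
      out[[paste0("iqr_", v)]] <- if (length(x) > 1) IQR(x) else 0
    }
    out$flag_small <- out$n < min_n
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no non-empty groups")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Mann-Whitney comparisons between conditions
#'
#' Runs [mann_whitney()] on every pair of conditions, separately within
#' each combination of the `within` columns.
#'
#' @param cells Per-cell results table.
#' @param value_col Column to compare (default `"D"`).
#' @param group_key Column defining the groups (default `"condition"`).
#' @param within Columns held fixed within a comparison (intersected with
#'   the available columns).
#' @return Data frame with `group_a`, `group_b`, the `within` labels, `n_a`,
#'   `n_b`, `U`, `p`, `stars`.
#' @export
compare_conditions <- function(cells, value_col = "D",
                               group_key = "condition",
                               within = c("compartment", "channel")) {
  stopifnot(is.data.frame(cells), group_key %in% names(cells))
  within <- intersect(within, names(cells))
  if ("qc_pass" %in% names(cells)) cells <- cells[cells$qc_pass %in% TRUE, ]
  strata <- if (length(within)) {
    interaction(cells[within], drop = TRUE, sep = "\r")
  } else {
    factor(rep("all", nrow(cells)))
  }
  out <- list()
  for (st in levels(strata)) {
    sub <- cells[strata == st, , drop = FALSE]
    groups <- unique(as.character(sub[[group_key]]))
    if (length(groups) < 2) next
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        xa <- sub[[value_col]][sub[[group_key]] == groups[i]]
        xb <- sub[[value_col]][sub[[group_key]] == groups[j]]
        xa <- xa[is.finite(xa)]
        xb <- xb[is.finite(xb)]
        if (length(xa) < 3 || length(xb) < 3) next
        mw <- mann_whitney(xa, xb)
        row <- data.frame(
          group_a = groups[i], group_b = groups[j],
          n_a = length(xa), n_b = length(xb),
          U = mw$U, p = mw$p, stars = mw$stars,
          stringsAsFactors = FALSE
        )
        if (length(within)) {
          labels <- strsplit(st, "\r", fixed = TRUE)[[1]]
          for (k in seq_along(within)) row[[within[k]]] <- labels[k]
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample a synthetic per-cell ensemble
#'
#' Draws per-cell values from a lognormal distribution with the given
#' median and coefficient of variation, emulating the cell-to-cell scatter
#' of single-cell FCS ensembles. Used for the operating characteristics of
#' the rank statistics (type-I error, power), where the trace-level
#' generator would be needlessly expensive.
#'
#' @param n Number of cells.
#' @param median_value Ensemble median of the quantity.
#' @param cv Coefficient of variation of the cell-to-cell scatter.
#' @return Numeric vector of length `n`.
#' @export
sample_ensemble <- function(n, median_value, cv = 0.3) {
  stopifnot(n >= 1, median_value > 0, cv >= 0)
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(median_value), sdlog = sdlog)
}
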