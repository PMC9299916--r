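#' Per-species MoA counts
#'
#' How many MoAs each species is resistant to (its column sum), with the
#' species' growth form — the per-species distribution behind "median number
#' of MoAs" summaries and the monocot/dicot comparison.
#'
#' @param x an [incidence_matrix].
#' @return data.frame with columns `species`, `growth_form`, `n_moas`,
#'   sorted by species.
#' @seealso [growth_form_summary()], [mood_median_test()]
#' @export
species_moa_counts <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  gf <- growth_forms(x)
  out <- data.frame(species = colnames(x),
                    growth_form = unname(gf[colnames(x)]),
                    n_moas = as.integer(colSums(x)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize MoA counts by growth form
#'
#' @param counts output of [species_moa_counts()].
#' @return data.frame with one row per growth form (monocot, dicot,
#'   unknown — empty strata included with `n = 0`): `n`, `median_moas`,
#'   `max_moas`.
#' @export
growth_form_summary <- function(counts) {
  gf <- factor(counts$growth_form, levels = .growth_forms)
  split_counts <- split(counts$n_moas, gf)
  data.frame(
    growth_form = .growth_forms,
    n = vapply(split_counts, length, integer(1)),
    median_moas = vapply(split_counts, function(v)
      if (length(v)) median(v) else NA_real_, numeric(1)),
    max_moas = vapply(split_counts, function(v)
      if (length(v)) max(v) else NA_integer_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Mood's median test
#'
#' Tests whether two or more groups share a common median. The grand median
#' of the pooled values is computed; each group is split into values above
#' versus at-or-below it (values equal to the grand median count as "at or
#' below" — the tie convention is configurable); and a Pearson chi-square
#' statistic is computed on the resulting 2 x g contingency table, with
#' g - 1 degrees of freedom and an upper-tail P value.
#'
#' @param groups named or unnamed list of two or more non-empty numeric
#'   vectors.
#' @param ties how values equal to the grand median are classified:
#'   `"below"` (default) or `"above"`.
#' @param correct apply the Yates continuity correction (2 x 2 tables
#'   only). Default `FALSE`.
#' @return a [stat_result()] with the chi-square `statistic`, `df`,
#'   `p_value`, `n` (pooled size), and the contingency `table`.
#' @examples
#' mood_median_test(list(dicot = c(2, 3, 3, 5), monocot = c(2, 2, 4, 6)))
#' @export
mood_median_test <- function(groups, ties = c("below", "above"),
                             correct = FALSE) {
  ties <- match.arg(ties)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two numeric vectors",
         call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate test: all pooled values are equal", call. = FALSE)
  }
  med <- median(pooled)
  above <- vapply(groups, function(v) {
    if (ties == "below") sum(v > med) else sum(v >= med)
  }, numeric(1))
  tab <- rbind(above = above, at_or_below = sizes - above)
  colnames(tab) <- if (is.null(names(groups)))
    paste0("group", seq_along(groups)) else names(groups)

  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_tab == 0)) {
    stop("degenerate contingency table (a margin is zero)", call. = FALSE)
  }
  dev <- abs(tab - exp_tab)
  if (correct && all(dim(tab) == 2L)) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / exp_tab)
  df <- length(groups) - 1L
  stat_result(estimate = med, statistic = statistic, df = df,
              p_value = pchisq(statistic, df, lower.tail = FALSE),
              n = length(pooled), table = tab)
}

#' Per-MoA resistance summary
#'
#' For each MoA: the number of species with any recorded resistance to it
#' (`n_resistant`, its prevalence), the number of those that are
#' multi-resistant, i.e. resistant to `multi_threshold` or more MoAs
#' (`n_multi`), and the percentage `pct_multi = 100 * n_multi / n_resistant`.
#'
#' Compute this on the *unfiltered* (but merged) matrix: prevalence counts
#' all resistant species, while the multi-resistant numerator is defined by
#' the species' total MoA count in that same matrix.
#'
#' @param x an [incidence_matrix].
#' @param multi_threshold minimum MoA count that makes a species
#'   multi-resistant (default 2).
#' @return data.frame with columns `moa`, `n_resistant`, `n_multi`,
#'   `pct_multi`.
#' @export
moa_summary <- function(x, multi_threshold = 2L) {
  stopifnot(inherits(x, "incidence_matrix"))
  m <- unclass(x)
  multi <- colSums(m) >= multi_threshold
  data.frame(moa = rownames(m),
             n_resistant = as.integer(rowSums(m)),
             n_multi = as.integer(rowSums(m[, multi, drop = FALSE])),
             pct_multi = 100 * rowSums(m[, multi, drop = FALSE]) / rowSums(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prevalence versus multi-resistance correlation
#'
#' Pearson correlation between the number of resistant species per MoA and
#' the percentage of those species that are multi-resistant, with
#' df = number of MoAs - 2 and a two-sided P value from the t transform.
#' A negative estimate means the MoAs with most resistant species are *not*
#' disproportionately prone to multi-resistance.
#'
#' @param summary data.frame from [moa_summary()] (columns `n_resistant`,
#'   `pct_multi`), at least 3 rows.
#' @return a [stat_result()] (`estimate` = r, plus `r_squared`).
#' @export
prevalence_vs_multiresistance <- function(summary) {
  need <- c("n_resistant", "pct_multi")
  if (!all(need %in% names(summary))) {
    stop("summary needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(summary) < 3L) stop("need at least 3 MoAs", call. = FALSE)
  pearson_result(summary$n_resistant, summary$pct_multi)
}
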