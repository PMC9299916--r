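#' MoA merge map
#'
#' Mapping from source HRAC group codes to merged codes. The default merges
#' the three carotenoid-biosynthesis-pathway groups (HRAC 12, 13 and 27) into
#' a single MoA, as is done when too few resistant species support the groups
#' individually; all other codes map to themselves.
#'
#' @param mapping named character vector, `names` = source codes,
#'   values = target codes. Codes not named map to themselves.
#' @return object of class `merge_map`.
#' @examples
#' merge_map()  # the carotenoid default
#' merge_map(c("12" = "carotenoid", "13" = "carotenoid", "27" = "carotenoid"))
#' @export
merge_map <- function(mapping = c("12" = "12+13+27",
                                  "13" = "12+13+27",
                                  "27" = "12+13+27")) {
  mapping <- vapply(mapping, as.character, character(1))
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop("`mapping` must be a named vector of source -> target codes",
         call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    stop("each source code may map to exactly one target", call. = FALSE)
  }
  structure(mapping, class = "merge_map")
}

apply_merge_map <- function(map, codes) {
  out <- as.character(codes)
  hit <- out %in% names(map)
  out[hit] <- unclass(map)[out[hit]]
  out
}

#' Merge MoA groups in an incidence matrix
#'
#' Rows whose codes share a merge target are combined by logical OR: the
#' merged MoA is resistant-in a species if any of its source groups was. A
#' species' support (set of distinct MoAs) can only shrink or stay equal,
#' never grow.
#'
#' @param x an [incidence_matrix].
#' @param map a [merge_map]; default merges HRAC 12/13/27.
#' @return an [incidence_matrix] with merged rows, rows re-sorted
#'   lexicographically.
#' @export
merge_moa_groups <- function(x, map = merge_map()) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (!inherits(map, "merge_map")) map <- merge_map(map)
  targets <- apply_merge_map(map, rownames(x))
  merged <- rowsum(unclass(x), group = targets)
  merged <- (merged > 0L) + 0L
  merged <- merged[sort_c(rownames(merged)), , drop = FALSE]
  incidence_matrix(merged, growth_form = growth_forms(x))
}

#' Filter policy for matrix consolidation
#'
#' @param min_moas_per_species keep only species resistant to at least this
#'   many distinct MoAs (default 2: multi-resistant species).
#' @param min_species_per_moa keep only MoAs with at least this many
#'   resistant species among the retained species (default 10).
#' @param iterate_to_fixed_point if `TRUE`, repeat both filters until the
#'   matrix stops changing, so the output satisfies both thresholds
#'   simultaneously. Default `FALSE`: one species pass then one MoA pass, in
#'   that order.
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(min_moas_per_species = 2L,
                          min_species_per_moa = 10L,
                          iterate_to_fixed_point = FALSE) {
  if (min_moas_per_species < 1L || min_species_per_moa < 1L) {
    stop("filter thresholds must be >= 1", call. = FALSE)
  }
  structure(list(min_moas_per_species = as.integer(min_moas_per_species),
                 min_species_per_moa = as.integer(min_species_per_moa),
                 iterate_to_fixed_point = isTRUE(iterate_to_fixed_point)),
            class = "filter_policy")
}

#' Consolidate an incidence matrix to multi-resistant species and
#' well-represented MoAs
#'
#' Drops species columns whose MoA count falls below
#' `min_moas_per_species`, then MoA rows whose species count (within the
#' retained species) falls below `min_species_per_moa`. In single-pass mode
#' (the default) each filter runs once, in that order; removing a MoA can
#' then leave a species below the species threshold, which
#' `iterate_to_fixed_point = TRUE` resolves by repeating both passes until
#' convergence.
#'
#' @param x an [incidence_matrix] (typically after [merge_moa_groups()]).
#' @param policy a [filter_policy].
#' @return the filtered [incidence_matrix], with a `filter_report`
#'   attribute: a list with elements `dropped_species`, `dropped_moas`
#'   (character vectors, in drop order), `passes` (number of filter passes
#'   executed) and `dims` (matrix dimension before and after).
#' @export
filter_matrix <- function(x, policy = filter_policy()) {
  stopifnot(inherits(x, "incidence_matrix"), inherits(policy, "filter_policy"))
  dropped_species <- character(0)
  dropped_moas <- character(0)
  dims_before <- dim(x)
  cells <- unclass(x)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    changed <- FALSE
    low_sp <- colSums(cells) < policy$min_moas_per_species
    if (any(low_sp)) {
      dropped_species <- c(dropped_species, colnames(cells)[low_sp])
      cells <- cells[, !low_sp, drop = FALSE]
      changed <- TRUE
    }
    if (ncol(cells) == 0L) {
      stop(sprintf(
        "all species eliminated by min_moas_per_species = %d",
        policy$min_moas_per_species), call. = FALSE)
    }
    low_moa <- rowSums(cells) < policy$min_species_per_moa
    if (any(low_moa)) {
      dropped_moas <- c(dropped_moas, rownames(cells)[low_moa])
      cells <- cells[!low_moa, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(cells) == 0L) {
      stop(sprintf(
        "all MoAs eliminated by min_species_per_moa = %d",
        policy$min_species_per_moa), call. = FALSE)
    }
    if (!policy$iterate_to_fixed_point || !changed) break
    if (policy$iterate_to_fixed_point && !any(colSums(cells) <
        policy$min_moas_per_species)) break
  }
  out <- incidence_matrix(cells, growth_form = growth_forms(x))
  attr(out, "filter_report") <- list(
    dropped_species = dropped_species,
    dropped_moas = dropped_moas,
    passes = passes,
    dims = list(before = dims_before, after = dim(cells)))
  out
}

#' Retrieve the filter report from a consolidated matrix
#'
#' @param x an [incidence_matrix] returned by [filter_matrix()].
#' @return the `filter_report` list, or `NULL` if `x` was never filtered.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Serialize a filter report to JSON
#'
#' @param report a filter report (see [filter_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(dropped_species = report$dropped_species,
         dropped_moas = report$dropped_moas,
         passes = report$passes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
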