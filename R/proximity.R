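#' Jaccard similarity between two species sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}. Chosen for asymmetric binary
#' data: species absent from both sets (joint absences) carry no information
#' about the relatedness of two MoAs and never influence the value, while
#' matches and mismatches among the present species are weighted equally.
#'
#' @param set_a,set_b character vectors of species identifiers; both must be
#'   non-empty (the similarity of an empty resistance profile is undefined).
#' @return similarity in \[0, 1\].
#' @examples
#' jaccard_pair(c("s1", "s2", "s3"), c("s2", "s3", "s4"))  # 2/4 = 0.5
#' @export
jaccard_pair <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("Jaccard similarity is undefined for an empty species set",
         call. = FALSE)
  }
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' Symmetric MoA-by-MoA Jaccard proximity matrix
#'
#' @param values symmetric numeric matrix with values in \[0, 1\], unit
#'   diagonal, and identical row/column MoA labels.
#' @param moa_names optional named character vector of descriptive MoA names
#'   (e.g. "ALS inhibitors"), names = MoA codes.
#' @return object of class `proximity_matrix`.
#' @export
proximity_matrix_from_values <- function(values, moa_names = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values) || nrow(values) < 2L)
    stop("`values` must be a square matrix of dimension >= 2", call. = FALSE)
  if (is.null(rownames(values))) stop("MoA labels required", call. = FALSE)
  if (!isTRUE(all.equal(values, t(values), tolerance = 0)))
    stop("proximity matrix must be exactly symmetric", call. = FALSE)
  if (any(values < 0 | values > 1)) stop("similarities must lie in [0, 1]",
                                         call. = FALSE)
  if (any(diag(values) != 1)) stop("diagonal must equal 1", call. = FALSE)
  colnames(values) <- rownames(values)
  structure(values, moa_names = moa_names,
            class = c("proximity_matrix", "matrix"))
}

#' @export
print.proximity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("proximity_matrix: %d MoAs (Jaccard similarity)\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Compute the Jaccard proximity matrix of an incidence matrix
#'
#' Entry (i, j) is the Jaccard similarity of the resistant-species sets of
#' MoAs i and j; the diagonal is 1 by convention.
#'
#' @param x an [incidence_matrix] with at least 2 MoA rows, none empty.
#' @return a [proximity_matrix_from_values()] object carrying the same MoA
#'   order as `x`.
#' @export
proximity_matrix <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (nrow(x) < 2L) stop("need at least 2 MoAs", call. = FALSE)
  if (any(rowSums(x) == 0L)) {
    stop("every MoA row must have at least one resistant species",
         call. = FALSE)
  }
  m <- unclass(x)
  inter <- tcrossprod(m)                   # |A n B|
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, `+`) - inter  # |A u B|
  s <- inter / uni
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  proximity_matrix_from_values(s)
}

#' Jaccard distance matrix from a proximity matrix
#'
#' The complement d = 1 - s (the Jaccard distance, a metric), the
#' dissimilarity fed to the clustering stage. Zero diagonal, symmetric.
#'
#' @param prox a proximity matrix.
#' @return base `matrix` of distances with the same labels.
#' @export
to_distance <- function(prox) {
  stopifnot(inherits(prox, "proximity_matrix"))
  d <- 1 - unclass(prox)
  diag(d) <- 0
  d
}

#' Write / read a labelled proximity (or distance) matrix CSV
#'
#' First column `moa` = MoA code, remaining columns named by MoA code.
#'
#' @param prox a `proximity_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `proximity_matrix` (reader).
#' @export
write_proximity_csv <- function(prox, path) {
  df <- data.frame(moa = rownames(prox), unclass(prox), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_proximity_csv
#' @export
read_proximity_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "moa"), drop = FALSE])
  rownames(vals) <- as.character(df$moa)
  proximity_matrix_from_values(vals)
}

#' The published ten-MoA proximity matrix
#'
#' Loads the package's read-only fixture: the printed Jaccard proximity
#' matrix between the ten herbicide MoAs retained after consolidation of the
#' global resistance database (multi-resistant species only, MoAs with ten
#' or more resistant species, carotenoid-pathway groups 12/13/27 merged).
#' Rows and columns are labelled by HRAC group code; descriptive names are
#' attached as the `moa_names` attribute.
#'
#' The underlying 101-species matrix is not redistributable (it derives from
#' a dated snapshot of a live database), so this 10 x 10 summary is the
#' canonical entry point for reproducing the published clustering.
#'
#' @return a `proximity_matrix` of dimension 10.
#' @examples
#' prox <- table1_proximity()
#' prox["2", "5"]  # ALS vs PSII inhibitors: 0.526
#' @export
table1_proximity <- function() {
  path <- system.file("extdata", "table1_proximity.csv",
                      package = "moaclust", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  codes <- as.character(df$hrac)
  vals <- as.matrix(df[, codes, drop = FALSE])
  rownames(vals) <- codes
  proximity_matrix_from_values(vals,
                               moa_names = setNames(df$moa, codes))
}
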