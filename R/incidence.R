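#' Binary MoA-by-species incidence matrix
#'
#' The central object of the pipeline: a binary matrix with herbicide modes
#' of action (MoAs, HRAC group codes) as rows and weed species as columns.
#' A cell of 1 records that resistance of that species to that MoA has been
#' reported somewhere; case counts are deliberately absent — the matrix
#' captures the potential for resistance, not its frequency.
#'
#' @param cells numeric or logical matrix of 0/1 with unique, non-empty
#'   rownames (MoA codes) and colnames (species).
#' @param growth_form optional named character vector mapping species to
#'   `"monocot"`, `"dicot"` or `"unknown"`. Species missing from the map are
#'   set to `"unknown"`.
#' @return An object of class `incidence_matrix`: the 0/1 integer matrix with
#'   a `growth_form` attribute.
#' @examples
#' m <- incidence_matrix(
#'   matrix(c(1, 1, 0, 1), 2, 2,
#'          dimnames = list(c("2", "5"), c("Lolium rigidum", "Poa annua"))),
#'   growth_form = c("Lolium rigidum" = "monocot", "Poa annua" = "monocot"))
#' moa_ids(m)
#' @export
incidence_matrix <- function(cells, growth_form = NULL) {
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  if (is.logical(cells)) cells[] <- as.integer(cells)
  if (!all(cells %in% c(0, 1))) {
    stop("incidence matrix cells must all be 0 or 1", call. = FALSE)
  }
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    stop("incidence matrix needs MoA rownames and species colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(cells)) || anyDuplicated(colnames(cells))) {
    stop("row (MoA) and column (species) labels must be unique",
         call. = FALSE)
  }
  if (any(!nzchar(rownames(cells))) || any(!nzchar(colnames(cells)))) {
    stop("empty MoA or species labels are not allowed", call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  gf <- rep("unknown", ncol(cells))
  names(gf) <- colnames(cells)
  if (!is.null(growth_form)) {
    growth_form <- normalize_growth_form(growth_form)
    keep <- intersect(names(growth_form), colnames(cells))
    gf[keep] <- growth_form[keep]
  }
  structure(cells, growth_form = gf, class = c("incidence_matrix", "matrix"))
}

# canonical growth-form levels; anything else maps to unknown (with warning
# at the ingest boundary, silently elsewhere)
.growth_forms <- c("monocot", "dicot", "unknown")

normalize_growth_form <- function(x, warn = FALSE) {
  out <- tolower(trimws(as.character(x)))
  bad <- !(out %in% .growth_forms)
  if (any(bad)) {
    if (warn) {
      warning(sprintf("unrecognized growth form(s) %s mapped to 'unknown'",
                      paste(sQuote(unique(out[bad])), collapse = ", ")),
              call. = FALSE)
    }
    out[bad] <- "unknown"
  }
  names(out) <- names(x)
  out
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d MoAs x %d species (%d resistance cells)\n",
              nrow(x), ncol(x), sum(x)))
  gf <- table(factor(attr(x, "growth_form"), levels = .growth_forms))
  cat("growth forms:", paste(names(gf), gf, sep = "=", collapse = ", "), "\n")
  print(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE])
  if (ncol(x) > 8L) cat(sprintf("... %d more species columns\n", ncol(x) - 8L))
  invisible(x)
}

#' @rdname incidence_matrix
#' @param x an `incidence_matrix`.
#' @export
moa_ids <- function(x) rownames(x)

#' @rdname incidence_matrix
#' @export
species_ids <- function(x) colnames(x)

#' @rdname incidence_matrix
#' @export
growth_forms <- function(x) attr(x, "growth_form")

#' Species sets per MoA
#'
#' @param x an `incidence_matrix`.
#' @return Named list: for each MoA, the character vector of species with a
#'   recorded resistance to it.
#' @keywords internal
moa_species_sets <- function(x) {
  lapply(setNames(rownames(x), rownames(x)),
         function(m) colnames(x)[x[m, ] == 1L])
}

#' Convert resistance records to an incidence matrix
#'
#' Each distinct (species, MoA) pair becomes a 1-cell; duplicates collapse.
#' Row and column labels are sorted lexicographically (C collation) so the
#' construction is invariant to record order and reproducible across runs.
#'
#' @param records data.frame of validated records as returned by
#'   [read_records()], with columns `species`, `growth_form`, `moa_group`.
#' @return An [incidence_matrix].
#' @seealso [matrix_to_records()] for the inverse.
#' @export
records_to_matrix <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0L) stop("no records to convert", call. = FALSE)
  moas <- sort_c(unique(records$moa_group))
  species <- sort_c(unique(records$species))
  cells <- matrix(0L, length(moas), length(species),
                  dimnames = list(moas, species))
  cells[cbind(match(records$moa_group, moas),
              match(records$species, species))] <- 1L
  gf <- tapply(records$growth_form, records$species, function(v) {
    v <- unique(v[v != "unknown"])
    if (length(v) == 1L) v else if (length(v) == 0L) "unknown" else "unknown"
  })
  incidence_matrix(cells, growth_form = setNames(as.character(gf), names(gf)))
}

#' Convert an incidence matrix back to a record table
#'
#' Inverse of [records_to_matrix()] on deduplicated record sets: one row per
#' 1-cell, carrying the species' growth form.
#'
#' @param x an [incidence_matrix].
#' @return data.frame with columns `species`, `growth_form`, `moa_group`.
#' @export
matrix_to_records <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  idx <- which(x == 1L, arr.ind = TRUE)
  gf <- growth_forms(x)
  out <- data.frame(
    species = colnames(x)[idx[, "col"]],
    growth_form = unname(gf[colnames(x)[idx[, "col"]]]),
    moa_group = rownames(x)[idx[, "row"]],
    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$moa_group, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# locale-independent sort, so label order (and thus all downstream
# tie-breaking) is identical on every system
sort_c <- function(x) sort(x, method = "radix")

#' Write / read an incidence matrix as labelled CSV
#'
#' Layout: first column `moa` holds the MoA code, remaining columns are named
#' by species and hold 0/1. Growth forms are stored in a companion header
#' comment-free sidecar when `growth_form_path` is given.
#'
#' @param x an [incidence_matrix].
#' @param path output CSV path.
#' @param growth_form_path optional CSV path for the species-to-growth-form
#'   map (`species,growth_form`).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, growth_form_path = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  df <- data.frame(moa = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (!is.null(growth_form_path)) {
    gf <- growth_forms(x)
    write.csv(data.frame(species = names(gf), growth_form = unname(gf),
                         stringsAsFactors = FALSE),
              growth_form_path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, growth_form_path = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"moa" %in% names(df) || ncol(df) < 2L) {
    stop("matrix CSV must have a `moa` column followed by species columns",
         call. = FALSE)
  }
  cells <- as.matrix(df[, setdiff(names(df), "moa"), drop = FALSE])
  rownames(cells) <- as.character(df$moa)
  gf <- NULL
  if (!is.null(growth_form_path)) {
    g <- read.csv(growth_form_path, stringsAsFactors = FALSE)
    gf <- setNames(g$growth_form, g$species)
  }
  incidence_matrix(cells, growth_form = gf)
}
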