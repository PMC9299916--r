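#' Read resistance records from CSV
#'
#' Reads a table of species-by-MoA resistance assertions, one row per record,
#' in the layout used by extracts of herbicide-resistance databases:
#' a header with columns for the species name, its growth form
#' (monocot/dicot) and the HRAC mode-of-action group code. Extra columns
#' (country, crop, year, ...) are accepted and ignored. Records are
#' validated, species names case-normalized, and duplicate
#' (species, MoA) pairs collapsed to one.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param columns named character vector mapping the required fields
#'   `species`, `growth_form`, `moa_group` to the column names used in the
#'   file. The default layout is `species,growth_form,hrac_group`.
#' @return data.frame with columns `species`, `growth_form`, `moa_group`,
#'   one row per distinct (species, MoA) pair, sorted by species then MoA.
#' @details Growth forms other than monocot/dicot (for example free-text
#'   entries such as "grass") are mapped to `"unknown"` with a warning.
#'   Species names are trimmed, internal whitespace collapsed, and
#'   case-folded to "Genus epithet" capitalization so that the same taxon
#'   spelled differently collapses to one column. No taxonomic synonym
#'   resolution is attempted.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,growth_form,hrac_group",
#'              "Lolium rigidum,monocot,2",
#'              "Lolium rigidum,monocot,2",
#'              "Amaranthus palmeri,dicot,9"), f)
#' read_records(f)
#' @export
read_records <- function(path,
                         columns = c(species = "species",
                                     growth_form = "growth_form",
                                     moa_group = "hrac_group")) {
  defaults <- c(species = "species", growth_form = "growth_form",
                moa_group = "hrac_group")
  defaults[names(columns)] <- columns
  columns <- defaults
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8"),
    error = function(e) stop("could not parse CSV: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L) stop("empty input: ", path, call. = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(species = df[[columns[["species"]]]],
                    growth_form = df[[columns[["growth_form"]]]],
                    moa_group = df[[columns[["moa_group"]]]],
                    stringsAsFactors = FALSE)
  validate_records(rec, warn_growth_form = TRUE)
}

#' Validate and canonicalize a record table
#'
#' @param records data.frame with columns `species`, `growth_form`,
#'   `moa_group`.
#' @param warn_growth_form warn when unrecognized growth forms are coerced
#'   to `"unknown"`.
#' @return canonical, deduplicated record data.frame.
#' @keywords internal
validate_records <- function(records, warn_growth_form = FALSE) {
  need <- c("species", "growth_form", "moa_group")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  species <- normalize_species(records$species)
  moa <- trimws(as.character(records$moa_group))
  keep <- nzchar(species) & nzchar(moa) & !is.na(species) & !is.na(moa)
  if (!all(keep)) {
    stop(sum(!keep), " record(s) with empty species or MoA group",
         call. = FALSE)
  }
  gf <- normalize_growth_form(records$growth_form, warn = warn_growth_form)
  out <- data.frame(species = species, growth_form = unname(gf),
                    moa_group = moa, stringsAsFactors = FALSE)
  # collapse duplicates; resolve conflicting growth forms for one species
  # in favour of the first non-unknown value
  out <- out[!duplicated(out[c("species", "moa_group")]), , drop = FALSE]
  known <- out$growth_form != "unknown"
  first_known <- tapply(ifelse(known, out$growth_form, NA_character_),
                        out$species, function(v) {
                          v <- v[!is.na(v)]
                          if (length(v)) v[[1L]] else "unknown"
                        })
  out$growth_form <- as.character(first_known[out$species])
  out <- out[order(out$species, out$moa_group, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# "  lolium  RIGIDUM " -> "Lolium rigidum"
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- tolower(x)
  first <- toupper(substring(x, 1L, 1L))
  paste0(first, substring(x, 2L))
}

#' Write resistance records to CSV
#'
#' Emits the canonical record layout `species,growth_form,moa_group`;
#' [read_records()] on the output returns the identical record set.
#'
#' @param records record data.frame (see [read_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  names(records)[names(records) == "moa_group"] <- "hrac_group"
  write.csv(records, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}
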