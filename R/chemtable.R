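#' Chemical property tables
#'
#' A `chem_table` is a plain `data.frame` (kept as an S3 subclass) holding one
#' row per chemical: an `id`, an optional `name`, the two macroscopic
#' descriptors `logKow` (log10 octanol-water partition coefficient) and
#' `logKaw` (log10 air-water partition coefficient), the six optional Abraham
#' solute descriptors `E`, `S`, `A`, `B`, `V`, `L`, and any number of observed
#' phase-water partition coefficient columns named `logK_<phase>` (for
#' example `logK_combined_structural_protein`). All partition coefficients
#' are base-10 logarithms of dimensionless concentration ratios.
#'
#' @param x A data.frame with at least an `id` column.
#' @return `chem_table()` returns the validated table with class
#'   `c("chem_table", "data.frame")`.
#' @examples
#' tab <- chem_table(data.frame(id = c("a", "b"), logKow = c(2, 3),
#'                              logKaw = c(-1, -2)))
#' phase_columns(tab)
#' @export
chem_table <- function(x) {
  if (!is.data.frame(x)) stop_lfer("chem_table() expects a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"id" %in% names(x)) stop_lfer("column 'id' is required")
  x$id <- as.character(x$id)
  if (any(is.na(x$id) | !nzchar(x$id))) stop_lfer("all ids must be non-empty")
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup)) {
    stop_lfer("duplicate ids: ", paste(dup, collapse = ", "))
  }
  for (col in intersect(c(.numeric_columns, grep("^logK_", names(x), value = TRUE)),
                        names(x))) {
    if (!is.numeric(x[[col]])) {
      stop_lfer("column '", col, "' must be numeric")
    }
    bad <- which(!is.na(x[[col]]) & !is.finite(x[[col]]))
    if (length(bad)) {
      stop_lfer("non-finite value in column '", col, "', row(s) ",
                paste(bad, collapse = ", "))
    }
  }
  class(x) <- c("chem_table", "data.frame")
  x
}

.numeric_columns <- c("logKow", "logKaw", "E", "S", "A", "B", "V", "L")

#' @rdname chem_table
#' @param table A `chem_table`.
#' @return `phase_columns()` returns the phase names for which the table has
#'   observed `logK_<phase>` columns.
#' @export
phase_columns <- function(table) {
  sub("^logK_", "", grep("^logK_", names(table), value = TRUE))
}

# Canonical column names matched case-insensitively (with '.'/'-'/' '
# treated as '_').  Observed-phase columns are matched as logK_<phase> with
# <phase> run through the phase synonym map.
.column_synonyms <- c(
  id = "id", chemical = "id", cas = "id",
  name = "name", chemical_name = "name",
  logkow = "logKow", log_kow = "logKow", kow = "logKow",
  logkaw = "logKaw", log_kaw = "logKaw", kaw = "logKaw",
  e = "E", s = "S", a = "A", b = "B", v = "V", l = "L"
)

.normalize_header <- function(x) {
  gsub("[^a-z0-9_]", "_", tolower(trimws(x)))
}

.map_column_name <- function(nm) {
  key <- .normalize_header(nm)
  if (key %in% names(.column_synonyms)) {
    return(unname(.column_synonyms[key]))
  }
  m <- regmatches(key, regexec("^log_?k_(.+)$", key))[[1]]
  if (length(m) == 2) {
    return(paste0("logK_", canonical_phase(m[2], strict = FALSE)))
  }
  nm
}

#' Read and write chemical tables as CSV
#'
#' The on-disk dialect is UTF-8 comma-separated text with a header row.
#' Column headers are matched case-insensitively against a synonym map
#' (`logKow`, `log_Kow`, `Kow` ... all map to `logKow`); columns named
#' `logK_<phase>` carry observed phase-water partition coefficients and the
#' `<phase>` part is run through the phase synonym map (so `logK_pw` becomes
#' `logK_combined_structural_protein`). Empty cells are missing values.
#' Unrecognized columns are preserved verbatim.
#'
#' @param path Path to a CSV file.
#' @param format Only `"csv"` is supported.
#' @return `read_chemical_table()` returns a [chem_table]. A read-write-read
#'   round trip preserves every finite value exactly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("id,logKow,logKaw\nchem1,2.5,-3.1\nchem2,4.0,", f)
#' tab <- read_chemical_table(f)
#' tab$logKaw   # chem2's value is missing (NA)
#' @export
read_chemical_table <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop_lfer("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0 && ncol(raw) == 0) stop_lfer("empty file: ", path)
  names(raw) <- vapply(names(raw), .map_column_name, character(1))
  if (!"id" %in% names(raw)) {
    stop_lfer("no id column found in ", path,
              " (headers: ", paste(names(raw), collapse = ", "), ")")
  }
  numeric_cols <- union(intersect(.numeric_columns, names(raw)),
                        grep("^logK_", names(raw), value = TRUE))
  for (col in numeric_cols) {
    cell <- trimws(raw[[col]])
    cell[cell == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(parsed))
    if (length(bad)) {
      stop_lfer("non-numeric value ", dQuote(cell[bad[1]]), " in column '",
                col, "', row ", bad[1], " of ", path)
    }
    raw[[col]] <- parsed
  }
  chem_table(raw)
}

#' @rdname read_chemical_table
#' @param table A [chem_table].
#' @export
write_chemical_table <- function(table, path) {
  stopifnot(inherits(table, "chem_table"))
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Merge chicken and fish structural-protein tables into a combined table
#'
#' Chicken and fish muscle protein bind neutral organic chemicals almost
#' identically, so their observed structural protein-water partition
#' coefficients can be pooled: for chemicals present in both tables the
#' combined value is the arithmetic mean of the two observations, and
#' chemicals present in only one table are retained with their single value
#' (a union policy, which maximizes the size of the combined calibration
#' set). Descriptor columns are merged and checked for conflicts.
#'
#' @param chicken,fish `chem_table`s carrying observed columns
#'   `logK_chicken_structural_protein` and `logK_fish_structural_protein`
#'   respectively.
#' @param tol Maximum absolute disagreement allowed between descriptor values
#'   reported for the same chemical in both tables.
#' @return A [chem_table] over the union of ids with an added
#'   `logK_combined_structural_protein` column. The operation is symmetric in
#'   its two arguments.
#' @export
average_protein_datasets <- function(chicken, fish, tol = 1e-6) {
  ch_col <- "logK_chicken_structural_protein"
  fi_col <- "logK_fish_structural_protein"
  # Accept the two tables in either order: each must carry exactly one of
  # the two structural-protein columns.
  if (fi_col %in% names(chicken) && ch_col %in% names(fish) &&
      !ch_col %in% names(chicken)) {
    tmp <- chicken; chicken <- fish; fish <- tmp
  }
  if (!ch_col %in% names(chicken)) {
    stop_lfer("chicken table lacks observed column ", ch_col)
  }
  if (!fi_col %in% names(fish)) {
    stop_lfer("fish table lacks observed column ", fi_col)
  }
  ids <- sort(union(chicken$id, fish$id))
  shared_cols <- union(names(chicken), names(fish))
  shared_cols <- setdiff(shared_cols, c(ch_col, fi_col))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  pick <- function(table, col) {
    if (col %in% names(table)) table[[col]][match(ids, table$id)] else rep(NA, length(ids))
  }
  for (col in setdiff(shared_cols, "id")) {
    a <- pick(chicken, col)
    b <- pick(fish, col)
    if (is.numeric(a) || is.numeric(b)) {
      a <- as.numeric(a); b <- as.numeric(b)
      both <- !is.na(a) & !is.na(b)
      conflict <- both & abs(a - b) > tol
      if (any(conflict)) {
        stop_lfer("conflicting values for column '", col, "' on id(s): ",
                  paste(ids[conflict], collapse = ", "))
      }
      out[[col]] <- ifelse(is.na(a), b, a)
    } else {
      a <- as.character(a); b <- as.character(b)
      out[[col]] <- ifelse(is.na(a), b, a)
    }
  }
  kch <- pick(chicken, ch_col)
  kfi <- pick(fish, fi_col)
  out$logK_combined_structural_protein <-
    rowMeans(cbind(kch, kfi), na.rm = TRUE)
  out$logK_combined_structural_protein[is.na(kch) & is.na(kfi)] <- NA_real_
  chem_table(out)
}
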