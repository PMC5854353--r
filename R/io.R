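# Specimen table I/O.  One row per specimen; columns named by character id;
# empty cell = missing; decimal point only.  Unknown columns are kept as
# metadata with a warning so collection fields (collector, locality, ...)
# survive a round trip.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a specimen table
#'
#' @param path CSV or TSV file with columns \code{id}, \code{morph} and any
#'   registered raw (non-ratio) character ids.
#' @param registry A \code{myz_registry} (defaults to the bundled one).
#' @return List of \code{myz_specimen}.  Unknown columns are carried in each
#'   specimen's \code{metadata} (with a warning); a cell with a decimal
#'   comma, a duplicated id, or a ratio character used as a raw column is an
#'   error naming the row.
#' @export
parse_specimen_table <- function(path, registry = load_registry()) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  df <- utils::read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("id", "morph") %in% names(df)))
    stop("specimen table ", path, " must have 'id' and 'morph' columns")
  if (anyDuplicated(df$id))
    stop("duplicated specimen id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  char_cols <- setdiff(names(df), c("id", "morph"))
  known <- char_cols[char_cols %in% names(registry)]
  unknown <- setdiff(char_cols, known)
  if (length(unknown))
    warning("unknown column(s) kept as metadata: ",
            paste(unknown, collapse = ", "))
  ratio_cols <- known[vapply(known, function(id)
    registry[[id]]$kind == "ratio", logical(1))]
  if (length(ratio_cols))
    stop("ratio character(s) cannot be raw columns: ",
         paste(ratio_cols, collapse = ", "))

  lapply(seq_len(nrow(df)), function(i) {
    lin <- numeric(); cnt <- integer(); sts <- character()
    for (col in known) {
      cell <- trimws(df[[col]][i])
      if (!nzchar(cell)) next
      kind <- registry[[col]]$kind
      if (kind == "categorical") { sts[col] <- cell; next }
      if (grepl(",", cell, fixed = TRUE))
        stop("row ", i + 1L, " (specimen ", df$id[i], "), column ", col,
             ": decimal comma in '", cell, "'; use '.'")
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        stop("row ", i + 1L, " (specimen ", df$id[i], "), column ", col,
             ": unparseable numeric cell '", cell, "'")
      if (kind == "count") cnt[col] <- v else lin[col] <- v
    }
    meta <- as.list(df[i, unknown, drop = FALSE])
    myz_specimen(df$id[i], df$morph[i], linear = lin, counts = cnt,
                 states = sts, metadata = meta)
  })
}

#' Write specimens to a table
#'
#' Inverse of \code{\link{parse_specimen_table}}: emits one row per
#' specimen with the union of raw characters as columns (empty cell =
#' missing).  Derived ratios are not written.
#'
#' @param specimens List of \code{myz_specimen}.
#' @param path Output path (\code{.tsv} extension selects tab separation).
#' @return \code{path}, invisibly.
#' @export
write_specimen_table <- function(specimens, path) {
  cols <- unique(unlist(lapply(specimens, function(sp)
    c(names(sp$linear), names(sp$counts), names(sp$states)))))
  rows <- lapply(specimens, function(sp) {
    vals <- specimen_values(sp)
    row <- c(id = sp$id, morph = sp$morph,
             vapply(cols, function(cl)
               if (cl %in% names(vals)) as.character(vals[[cl]]) else "",
               character(1)))
    as.data.frame(as.list(row), check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(id = character(), morph = character(), check.names = FALSE)
  utils::write.table(df, path, sep = if (grepl("[.]tsv$", path)) "\t" else ",",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
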