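# Character registry: the dictionary of measurable, ratio, count and
# categorical characters that every other component refers to by id.

myz_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "myzaphid", mustWork = FALSE)
  if (!nzchar(p)) stop("bundled reference file not found: ", file.path(...))
  p
}

#' Load the character registry
#'
#' Reads the bundled registry of character definitions (or one supplied by the
#' user) and checks its structural invariants: unique ids, ratio characters
#' referring to two existing non-ratio characters, categorical characters with
#' a non-empty state list, and the "mm" unit reserved for linear characters.
#'
#' @param path Path to a registry JSON file. Defaults to the bundled registry.
#' @return An object of class \code{myz_registry}: a list with one entry per
#'   character (fields \code{id}, \code{name}, \code{kind}, \code{unit}, and
#'   for ratios \code{numerator_id}/\code{denominator_id}, for categoricals
#'   \code{allowed_states}).
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) path <- myz_extdata("registry.json")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$characters) || length(raw$characters) == 0L)
    stop("registry file ", path, ": no characters defined")
  chars <- raw$characters
  ids <- vapply(chars, function(ch) ch$id %||% NA_character_, character(1))
  if (anyNA(ids)) stop("registry file ", path, ": character without an id")
  if (anyDuplicated(ids))
    stop("registry: duplicated character id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(chars) <- ids
  for (ch in chars) {
    kind <- ch$kind %||% stop("registry: character ", ch$id, " has no kind")
    if (!kind %in% c("linear", "count", "ratio", "categorical"))
      stop("registry: character ", ch$id, " has unknown kind '", kind, "'")
    if (kind == "linear" && !identical(ch$unit, "mm"))
      stop("registry: linear character ", ch$id, " must have unit 'mm'")
    if (kind != "linear" && nzchar(ch$unit %||% ""))
      stop("registry: non-linear character ", ch$id, " must have empty unit")
    if (kind == "ratio") {
      num <- ch$numerator_id; den <- ch$denominator_id
      if (is.null(num) || is.null(den))
        stop("registry: ratio ", ch$id, " lacks numerator/denominator")
      for (part in c(num, den)) {
        if (!part %in% ids)
          stop("registry: ratio ", ch$id, " refers to unknown character ", part)
        if (identical(chars[[part]]$kind, "ratio"))
          stop("registry: ratio ", ch$id, " refers to ratio character ", part)
      }
    } else if (!is.null(ch$numerator_id) || !is.null(ch$denominator_id)) {
      stop("registry: non-ratio character ", ch$id, " carries ratio fields")
    }
    if (kind == "categorical") {
      if (length(ch$allowed_states) == 0L)
        stop("registry: categorical ", ch$id, " has no allowed states")
    } else if (length(ch$allowed_states) > 0L) {
      stop("registry: non-categorical ", ch$id, " carries allowed_states")
    }
  }
  structure(chars, class = "myz_registry")
}

#' @export
print.myz_registry <- function(x, ...) {
  kinds <- vapply(x, function(ch) ch$kind, character(1))
  cat("myz_registry:", length(x), "characters (",
      paste(names(table(kinds)), table(kinds), collapse = ", "), ")\n")
  invisible(x)
}

char_kind <- function(registry, id) {
  ch <- registry[[id]]
  if (is.null(ch)) stop("unknown character id: ", id)
  ch$kind
}

char_ids <- function(registry, kind = NULL) {
  if (is.null(kind)) return(names(registry))
  names(registry)[vapply(registry, function(ch) ch$kind, character(1)) %in% kind]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
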