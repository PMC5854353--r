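# Specimens: one individual's raw values.  Raw maps hold only measurable,
# count and categorical characters; ratio characters are always derived.

#' Construct a specimen
#'
#' @param id Specimen identifier.
#' @param morph One of fundatrix, aptera, alata, ovipara, male.
#' @param linear Named numeric vector of linear measurements in mm (partial).
#' @param counts Named integer vector of counts (partial).
#' @param states Named character vector of categorical states (partial).
#' @param metadata Optional named list kept verbatim (e.g. collector).
#' @return A \code{myz_specimen}.
#' @export
myz_specimen <- function(id, morph, linear = numeric(), counts = integer(),
                         states = character(), metadata = list()) {
  if (missing(morph) || is.na(morph) || !nzchar(morph))
    stop("specimen ", id, ": morph must be set")
  linear <- unlist(linear); counts <- unlist(counts); states <- unlist(states)
  if (length(linear) == 0L) linear <- stats::setNames(numeric(), character())
  if (length(counts) == 0L) counts <- stats::setNames(integer(), character())
  if (length(states) == 0L) states <- stats::setNames(character(), character())
  if (any(linear < 0, na.rm = TRUE) || any(counts < 0, na.rm = TRUE))
    stop("specimen ", id, ": negative raw values")
  if (any(counts %% 1 != 0, na.rm = TRUE))
    stop("specimen ", id, ": non-integer counts")
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  structure(list(id = as.character(id), morph = morph,
                 linear = linear, counts = cnt,
                 states = states, ratios = NULL, metadata = metadata),
            class = "myz_specimen")
}

#' @export
print.myz_specimen <- function(x, ...) {
  cat("myz_specimen ", x$id, " (", x$morph, "): ",
      length(x$linear), " linear, ", length(x$counts), " counts, ",
      length(x$states), " states",
      if (!is.null(x$ratios)) paste0(", ", length(x$ratios), " derived ratios"),
      "\n", sep = "")
  invisible(x)
}

assert_no_ratio_raw <- function(specimen, registry) {
  raw_ids <- c(names(specimen$linear), names(specimen$counts), names(specimen$states))
  known <- raw_ids[raw_ids %in% names(registry)]
  bad <- known[vapply(known, function(id) registry[[id]]$kind == "ratio", logical(1))]
  if (length(bad))
    stop("specimen ", specimen$id, ": ratio character(s) supplied as raw input: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Compute derived ratio characters
#'
#' For every ratio character in the registry whose numerator and denominator
#' are both present on the specimen, computes numerator/denominator.  Ratios
#' with a missing part are absent from the result; a denominator of exactly
#' zero is recorded as a per-ratio error (attribute \code{"errors"}) and does
#' not affect the other ratios.
#'
#' @param specimen A \code{myz_specimen}.
#' @param registry A \code{myz_registry}.
#' @return Named numeric vector of ratio values.
#' @export
compute_ratios <- function(specimen, registry) {
  stopifnot(inherits(specimen, "myz_specimen"), inherits(registry, "myz_registry"))
  assert_no_ratio_raw(specimen, registry)
  vals <- specimen$linear
  out <- numeric(); errs <- character()
  for (id in char_ids(registry, "ratio")) {
    ch <- registry[[id]]
    if (!ch$numerator_id %in% names(vals) || !ch$denominator_id %in% names(vals)) next
    num <- vals[[ch$numerator_id]]
    den <- vals[[ch$denominator_id]]
    if (is.na(num) || is.na(den)) next
    if (den == 0) { errs[id] <- "denominator is zero"; next }
    out[id] <- num / den
  }
  attr(out, "errors") <- errs
  out
}

#' Augment a specimen with all computable ratios
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @inheritParams compute_ratios
#' @return The specimen with its \code{ratios} field populated.
#' @export
ratio_closure <- function(specimen, registry) {
  specimen$ratios <- compute_ratios(specimen, registry)
  specimen
}

# flat named list of every value the specimen carries, ratios included
specimen_values <- function(specimen) {
  c(as.list(specimen$linear), as.list(specimen$counts),
    as.list(specimen$states),
    if (!is.null(specimen$ratios)) as.list(unclass(specimen$ratios)))
}
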