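# Consistency audit of a loaded reference dataset.  Produces findings, never
# exceptions: the as-printed layer is expected to carry the source treatment's own
# anomalies and the audit is how they surface.

finding <- function(severity, taxon, morph, character_id, message, as_printed) {
  data.frame(severity = severity, taxon = taxon, morph = morph,
             character_id = character_id, message = message,
             as_printed = as_printed, stringsAsFactors = FALSE)
}

#' Audit a reference dataset for internal consistency
#'
#' Deterministic checks on every profile entry: interval orientation
#' (lo <= hi), non-negativity, integrality of counts, unit sanity for linear
#' measurements (no aphid here approaches 5 mm), part-versus-whole
#' plausibility of antennal segments against the whole antenna, additivity of
#' the last antennal segment (BASE + PT), and morphs with no examined
#' specimens.  Findings are ordered by taxon, morph and character.
#'
#' @param ds A \code{myz_dataset}.
#' @return A data frame of findings (severity \code{"error"} or
#'   \code{"warning"}); zero rows when the layer is internally consistent.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "myz_dataset"))
  prof <- ds$profiles
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f

  quant <- prof[is.na(prof$state), ]
  for (i in seq_len(nrow(quant))) {
    r <- quant[i, ]
    if (is.na(r$lo) || is.na(r$hi)) {
      add(finding("error", r$taxon, r$morph, r$character_id,
                  "unparseable numeric range", r$as_printed))
      next
    }
    if (r$lo > r$hi)
      add(finding("error", r$taxon, r$morph, r$character_id,
                  sprintf("inverted interval: lo %g > hi %g", r$lo, r$hi),
                  r$as_printed))
    if (r$lo < 0)
      add(finding("error", r$taxon, r$morph, r$character_id,
                  "negative value", r$as_printed))
    if (r$kind == "linear" && max(r$lo, r$hi) >= 5)
      add(finding("error", r$taxon, r$morph, r$character_id,
                  "linear value >= 5 mm: implausible for these aphids",
                  r$as_printed))
    if (r$kind == "count" && (r$lo %% 1 != 0 || r$hi %% 1 != 0))
      add(finding("error", r$taxon, r$morph, r$character_id,
                  "non-integer count", r$as_printed))
  }

  # part vs whole: no antennal segment can exceed the whole antenna, and the
  # last segment must be consistent with BASE + PT
  segs <- c("ANT_III", "ANT_IV", "ANT_V", "ANT_VI", "BASE", "PT")
  for (i in seq_len(nrow(ds$morphs))) {
    tx <- ds$morphs$taxon[i]; mo <- ds$morphs$morph[i]
    p <- profile_rows(ds, tx, mo)
    getr <- function(id) {
      r <- p[p$character_id == id & is.na(p$state), ]
      if (nrow(r)) c(r$lo[1], r$hi[1]) else NULL
    }
    ant <- getr("ANT")
    if (!is.null(ant)) {
      for (s in segs) {
        sr <- getr(s)
        if (is.null(sr)) next
        if (sr[1] > ant[2] || sr[2] > ant[2])
          add(finding("error", tx, mo, s,
                      sprintf("segment (%g-%g) exceeds whole antenna (hi %g)",
                              sr[1], sr[2], ant[2]),
                      p$as_printed[p$character_id == s][1]))
      }
    }
    nseg <- p$state[p$character_id == "ANT_SEGMENTS"]
    last <- getr(if (length(nseg) && nseg[1] == "5") "ANT_V" else "ANT_VI")
    base <- getr("BASE"); pt <- getr("PT")
    if (!is.null(last) && !is.null(base) && !is.null(pt)) {
      if (base[1] + pt[1] > last[2] + 1e-9 || base[2] + pt[2] < last[1] - 1e-9)
        add(finding("error", tx, mo, "BASE",
                    sprintf("BASE+PT (%g-%g) inconsistent with last segment (%g-%g)",
                            base[1] + pt[1], base[2] + pt[2], last[1], last[2]),
                    ""))
    }
    if (ds$morphs$n_examined[i] == 0L)
      add(finding("warning", tx, mo, "", "profile with n examined = 0", ""))
  }

  if (!length(out))
    return(empty_findings())
  res <- do.call(rbind, out)
  res <- res[order(res$taxon, res$morph, res$character_id), ]
  rownames(res) <- NULL
  res
}

empty_findings <- function() {
  data.frame(severity = character(), taxon = character(), morph = character(),
             character_id = character(), message = character(),
             as_printed = character(), stringsAsFactors = FALSE)
}
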