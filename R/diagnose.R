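# Pairwise diagnosability: which characters separate which species pairs,
# per morph, and by how much.  The operational rule matches the Diagnosis
# style of comparative descriptions: two taxa are separable on a character
# when their printed intervals do not meet; a shared endpoint counts as
# overlap, because a specimen at the boundary is genuinely ambiguous.

#' Disjointness and gap of two closed intervals
#'
#' @param a,b Numeric length-2 vectors \code{c(lo, hi)}.
#' @return List with \code{disjoint} (logical; shared endpoints are NOT
#'   disjoint) and \code{gap} (distance between the nearer endpoints, 0 when
#'   the intervals meet or overlap).
#' @export
interval_disjoint <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  disjoint <- a[2] < b[1] || b[2] < a[1]
  gap <- max(0, b[1] - a[2], a[1] - b[2])
  list(disjoint = disjoint, gap = unname(gap))
}

#' Diagnosability of one species pair
#'
#' Enumerates every character recorded in both taxa's profiles for the given
#' morph.  Quantitative characters discriminate when their intervals are
#' disjoint; categorical ones when the state tokens differ.  Discriminating
#' characters are sorted by descending relative gap, the absolute gap scaled
#' by the pooled span of the pair (max hi - min lo).
#'
#' @param ds A \code{myz_dataset}.
#' @param taxon_a,taxon_b Species epithets (order does not matter).
#' @param morph Morph whose profiles to compare.
#' @return A \code{myz_diagnosis}: list with the pair, morph,
#'   \code{discriminating} (data frame: character, both intervals or states,
#'   gap, relative gap), \code{n_overlapping}, and \code{verdict}
#'   ("diagnosable" or "not-diagnosable-on-encoded-characters").
#' @export
diagnose_pair <- function(ds, taxon_a, taxon_b, morph) {
  stopifnot(inherits(ds, "myz_dataset"))
  for (tx in c(taxon_a, taxon_b))
    if (!has_profile(ds, tx, morph))
      stop("no ", morph, " profile for ", tx)
  pa <- profile_rows(ds, taxon_a, morph)
  pb <- profile_rows(ds, taxon_b, morph)
  shared <- intersect(pa$character_id, pb$character_id)
  disc <- list(); n_overlap <- 0L
  for (ch in sort(shared)) {
    ra <- pa[pa$character_id == ch, ]; rb <- pb[pb$character_id == ch, ]
    if (!is.na(ra$state[1]) || !is.na(rb$state[1])) {
      if (is.na(ra$state[1]) || is.na(rb$state[1])) next
      if (identical(ra$state[1], rb$state[1])) { n_overlap <- n_overlap + 1L; next }
      disc[[ch]] <- data.frame(
        character_id = ch, kind = "categorical",
        a_lo = NA_real_, a_hi = NA_real_, b_lo = NA_real_, b_hi = NA_real_,
        state_a = ra$state[1], state_b = rb$state[1],
        gap = NA_real_, relative_gap = NA_real_, stringsAsFactors = FALSE)
      next
    }
    d <- interval_disjoint(c(ra$lo[1], ra$hi[1]), c(rb$lo[1], rb$hi[1]))
    if (!d$disjoint) { n_overlap <- n_overlap + 1L; next }
    span <- max(ra$hi[1], rb$hi[1]) - min(ra$lo[1], rb$lo[1])
    disc[[ch]] <- data.frame(
      character_id = ch, kind = ra$kind[1],
      a_lo = ra$lo[1], a_hi = ra$hi[1], b_lo = rb$lo[1], b_hi = rb$hi[1],
      state_a = NA_character_, state_b = NA_character_,
      gap = d$gap, relative_gap = if (span > 0) d$gap / span else Inf,
      stringsAsFactors = FALSE)
  }
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(character_id = character(), kind = character(),
               a_lo = numeric(), a_hi = numeric(), b_lo = numeric(),
               b_hi = numeric(), state_a = character(), state_b = character(),
               gap = numeric(), relative_gap = numeric())
  ord <- order(-ifelse(is.na(disc$relative_gap), Inf, disc$relative_gap),
               disc$character_id)
  disc <- disc[ord, ]
  rownames(disc) <- NULL
  structure(list(pair = sort(c(taxon_a, taxon_b)), morph = morph,
                 discriminating = disc, n_overlapping = n_overlap,
                 verdict = if (nrow(disc)) "diagnosable"
                           else "not-diagnosable-on-encoded-characters"),
            class = "myz_diagnosis")
}

#' @export
print.myz_diagnosis <- function(x, ...) {
  cat("diagnosis ", x$pair[1], " vs ", x$pair[2], " (", x$morph, "): ",
      x$verdict, "; ", nrow(x$discriminating), " discriminating, ",
      x$n_overlapping, " overlapping\n", sep = "")
  invisible(x)
}

#' Count disjoint pairs for one character
#'
#' Over all taxa whose profile for the morph records the character, counts
#' the unordered pairs with disjoint intervals (categorical: differing
#' states).
#'
#' @param ds A \code{myz_dataset}.
#' @param morph Morph.
#' @param character_id Registered character id carried by at least two
#'   profiles.
#' @param taxa Optional character vector restricting the comparison (e.g.
#'   the species of one genus); default all carriers.
#' @return Integer count of disjoint pairs.
#' @export
pairwise_count <- function(ds, morph, character_id, taxa = NULL) {
  prof <- ds$profiles[ds$profiles$morph == morph &
                      ds$profiles$character_id == character_id, ]
  if (!is.null(taxa)) prof <- prof[prof$taxon %in% taxa, ]
  if (nrow(prof) < 2L)
    stop("character ", character_id, " carried by fewer than two ",
         morph, " profiles")
  n <- 0L
  for (i in seq_len(nrow(prof) - 1L)) {
    for (j in seq(i + 1L, nrow(prof))) {
      if (!is.na(prof$state[i])) {
        if (!identical(prof$state[i], prof$state[j])) n <- n + 1L
      } else if (interval_disjoint(c(prof$lo[i], prof$hi[i]),
                                   c(prof$lo[j], prof$hi[j]))$disjoint) {
        n <- n + 1L
      }
    }
  }
  n
}
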