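# Multi-access (matrix) identification: score a specimen against every
# interval profile of its morph by closed-interval containment and rank the
# candidates.

#' Score a specimen against one profile
#'
#' A character is evaluable when it is present on both the specimen (raw or
#' derived ratio) and the profile.  A quantitative verdict is "in" iff the
#' value lies in the closed profile interval; a categorical one iff the state
#' tokens are equal.  The score is the fraction of evaluable characters with
#' verdict "in".  Ratio characters are scored against the
#' description-derived ratio ranges only: quotients of table endpoints are
#' not specimen-wise bounds and are never used.
#'
#' @param specimen A \code{myz_specimen} (ratios computed if absent).
#' @param ds A \code{myz_dataset}.
#' @param taxon,morph Profile to score against; \code{morph} must equal the
#'   specimen's morph.
#' @return List with \code{score}, \code{n_evaluated} and a per-character
#'   \code{verdicts} data frame.
#' @export
score_profile <- function(specimen, ds, taxon, morph = specimen$morph) {
  stopifnot(inherits(specimen, "myz_specimen"), inherits(ds, "myz_dataset"))
  if (!identical(specimen$morph, morph))
    stop("specimen morph '", specimen$morph, "' does not match profile morph '",
         morph, "'")
  if (!has_profile(ds, taxon, morph))
    stop("no ", morph, " profile for ", taxon)
  if (is.null(specimen$ratios)) specimen <- ratio_closure(specimen, ds$registry)
  values <- specimen_values(specimen)
  prof <- profile_rows(ds, taxon, morph)
  prof <- prof[prof$character_id %in% names(values), ]
  if (!nrow(prof))
    stop("no evaluable characters shared between specimen ", specimen$id,
         " and profile ", taxon, "/", morph)
  vals <- values[prof$character_id]
  is_state <- !is.na(prof$state)
  verdict <- character(nrow(prof))
  if (any(is_state))
    verdict[is_state] <- ifelse(
      vapply(which(is_state),
             function(i) identical(as.character(vals[[i]]), prof$state[i]),
             logical(1)), "in", "out")
  if (any(!is_state)) {
    num <- vapply(vals[!is_state], function(v) as.numeric(v[1]), numeric(1))
    verdict[!is_state] <- ifelse(
      num >= prof$lo[!is_state] & num <= prof$hi[!is_state], "in", "out")
  }
  vd <- data.frame(character_id = prof$character_id, kind = prof$kind,
                   verdict = verdict, provenance = prof$provenance,
                   stringsAsFactors = FALSE)
  list(score = mean(verdict == "in"), n_evaluated = nrow(vd), verdicts = vd)
}

#' Identify a specimen against all profiles of its morph
#'
#' Scores the specimen against every taxon profiled for the morph and ranks
#' the candidates by descending score (ties broken alphabetically).  Profiles
#' sharing fewer than \code{min_characters} evaluable characters with the
#' specimen are reported as warnings, not ranked: a one-character match is
#' taxonomically meaningless.
#'
#' @param specimen A \code{myz_specimen}.
#' @param ds A \code{myz_dataset}.
#' @param morph Morph whose profiles to use; defaults to the specimen's.
#' @param min_characters Minimum evaluable characters for a candidate to be
#'   ranked (default 3).
#' @return A \code{myz_identification}: list with \code{ranking} (data frame:
#'   taxon, score, n_evaluated, n_in), \code{warnings}, \code{morph} and the
#'   per-candidate verdict tables.
#' @export
identify_specimen <- function(specimen, ds, morph = specimen$morph,
                              min_characters = 3L) {
  stopifnot(inherits(ds, "myz_dataset"))
  cand <- ds$morphs$taxon[ds$morphs$morph == morph]
  if (!length(cand))
    stop("no profiles for morph '", morph, "' (available: ",
         paste(sort(unique(ds$morphs$morph)), collapse = ", "), ")")
  specimen <- ratio_closure(specimen, ds$registry)
  rows <- list(); warns <- character(); details <- list()
  for (tx in sort(cand)) {
    sc <- tryCatch(score_profile(specimen, ds, tx, morph), error = function(e) e)
    if (inherits(sc, "error")) {
      warns <- c(warns, paste0(tx, ": ", conditionMessage(sc)))
      next
    }
    if (sc$n_evaluated < min_characters) {
      warns <- c(warns, paste0(tx, ": insufficient data (",
                               sc$n_evaluated, " evaluable characters)"))
      next
    }
    details[[tx]] <- sc$verdicts
    rows[[tx]] <- data.frame(taxon = tx, score = sc$score,
                             n_evaluated = sc$n_evaluated,
                             n_in = sum(sc$verdicts$verdict == "in"),
                             stringsAsFactors = FALSE)
  }
  ranking <- if (length(rows)) do.call(rbind, rows)
             else data.frame(taxon = character(), score = numeric(),
                             n_evaluated = integer(), n_in = integer())
  ranking <- ranking[order(-ranking$score, ranking$taxon), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, warnings = warns, morph = morph,
                 specimen = specimen$id, details = details),
            class = "myz_identification")
}

#' @export
print.myz_identification <- function(x, ...) {
  cat("identification of", x$specimen, "(", x$morph, "):\n")
  print(x$ranking, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Taxa attaining the top identification score
#'
#' @param ident A \code{myz_identification}.
#' @param tol Scores within \code{tol} of the maximum count as top.
#' @return Character vector of taxa (empty if nothing was ranked).
#' @export
top_candidates <- function(ident, tol = 1e-9) {
  rk <- ident$ranking
  if (!nrow(rk)) return(character())
  rk$taxon[rk$score >= max(rk$score) - tol]
}

#' Midpoint specimen of a profile
#'
#' Builds the specimen whose every raw quantitative character sits at the
#' midpoint of the profile interval (counts at the rounded-down midpoint, so
#' they stay integers inside the interval) and whose states are copied.
#' Useful as the canonical in-range representative of a taxon and morph.
#'
#' @param ds A \code{myz_dataset}.
#' @param taxon,morph Profile to summarize.
#' @param id Specimen id (default derived from taxon and morph).
#' @return A \code{myz_specimen}.
#' @export
midpoint_specimen <- function(ds, taxon, morph,
                              id = paste(taxon, morph, "mid", sep = "_")) {
  if (!has_profile(ds, taxon, morph))
    stop("no ", morph, " profile for ", taxon)
  prof <- profile_rows(ds, taxon, morph)
  lin <- numeric(); cnt <- integer(); sts <- character()
  for (i in seq_len(nrow(prof))) {
    r <- prof[i, ]
    if (!is.na(r$state)) { sts[r$character_id] <- r$state; next }
    if (r$kind == "linear") lin[r$character_id] <- (r$lo + r$hi) / 2
    if (r$kind == "count") cnt[r$character_id] <- floor((r$lo + r$hi) / 2)
  }
  myz_specimen(id, morph, linear = lin, counts = cnt, states = sts)
}
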