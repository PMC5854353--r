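# Dichotomous keys as couplet graphs.  Keys are data, not code: they ship in
# the bundle as JSON files users can author.  Traversal has explicit
# ambiguity semantics: a couplet whose two leads are both satisfiable (or
# undecidable for lack of data) is followed both ways and the terminal sets
# are unioned.

normalize_predicate <- function(p, about_tolerance) {
  ch <- p$character %||% stop("key predicate without character id")
  op <- p$op %||% stop("key predicate without op")
  out <- list(character = ch, op = op)
  if (op == "in") {
    out$lo <- as.numeric(p$lo); out$hi <- as.numeric(p$hi)
  } else if (op == "le") {
    out$lo <- 0; out$hi <- as.numeric(p$hi)
  } else if (op == "ge") {
    out$lo <- as.numeric(p$lo); out$hi <- Inf
  } else if (op == "about") {
    v <- as.numeric(p$value)
    out$lo <- v * (1 - about_tolerance); out$hi <- v * (1 + about_tolerance)
  } else if (op == "eq") {
    out$states <- unlist(p$states)
    if (!length(out$states)) stop("eq predicate without states: ", ch)
  } else if (op == "present") {
    out$present <- isTRUE(p$value)
  } else stop("unknown predicate op '", op, "' on ", ch)
  if (!is.null(out$lo) && (is.na(out$lo) || is.na(out$hi) || out$lo > out$hi))
    stop("invalid predicate interval on ", ch)
  out
}

#' Load the bundled dichotomous keys
#'
#' Reads every key file in a bundle's \code{keys/} directory, validates each
#' against the registry and taxon list, and (for the curated layer) applies
#' the documented key corrections.  "about x" leads and "x or less/more"
#' phrasings are represented as closed intervals; the about-tolerance matches
#' the dataset's.
#'
#' @param ds A \code{myz_dataset} (supplies registry, taxa, tolerance, path).
#' @param layer Key layer; defaults to the dataset's layer.
#' @return Named list of \code{myz_key} objects.
#' @export
load_keys <- function(ds, layer = ds$layer) {
  stopifnot(inherits(ds, "myz_dataset"))
  kdir <- file.path(ds$path, "keys")
  files <- list.files(kdir, "[.]json$", full.names = TRUE)
  if (!length(files)) stop("no key files under ", kdir)
  curation <- if (identical(layer, "curated") &&
                  file.exists(file.path(ds$path, "key_curation.json"))) {
    jsonlite::read_json(file.path(ds$path, "key_curation.json"),
                        simplifyVector = FALSE)
  } else list()

  keys <- list()
  for (f in files) {
    k <- jsonlite::read_json(f, simplifyVector = FALSE)
    for (cu in curation) {
      if (!identical(cu$key, k$id)) next
      lead <- k$couplets[[cu$couplet]][[cu$lead]]
      if (is.null(lead)) stop("key curation refers to absent lead: ",
                              cu$key, " couplet ", cu$couplet, cu$lead)
      hit <- FALSE
      for (j in seq_along(lead$predicates)) {
        if (identical(lead$predicates[[j]]$character, cu$character)) {
          lead$predicates[[j]] <- cu$replace; hit <- TRUE
        }
      }
      if (!hit) stop("key curation: predicate on ", cu$character,
                     " not found in ", cu$key, " couplet ", cu$couplet, cu$lead)
      k$couplets[[cu$couplet]][[cu$lead]] <- lead
    }
    for (cid in names(k$couplets)) {
      for (side in c("a", "b")) {
        lead <- k$couplets[[cid]][[side]]
        if (is.null(lead)) stop("key ", k$id, ": couplet ", cid,
                                " lacks lead ", side)
        if (!length(lead$predicates))
          stop("key ", k$id, ": couplet ", cid, side, " has no predicates")
        lead$predicates <- lapply(lead$predicates, normalize_predicate,
                                  about_tolerance = ds$about_tolerance)
        k$couplets[[cid]][[side]] <- lead
      }
    }
    k$layer <- layer
    class(k) <- "myz_key"
    validate_key(k, ds)
    keys[[k$id]] <- k
  }
  keys
}

#' Structural validation of a key
#'
#' Rejects couplets with other than two leads, predicates on unregistered
#' characters or with invalid bounds, cycles, couplets unreachable from the
#' root, unresolvable lead outcomes, and terminals absent from the taxonomy.
#'
#' @param key A \code{myz_key}.
#' @param ds The dataset whose registry and taxon list the key must resolve
#'   against.
#' @return Invisibly, the sorted terminal set.
#' @export
validate_key <- function(key, ds) {
  registry <- ds$registry
  known_terminals <- c(vapply(ds$taxa$species, `[[`, "", "taxon"),
                       unlist(ds$taxa$genera))
  for (cid in names(key$couplets)) {
    for (side in c("a", "b")) {
      lead <- key$couplets[[cid]][[side]]
      for (p in lead$predicates) {
        if (!p$character %in% names(registry))
          stop("key ", key$id, ": predicate on unregistered character ",
               p$character, " (couplet ", cid, side, ")")
        if (!is.null(p$states)) {
          allowed <- unlist(registry[[p$character]]$allowed_states)
          bad <- setdiff(p$states, allowed)
          if (length(bad))
            stop("key ", key$id, ": state(s) ", paste(bad, collapse = ","),
                 " not allowed for ", p$character)
        }
      }
      has_goto <- !is.null(lead$goto); has_taxon <- !is.null(lead$taxon)
      if (has_goto == has_taxon)
        stop("key ", key$id, ": couplet ", cid, side,
             " must have exactly one of goto/taxon")
      if (has_goto && is.null(key$couplets[[lead$goto]]))
        stop("key ", key$id, ": couplet ", cid, side,
             " points to absent couplet ", lead$goto)
      if (has_taxon && !lead$taxon %in% known_terminals)
        stop("key ", key$id, ": terminal '", lead$taxon,
             "' is not in the taxonomy")
    }
  }
  # reachability and acyclicity from the root
  seen <- character(); stack <- character()
  terminals <- character()
  walk <- function(cid) {
    if (cid %in% stack) stop("key ", key$id, ": cycle through couplet ", cid)
    if (cid %in% seen) return(invisible())
    stack <<- c(stack, cid); seen <<- c(seen, cid)
    for (side in c("a", "b")) {
      lead <- key$couplets[[cid]][[side]]
      if (!is.null(lead$goto)) walk(lead$goto)
      else terminals <<- c(terminals, lead$taxon)
    }
    stack <<- stack[-length(stack)]
  }
  walk(key$root)
  unreachable <- setdiff(names(key$couplets), seen)
  if (length(unreachable))
    stop("key ", key$id, ": unreachable couplet(s) ",
         paste(unreachable, collapse = ", "))
  invisible(sort(unique(terminals)))
}

key_terminals <- function(key) {
  unlist(lapply(key$couplets, function(cp)
    c(cp$a$taxon, cp$b$taxon)), use.names = FALSE)
}

#' @export
print.myz_key <- function(x, ...) {
  cat("myz_key ", x$id, " (", x$morph, ", ", x$layer, "): ",
      length(x$couplets), " couplets, ",
      length(key_terminals(x)), " terminals\n", sep = "")
  invisible(x)
}

evaluate_predicate <- function(values, pred) {
  v <- values[[pred$character]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA)
  if (pred$op == "present") return(TRUE)
  if (!is.null(pred$states)) return(as.character(v) %in% pred$states)
  v <- as.numeric(v)
  v >= pred$lo & v <= pred$hi
}

#' Evaluate one key lead against a specimen
#'
#' A lead is a conjunction: \code{"true"} iff all predicates hold,
#' \code{"false"} if any predicate fails, and \code{"unknown"} if no
#' predicate fails but at least one refers to a character the specimen lacks.
#'
#' @param specimen A \code{myz_specimen}; its ratios are computed if absent.
#' @param lead One lead of a loaded key couplet.
#' @param registry A \code{myz_registry}.
#' @return \code{"true"}, \code{"false"} or \code{"unknown"}.
#' @export
evaluate_lead <- function(specimen, lead, registry) {
  if (is.null(specimen$ratios)) specimen <- ratio_closure(specimen, registry)
  values <- specimen_values(specimen)
  verdicts <- vapply(lead$predicates, function(p) {
    r <- evaluate_predicate(values, p)
    if (is.na(r)) NA else r
  }, logical(1))
  if (any(!verdicts, na.rm = TRUE)) return("false")
  if (anyNA(verdicts)) return("unknown")
  "true"
}

#' Traverse a key with a specimen
#'
#' Depth-first from the root.  At each couplet: (true, false) follows lead a,
#' (false, true) lead b, (false, false) records "neither" and contributes no
#' terminal, and any other combination -- both leads true, or any lead
#' undecidable for lack of data -- follows both and unions the terminals.
#' Output is deterministic (terminals sorted alphabetically).
#'
#' @param specimen A \code{myz_specimen}.
#' @param key A \code{myz_key}.
#' @param registry A \code{myz_registry}.
#' @param check_morph If TRUE (default), a specimen whose morph does not
#'   match the key scope is an error.
#' @return A \code{myz_traversal}: list with \code{terminals}, a per-couplet
#'   \code{trace} data frame, and \code{notes}.
#' @export
traverse <- function(specimen, key, registry, check_morph = TRUE) {
  stopifnot(inherits(key, "myz_key"))
  if (check_morph && !identical(specimen$morph, key$morph))
    stop("specimen morph '", specimen$morph, "' does not match key scope '",
         key$morph, "'")
  specimen <- ratio_closure(specimen, registry)
  trace <- list(); terminals <- character()
  follow <- function(cid) {
    cp <- key$couplets[[cid]]
    va <- evaluate_lead(specimen, cp$a, registry)
    vb <- evaluate_lead(specimen, cp$b, registry)
    decision <- if (va == "false" && vb == "false") "neither"
                else if (va == "true" && vb == "false") "a"
                else if (va == "false" && vb == "true") "b"
                else "both"
    trace[[length(trace) + 1L]] <<- data.frame(
      couplet = cid, lead_a = va, lead_b = vb, decision = decision,
      stringsAsFactors = FALSE)
    sides <- switch(decision, a = "a", b = "b", both = c("a", "b"),
                    neither = character())
    for (side in sides) {
      lead <- cp[[side]]
      if (!is.null(lead$taxon)) terminals <<- c(terminals, lead$taxon)
      else follow(lead$goto)
    }
  }
  follow(key$root)
  trace <- do.call(rbind, trace)
  notes <- character()
  if (!length(terminals))
    notes <- "no terminal reached: some path ended with both leads false"
  structure(list(terminals = sort(unique(terminals)), trace = trace,
                 notes = notes, key = key$id, specimen = specimen$id),
            class = "myz_traversal")
}

#' @export
print.myz_traversal <- function(x, ...) {
  cat("traversal of", x$key, "for specimen", x$specimen, "->",
      if (length(x$terminals)) paste(x$terminals, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

# path (couplet/side pairs) from the root to a terminal taxon
key_path <- function(key, terminal) {
  path <- NULL
  dfs <- function(cid, acc) {
    cp <- key$couplets[[cid]]
    for (side in c("a", "b")) {
      lead <- cp[[side]]
      step <- list(list(couplet = cid, side = side, lead = lead))
      if (!is.null(lead$taxon)) {
        if (identical(lead$taxon, terminal)) path <<- c(acc, step)
      } else dfs(lead$goto, c(acc, step))
    }
  }
  dfs(key$root, list())
  if (is.null(path)) stop("terminal '", terminal, "' not in key ", key$id)
  path
}

#' Audit a key against the reference dataset
#'
#' Replays each terminal taxon's path through the key with that taxon's own
#' interval profile in place of a specimen.  A predicate "holds" when the
#' profile interval is contained in the predicate interval (states: the
#' profile state is among the admitted ones), "fails" when they are
#' disjoint, and is "partial" otherwise; leads that fail or are partial on
#' the taxon's own path are reported (fails as errors, partials as
#' warnings).  Predicates on characters the profile does not record are
#' skipped.
#'
#' @param key A \code{myz_key}.
#' @param ds A \code{myz_dataset}.
#' @return A findings data frame as in \code{\link{validate_dataset}}.
#' @export
audit_key <- function(key, ds) {
  stopifnot(inherits(key, "myz_key"), inherits(ds, "myz_dataset"))
  genus_of <- vapply(ds$taxa$species, `[[`, "", "genus")
  names(genus_of) <- vapply(ds$taxa$species, `[[`, "", "taxon")
  out <- list()
  for (terminal in sort(unique(key_terminals(key)))) {
    # a genus terminal is audited through any bundled species of that genus
    taxa <- if (terminal %in% names(genus_of)) terminal
            else names(genus_of)[genus_of == terminal]
    taxa <- taxa[vapply(taxa, has_profile, logical(1), ds = ds, morph = key$morph)]
    for (tx in taxa) {
      prof <- profile_rows(ds, tx, key$morph)
      for (step in key_path(key, terminal)) {
        for (p in step$lead$predicates) {
          row <- prof[prof$character_id == p$character, ]
          if (nrow(row) == 0L) next
          if (!is.na(row$state[1])) {
            verdict <- if (row$state[1] %in% p$states) "holds" else "fails"
          } else {
            lo <- row$lo[1]; hi <- row$hi[1]
            verdict <- if (lo >= p$lo && hi <= p$hi) "holds"
                       else if (hi < p$lo || lo > p$hi) "fails"
                       else "partial"
          }
          if (verdict != "holds")
            out[[length(out) + 1L]] <- finding(
              if (verdict == "fails") "error" else "warning",
              tx, key$morph, p$character,
              sprintf("key %s couplet %s%s %s for %s (profile %s vs lead %s)",
                      key$id, step$couplet, step$side, verdict, terminal,
                      if (!is.na(row$state[1])) row$state[1]
                      else sprintf("[%g, %g]", row$lo[1], row$hi[1]),
                      if (!is.null(p$states)) paste(p$states, collapse = "/")
                      else sprintf("[%g, %g]", p$lo, p$hi)),
              row$as_printed[1])
        }
      }
    }
  }
  if (!length(out))
    return(empty_findings())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
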