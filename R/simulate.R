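# Seedable synthetic specimens.  Raw values honor the printed per-profile
# intervals; in ratio-constrained mode every encoded ratio range holds as
# well.  Ratio constraints are enforced by sequential interval propagation --
# characters are fixed one at a time, each sampled from the intersection of
# its absolute interval with the intervals implied by already-fixed ratio
# partners -- followed by rejection of the rare draws that still violate a
# not-yet-propagated constraint.

# fixation order: shared denominators first, then numerators, then the
# ratio-only seta/diameter cluster
FIX_ORDER <- c("BL", "HW", "ANT", "ANT_III", "ANT_VI", "ANT_V", "ANT_IV",
               "BASE", "PT", "CAUDA", "SIPH", "HT_II", "URS",
               "BD_III", "LS_III", "HLS")

# fallback domains (mm) for characters constrained only through ratios; the
# basal diameter of ANT III is never printed as an absolute length
DEFAULT_DOMAIN <- list(BD_III = c(0.010, 0.035), default = c(0.003, 1.5))

sample_in <- function(lo, hi, distribution, sd_fraction) {
  if (!is.finite(hi)) hi <- lo * 1.5 + 0.1
  if (distribution == "uniform") return(stats::runif(1, lo, hi))
  mid <- (lo + hi) / 2; sd <- sd_fraction * (hi - lo) / 2
  if (sd <= 0) return(mid)
  for (k in 1:100) {
    v <- stats::rnorm(1, mid, sd)
    if (v >= lo && v <= hi) return(v)
  }
  mid
}

sample_count <- function(lo, hi) {
  if (!is.finite(hi)) hi <- lo + 5
  lo <- ceiling(lo); hi <- floor(hi)
  if (lo > hi) return(NULL)
  if (lo == hi) lo else sample(seq(lo, hi), 1)
}

# one draw under a constraint set; on failure returns a marker naming the
# binding constraint
draw_fail <- function(ch) list(ok = FALSE, binding = ch)

draw_specimen <- function(constraints, registry, distribution, sd_fraction) {
  abs_int <- constraints$absolute   # named list of c(lo, hi)
  ratios <- constraints$ratios      # list of (id, num, den, lo, hi)
  chars <- unique(c(names(abs_int),
                    unlist(lapply(ratios, function(r) c(r$num, r$den)))))
  kinds <- vapply(chars, function(id) registry[[id]]$kind, character(1))
  ord <- c(intersect(FIX_ORDER, chars), sort(setdiff(chars, FIX_ORDER)))
  fixed <- list()
  for (ch in ord) {
    dom <- abs_int[[ch]] %||%
      DEFAULT_DOMAIN[[ch]] %||%
      (if (kinds[[ch]] == "count") c(0, 50) else DEFAULT_DOMAIN$default)
    lo <- dom[1]; hi <- dom[2]
    for (r in ratios) {
      if (r$num == ch && !is.null(fixed[[r$den]])) {
        lo <- max(lo, r$lo * fixed[[r$den]]); hi <- min(hi, r$hi * fixed[[r$den]])
      } else if (r$den == ch && !is.null(fixed[[r$num]])) {
        lo <- max(lo, fixed[[r$num]] / r$hi); hi <- min(hi, fixed[[r$num]] / r$lo)
      }
    }
    if (lo > hi) return(draw_fail(ch))
    if (kinds[[ch]] == "count") {
      v <- sample_count(lo, hi)
      if (is.null(v)) return(draw_fail(ch))
    } else v <- sample_in(lo, hi, distribution, sd_fraction)
    fixed[[ch]] <- v
  }
  # verify every ratio constraint (propagation is order-dependent)
  for (r in ratios) {
    v <- fixed[[r$num]] / fixed[[r$den]]
    if (v < r$lo - 1e-12 || v > r$hi + 1e-12)
      return(draw_fail(r$id))
  }
  list(ok = TRUE, fixed = fixed)
}

profile_constraints <- function(ds, taxon, morph, with_ratios) {
  prof <- profile_rows(ds, taxon, morph)
  absolute <- list(); states <- character(); ratios <- list()
  for (i in seq_len(nrow(prof))) {
    r <- prof[i, ]
    if (!is.na(r$state)) { states[r$character_id] <- r$state; next }
    if (r$kind %in% c("linear", "count")) {
      absolute[[r$character_id]] <- c(r$lo, r$hi)
    } else if (r$kind == "ratio" && with_ratios) {
      ch <- ds$registry[[r$character_id]]
      ratios[[length(ratios) + 1L]] <- list(id = r$character_id,
        num = ch$numerator_id, den = ch$denominator_id, lo = r$lo, hi = r$hi)
    }
  }
  list(absolute = absolute, states = states, ratios = ratios)
}

# Reconcile ratio constraints with the absolute intervals they must span.
# Printed tables and printed ratio ranges come from the same specimens but
# are rounded independently, so a ratio range can be (a) satisfiable as
# printed, (b) satisfiable only within half the printed resolution, or
# (c) flatly contradicted by the tables.  Case (b) widens the constraint,
# case (c) drops it; both are reported as the profile's health check.
reconcile_constraints <- function(cons, resolution) {
  kept <- list(); relaxed <- character(); dropped <- character()
  for (r in cons$ratios) {
    a_num <- cons$absolute[[r$num]]; a_den <- cons$absolute[[r$den]]
    if (is.null(a_num) || is.null(a_den) || a_den[1] <= 0) {
      kept[[length(kept) + 1L]] <- r
      next
    }
    achievable <- c(a_num[1] / a_den[2], a_num[2] / a_den[1])
    if (max(r$lo, achievable[1]) <= min(r$hi, achievable[2])) {
      kept[[length(kept) + 1L]] <- r
    } else {
      lo2 <- r$lo - resolution / 2; hi2 <- r$hi + resolution / 2
      if (max(lo2, achievable[1]) <= min(hi2, achievable[2])) {
        r$lo <- lo2; r$hi <- hi2
        kept[[length(kept) + 1L]] <- r
        relaxed <- c(relaxed, r$id)
      } else {
        dropped <- c(dropped, r$id)
      }
    }
  }
  cons$ratios <- kept
  cons$health <- list(relaxed = relaxed, dropped = dropped)
  cons
}

path_constraints <- function(key, terminal, registry) {
  absolute <- list()      # character -> c(lo, hi), intersected
  state_sets <- list()    # character -> admissible state set, intersected
  ratio_int <- list()     # ratio id -> c(lo, hi), intersected
  add_interval <- function(store, id, lo, hi) {
    cur <- store[[id]] %||% c(0, Inf)
    store[[id]] <- c(max(cur[1], lo), min(cur[2], hi))
    if (store[[id]][1] > store[[id]][2])
      stop("contradictory interval constraints on ", id,
           " along the path to ", terminal)
    store
  }
  path <- key_path(key, terminal)
  for (step in path) {
    for (p in step$lead$predicates) {
      if (!is.null(p$states)) {
        cur <- state_sets[[p$character]] %||%
          unlist(registry[[p$character]]$allowed_states)
        nw <- intersect(cur, p$states)
        if (!length(nw))
          stop("contradictory state constraints on ", p$character,
               " along the path to ", terminal)
        state_sets[[p$character]] <- nw
      } else if (registry[[p$character]]$kind == "ratio") {
        ratio_int <- add_interval(ratio_int, p$character, p$lo, p$hi)
      } else {
        absolute <- add_interval(absolute, p$character, p$lo, p$hi)
      }
    }
    # make the sibling lead decidably false where it tests otherwise
    # unconstrained characters
    sib <- key$couplets[[step$couplet]][[if (step$side == "a") "b" else "a"]]
    already_false <- FALSE
    for (p in sib$predicates) {
      if (!is.null(p$states)) {
        cur <- state_sets[[p$character]]
        if (!is.null(cur) && !length(intersect(cur, p$states))) {
          already_false <- TRUE; break
        }
      } else {
        cur <- if (registry[[p$character]]$kind == "ratio")
          ratio_int[[p$character]] else absolute[[p$character]]
        if (!is.null(cur) && (cur[2] < p$lo || cur[1] > p$hi)) {
          already_false <- TRUE; break
        }
      }
    }
    if (!already_false) {
      for (p in sib$predicates) {
        kind <- registry[[p$character]]$kind
        if (!is.null(p$states)) {
          cur <- state_sets[[p$character]] %||%
            unlist(registry[[p$character]]$allowed_states)
          rest <- setdiff(cur, p$states)
          if (length(rest)) { state_sets[[p$character]] <- rest; break }
        } else if (kind != "ratio" && is.null(absolute[[p$character]])) {
          if (is.finite(p$hi)) {
            step_up <- if (kind == "count") 1 else max(0.05 * p$hi, 0.005)
            absolute[[p$character]] <- c(p$hi + step_up, p$hi + 2 * step_up)
          } else if (p$lo > 0) {
            absolute[[p$character]] <- c(max(0, p$lo * 0.5), p$lo * 0.9)
          }
          break
        }
      }
    }
  }
  states <- vapply(state_sets, `[[`, "", 1L)
  ratios <- lapply(names(ratio_int), function(id) {
    ch <- registry[[id]]
    list(id = id, num = ch$numerator_id, den = ch$denominator_id,
         lo = ratio_int[[id]][1], hi = ratio_int[[id]][2])
  })
  list(absolute = absolute, states = states, ratios = ratios)
}

fixed_to_specimen <- function(fixed, states, registry, id, morph) {
  kinds <- vapply(names(fixed), function(ch) registry[[ch]]$kind, character(1))
  lin <- unlist(fixed[kinds == "linear"])
  cnt <- unlist(fixed[kinds == "count"])
  myz_specimen(id, morph,
               linear = if (length(lin)) lin else numeric(),
               counts = if (length(cnt)) cnt else integer(),
               states = states)
}

#' Generate synthetic specimens
#'
#' Three modes. \code{"table_only"}: every raw value is drawn from its
#' printed per-profile interval (counts as integers; states copied).
#' \code{"ratio_constrained"} (the default): additionally, every
#' description-derived ratio range encoded for the profile holds for every
#' emitted specimen.  \code{"path_constrained"}: specimens are built from the
#' predicates along a key path so that traversal returns exactly the
#' requested terminal; a taxon profile is not required.
#'
#' The same seed yields identical output.  Joint satisfiability of printed
#' absolute and ratio ranges is not assumed: the generator reports the
#' rejection rate per batch and errors, naming the binding constraint, when
#' a specimen cannot be produced within \code{max_rejections} draws.
#'
#' @param ds A \code{myz_dataset}.
#' @param n Number of specimens.
#' @param taxon,morph Profile to emulate (ignored for taxon in
#'   \code{path_constrained} mode).
#' @param mode Generation mode, see above.
#' @param seed Integer seed.
#' @param distribution \code{"uniform"} or \code{"truncated_normal"}
#'   (centered at the interval midpoint, sd = \code{sd_fraction} times the
#'   half-width, clipped by resampling).
#' @param sd_fraction Spread for the truncated normal (default 0.25).
#' @param max_rejections Rejection cap per specimen (default 1000).
#' @param ratio_resolution Printed resolution of ratio values (default 0.01,
#'   two decimals).  When a profile's strictly read intervals are jointly
#'   unsatisfiable -- printed values are rounded -- ratio bounds are widened
#'   by half this resolution and the batch is flagged
#'   (\code{report$strictly_satisfiable = FALSE}).
#' @param key,terminal For \code{path_constrained} mode: a \code{myz_key}
#'   and one of its terminal taxa.
#' @return List with \code{specimens} (list of \code{myz_specimen}) and
#'   \code{report} (rejection rate, per-batch derived sampling domains).
#' @export
generate_specimens <- function(ds, n, taxon = NULL, morph = NULL,
                               mode = c("ratio_constrained", "table_only",
                                        "path_constrained"),
                               seed = 1L,
                               distribution = c("uniform", "truncated_normal"),
                               sd_fraction = 0.25, max_rejections = 1000L,
                               key = NULL, terminal = NULL,
                               ratio_resolution = 0.01) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  stopifnot(n >= 0, max_rejections >= 1)
  if (mode == "path_constrained") {
    if (is.null(key) || is.null(terminal))
      stop("path_constrained mode needs a key and a terminal")
    if (!terminal %in% key_terminals(key))
      stop("terminal '", terminal, "' is not reachable in key ", key$id)
    morph <- key$morph
    cons <- path_constraints(key, terminal, ds$registry)
    label <- terminal
  } else {
    if (is.null(taxon) || is.null(morph))
      stop("profile modes need taxon and morph")
    if (!has_profile(ds, taxon, morph))
      stop("no ", morph, " profile for ", taxon)
    cons <- profile_constraints(ds, taxon, morph,
                                with_ratios = mode == "ratio_constrained")
    if (mode == "ratio_constrained")
      cons <- reconcile_constraints(cons, ratio_resolution)
    label <- paste(taxon, morph, sep = "_")
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  specimens <- vector("list", n)
  rejected <- 0L
  relax_rounds <- 0L; max_relax_rounds <- 4L
  i <- 1L
  while (i <= n) {
    sp <- NULL; last_binding <- "unknown"
    for (try in seq_len(max_rejections)) {
      dr <- draw_specimen(cons, ds$registry, distribution, sd_fraction)
      if (!dr$ok) { rejected <- rejected + 1L; last_binding <- dr$binding; next }
      cand <- fixed_to_specimen(dr$fixed, cons$states, ds$registry,
                                sprintf("%s_%03d", label, i), morph)
      if (mode == "path_constrained") {
        tr <- traverse(cand, key, ds$registry, check_morph = FALSE)
        if (!identical(tr$terminals, terminal)) {
          rejected <- rejected + 1L; last_binding <- "traversal"; next
        }
      }
      sp <- cand
      break
    }
    if (is.null(sp) && mode == "ratio_constrained" &&
        relax_rounds < max_relax_rounds) {
      # Printed values are rounded (lengths to 0.01 mm, ratios to 2
      # decimals), so strictly read intervals can be jointly unsatisfiable
      # even when the underlying measurements were consistent.  Relax the
      # ratio bounds by half the printed resolution and retry (up to
      # max_relax_rounds times); the batch report flags the profile as not
      # strictly satisfiable and records the rounds used.
      cons$ratios <- lapply(cons$ratios, function(r) {
        r$lo <- r$lo - ratio_resolution / 2; r$hi <- r$hi + ratio_resolution / 2
        r
      })
      relax_rounds <- relax_rounds + 1L
      next
    }
    if (is.null(sp))
      stop("could not generate specimen for ", label, " within ",
           max_rejections, " draws; binding constraint: ", last_binding)
    specimens[[i]] <- sp
    i <- i + 1L
  }
  derived <- setdiff(
    unique(unlist(lapply(cons$ratios, function(r) c(r$num, r$den)))),
    names(cons$absolute))
  list(specimens = specimens,
       report = list(
         rejection_rate = if (n > 0) rejected / (rejected + n) else 0,
         n = n, mode = mode, seed = seed, label = label,
         strictly_satisfiable = relax_rounds == 0L &&
           length(c(cons$health$relaxed, cons$health$dropped)) == 0L,
         relax_rounds = relax_rounds,
         ratio_constraints_relaxed = cons$health$relaxed,
         ratio_constraints_dropped = cons$health$dropped,
         derived_domain_characters = derived))
}

#' Corrupt specimens by masking and noising
#'
#' Masks each raw character independently with probability
#' \code{missing_fraction} and perturbs each surviving quantitative value
#' multiplicatively (uniform in \code{1 +/- noise_amount}) with probability
#' \code{noise_fraction}.  Seeded and reproducible; fractions of 0 leave the
#' specimens untouched.
#'
#' @param specimens List of \code{myz_specimen}.
#' @param missing_fraction,noise_fraction Probabilities in [0, 1].
#' @param seed Integer seed.
#' @param noise_amount Relative half-width of the multiplicative noise
#'   (default 0.1).
#' @return List of corrupted specimens.
#' @export
corrupt_specimens <- function(specimens, missing_fraction = 0,
                              noise_fraction = 0, seed = 1L,
                              noise_amount = 0.1) {
  stopifnot(missing_fraction >= 0, missing_fraction <= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  lapply(specimens, function(sp) {
    mask <- function(x) {
      if (!length(x)) return(x)
      x[stats::runif(length(x)) >= missing_fraction]
    }
    sp$linear <- mask(sp$linear)
    sp$counts <- mask(sp$counts)
    sp$states <- mask(sp$states)
    if (noise_fraction > 0 && length(sp$linear)) {
      hit <- stats::runif(length(sp$linear)) < noise_fraction
      f <- stats::runif(sum(hit), 1 - noise_amount, 1 + noise_amount)
      sp$linear[hit] <- sp$linear[hit] * f
    }
    if (noise_fraction > 0 && length(sp$counts)) {
      hit <- stats::runif(length(sp$counts)) < noise_fraction
      f <- stats::runif(sum(hit), 1 - noise_amount, 1 + noise_amount)
      sp$counts[hit] <- as.integer(pmax(0, round(sp$counts[hit] * f)))
    }
    sp$ratios <- NULL
    sp
  })
}
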