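# Reference dataset: taxon records plus one interval profile per taxon x
# morph, assembled from the bundled transcription of the measurement tables,
# the description-derived ratio/count/state records, and (in the curated
# layer) a documented correction table.

MORPHS <- c("fundatrix", "aptera", "alata", "ovipara", "male")

read_bundle_csv <- function(dir, file, required) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("reference bundle: missing file ", file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("reference bundle: file ", file, " lacks column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Load the reference dataset
#'
#' Assembles the character registry, the taxon records and all taxon-by-morph
#' interval profiles from a reference bundle directory.  Two data layers are
#' available: \code{"as_printed"} is the verbatim transcription, anomalies
#' included; \code{"curated"} (the default for all analysis) applies the
#' bundled correction table, each entry of which carries a justification.
#' Ranges printed as "about x" are expanded to a symmetric interval of
#' half-width \code{about_tolerance * x}.
#'
#' @param path Directory holding the bundle. Defaults to the bundled dataset.
#' @param layer Data layer, \code{"curated"} or \code{"as_printed"}.
#' @param about_tolerance Relative half-width used to expand "about x"
#'   values into intervals (default 0.05).
#' @return A \code{myz_dataset}: list with elements \code{registry},
#'   \code{taxa}, \code{profiles} (one row per taxon, morph and character:
#'   \code{lo}/\code{hi} for quantitative characters, \code{state} for
#'   categorical ones, plus provenance and the verbatim printed string),
#'   \code{morphs} (n examined per profile), \code{material_counts}, and
#'   \code{layer}.
#' @export
load_reference <- function(path = NULL,
                           layer = c("curated", "as_printed"),
                           about_tolerance = 0.05) {
  layer <- match.arg(layer)
  if (is.null(path)) path <- myz_extdata(".")
  if (!dir.exists(path)) stop("reference bundle directory not found: ", path)

  for (f in c("registry.json", "taxa.json"))
    if (!file.exists(file.path(path, f)))
      stop("reference bundle: missing file ", f)
  registry <- load_registry(file.path(path, "registry.json"))
  taxa <- jsonlite::read_json(file.path(path, "taxa.json"), simplifyVector = FALSE)
  if (length(taxa$species) == 0L) stop("reference bundle: empty taxon list")

  meas <- read_bundle_csv(path, "measurements.csv",
    c("taxon", "morph", "character_id", "lo", "hi", "provenance", "as_printed"))
  desc <- read_bundle_csv(path, "description_ranges.csv",
    c("taxon", "morph", "character_id", "lo", "hi", "approx", "provenance", "as_printed"))
  states <- read_bundle_csv(path, "states.csv",
    c("taxon", "morph", "character_id", "state", "provenance"))
  morphs <- read_bundle_csv(path, "morphs.csv",
    c("taxon", "morph", "n_examined", "provenance"))
  if (nrow(meas) == 0L) stop("reference bundle: measurements.csv is empty")

  meas$approx <- "0"
  quant <- rbind(meas[, c("taxon", "morph", "character_id", "lo", "hi",
                          "approx", "provenance", "as_printed")],
                 desc[, c("taxon", "morph", "character_id", "lo", "hi",
                          "approx", "provenance", "as_printed")])
  quant$lo <- as.numeric(quant$lo)
  quant$hi <- as.numeric(quant$hi)
  quant$approx <- quant$approx == "1"
  quant$state <- NA_character_

  states$lo <- NA_real_; states$hi <- NA_real_
  states$approx <- FALSE; states$as_printed <- states$state
  prof <- rbind(quant,
                states[, c("taxon", "morph", "character_id", "lo", "hi",
                           "approx", "provenance", "as_printed", "state")])

  # sanity of the transcription itself
  bad_char <- setdiff(unique(prof$character_id), names(registry))
  if (length(bad_char))
    stop("reference bundle: unregistered character id(s): ",
         paste(bad_char, collapse = ", "))
  known_taxa <- vapply(taxa$species, `[[`, "", "taxon")
  bad_taxon <- setdiff(unique(prof$taxon), known_taxa)
  if (length(bad_taxon))
    stop("reference bundle: unknown taxon in profiles: ",
         paste(bad_taxon, collapse = ", "))
  key <- paste(prof$taxon, prof$morph, prof$character_id)
  if (anyDuplicated(key))
    stop("reference bundle: duplicated profile entry: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  mkey <- paste(morphs$taxon, morphs$morph)
  if (anyDuplicated(mkey))
    stop("reference bundle: duplicated (taxon, morph): ",
         paste(mkey[duplicated(mkey)], collapse = "; "))

  # genus- and taxon-level traits apply to every profile of the taxon
  genus_of <- vapply(taxa$species, `[[`, "", "genus")
  names(genus_of) <- known_taxa
  trait_rows <- list()
  add_trait <- function(taxon, morph, tr) {
    data.frame(taxon = taxon, morph = morph, character_id = tr$character_id,
               lo = as.numeric(tr$lo), hi = as.numeric(tr$hi), approx = FALSE,
               provenance = tr$provenance %||% "trait",
               as_printed = paste0(tr$lo, "–", tr$hi),
               state = NA_character_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(morphs))) {
    tx <- morphs$taxon[i]; mo <- morphs$morph[i]
    traits <- c(taxa$genus_traits[[genus_of[[tx]]]] %||% list(),
                taxa$taxon_traits[[tx]] %||% list())
    for (tr in traits) {
      if (!is.null(tr$morphs) && !mo %in% unlist(tr$morphs)) next
      if (any(prof$taxon == tx & prof$morph == mo &
              prof$character_id == tr$character_id)) next
      trait_rows[[length(trait_rows) + 1L]] <- add_trait(tx, mo, tr)
    }
  }
  if (length(trait_rows)) prof <- rbind(prof, do.call(rbind, trait_rows))

  if (layer == "curated") {
    cur <- read_bundle_csv(path, "curation.csv",
      c("taxon", "morph", "character_id", "action", "lo", "hi", "justification"))
    for (i in seq_len(nrow(cur))) {
      sel <- prof$taxon == cur$taxon[i] & prof$morph == cur$morph[i] &
             prof$character_id == cur$character_id[i]
      if (!any(sel))
        stop("curation entry refers to absent profile entry: ",
             cur$taxon[i], "/", cur$morph[i], "/", cur$character_id[i])
      if (cur$action[i] == "drop") {
        prof <- prof[!sel, ]
      } else if (cur$action[i] == "replace") {
        prof$lo[sel] <- as.numeric(cur$lo[i])
        prof$hi[sel] <- as.numeric(cur$hi[i])
      } else stop("curation: unknown action '", cur$action[i], "'")
    }
  }

  # expand "about x" records into closed intervals
  ab <- prof$approx & !is.na(prof$lo)
  prof$lo[ab] <- prof$lo[ab] * (1 - about_tolerance)
  prof$hi[ab] <- prof$hi[ab] * (1 + about_tolerance)

  kinds <- vapply(registry, function(ch) ch$kind, character(1))
  prof$kind <- unname(kinds[prof$character_id])
  # radix: byte-wise, locale-independent ordering
  ord <- order(prof$taxon, prof$morph, prof$character_id, method = "radix")
  prof <- prof[ord, ]
  rownames(prof) <- NULL

  morphs$n_examined <- as.integer(morphs$n_examined)

  raw_files <- c("registry.json", "taxa.json", "measurements.csv",
                 "description_ranges.csv", "states.csv", "morphs.csv",
                 "curation.csv", "key_curation.json",
                 file.path("keys", list.files(file.path(path, "keys"), "[.]json$")))
  raw <- lapply(raw_files, function(f)
    readChar(file.path(path, f), file.size(file.path(path, f)), useBytes = TRUE))
  names(raw) <- raw_files

  structure(list(registry = registry, taxa = taxa, profiles = prof,
                 morphs = morphs,
                 material_counts = taxa$material_counts,
                 layer = layer, about_tolerance = about_tolerance,
                 path = path, raw = raw),
            class = "myz_dataset")
}

#' Re-serialize a loaded reference bundle
#'
#' Writes the dataset's source files back to a directory, byte-identically to
#' the bundle they were loaded from, so that \code{load_reference} composed
#' with \code{write_reference} is the identity on the transcription.
#'
#' @param ds A \code{myz_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_reference <- function(ds, dir) {
  stopifnot(inherits(ds, "myz_dataset"))
  dir.create(file.path(dir, "keys"), recursive = TRUE, showWarnings = FALSE)
  for (f in names(ds$raw)) {
    con <- file(file.path(dir, f), "wb")
    writeChar(ds$raw[[f]], con, eos = NULL, useBytes = TRUE)
    close(con)
  }
  invisible(dir)
}

#' @export
print.myz_dataset <- function(x, ...) {
  cat("myz_dataset (", x$layer, " layer): ",
      nrow(x$morphs), " profiles, ", nrow(x$profiles), " profile entries, ",
      length(x$taxa$species), " taxa\n", sep = "")
  invisible(x)
}

profile_rows <- function(ds, taxon, morph) {
  ds$profiles[ds$profiles$taxon == taxon & ds$profiles$morph == morph, ]
}

has_profile <- function(ds, taxon, morph) {
  any(ds$morphs$taxon == taxon & ds$morphs$morph == morph)
}

#' Query one reference value
#'
#' Returns the transcribed interval (for quantitative characters) or state
#' token (for categorical ones) for a given taxon, morph and character.
#'
#' @param ds A \code{myz_dataset}.
#' @param taxon Species epithet (e.g. \code{"oezdemirae"}).
#' @param morph One of fundatrix, aptera, alata, ovipara, male.
#' @param character_id Registered character id.
#' @return Numeric \code{c(lo, hi)} or a state string.
#' @export
query_range <- function(ds, taxon, morph, character_id) {
  stopifnot(inherits(ds, "myz_dataset"))
  known <- vapply(ds$taxa$species, `[[`, "", "taxon")
  if (!taxon %in% known)
    stop("unknown taxon '", taxon, "' (known: ", paste(known, collapse = ", "), ")")
  if (!has_profile(ds, taxon, morph)) {
    avail <- ds$morphs$morph[ds$morphs$taxon == taxon]
    stop("no ", morph, " profile for ", taxon,
         " (described morphs: ", paste(avail, collapse = ", "), ")")
  }
  if (!character_id %in% names(ds$registry))
    stop("unknown character id '", character_id, "'")
  row <- ds$profiles[ds$profiles$taxon == taxon & ds$profiles$morph == morph &
                     ds$profiles$character_id == character_id, ]
  if (nrow(row) == 0L)
    stop("character ", character_id, " not recorded for ", taxon, " ", morph)
  if (!is.na(row$state[1])) row$state[1] else c(lo = row$lo[1], hi = row$hi[1])
}

#' Species of one genus present in the dataset
#'
#' @param ds A \code{myz_dataset}.
#' @param genus Genus name (e.g. \code{"Myzaphis"}).
#' @return Character vector of species epithets.
#' @export
genus_species <- function(ds, genus) {
  sp <- ds$taxa$species
  vapply(sp, `[[`, "", "taxon")[vapply(sp, `[[`, "", "genus") == genus]
}
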