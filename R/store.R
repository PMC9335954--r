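#' Open (or create) a record store
#'
#' A record store keeps, per patient, an append-only history of saved
#' phenotype records: one subdirectory per patient, one canonical-JSON file
#' per record version, named by the zero-padded version number.  Records are
#' immutable once written; each save appends a full snapshot at version
#' `latest + 1`.
#'
#' @param dir Backing directory; created if missing.
#' @return A `record_store` object.
#' @export
record_store <- function(dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop(sprintf("cannot create store directory '%s'", dir))
  }
  structure(list(dir = normalizePath(dir)), class = "record_store")
}

patient_dir <- function(store, patient_id) file.path(store$dir, patient_id)

record_path <- function(store, patient_id, version) {
  file.path(patient_dir(store, patient_id), sprintf("%06d.json", version))
}

record_versions <- function(store, patient_id) {
  d <- patient_dir(store, patient_id)
  if (!dir.exists(d)) return(integer(0))
  files <- list.files(d, pattern = "^[0-9]{6}\\.json$")
  sort(as.integer(sub("\\.json$", "", files)))
}

#' Save a cart as a new record version
#'
#' Appends a full snapshot of the cart to the patient's history at version
#' `latest + 1` (1 for the first save).  Snapshot-per-save semantics mean the
#' latest record always shows the complete cross-encounter term set; the
#' encounter-level changes are still recoverable via [record_history()].
#'
#' The cart is expected to be free of blocking validation issues (see
#' [validate_cart()]); structural duplicates are rejected here.  Concurrency
#' is handled optimistically: a caller that read version `n` can pass
#' `expected_version = n + 1`; if another writer has taken that slot in the
#' meantime the save fails with a conflict error — the last writer never
#' silently wins.
#'
#' @param store A [record_store()].
#' @param cart An [annotation_cart()].
#' @param now Save timestamp (POSIXct or ISO 8601 string).
#' @param expected_version Optional version this save expects to create; a
#'   collision with an existing version is a conflict error.
#' @return The saved `phenotype_record`.
#' @export
save_record <- function(store, cart, now = Sys.time(), expected_version = NULL) {
  stopifnot(inherits(store, "record_store"), inherits(cart, "annotation_cart"))
  if (anyDuplicated(cart$items$term_id)) {
    stop("cart contains duplicate term ids; refusing to save")
  }
  versions <- record_versions(store, cart$patient_id)
  version <- expected_version %||% if (length(versions)) max(versions) + 1L else 1L
  if (version %in% versions) {
    stop(sprintf("version conflict: record %d for patient '%s' already exists",
                 version, cart$patient_id))
  }
  ont_version <- if (nrow(cart$items)) cart$items$ontology_version[nrow(cart$items)] else ""

  record <- structure(
    list(patient_id = cart$patient_id,
         record_version = version,
         saved_at = iso_utc(now),
         ontology_version = ont_version,
         annotations = cart$items),
    class = "phenotype_record"
  )

  d <- patient_dir(store, cart$patient_id)
  if (!dir.exists(d) && !dir.create(d, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create patient directory '%s'", d))
  }
  path <- record_path(store, cart$patient_id, version)
  if (file.exists(path)) {
    stop(sprintf("version conflict: record %d for patient '%s' already exists",
                 version, cart$patient_id))
  }
  writeLines(serialize_record(record), path, useBytes = TRUE)
  record
}

#' Load a saved record
#'
#' @inheritParams save_record
#' @param patient_id Patient identifier.
#' @param version Record version to load; `NULL` (default) loads the latest.
#' @return A `phenotype_record`.
#' @export
load_record <- function(store, patient_id, version = NULL) {
  stopifnot(inherits(store, "record_store"))
  versions <- record_versions(store, patient_id)
  if (!length(versions)) stop(sprintf("no records for patient '%s'", patient_id))
  if (is.null(version)) version <- max(versions)
  if (!version %in% versions) {
    stop(sprintf("no record version %d for patient '%s'", version, patient_id))
  }
  payload <- paste(readLines(record_path(store, patient_id, version), warn = FALSE),
                   collapse = "\n")
  parse_record(payload)
}

#' Per-patient save history
#'
#' One entry per saved version, chronologically ordered, each with the
#' change set relative to the previous version (the first version diffs
#' against an empty set, so everything counts as added).
#'
#' @inheritParams load_record
#' @return A list of class `record_history`; each element has
#'   `record_version`, `saved_at`, `term_count` and `diff` (a
#'   [diff_annotations()] result).
#' @export
record_history <- function(store, patient_id) {
  versions <- record_versions(store, patient_id)
  if (!length(versions)) stop(sprintf("no records for patient '%s'", patient_id))
  prev <- empty_cart_items()
  out <- vector("list", length(versions))
  for (k in seq_along(versions)) {
    rec <- load_record(store, patient_id, versions[k])
    out[[k]] <- list(record_version = rec$record_version,
                     saved_at = rec$saved_at,
                     term_count = nrow(rec$annotations),
                     diff = diff_annotations(prev, rec$annotations))
    prev <- rec$annotations
  }
  structure(out, class = "record_history")
}

#' @export
print.record_history <- function(x, ...) {
  for (e in x) {
    cat(sprintf("v%d  %s  %d term(s)  (+%d -%d ~%d)\n",
                e$record_version, e$saved_at, e$term_count,
                length(e$diff$added), length(e$diff$removed), length(e$diff$modified)))
  }
  invisible(x)
}

#' Serialize a record as canonical JSON
#'
#' The canonical payload is the persistence and interchange format: UTF-8,
#' keys sorted lexicographically at every level, no insignificant whitespace.
#' Canonical form makes byte equality equivalent to structural equality and
#' makes `serialize -> parse -> serialize` a fixpoint.
#'
#' Schema (`schema_version` `"1.0"`): top-level keys `ontology_version`,
#' `patient_id`, `record_version`, `saved_at`, `schema_version`, `terms`;
#' each element of `terms` has keys `added_at`, `comment` (JSON `null` when
#' absent), `id`, `name`, `negated`.  The `terms` array preserves cart
#' insertion order.
#'
#' @param record A `phenotype_record`.
#' @return A single JSON string.
#' @export
serialize_record <- function(record) {
  stopifnot(inherits(record, "phenotype_record"))
  items <- record$annotations
  terms <- lapply(seq_len(nrow(items)), function(i) {
    list(added_at = items$added_at[i],
         comment = items$comment[i],   # NA -> null
         id = items$term_id[i],
         name = items$term_name[i],
         negated = items$negated[i])
  })
  payload <- list(
    ontology_version = record$ontology_version,
    patient_id = record$patient_id,
    record_version = as.integer(record$record_version),
    saved_at = record$saved_at,
    schema_version = "1.0",
    terms = terms
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null", digits = NA))
}

#' Parse a canonical JSON record payload
#'
#' Inverse of [serialize_record()].  The payload must declare
#' `schema_version` `"1.0"`; a missing required key is a schema error naming
#' the key.
#'
#' @param payload JSON text.
#' @return A `phenotype_record`.
#' @export
parse_record <- function(payload) {
  x <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  req <- c("ontology_version", "patient_id", "record_version", "saved_at",
           "schema_version", "terms")
  for (k in req) {
    if (!k %in% names(x)) stop(sprintf("record payload is missing required key '%s'", k))
  }
  if (!identical(x$schema_version, "1.0")) {
    stop(sprintf("unsupported record schema_version '%s'", x$schema_version))
  }
  term_req <- c("added_at", "comment", "id", "name", "negated")
  rows <- lapply(x$terms, function(t) {
    for (k in term_req) {
      if (!k %in% names(t)) stop(sprintf("record term entry is missing required key '%s'", k))
    }
    data.frame(term_id = t$id, term_name = t$name,
               negated = isTRUE(t$negated),
               comment = if (is.null(t$comment)) NA_character_ else t$comment,
               added_at = t$added_at,
               ontology_version = x$ontology_version,
               stringsAsFactors = FALSE)
  })
  items <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_cart_items()
  }
  structure(
    list(patient_id = x$patient_id,
         record_version = as.integer(x$record_version),
         saved_at = x$saved_at,
         ontology_version = x$ontology_version,
         annotations = items),
    class = "phenotype_record"
  )
}

#' @export
print.phenotype_record <- function(x, ...) {
  cat(sprintf("<phenotype_record> patient '%s' v%d saved %s (ontology '%s'), %d term(s)\n",
              x$patient_id, x$record_version, x$saved_at, x$ontology_version,
              nrow(x$annotations)))
  invisible(x)
}
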