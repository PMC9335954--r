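#' Create an empty annotation cart
#'
#' The cart is the working set of phenotype annotations for one patient,
#' assembled term by term before being saved as a record.  It behaves like a
#' shopping cart: terms can be added (with a negation flag and a free-text
#' comment), updated in place, and removed; order is insertion order and no
#' term appears twice.
#'
#' @param patient_id Opaque patient identifier.
#' @return An `annotation_cart` object.
#' @export
annotation_cart <- function(patient_id) {
  stopifnot(is.character(patient_id), length(patient_id) == 1, nzchar(patient_id))
  structure(list(patient_id = patient_id, items = empty_cart_items()),
            class = "annotation_cart")
}

empty_cart_items <- function() {
  data.frame(term_id = character(0), term_name = character(0),
             negated = logical(0), comment = character(0),
             added_at = character(0), ontology_version = character(0),
             stringsAsFactors = FALSE)
}

#' Add (or update) a phenotype term in a cart
#'
#' The term's name and the ontology version are snapshotted at add time, so a
#' saved record remains interpretable even after the ontology moves on.
#' Alternate ids are accepted and stored under their primary id.  Adding a
#' term that is already in the cart updates its `negated`/`comment` fields in
#' place (position preserved) and refreshes `added_at`.
#'
#' Obsolete ids are rejected; when a unique replacement exists the error
#' message suggests it, but a replacement is never substituted silently.
#'
#' @param cart An [annotation_cart()].
#' @param ontology A `phenotype_ontology`.
#' @param id Term id to add (primary or alternate).
#' @param negated Is the phenotype explicitly absent in the patient?
#' @param comment Optional free-text comment (e.g. linked genes); carries no
#'   structural meaning.
#' @param now Timestamp of the addition (POSIXct or ISO 8601 string);
#'   injectable for reproducibility.
#' @return The updated cart.
#' @export
add_term <- function(cart, ontology, id, negated = FALSE, comment = NULL,
                     now = Sys.time()) {
  stopifnot(inherits(cart, "annotation_cart"))
  r <- resolve_term(ontology, id)
  if (r$status == "unknown") {
    stop(sprintf("unknown term id '%s'", id))
  }
  if (r$status == "obsolete_replaced") {
    stop(sprintf("term '%s' is obsolete; consider its replacement '%s'",
                 id, r$primary))
  }
  if (r$status == "obsolete_unreplaced") {
    stop(sprintf("term '%s' is obsolete and has no unique replacement", id))
  }
  pid <- r$primary
  row <- data.frame(
    term_id = pid,
    term_name = ontology$terms[[pid]]$name,
    negated = isTRUE(negated),
    comment = if (is.null(comment) || is.na(comment)) NA_character_ else as.character(comment),
    added_at = iso_utc(now),
    ontology_version = ontology$version_label,
    stringsAsFactors = FALSE
  )
  i <- match(pid, cart$items$term_id)
  if (is.na(i)) {
    cart$items <- rbind(cart$items, row, make.row.names = FALSE)
  } else {
    cart$items[i, ] <- row
  }
  cart
}

#' Remove a term from a cart
#'
#' Removing an id that is not in the cart is a no-op that signals a warning.
#' Alternate ids are resolved before matching.
#'
#' @inheritParams add_term
#' @return The updated cart.
#' @export
remove_term <- function(cart, id, ontology = NULL) {
  stopifnot(inherits(cart, "annotation_cart"))
  target <- id
  if (!is.null(ontology)) {
    r <- resolve_term(ontology, id)
    if (r$status %in% c("primary", "alt")) target <- r$primary
  }
  i <- match(target, cart$items$term_id)
  if (is.na(i)) {
    warning(sprintf("term '%s' is not in the cart for patient '%s'",
                    id, cart$patient_id))
    return(cart)
  }
  cart$items <- cart$items[-i, , drop = FALSE]
  rownames(cart$items) <- NULL
  cart
}

#' Validate a cart against the ontology
#'
#' Quality gate before saving.  Issues of kind `unknown`, `obsolete` and
#' `duplicate` are blocking; `redundant_ancestor` — the cart contains both a
#' term and one of its proper ancestors — is a warning only, since choosing a
#' less specific term alongside a more specific one is a legitimate clinical
#' decision.
#'
#' @inheritParams add_term
#' @return Data frame with columns `term_id`, `kind`, `message`, sorted by
#'   `(kind, term_id)`; zero rows when the cart is clean.
#' @export
validate_cart <- function(cart, ontology) {
  stopifnot(inherits(cart, "annotation_cart"))
  issues <- list()
  push <- function(term_id, kind, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      term_id = term_id, kind = kind, message = message, stringsAsFactors = FALSE)
  }
  ids <- cart$items$term_id
  for (dup in unique(ids[duplicated(ids)])) {
    push(dup, "duplicate", sprintf("term '%s' appears more than once", dup))
  }
  live <- character(0)
  for (id in unique(ids)) {
    r <- resolve_term(ontology, id)
    if (r$status == "unknown") {
      push(id, "unknown", sprintf("term '%s' is not in the ontology", id))
    } else if (r$status %in% c("obsolete_replaced", "obsolete_unreplaced")) {
      push(id, "obsolete", sprintf("term '%s' is obsolete", id))
    } else {
      live <- c(live, r$primary)
    }
  }
  for (id in live) {
    anc <- term_ancestors(ontology, id, include_self = FALSE)
    for (a in intersect(anc, live)) {
      push(a, "redundant_ancestor",
           sprintf("term '%s' is an ancestor of '%s', also in the cart", a, id))
    }
  }
  out <- if (length(issues)) {
    do.call(rbind, c(issues, list(make.row.names = FALSE)))
  } else {
    data.frame(term_id = character(0), kind = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out[order(out$kind, out$term_id), , drop = FALSE]
}

blocking_issues <- function(issues) {
  issues[issues$kind %in% c("unknown", "obsolete", "duplicate"), , drop = FALSE]
}

#' Difference between two annotation sets
#'
#' Computes which terms were added, removed, or modified between two carts
#' (or their item tables).  A term is *modified* when it is present in both
#' with a different negation flag or comment; `added_at` timestamps are
#' ignored.  The three sets are pairwise disjoint.
#'
#' @param old,new Carts or cart item data frames.
#' @return List with sorted character vectors `added`, `removed`, `modified`.
#' @export
diff_annotations <- function(old, new) {
  old <- as_cart_items(old)
  new <- as_cart_items(new)
  added <- setdiff(new$term_id, old$term_id)
  removed <- setdiff(old$term_id, new$term_id)
  common <- intersect(old$term_id, new$term_id)
  modified <- Filter(function(id) {
    i <- match(id, old$term_id); j <- match(id, new$term_id)
    !identical(old$negated[i], new$negated[j]) ||
      !identical(old$comment[i], new$comment[j])
  }, common)
  list(added = sort(added), removed = sort(removed),
       modified = sort(as.character(modified)))
}

as_cart_items <- function(x) {
  if (inherits(x, "annotation_cart")) return(x$items)
  if (inherits(x, "phenotype_record")) return(x$annotations)
  stopifnot(is.data.frame(x))
  x
}

#' @export
print.annotation_cart <- function(x, ...) {
  cat(sprintf("<annotation_cart> patient '%s', %d term(s)\n",
              x$patient_id, nrow(x$items)))
  if (nrow(x$items)) {
    for (i in seq_len(nrow(x$items))) {
      cat(sprintf("  %s  %s%s%s\n", x$items$term_id[i], x$items$term_name[i],
                  if (x$items$negated[i]) "  [negated]" else "",
                  if (!is.na(x$items$comment[i])) paste0("  # ", x$items$comment[i]) else ""))
    }
  }
  invisible(x)
}
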