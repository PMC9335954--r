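#' Resolve a term identifier to its current primary term
#'
#' Legacy identifiers accumulate in clinical records as an ontology evolves:
#' terms get merged (the old id survives as an `alt_id`) or obsoleted (with
#' an optional `replaced_by` pointer).  `resolve_term()` maps any identifier
#' to the current primary term where possible and reports how it got there.
#'
#' @param ontology A `phenotype_ontology` from [parse_obo()].
#' @param id A term identifier (CURIE text, e.g. `"HP:0001250"`).
#' @return A list with `primary` (the resolved id; echoes the input when it
#'   cannot be resolved) and `status`, one of `"primary"`, `"alt"`,
#'   `"obsolete_replaced"` (exactly one `replaced_by`), `"obsolete_unreplaced"`
#'   (none, or several — a replacement is never guessed) or `"unknown"`.
#'   Resolution is idempotent: resolving a resolved primary id returns status
#'   `"primary"`.
#' @examples
#' ont <- parse_obo(toy_ontology_obo())
#' resolve_term(ont, "T:0000099")  # alt id of Syndactyly
#' resolve_term(ont, "T:0000030")  # obsolete, replaced by Seizure
#' @export
resolve_term <- function(ontology, id) {
  stopifnot(inherits(ontology, "phenotype_ontology"), is.character(id), length(id) == 1)
  if (id %in% names(ontology$terms)) {
    t <- ontology$terms[[id]]
    if (!t$obsolete) return(list(primary = id, status = "primary"))
    if (length(t$replaced_by) == 1) {
      return(list(primary = t$replaced_by, status = "obsolete_replaced"))
    }
    return(list(primary = id, status = "obsolete_unreplaced"))
  }
  if (id %in% names(ontology$alt_index)) {
    return(list(primary = unname(ontology$alt_index[[id]]), status = "alt"))
  }
  list(primary = id, status = "unknown")
}

# Resolve for traversal: unknown or obsolete ids are lookup errors; alt ids
# and replaced obsolete ids are followed to their primary term.
resolve_live <- function(ontology, id, follow_obsolete = FALSE) {
  r <- resolve_term(ontology, id)
  if (r$status == "unknown") stop(sprintf("unknown term id '%s'", id))
  if (r$status == "obsolete_unreplaced") {
    stop(sprintf("term '%s' is obsolete with no unique replacement", id))
  }
  if (r$status == "obsolete_replaced" && !follow_obsolete) {
    stop(sprintf("term '%s' is obsolete (replaced by '%s')", id, r$primary))
  }
  r$primary
}

#' Transitive ancestors of a term
#'
#' Transitive closure of the `is_a` relation, upward.  Obsolete terms take no
#' part in the hierarchy and raise a lookup error; alternate ids are resolved
#' to their primary term first.
#'
#' @inheritParams resolve_term
#' @param include_self Should `id` itself be included?
#' @return Sorted character vector of term ids.
#' @seealso [term_descendants()] — the exact mirror: `s` is an ancestor of `t`
#'   iff `t` is a descendant of `s`.
#' @examples
#' ont <- parse_obo(toy_ontology_obo())
#' term_ancestors(ont, "T:0000021")  # Febrile seizure -> Seizure -> root
#' @export
term_ancestors <- function(ontology, id, include_self = FALSE) {
  traverse(ontology, id, include_self, up = TRUE)
}

#' Transitive descendants of a term
#'
#' @inheritParams term_ancestors
#' @return Sorted character vector of term ids.
#' @export
term_descendants <- function(ontology, id, include_self = FALSE) {
  traverse(ontology, id, include_self, up = FALSE)
}

traverse <- function(ontology, id, include_self, up) {
  pid <- resolve_live(ontology, id)
  live <- function(ids) {
    ids[vapply(ids, function(i) {
      i %in% names(ontology$terms) && !ontology$terms[[i]]$obsolete
    }, logical(1))]
  }
  step <- if (up) {
    function(i) live(ontology$terms[[i]]$parents)
  } else {
    function(i) ontology$children_index[[i]] %||% character(0)
  }
  seen <- character(0)
  queue <- step(pid)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, step(t))
  }
  if (include_self) seen <- c(seen, pid)
  sort(unique(seen))
}

#' Detail view of one term
#'
#' Everything the "Details" pane of a term browser shows: definition,
#' synonyms, direct superclasses and subclasses (one step only, so the user
#' can navigate to a more or less specific term), and the genes directly
#' associated with the term.  Gene associations are *not* propagated from
#' descendants here; propagated annotation is the business of
#' [build_gene_corpus()].
#'
#' @inheritParams resolve_term
#' @param genes Optional data frame of gene associations from
#'   [load_gene_associations()].
#' @return A `term_details` list: `id`, `name`, `definition`, `synonyms`
#'   (data frame), `superclasses` and `subclasses` (data frames with columns
#'   `term_id`, `name`, sorted by `term_id`), and `genes` (deduplicated,
#'   sorted character vector).
#' @export
term_details <- function(ontology, id, genes = NULL) {
  pid <- resolve_live(ontology, id)
  term <- ontology$terms[[pid]]

  rel_df <- function(ids) {
    ids <- sort(unique(ids))
    data.frame(
      term_id = ids,
      name = vapply(ids, function(i) ontology$terms[[i]]$name, character(1),
                    USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  live_parents <- term$parents[vapply(term$parents, function(p) {
    p %in% names(ontology$terms) && !ontology$terms[[p]]$obsolete
  }, logical(1))]

  gsyms <- character(0)
  if (!is.null(genes) && nrow(genes)) {
    gsyms <- sort(unique(genes$gene_symbol[genes$term_id == pid]))
  }

  structure(
    list(id = pid, name = term$name, definition = term$definition,
         synonyms = term$synonyms,
         superclasses = rel_df(live_parents),
         subclasses = rel_df(ontology$children_index[[pid]] %||% character(0)),
         genes = gsyms),
    class = "term_details"
  )
}

#' @export
print.term_details <- function(x, ...) {
  cat(sprintf("%s  %s\n", x$id, x$name))
  if (!is.na(x$definition)) cat("  ", x$definition, "\n", sep = "")
  if (nrow(x$synonyms)) {
    cat("  synonyms: ",
        paste(sprintf("%s (%s)", x$synonyms$label, x$synonyms$scope), collapse = "; "),
        "\n", sep = "")
  }
  fmt <- function(df) if (nrow(df)) paste(sprintf("%s %s", df$term_id, df$name), collapse = "; ") else "-"
  cat("  superclasses: ", fmt(x$superclasses), "\n", sep = "")
  cat("  subclasses:   ", fmt(x$subclasses), "\n", sep = "")
  cat("  genes: ", if (length(x$genes)) paste(x$genes, collapse = ", ") else "-", "\n", sep = "")
  invisible(x)
}

#' Autocomplete-style term search
#'
#' Case-insensitive search over the names and synonyms of non-obsolete terms,
#' on whitespace-normalized labels.  Hits are ranked in four tiers — name
#' prefix, synonym prefix, name substring, synonym substring — with shorter
#' matched labels first within a tier, then term id.  Each term is reported
#' once, at its best tier.
#'
#' @inheritParams resolve_term
#' @param query Query text; an empty or whitespace-only query returns zero
#'   hits (not an error).
#' @param limit Maximum number of hits (>= 1).
#' @return Data frame with columns `term_id`, `matched_label`, `match_kind`
#'   (one of `name_prefix`, `synonym_prefix`, `name_substring`,
#'   `synonym_substring`) and `rank` (consecutive from 1).
#' @examples
#' ont <- parse_obo(toy_ontology_obo())
#' search_terms(ont, "seizure")
#' @export
search_terms <- function(ontology, query, limit = 10L) {
  stopifnot(limit >= 1)
  empty <- data.frame(term_id = character(0), matched_label = character(0),
                      match_kind = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  q <- normalize_label(query)
  if (!nzchar(q)) return(empty)

  labs <- label_table(ontology)
  norm <- labs$norm
  is_sub <- grepl(q, norm, fixed = TRUE)
  if (!any(is_sub)) return(empty)
  is_pre <- startsWith(norm, q)
  tier <- ifelse(is_pre,
                 ifelse(labs$is_name, 1L, 2L),
                 ifelse(labs$is_name, 3L, 4L))
  tier[!is_sub] <- NA_integer_

  hits <- labs[!is.na(tier), , drop = FALSE]
  hits$tier <- tier[!is.na(tier)]
  # best label per term: tier, then label length, then label, for determinism
  o <- order(hits$tier, nchar(hits$label), hits$label, hits$term_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$term_id), , drop = FALSE]
  # rank terms: tier, matched-label length, term id
  o <- order(hits$tier, nchar(hits$label), hits$term_id)
  hits <- hits[o, , drop = FALSE]
  hits <- utils::head(hits, limit)

  kinds <- c("name_prefix", "synonym_prefix", "name_substring", "synonym_substring")
  data.frame(term_id = hits$term_id,
             matched_label = hits$label,
             match_kind = kinds[hits$tier],
             rank = seq_len(nrow(hits)),
             stringsAsFactors = FALSE, row.names = NULL)
}

label_table <- function(ontology) {
  rows <- lapply(ontology$terms, function(t) {
    if (t$obsolete) return(NULL)
    labels <- c(t$name, t$synonyms$label)
    data.frame(term_id = t$id, label = labels,
               is_name = c(TRUE, rep(FALSE, length(labels) - 1L)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(term_id = character(0), label = character(0),
               is_name = logical(0), stringsAsFactors = FALSE)
  }
  out$norm <- normalize_label(out$label)
  out
}

#' Load gene-phenotype associations from TSV
#'
#' Reads a three-column table (`term_id`, `gene_symbol`, `gene_id`) in the
#' style of the HPO `genes_to_phenotype` download.  A header line is detected
#' by its first field not being a CURIE.  Term ids are passed through
#' [resolve_term()]: alternate and replaced-obsolete ids are stored under
#' their primary term; rows whose id cannot be resolved are dropped with one
#' summary warning.
#'
#' @param x Path, single string, or character vector of TSV lines.
#' @inheritParams resolve_term
#' @return Data frame with columns `term_id` (resolved primary id),
#'   `gene_symbol`, `gene_id`.
#' @export
load_gene_associations <- function(x, ontology) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(term_id = character(0), gene_symbol = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (!is_curie(fields[[1]][1])) 2L else 1L
  rows <- vector("list", length(lines))
  dropped <- 0L
  data_idx <- if (start > length(lines)) integer(0) else start:length(lines)
  for (i in data_idx) {
    f <- fields[[i]]
    if (length(f) == 2L) f <- c(f, "")  # empty trailing gene_id
    if (length(f) != 3L) {
      stop(sprintf("malformed gene association row at line %d: expected 3 fields, got %d",
                   i, length(fields[[i]])))
    }
    r <- resolve_term(ontology, trimws(f[1]))
    if (r$status == "unknown") { dropped <- dropped + 1L; next }
    rows[[i]] <- data.frame(term_id = r$primary, gene_symbol = trimws(f[2]),
                            gene_id = trimws(f[3]), stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(sprintf("%d association row(s) referenced unknown term ids and were dropped",
                    dropped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), gene_symbol = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
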