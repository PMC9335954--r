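#' Parse an OBO-format ontology
#'
#' Reads a flat-file ontology in OBO format (the dialect used by the Human
#' Phenotype Ontology) into an indexed in-memory directed acyclic graph.
#' Only `[Term]` stanzas are interpreted; recognized tags are `id`, `name`,
#' `def`, `synonym` (with its scope keyword), `is_a`, `alt_id`,
#' `is_obsolete`, `replaced_by` and `consider`, plus the header tag
#' `data-version`.  Every other tag or stanza type is ignored, so a full
#' `hp.obo` release parses cleanly.
#'
#' Parsing is order-insensitive: shuffling `[Term]` stanzas yields a
#' structurally identical ontology.  The `is_a` graph over non-obsolete terms
#' is checked for cycles at parse time, so downstream traversals may assume
#' acyclicity.
#'
#' @param x Path to an OBO file, a single string of OBO text, or a character
#'   vector of lines.
#' @return An object of class `phenotype_ontology`: a list with
#'   `version_label` (from the `data-version` header, `""` if absent),
#'   `terms` (named list of term records), `alt_index` (named character
#'   vector mapping alternate ids to primary ids) and `children_index`
#'   (named list inverting the `is_a` relation among non-obsolete terms).
#'   Each term record has fields `id`, `name`, `definition` (`NA` if absent),
#'   `synonyms` (data frame with columns `label`, `scope`), `alt_ids`,
#'   `parents`, `obsolete`, `replaced_by` and `consider`.
#' @examples
#' ont <- parse_obo(toy_ontology_obo())
#' ont$version_label
#' sum(!vapply(ont$terms, `[[`, logical(1), "obsolete"))
#' @export
parse_obo <- function(x) {
  lines <- read_text_lines(x)
  lines <- sub("\r$", "", lines)

  stanza_heads <- grep("^\\[", lines)
  header <- if (length(stanza_heads)) lines[seq_len(stanza_heads[1] - 1L)] else lines
  dv <- grep("^data-version:", header, value = TRUE)
  version_label <- if (length(dv)) trimws(sub("^data-version:", "", dv[1])) else ""

  terms <- list()
  ordinal <- 0L
  bounds <- c(stanza_heads, length(lines) + 1L)
  for (k in seq_along(stanza_heads)) {
    head_line <- lines[stanza_heads[k]]
    if (trimws(head_line) != "[Term]") next
    ordinal <- ordinal + 1L
    body <- lines[seq(stanza_heads[k] + 1L, bounds[k + 1L] - 1L)]
    term <- parse_term_stanza(body, ordinal)
    if (term$id %in% names(terms)) {
      stop(sprintf("duplicate primary term id '%s' (term stanza %d)", term$id, ordinal))
    }
    terms[[term$id]] <- term
  }
  terms <- terms[order(names(terms))]

  ont <- structure(
    list(version_label = version_label, terms = terms,
         alt_index = character(0), children_index = list()),
    class = "phenotype_ontology"
  )
  ont$alt_index <- build_alt_index(terms)
  ont$children_index <- build_children_index(terms)
  check_acyclic(ont)
  ont
}

parse_term_stanza <- function(body, ordinal) {
  tag_lines <- grep("^[A-Za-z_-]+:", body, value = TRUE)
  tags <- sub("^([A-Za-z_-]+):.*$", "\\1", tag_lines)
  vals <- trimws(sub("^[A-Za-z_-]+:", "", tag_lines))

  get_all <- function(tag) vals[tags == tag]
  # id-valued tags may carry an OBO trailing comment: "T:1 ! Root"
  strip_comment <- function(v) trimws(sub("\\s+!.*$", "", v))

  ids <- strip_comment(get_all("id"))
  if (length(ids) == 0 || !nzchar(ids[1])) {
    stop(sprintf("term stanza %d is missing an id", ordinal))
  }
  id <- ids[1]

  obsolete <- any(tolower(strip_comment(get_all("is_obsolete"))) == "true")
  name <- trimws(get_all("name")[1] %||% NA_character_)
  if (!obsolete && (is.na(name) || !nzchar(name))) {
    stop(sprintf("non-obsolete term '%s' (stanza %d) has no name", id, ordinal))
  }

  defs <- get_all("def")
  definition <- if (length(defs)) extract_quoted(defs[1]) else NA_character_

  synonyms <- parse_synonyms(get_all("synonym"))
  parents <- unique(strip_comment(get_all("is_a")))
  parents <- parents[nzchar(parents)]

  list(
    id = id,
    name = if (is.na(name)) "" else name,
    definition = definition,
    synonyms = synonyms,
    alt_ids = unique(strip_comment(get_all("alt_id"))),
    parents = parents,
    obsolete = obsolete,
    replaced_by = unique(strip_comment(get_all("replaced_by"))),
    consider = unique(strip_comment(get_all("consider")))
  )
}

extract_quoted <- function(v) {
  m <- regmatches(v, regexpr('"(\\\\.|[^"\\\\])*"', v))
  if (!length(m)) return(trimws(v))
  inner <- substr(m, 2L, nchar(m) - 1L)
  gsub('\\\\(.)', "\\1", inner)
}

parse_synonyms <- function(vs) {
  scopes_known <- c("EXACT", "BROAD", "NARROW", "RELATED")
  labs <- character(0); scopes <- character(0)
  for (v in vs) {
    lab <- normalize_ws(extract_quoted(v))
    if (!nzchar(lab)) next
    rest <- sub('^[^"]*"(\\\\.|[^"\\\\])*"', "", v)
    first_word <- sub("^\\s*(\\S+).*$", "\\1", rest)
    scope <- if (first_word %in% scopes_known) tolower(first_word) else "related"
    labs <- c(labs, lab); scopes <- c(scopes, scope)
  }
  keep <- !duplicated(paste(labs, scopes))
  data.frame(label = labs[keep], scope = scopes[keep], stringsAsFactors = FALSE)
}

normalize_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

build_alt_index <- function(terms) {
  alt <- character(0)
  primary_ids <- names(terms)
  for (t in terms) {
    for (a in t$alt_ids) {
      if (a %in% primary_ids) {
        stop(sprintf("alt_id '%s' of term '%s' collides with a primary term id", a, t$id))
      }
      if (a %in% names(alt)) {
        stop(sprintf("alt_id '%s' is declared by both '%s' and '%s'", a, alt[[a]], t$id))
      }
      alt[[a]] <- t$id
    }
  }
  alt
}

build_children_index <- function(terms) {
  idx <- list()
  live <- names(terms)[!vapply(terms, `[[`, logical(1), "obsolete")]
  for (id in live) {
    for (p in terms[[id]]$parents) {
      if (p %in% live) idx[[p]] <- c(idx[[p]], id)
    }
  }
  if (!length(idx)) return(list())
  lapply(idx[order(names(idx))], function(v) sort(unique(v)))
}

# Kahn's algorithm over the non-obsolete is_a subgraph; on failure, walk the
# residual graph to report one concrete cycle.
check_acyclic <- function(ont) {
  live <- names(ont$terms)[!vapply(ont$terms, `[[`, logical(1), "obsolete")]
  parents <- lapply(ont$terms[live], function(t) intersect(t$parents, live))
  indeg <- vapply(parents, length, integer(1))  # edges child -> parent
  children <- ont$children_index
  queue <- names(indeg)[indeg == 0L]
  done <- 0L
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]; done <- done + 1L
    for (ch in children[[p]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(live)) {
    residual <- names(indeg)[indeg > 0L]
    cyc <- find_cycle(parents, residual)
    stop(sprintf("is_a cycle among non-obsolete terms: %s", paste(cyc, collapse = " -> ")))
  }
  invisible(TRUE)
}

find_cycle <- function(parents, residual) {
  node <- residual[1]
  path <- character(0)
  repeat {
    if (node %in% path) {
      i <- match(node, path)
      return(c(path[seq(i, length(path))], node))
    }
    path <- c(path, node)
    nxt <- intersect(parents[[node]], residual)
    node <- nxt[1]
  }
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  obs <- vapply(x$terms, `[[`, logical(1), "obsolete")
  cat(sprintf("<phenotype_ontology> %d terms (%d obsolete), %d alt ids, version '%s'\n",
              length(x$terms), sum(obs), length(x$alt_index), x$version_label))
  invisible(x)
}
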