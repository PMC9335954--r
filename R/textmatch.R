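# Dictionary-based concept extraction: the free-text comparison arm.
# Structured capture stores term ids directly; the legacy workflow pastes
# term labels into notes and recovers them later by dictionary matching.
# This module implements that recovery step (an Aho-Corasick automaton over
# term names and exact synonyms) plus reproducible copy-paste corruption
# operators, so the two workflows can be compared on the same note.

#' Build a dictionary index over an ontology's surface forms
#'
#' The dictionary holds the normalized (lowercase, whitespace-collapsed)
#' names of all non-obsolete terms plus their exact-scope synonyms — the same
#' normalization the autocomplete search uses.  Broad/narrow/related synonyms
#' are deliberately excluded to keep extraction conservative.  An
#' Aho-Corasick automaton over all forms supports simultaneous matching in a
#' single pass over the text.
#'
#' @param ontology A `phenotype_ontology`.
#' @return A `term_dictionary`: `entries` (named list mapping each normalized
#'   form to its sorted term ids — a form shared by several terms maps to all
#'   of them), `forms` (the form vector) and the automaton.
#' @export
build_term_dictionary <- function(ontology) {
  entries <- list()
  for (t in ontology$terms) {
    if (t$obsolete) next
    forms <- normalize_label(t$name)
    if (nrow(t$synonyms)) {
      forms <- c(forms, normalize_label(t$synonyms$label[t$synonyms$scope == "exact"]))
    }
    for (f in unique(forms[nzchar(forms)])) {
      entries[[f]] <- sort(unique(c(entries[[f]], t$id)))
    }
  }
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, forms = names(entries),
                 automaton = ac_build(names(entries))),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d surface form(s)\n", length(x$forms)))
  invisible(x)
}

# --- Aho-Corasick automaton -------------------------------------------------
# Classic goto/failure/output construction.  Nodes are integers (1 = root);
# children are named integer vectors keyed by single characters; `out` holds
# indices into the pattern vector.

ac_build <- function(patterns) {
  children <- list(integer(0))
  out <- list(integer(0))
  for (p in seq_along(patterns)) {
    node <- 1L
    for (ch in strsplit(patterns[p], "", fixed = TRUE)[[1]]) {
      nxt <- unname(children[[node]][ch])
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer(0)
        out[[length(children)]] <- integer(0)
        nxt <- length(children)
        children[[node]][[ch]] <- nxt
      }
      node <- nxt
    }
    out[[node]] <- c(out[[node]], p)
  }
  n <- length(children)
  fail <- rep(1L, n)
  queue <- unname(children[[1]])
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    for (ch in names(children[[u]])) {
      v <- children[[u]][[ch]]
      f <- fail[u]
      nxt <- NA_integer_
      repeat {
        nxt <- unname(children[[f]][ch])
        if (!is.na(nxt) && nxt != v) break
        if (f == 1L) { if (!is.na(nxt) && nxt == v) nxt <- NA_integer_; break }
        f <- fail[f]
      }
      fail[v] <- if (is.na(nxt)) 1L else nxt
      out[[v]] <- c(out[[v]], out[[fail[v]]])
      queue <- c(queue, v)
    }
  }
  list(children = children, fail = fail, out = out, plen = nchar(patterns))
}

# Scan `chars` (character vector, one element per character) and return all
# pattern occurrences as (pattern index, start, end), 1-based inclusive.
ac_scan <- function(ac, chars) {
  pat <- integer(0); s <- integer(0); e <- integer(0)
  state <- 1L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    repeat {
      nxt <- unname(ac$children[[state]][ch])
      if (!is.na(nxt)) { state <- nxt; break }
      if (state == 1L) break
      state <- ac$fail[state]
    }
    if (is.na(nxt)) state <- 1L
    hits <- ac$out[[state]]
    if (length(hits)) {
      pat <- c(pat, hits)
      e <- c(e, rep(i, length(hits)))
      s <- c(s, i - ac$plen[hits] + 1L)
    }
  }
  list(pattern = pat, start = s, end = e)
}

# --- Normalization with offset map ------------------------------------------
# Lowercase and collapse whitespace runs to single spaces while remembering,
# for every normalized character, the original character range it came from.
normalize_with_map <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_ws <- grepl("[[:space:]]", chars)
  out <- character(n); ostart <- integer(n); oend <- integer(n)
  k <- 0L; i <- 1L
  while (i <= n) {
    if (is_ws[i]) {
      j <- i
      while (j < n && is_ws[j + 1L]) j <- j + 1L
      k <- k + 1L; out[k] <- " "; ostart[k] <- i; oend[k] <- j
      i <- j + 1L
    } else {
      k <- k + 1L; out[k] <- tolower(chars[i]); ostart[k] <- i; oend[k] <- i
      i <- i + 1L
    }
  }
  idx <- seq_len(k)
  list(chars = out[idx], ostart = ostart[idx], oend = oend[idx])
}

empty_matches <- function() {
  data.frame(term_id = character(0), surface = character(0),
             start = integer(0), end = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Extract ontology terms from free text
#'
#' Case-insensitive dictionary matching on the whitespace-normalized
#' projection of the text, with offsets mapped back to the original text.
#' Matches are constrained to word boundaries (the characters adjacent to a
#' match, if any, must be non-alphanumeric, so "lim" never matches inside
#' "climb").  Overlaps are resolved greedily: the longest match wins, ties go
#' to the leftmost; a form shared by several terms emits one match per term
#' over the same span.
#'
#' There is no stemming, abbreviation expansion or negation detection:
#' truncated or misspelled mentions (e.g. "limb" pasted as "lim") are simply
#' missed, which is exactly the failure mode the structured-capture
#' comparison quantifies.
#'
#' @param index A [build_term_dictionary()] index.
#' @param text A single string.
#' @return Data frame of matches sorted by `start` (`term_id`, `surface` as
#'   it appeared in the text, `start`, `end` as 0-based half-open character
#'   offsets, and `label`, the dictionary form matched).  Matches are
#'   non-overlapping.
#' @export
extract_terms <- function(index, text) {
  stopifnot(inherits(index, "term_dictionary"),
            is.character(text), length(text) == 1)
  if (!nzchar(text) || !length(index$forms)) return(empty_matches())
  nm <- normalize_with_map(text)
  raw <- ac_scan(index$automaton, nm$chars)
  if (!length(raw$pattern)) return(empty_matches())

  len <- length(nm$chars)
  is_word <- grepl("[a-z0-9]", nm$chars)
  keep <- vapply(seq_along(raw$pattern), function(i) {
    s <- raw$start[i]; e <- raw$end[i]
    (s == 1L || !is_word[s - 1L]) && (e == len || !is_word[e + 1L])
  }, logical(1))
  if (!any(keep)) return(empty_matches())
  cand <- data.frame(pattern = raw$pattern[keep], start = raw$start[keep],
                     end = raw$end[keep])
  cand <- unique(cand)
  # longest first, then leftmost; greedy non-overlapping selection
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  chosen_s <- integer(0); chosen_e <- integer(0); chosen_p <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s <= chosen_e & e >= chosen_s)) {
      chosen_s <- c(chosen_s, s); chosen_e <- c(chosen_e, e)
      chosen_p <- c(chosen_p, cand$pattern[i])
    }
  }
  o <- order(chosen_s)
  rows <- lapply(o, function(i) {
    form <- index$forms[chosen_p[i]]
    os <- nm$ostart[chosen_s[i]]; oe <- nm$oend[chosen_e[i]]
    data.frame(term_id = index$entries[[form]],
               surface = substr(text, os, oe),
               start = os - 1L, end = oe,
               label = form, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$start, out$term_id), , drop = FALSE]
}

#' Apply reproducible copy-paste corruptions to mentioned spans
#'
#' Simulates the transcription errors that plague manual copy-paste of term
#' labels into notes: suffix truncation ("limb" pasted as "lim"), a dropped
#' character, or two adjacent characters transposed.  Each operation targets
#' exactly one ground-truth mention span; text outside the targeted mentions
#' is untouched.
#'
#' @param text The note text.
#' @param mentions Data frame of ground-truth mention spans with columns
#'   `start`, `end` (0-based half-open) and `surface`, e.g. from
#'   [synthesize_note()].
#' @param ops Data frame of operations with columns `kind` (one of
#'   `truncate_suffix`, `delete_char`, `transpose_adjacent`), `mention`
#'   (1-based index into `mentions`) and `param` (characters to truncate, or
#'   1-based position within the mention; `NA` picks one reproducibly from
#'   `seed`).
#' @param seed Integer seed driving any unpinned `param`.
#' @return List with `text` (the corrupted note) and `log` (data frame of
#'   `kind`, `mention`, `before`, `after`).
#' @export
corrupt_text <- function(text, mentions, ops, seed = 1L) {
  stopifnot(is.character(text), length(text) == 1, is.data.frame(mentions))
  if (is.null(ops) || nrow(ops) == 0) {
    return(list(text = text,
                log = data.frame(kind = character(0), mention = integer(0),
                                 before = character(0), after = character(0),
                                 stringsAsFactors = FALSE)))
  }
  kinds <- c("truncate_suffix", "delete_char", "transpose_adjacent")
  if (any(!ops$kind %in% kinds)) {
    stop(sprintf("unknown corruption kind '%s'", setdiff(ops$kind, kinds)[1]))
  }
  if (any(ops$mention < 1 | ops$mention > nrow(mentions))) {
    stop("corruption op targets a mention index out of range")
  }
  with_seed(seed, {
    # apply right-to-left so earlier mention offsets stay valid
    ord <- order(-mentions$start[ops$mention])
    log_rows <- vector("list", nrow(ops))
    for (k in ord) {
      m <- ops$mention[k]
      s <- mentions$start[m] + 1L   # to 1-based inclusive
      e <- mentions$end[m]
      seg <- substr(text, s, e)
      nc <- nchar(seg)
      param <- ops$param[k]
      new_seg <- switch(
        ops$kind[k],
        truncate_suffix = {
          drop <- if (is.na(param)) 1L else as.integer(param)
          if (drop < 1L || drop >= nc) stop("truncate_suffix parameter out of range")
          substr(seg, 1L, nc - drop)
        },
        delete_char = {
          pos <- if (is.na(param)) sample.int(nc, 1L) else as.integer(param)
          if (pos < 1L || pos > nc) stop("delete_char position out of range")
          paste0(substr(seg, 1L, pos - 1L), substring(seg, pos + 1L))
        },
        transpose_adjacent = {
          if (nc < 2L) stop("mention too short to transpose")
          pos <- if (is.na(param)) sample.int(nc - 1L, 1L) else as.integer(param)
          if (pos < 1L || pos >= nc) stop("transpose_adjacent position out of range")
          paste0(substr(seg, 1L, pos - 1L),
                 substr(seg, pos + 1L, pos + 1L), substr(seg, pos, pos),
                 substring(seg, pos + 2L))
        })
      text <- paste0(substr(text, 1L, s - 1L), new_seg, substring(text, e + 1L))
      log_rows[[k]] <- data.frame(kind = ops$kind[k], mention = m,
                                  before = seg, after = new_seg,
                                  stringsAsFactors = FALSE)
    }
    list(text = text,
         log = do.call(rbind, c(log_rows, list(make.row.names = FALSE))))
  })
}

#' Compare structured capture with dictionary extraction
#'
#' The head-to-head report: which of the structurally captured terms does
#' free-text extraction retain, which does it lose, and what extra terms does
#' it pick up.
#'
#' @param structured Character vector of term ids captured structurally (or
#'   an `annotation_cart`).
#' @param extracted A match data frame from [extract_terms()] (or a character
#'   vector of term ids).
#' @return List with sorted character vectors `retained`, `lost`, `spurious`.
#'   `length(retained) + length(lost)` always equals the number of distinct
#'   structured ids.
#' @export
compare_capture <- function(structured, extracted) {
  if (inherits(structured, "annotation_cart")) structured <- structured$items$term_id
  ids <- if (is.data.frame(extracted)) extracted$term_id else extracted
  structured <- unique(structured)
  ids <- unique(ids)
  list(retained = sort(intersect(structured, ids)),
       lost = sort(setdiff(structured, ids)),
       spurious = sort(setdiff(ids, structured)))
}
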