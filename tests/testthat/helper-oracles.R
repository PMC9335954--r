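# Independent oracles for property tests.  These deliberately share no code
# with the package internals: closures are computed by one-step expansion to
# a fixpoint, search by a plain linear scan, extraction by a quadratic
# substring scan.

toy_ontology <- function() parse_obo(toy_ontology_obo())

# run code under a fixed seed without disturbing the suite's RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

toy_associations <- function(ont = toy_ontology()) {
  load_gene_associations(toy_gene_table_tsv(), ont)
}

# parents per term (non-obsolete subgraph), as plain named list
live_parents_list <- function(ont) {
  live <- names(ont$terms)[!vapply(ont$terms, `[[`, logical(1), "obsolete")]
  out <- lapply(ont$terms[live], function(t) intersect(t$parents, live))
  names(out) <- live
  out
}

# transitive closure upward by repeated one-step parent expansion
oracle_ancestors <- function(parents, id) {
  s <- unique(parents[[id]])
  repeat {
    s2 <- unique(c(s, unlist(parents[s], use.names = FALSE)))
    if (length(s2) == length(s)) break
    s <- s2
  }
  sort(s)
}

oracle_descendants <- function(parents, id) {
  all_ids <- names(parents)
  sort(all_ids[vapply(all_ids, function(x) id %in% oracle_ancestors(parents, x),
                      logical(1))])
}

# linear-scan autocomplete oracle: scan every label of every live term,
# classify into the four tiers, keep each term's best label, sort, truncate
oracle_search <- function(ont, query, limit) {
  norm <- function(x) trimws(gsub("[[:space:]]+", " ", tolower(x)))
  q <- norm(query)
  empty <- data.frame(term_id = character(0), matched_label = character(0),
                      match_kind = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(q)) return(empty)
  kinds <- c("name_prefix", "synonym_prefix", "name_substring", "synonym_substring")
  best <- list()
  for (t in ont$terms) {
    if (t$obsolete) next
    labels <- c(t$name, t$synonyms$label)
    is_name <- c(TRUE, rep(FALSE, nrow(t$synonyms)))
    tiers <- rep(NA_integer_, length(labels))
    for (i in seq_along(labels)) {
      nl <- norm(labels[i])
      if (!grepl(q, nl, fixed = TRUE)) next
      tiers[i] <- if (startsWith(nl, q)) {
        if (is_name[i]) 1L else 2L
      } else {
        if (is_name[i]) 3L else 4L
      }
    }
    if (all(is.na(tiers))) next
    cand <- order(tiers, nchar(labels), labels)[1]
    best[[t$id]] <- list(term_id = t$id, label = labels[cand], tier = tiers[cand])
  }
  if (!length(best)) return(empty)
  df <- do.call(rbind, lapply(best, function(b) {
    data.frame(term_id = b$term_id, matched_label = b$label, tier = b$tier,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$tier, nchar(df$matched_label), df$term_id), , drop = FALSE]
  df <- utils::head(df, limit)
  data.frame(term_id = df$term_id, matched_label = df$matched_label,
             match_kind = kinds[df$tier], rank = seq_len(nrow(df)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# quadratic naive extraction oracle over a form -> term-ids mapping
oracle_extract <- function(entries, text) {
  # own normalization + offset map
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_ws <- grepl("[[:space:]]", chars)
  nchars <- character(0); omap_s <- integer(0); omap_e <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (is_ws[i]) {
      j <- i
      while (j < length(chars) && is_ws[j + 1L]) j <- j + 1L
      nchars <- c(nchars, " "); omap_s <- c(omap_s, i); omap_e <- c(omap_e, j)
      i <- j + 1L
    } else {
      nchars <- c(nchars, tolower(chars[i])); omap_s <- c(omap_s, i); omap_e <- c(omap_e, i)
      i <- i + 1L
    }
  }
  ntext <- paste(nchars, collapse = "")
  len <- nchar(ntext)
  wordch <- grepl("[a-z0-9]", nchars)
  cands <- list()
  for (form in names(entries)) {
    fl <- nchar(form)
    if (fl > len) next
    for (s in seq_len(len - fl + 1L)) {
      e <- s + fl - 1L
      if (substr(ntext, s, e) != form) next
      if (s > 1 && wordch[s - 1]) next
      if (e < len && wordch[e + 1]) next
      cands[[length(cands) + 1]] <- list(s = s, e = e, form = form)
    }
  }
  if (!length(cands)) {
    return(data.frame(term_id = character(0), surface = character(0),
                      start = integer(0), end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  lens <- vapply(cands, function(c) c$e - c$s, integer(1))
  starts <- vapply(cands, function(c) c$s, integer(1))
  cands <- cands[order(-lens, starts)]
  chosen <- list()
  for (c in cands) {
    clash <- any(vapply(chosen, function(d) c$s <= d$e && c$e >= d$s, logical(1)))
    if (!clash) chosen[[length(chosen) + 1]] <- c
  }
  chosen <- chosen[order(vapply(chosen, function(c) c$s, integer(1)))]
  rows <- lapply(chosen, function(c) {
    data.frame(term_id = sort(entries[[c$form]]),
               surface = substr(text, omap_s[c$s], omap_e[c$e]),
               start = omap_s[c$s] - 1L, end = omap_e[c$e],
               label = c$form, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$start, out$term_id), , drop = FALSE]
}

# plain form -> term-ids map built directly from parsed terms (names + exact
# synonyms), independent of build_term_dictionary()
oracle_entries <- function(ont) {
  norm <- function(x) trimws(gsub("[[:space:]]+", " ", tolower(x)))
  entries <- list()
  for (t in ont$terms) {
    if (t$obsolete) next
    forms <- unique(norm(c(t$name, t$synonyms$label[t$synonyms$scope == "exact"])))
    for (f in forms[nzchar(forms)]) entries[[f]] <- sort(unique(c(entries[[f]], t$id)))
  }
  entries
}

# replay a diff_annotations() result on top of `old` items, pulling added and
# modified rows from `new`; result should equal `new` as a set (timestamps
# ignored)
replay_diff <- function(old, new, d) {
  keep <- old[!old$term_id %in% d$removed & !old$term_id %in% d$modified, , drop = FALSE]
  pulled <- new[new$term_id %in% c(d$added, d$modified), , drop = FALSE]
  rbind(keep, pulled, make.row.names = FALSE)
}

items_as_set <- function(items) {
  x <- items[order(items$term_id), c("term_id", "negated", "comment"), drop = FALSE]
  rownames(x) <- NULL
  x
}

# a random cart over the toy ontology for store/diff round-trip tests
random_toy_cart <- function(ont, patient = "P1", n_max = 5) {
  live <- c("T:0000010", "T:0000011", "T:0000012", "T:0000020", "T:0000021")
  cart <- annotation_cart(patient)
  ids <- sample(live, sample.int(n_max, 1))
  for (id in ids) {
    cart <- add_term(cart, ont, id,
                     negated = runif(1) < 0.3,
                     comment = if (runif(1) < 0.5) NULL else
                       paste0(sample(c("linked gene ", "see \"note\"\n", "a\\b{c}"), 1),
                              sample.int(100, 1)),
                     now = sprintf("2021-03-%02dT%02d:00:00Z",
                                   sample.int(28, 1), sample.int(23, 1)))
  }
  cart
}

count_fixed <- function(x, token) {
  lengths(regmatches(x, gregexpr(token, x, fixed = TRUE)))
}
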