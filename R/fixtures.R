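# Deterministic generators for mini-ontologies, gene tables and synthetic
# clinical notes.  Everything the package needs for development, testing and
# the capture demonstration can be generated offline; no downloads.

#' The built-in toy ontology (OBO text)
#'
#' A fixed seven-term ontology in OBO format, used throughout the examples
#' and tests: a phenotypic-abnormality root with a limb branch (abnormal limb
#' morphology with exact synonym "Limb abnormality"; polydactyly; syndactyly,
#' which also carries the alternate id `T:0000099`) and a seizure branch
#' (seizure with exact synonym "Epileptic seizure"; febrile seizure), plus an
#' obsolete term replaced by Seizure.  Byte-identical on every call.
#'
#' @return A single string of OBO text.
#' @seealso [toy_gene_table_tsv()] for the matching gene association table.
#' @export
toy_ontology_obo <- function() {
  paste(c(
    "format-version: 1.2",
    "data-version: toy/2021-01-01",
    "",
    "[Term]",
    "id: T:0000001",
    "name: Phenotypic abnormality",
    "def: \"A phenotypic abnormality observed in a patient.\" []",
    "",
    "[Term]",
    "id: T:0000010",
    "name: Abnormal limb morphology",
    "def: \"A structural anomaly of the limb.\" []",
    "synonym: \"Limb abnormality\" EXACT []",
    "is_a: T:0000001 ! Phenotypic abnormality",
    "",
    "[Term]",
    "id: T:0000011",
    "name: Polydactyly",
    "def: \"Supernumerary digits.\" []",
    "is_a: T:0000010 ! Abnormal limb morphology",
    "",
    "[Term]",
    "id: T:0000012",
    "name: Syndactyly",
    "def: \"Webbing or fusion of digits.\" []",
    "alt_id: T:0000099",
    "is_a: T:0000010 ! Abnormal limb morphology",
    "",
    "[Term]",
    "id: T:0000020",
    "name: Seizure",
    "def: \"A sudden attack of involuntary muscular contractions.\" []",
    "synonym: \"Epileptic seizure\" EXACT []",
    "is_a: T:0000001 ! Phenotypic abnormality",
    "",
    "[Term]",
    "id: T:0000021",
    "name: Febrile seizure",
    "def: \"A seizure associated with fever.\" []",
    "is_a: T:0000020 ! Seizure",
    "",
    "[Term]",
    "id: T:0000030",
    "name: obsolete Convulsion",
    "is_obsolete: true",
    "replaced_by: T:0000020",
    ""
  ), collapse = "\n")
}

#' The built-in toy gene association table (TSV text)
#'
#' Five direct gene-phenotype associations matching [toy_ontology_obo()]:
#' GENE1 with the two digit anomalies, GENE2 with seizure, GENE3 with febrile
#' seizure and with the limb branch term directly.
#'
#' @return A single string of TSV text (with header).
#' @export
toy_gene_table_tsv <- function() {
  paste(c(
    "term_id\tgene_symbol\tgene_id",
    "T:0000011\tGENE1\t101",
    "T:0000012\tGENE1\t101",
    "T:0000020\tGENE2\t102",
    "T:0000021\tGENE3\t103",
    "T:0000010\tGENE3\t103",
    ""
  ), collapse = "\n")
}

# Pronounceable unique nonsense word, alternating consonant/vowel syllables.
# Nonsense vocabulary keeps generated labels disjoint from the fixed English
# filler-sentence bank used by synthesize_note().
random_word <- function(n_syllables = 3L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(sample(cons, n_syllables, replace = TRUE),
         sample(vow, n_syllables, replace = TRUE), collapse = "")
}

#' Generate a random acyclic mini-ontology (OBO text)
#'
#' Terms are indexed 1..n with term 1 as the single root; `is_a` edges only
#' ever point from a higher-indexed term to a lower-indexed one, so the graph
#' is acyclic by construction.  Every non-root term has at least one parent.
#' Names (and occasional exact synonyms) are pronounceable unique nonsense
#' words.  Deterministic per seed.
#'
#' @param n_terms Number of terms (>= 2).
#' @param edge_prob Probability of an `is_a` edge to each lower-indexed term.
#' @param seed Integer seed.
#' @param synonym_prob Probability that a term gets one exact synonym.
#' @return A single string of OBO text with `data-version` `rand/<seed>`.
#' @export
random_ontology_obo <- function(n_terms, edge_prob = 0.08, seed = 1L,
                                synonym_prob = 0.3) {
  stopifnot(n_terms >= 2, edge_prob > 0, edge_prob < 1)
  with_seed(seed, {
    used <- character(0)
    fresh_word <- function() {
      repeat {
        w <- random_word(sample(2:4, 1L))
        if (!w %in% used) { used <<- c(used, w); return(w) }
      }
    }
    ids <- sprintf("T:%07d", seq_len(n_terms))
    names_ <- vapply(seq_len(n_terms), function(i) fresh_word(), character(1))
    lines <- c("format-version: 1.2", sprintf("data-version: rand/%d", seed), "")
    for (i in seq_len(n_terms)) {
      lines <- c(lines, "[Term]", paste0("id: ", ids[i]), paste0("name: ", names_[i]))
      if (stats::runif(1) < synonym_prob) {
        lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", fresh_word()))
      }
      if (i > 1L) {
        parents <- which(stats::runif(i - 1L) < edge_prob)
        if (!length(parents)) parents <- sample.int(i - 1L, 1L)
        lines <- c(lines, paste0("is_a: ", ids[parents]))
      }
      lines <- c(lines, "")
    }
    paste(lines, collapse = "\n")
  })
}

#' Generate a random gene association table (TSV text)
#'
#' @param ontology A `phenotype_ontology` the associations refer to.
#' @param n_genes Number of genes (>= 1); symbols are `GENE001`, `GENE002`, ...
#' @param assoc_per_gene Direct associations per gene, drawn uniformly over
#'   the non-obsolete terms without replacement; must not exceed the
#'   non-obsolete term count.
#' @param seed Integer seed.
#' @return A single string of TSV text (with header).
#' @export
random_gene_table <- function(ontology, n_genes, assoc_per_gene, seed = 1L) {
  stopifnot(n_genes >= 1, assoc_per_gene >= 1)
  live <- names(ontology$terms)[!vapply(ontology$terms, `[[`, logical(1), "obsolete")]
  if (assoc_per_gene > length(live)) {
    stop(sprintf("assoc_per_gene (%d) exceeds the non-obsolete term count (%d)",
                 assoc_per_gene, length(live)))
  }
  with_seed(seed, {
    rows <- unlist(lapply(seq_len(n_genes), function(g) {
      terms <- sample(live, assoc_per_gene)
      sprintf("%s\tGENE%03d\t%d", terms, g, 1000L + g)
    }))
    paste(c("term_id\tgene_symbol\tgene_id", rows, ""), collapse = "\n")
  })
}

# Fixed neutral filler bank; contains no ontology surface forms (the toy
# ontology's labels are clinical phrases absent here, and random ontologies
# use nonsense vocabulary).
note_filler_bank <- function() {
  c("The family attended the visit together.",
    "Review of prior records was completed.",
    "Growth measurements were recorded in the chart.",
    "The care plan was discussed at length.",
    "A follow-up visit was arranged for next quarter.",
    "Previous laboratory results were reviewed.",
    "Medication doses remain unchanged since the last visit.",
    "The consent forms were signed and filed.")
}

#' Synthesize a clinical note with known term mentions
#'
#' Builds a plain-text note that embeds, once each, a canonical surface form
#' (the term name or a randomly chosen exact synonym) for every requested
#' term, separated by neutral filler sentences that contain no dictionary
#' forms.  The ground-truth mention spans are recorded, so extraction recall
#' can be measured exactly.
#'
#' @param ontology A `phenotype_ontology`.
#' @param terms Character vector of term ids to embed (may be empty).
#' @param filler_seed Integer seed driving filler and synonym choices.
#' @return A `synthetic_note` list: `text`, `mentions` (data frame with
#'   columns `term_id`, `start`, `end` — 0-based half-open — and `surface`)
#'   and `seed`.
#' @export
synthesize_note <- function(ontology, terms, filler_seed = 1L) {
  with_seed(filler_seed, {
    bank <- note_filler_bank()
    text <- ""
    rows <- vector("list", length(terms))
    for (k in seq_along(terms)) {
      pid <- resolve_live(ontology, terms[k])
      t <- ontology$terms[[pid]]
      surfaces <- c(t$name, t$synonyms$label[t$synonyms$scope == "exact"])
      surfaces <- surfaces[nzchar(trimws(surfaces))]
      if (!length(surfaces)) stop(sprintf("term '%s' has no surface form", pid))
      surface <- if (length(surfaces) == 1L) surfaces else sample(surfaces, 1L)
      text <- paste0(text, sample(bank, 1L), " Noted finding: ")
      start <- nchar(text)
      text <- paste0(text, surface)
      rows[[k]] <- data.frame(term_id = pid, start = start,
                              end = nchar(text), surface = surface,
                              stringsAsFactors = FALSE)
      text <- paste0(text, ". ")
    }
    text <- paste0(text, sample(bank, 1L))
    mentions <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(term_id = character(0), start = integer(0), end = integer(0),
                 surface = character(0), stringsAsFactors = FALSE)
    }
    structure(list(text = text, mentions = mentions, seed = filler_seed),
              class = "synthetic_note")
  })
}

#' @export
print.synthetic_note <- function(x, ...) {
  cat(sprintf("<synthetic_note> %d character(s), %d mention(s), seed %d\n",
              nchar(x$text), nrow(x$mentions), x$seed))
  invisible(x)
}
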