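# Baseline phenotype-driven gene ranking.  This is a transparent
# information-content sum, not a re-implementation of any external ranker's
# knowledgebase: its job is to make the downstream consequence of losing
# phenotype terms measurable and reproducible at desk scale.

#' Build an annotation corpus for gene ranking
#'
#' Direct gene-term associations are propagated up the hierarchy under the
#' true-path rule: gene `g` is propagated-associated with term `t` iff `g` is
#' directly associated with `t` or with any descendant of `t`.  The
#' propagated sets drive both information content and scoring.
#'
#' @param ontology A `phenotype_ontology`.
#' @param associations Data frame from [load_gene_associations()] (term ids
#'   already resolved to primary).
#' @return A `gene_corpus`: `genes` (sorted), `n_genes`, `direct` and
#'   `propagated` (named lists term id -> sorted gene symbols), and the
#'   ontology.
#' @export
build_gene_corpus <- function(ontology, associations) {
  stopifnot(is.data.frame(associations))
  genes <- sort(unique(associations$gene_symbol))
  if (!length(genes)) stop("association table contains no genes")
  direct <- lapply(split(associations$gene_symbol, associations$term_id),
                   function(g) sort(unique(g)))
  live <- names(ontology$terms)[!vapply(ontology$terms, `[[`, logical(1), "obsolete")]
  propagated <- lapply(live, function(t) {
    below <- term_descendants(ontology, t, include_self = TRUE)
    g <- unlist(direct[intersect(below, names(direct))], use.names = FALSE)
    sort(unique(as.character(g)))
  })
  names(propagated) <- live
  structure(list(ontology = ontology, genes = genes, n_genes = length(genes),
                 direct = direct, propagated = propagated),
            class = "gene_corpus")
}

#' @export
print.gene_corpus <- function(x, ...) {
  cat(sprintf("<gene_corpus> %d gene(s) over %d term(s)\n",
              x$n_genes, length(x$propagated)))
  invisible(x)
}

#' Information content of a term
#'
#' Resnik-style IC on annotation frequency: `IC(t) = -ln(n_t / N)` where
#' `n_t` is the number of genes propagated-associated with `t` and `N` the
#' corpus gene count.  A term with no annotated genes gets the smoothed value
#' `-ln(1 / (N + 1))` — more informative than any annotated term, but finite.
#' IC is monotone non-decreasing from root to leaves, so more specific terms
#' always carry at least as much signal.
#'
#' @param corpus A [build_gene_corpus()] corpus.
#' @param term_id A term id (resolved through the ontology).
#' @return Non-negative scalar.
#' @export
term_ic <- function(corpus, term_id) {
  stopifnot(inherits(corpus, "gene_corpus"))
  pid <- resolve_live(corpus$ontology, term_id)
  n_t <- length(corpus$propagated[[pid]])
  N <- corpus$n_genes
  if (n_t == 0L) -log(1 / (N + 1)) else -log(n_t / N)
}

#' Rank genes by summed information content over a phenotype profile
#'
#' Each gene scores the sum of `IC(t)` over the patient terms it is
#' propagated-associated with.  Every gene in the corpus receives a score
#' (possibly 0) and a 1-based rank; ranks are assigned by descending score
#' with ties broken by gene symbol, so the ranking is deterministic.
#' Removing a term can never increase any gene's score.
#'
#' @param corpus A [build_gene_corpus()] corpus.
#' @param patient_terms Non-empty character vector of term ids (treated as a
#'   set).
#' @return Data frame with columns `gene_symbol`, `score`, `rank`, ordered by
#'   rank.
#' @export
rank_genes <- function(corpus, patient_terms) {
  stopifnot(inherits(corpus, "gene_corpus"))
  patient_terms <- unique(patient_terms)
  if (!length(patient_terms)) stop("patient term set is empty")
  score <- stats::setNames(numeric(corpus$n_genes), corpus$genes)
  for (t in patient_terms) {
    pid <- resolve_live(corpus$ontology, t)
    ic <- term_ic(corpus, pid)
    hit <- corpus$propagated[[pid]]
    if (length(hit)) score[hit] <- score[hit] + ic
  }
  o <- order(-score, names(score))
  data.frame(gene_symbol = names(score)[o],
             score = unname(score[o]),
             rank = seq_along(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Look up a gene's rank
#'
#' @param scores A [rank_genes()] result.
#' @param gene Gene symbol.
#' @return The gene's 1-based rank.
#' @export
gene_rank <- function(scores, gene) {
  i <- match(gene, scores$gene_symbol)
  if (is.na(i)) stop(sprintf("gene '%s' is not in the ranking", gene))
  scores$rank[i]
}
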