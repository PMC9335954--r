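test_that("canonical toy ontology parses with expected structure", {
  ont <- toy_ontology()
  obs <- vapply(ont$terms, `[[`, logical(1), "obsolete")
  expect_length(ont$terms, 7)
  expect_equal(sum(!obs), 6)
  expect_equal(sum(obs), 1)
  expect_equal(ont$version_label, "toy/2021-01-01")
  expect_equal(unname(ont$alt_index[["T:0000099"]]), "T:0000012")
  expect_equal(ont$children_index[["T:0000010"]], c("T:0000011", "T:0000012"))
  expect_equal(ont$terms[["T:0000010"]]$synonyms$label, "Limb abnormality")
  expect_equal(ont$terms[["T:0000010"]]$synonyms$scope, "exact")
})

test_that("parsing is order-insensitive over term stanzas", {
  lines <- strsplit(toy_ontology_obo(), "\n", fixed = TRUE)[[1]]
  heads <- grep("^\\[Term\\]$", lines)
  header <- lines[seq_len(heads[1] - 1)]
  bounds <- c(heads, length(lines) + 1)
  stanzas <- lapply(seq_along(heads), function(k) lines[heads[k]:(bounds[k + 1] - 1)])
  for (s in c(7, 19, 3)) {
    shuffled <- with_seed_local(s, sample(stanzas))
    reparsed <- parse_obo(c(header, unlist(shuffled)))
    expect_equal(reparsed, toy_ontology())
  }
})

test_that("malformed inputs are parse errors naming the problem", {
  expect_error(parse_obo(c("[Term]", "name: anonymous")), "missing an id")
  expect_error(
    parse_obo(c("[Term]", "id: A:1", "name: x", "is_a: A:2",
                "", "[Term]", "id: A:2", "name: y", "is_a: A:1")),
    "cycle")
  expect_error(
    parse_obo(c("[Term]", "id: A:1", "name: x",
                "", "[Term]", "id: A:1", "name: y")),
    "duplicate")
  expect_error(
    parse_obo(c("[Term]", "id: A:1", "name: x", "is_a: A:1")),
    "cycle")
})

test_that("unrecognized tags and stanza types are ignored", {
  ont <- parse_obo(c(
    "data-version: x/1", "",
    "[Typedef]", "id: part_of", "",
    "[Term]", "id: A:1", "name: root", "xref: UMLS:C000",
    "comment: free text", "created_by: someone"))
  expect_length(ont$terms, 1)
  expect_equal(ont$terms[["A:1"]]$name, "root")
})

test_that("resolve_term covers all statuses and is idempotent", {
  ont <- toy_ontology()
  expect_equal(resolve_term(ont, "T:0000099"),
               list(primary = "T:0000012", status = "alt"))
  expect_equal(resolve_term(ont, "T:0000030"),
               list(primary = "T:0000020", status = "obsolete_replaced"))
  expect_equal(resolve_term(ont, "T:9999999"),
               list(primary = "T:9999999", status = "unknown"))
  expect_equal(resolve_term(ont, "T:0000020"),
               list(primary = "T:0000020", status = "primary"))
  for (id in c("T:0000099", "T:0000030", "T:0000020", "T:0000011")) {
    r <- resolve_term(ont, id)
    if (r$status != "unknown") {
      expect_equal(resolve_term(ont, r$primary)$status, "primary")
    }
  }
})

test_that("ancestors and descendants match the fixture hierarchy", {
  ont <- toy_ontology()
  expect_equal(term_ancestors(ont, "T:0000021"), c("T:0000001", "T:0000020"))
  expect_equal(term_ancestors(ont, "T:0000001"), character(0))
  expect_equal(term_ancestors(ont, "T:0000021", include_self = TRUE),
               c("T:0000001", "T:0000020", "T:0000021"))
  expect_equal(term_descendants(ont, "T:0000010"), c("T:0000011", "T:0000012"))
  expect_equal(term_descendants(ont, "T:0000011"), character(0))
  expect_error(term_ancestors(ont, "T:9999999"), "unknown")
  expect_error(term_ancestors(ont, "T:0000030"), "obsolete")
})

test_that("traversal equals brute-force closure and mirrors on random DAGs", {
  for (seed in 0:9) {
    ont <- parse_obo(random_ontology_obo(30, edge_prob = 0.1, seed = seed))
    parents <- live_parents_list(ont)
    ids <- names(parents)
    for (id in with_seed_local(seed + 1000, sample(ids, 8))) {
      expect_equal(term_ancestors(ont, id), oracle_ancestors(parents, id))
      expect_equal(term_descendants(ont, id), oracle_descendants(parents, id))
    }
    # mirror property on every edge
    for (child in ids) {
      for (p in parents[[child]]) {
        expect_true(child %in% term_descendants(ont, p))
        expect_true(p %in% term_ancestors(ont, child))
      }
    }
  }
})

test_that("term_details reports direct relations and direct genes only", {
  ont <- toy_ontology()
  assoc <- toy_associations(ont)
  d <- term_details(ont, "T:0000020", assoc)
  expect_equal(d$superclasses$term_id, "T:0000001")
  expect_equal(d$superclasses$name, "Phenotypic abnormality")
  expect_equal(d$subclasses$term_id, "T:0000021")
  expect_equal(d$genes, "GENE2")
  expect_equal(term_details(ont, "T:0000001", assoc)$superclasses$term_id, character(0))
  # direct association only: GENE1 annotates children of T:0000010, not itself
  expect_equal(term_details(ont, "T:0000010", assoc)$genes, "GENE3")
  expect_error(term_details(ont, "T:9999999"), "unknown")
})

test_that("search ranks tiers and breaks ties as specified", {
  ont <- toy_ontology()
  lim <- search_terms(ont, "lim", 10)
  expect_equal(lim$term_id, "T:0000010")
  expect_equal(lim$matched_label, "Limb abnormality")
  expect_equal(lim$match_kind, "synonym_prefix")

  sz <- search_terms(ont, "seizure", 10)
  expect_equal(sz$term_id, c("T:0000020", "T:0000021"))
  expect_equal(sz$match_kind, c("name_prefix", "name_substring"))
  expect_equal(sz$rank, 1:2)

  expect_equal(nrow(search_terms(ont, "", 10)), 0)
  expect_equal(nrow(search_terms(ont, "   ", 10)), 0)
  expect_equal(nrow(search_terms(ont, "seizure", 1)), 1)
  # obsolete terms are not searchable
  expect_false("T:0000030" %in% search_terms(ont, "convulsion", 10)$term_id)
})

test_that("search equals the linear-scan oracle on random fixtures", {
  for (seed in 0:4) {
    ont <- parse_obo(random_ontology_obo(40, edge_prob = 0.1, seed = seed))
    labels <- unlist(lapply(ont$terms, function(t) c(t$name, t$synonyms$label)))
    queries <- with_seed_local(seed, {
      full <- sample(labels, 5)
      pre <- substr(sample(labels, 5), 1, 3)
      mid <- substr(sample(labels, 5), 2, 5)
      c(full, pre, mid, "zz-nohit")
    })
    for (q in queries) {
      expect_equal(search_terms(ont, q, 10), oracle_search(ont, q, 10), info = q)
    }
  }
})

test_that("gene associations load, resolve and report problems", {
  ont <- toy_ontology()
  assoc <- toy_associations(ont)
  expect_equal(nrow(assoc), 5)
  # alt id stored under primary
  via_alt <- load_gene_associations("T:0000099\tGENEX\t9", ont)
  expect_equal(via_alt$term_id, "T:0000012")
  expect_warning(
    dropped <- load_gene_associations(
      c("T:0000011\tGENE1\t101", "T:9999999\tGENEY\t1"), ont),
    "1 association row")
  expect_equal(nrow(dropped), 1)
  expect_error(load_gene_associations("T:0000011\tGENE1\t1\textra\tfields", ont),
               "line 1")
  # header detection
  with_header <- load_gene_associations(
    c("term_id\tgene_symbol\tgene_id", "T:0000011\tGENE1\t101"), ont)
  expect_equal(nrow(with_header), 1)
})
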