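ont <- toy_ontology()
dict <- build_term_dictionary(ont)

test_that("dictionary holds names plus exact synonyms of live terms", {
  expect_length(dict$forms, 8)  # 6 names + 2 exact synonyms
  expect_true(all(c("limb abnormality", "epileptic seizure") %in% dict$forms))
  expect_false("obsolete convulsion" %in% dict$forms)
  # only exact-scope synonyms enter
  scoped <- parse_obo(c(
    "[Term]", "id: A:1", "name: alpha",
    "synonym: \"broadish\" BROAD []", "synonym: \"near\" RELATED []",
    "synonym: \"precise\" EXACT []"))
  d2 <- build_term_dictionary(scoped)
  expect_setequal(d2$forms, c("alpha", "precise"))
})

test_that("a form shared by two terms maps to both, order-independently", {
  shared <- c(
    "[Term]", "id: A:1", "name: alpha", "synonym: \"twin\" EXACT []", "",
    "[Term]", "id: A:2", "name: beta", "synonym: \"twin\" EXACT []")
  d1 <- build_term_dictionary(parse_obo(shared))
  expect_equal(d1$entries[["twin"]], c("A:1", "A:2"))
  # stanza order does not change the dictionary
  d2 <- build_term_dictionary(parse_obo(shared[c(6:9, 5, 1:4)]))
  expect_equal(d1$entries, d2$entries)
  m <- extract_terms(d1, "a twin appeared")
  expect_equal(m$term_id, c("A:1", "A:2"))
  expect_equal(unique(m$start), 2L)
})

test_that("longest match wins and boundaries block partial words", {
  m <- extract_terms(dict, "patient has febrile seizure today")
  expect_equal(nrow(m), 1)  # no nested 'seizure' match
  expect_equal(m$term_id, "T:0000021")
  expect_equal(substr("patient has febrile seizure today", m$start + 1, m$end),
               "febrile seizure")

  syn <- extract_terms(dict, "Limb abnormality noted")
  expect_equal(syn$term_id, "T:0000010")
  expect_equal(syn$surface, "Limb abnormality")

  # the classic copy-paste truncation produces a missing term
  expect_equal(nrow(extract_terms(dict, "lim abnormality noted")), 0)
  # no matching inside words
  expect_equal(nrow(extract_terms(dict, "preseizurey climb")), 0)
  # case-insensitive, whitespace-normalized
  sloppy <- extract_terms(dict, "FEBRILE    seizure")
  expect_equal(sloppy$term_id, "T:0000021")
  expect_equal(sloppy$surface, "FEBRILE    seizure")
})

test_that("extraction equals the naive-scan oracle on random notes", {
  n_checked <- 0
  for (seed in 0:9) {
    ront <- parse_obo(random_ontology_obo(25, edge_prob = 0.12, seed = seed))
    rdict <- build_term_dictionary(ront)
    entries <- oracle_entries(ront)
    live <- names(ront$terms)
    with_seed_local(seed + 500, {
      for (j in 1:8) {
        terms <- sample(live, sample(0:4, 1))
        note <- synthesize_note(ront, terms, filler_seed = sample.int(1e6, 1))
        got <- extract_terms(rdict, note$text)
        want <- oracle_extract(entries, note$text)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
        n_checked <- n_checked + 1
      }
    })
  }
  expect_gte(n_checked, 80)
})

test_that("corruption operators are local, logged and reproducible", {
  note <- synthesize_note(ont, c("T:0000010", "T:0000020"), filler_seed = 3)
  ops <- data.frame(kind = "truncate_suffix", mention = 1L, param = 1L)
  out <- corrupt_text(note$text, note$mentions, ops, seed = 1)
  expect_equal(nchar(out$text), nchar(note$text) - 1)
  expect_equal(out$log$after, substr(out$log$before, 1, nchar(out$log$before) - 1))
  # text outside the mention is untouched
  expect_equal(substr(out$text, 1, note$mentions$start[1]),
               substr(note$text, 1, note$mentions$start[1]))
  # deterministic given seed and ops
  again <- corrupt_text(note$text, note$mentions, ops, seed = 1)
  expect_identical(out, again)
  # identity on empty ops; range errors
  expect_equal(corrupt_text(note$text, note$mentions, NULL)$text, note$text)
  bad <- data.frame(kind = "delete_char", mention = 9L, param = 1L)
  expect_error(corrupt_text(note$text, note$mentions, bad), "out of range")

  # the paper's example: "limb" -> "lim"
  mentions <- data.frame(term_id = "X:1", start = 8L, end = 12L, surface = "limb")
  tr <- corrupt_text("patient limb pain", mentions,
                     data.frame(kind = "truncate_suffix", mention = 1L, param = 1L))
  expect_equal(tr$text, "patient lim pain")
})

test_that("delete and transpose corruptions break matching of their mention", {
  note <- synthesize_note(ont, c("T:0000011", "T:0000012", "T:0000021"),
                          filler_seed = 5)
  before <- extract_terms(dict, note$text)
  expect_setequal(before$term_id, note$mentions$term_id)
  for (kind in c("delete_char", "transpose_adjacent")) {
    ops <- data.frame(kind = kind, mention = 1L, param = 2L)
    cor <- corrupt_text(note$text, note$mentions, ops, seed = 2)
    after <- extract_terms(dict, cor$text)
    expect_setequal(after$term_id, note$mentions$term_id[-1])
  }
})

test_that("capture comparison partitions the structured set", {
  rep1 <- compare_capture(c("A:1", "A:2", "A:3"), c("A:2", "A:3", "A:9"))
  expect_equal(rep1, list(retained = c("A:2", "A:3"), lost = "A:1",
                          spurious = "A:9"))
  expect_equal(length(rep1$retained) + length(rep1$lost), 3)
  same <- compare_capture(c("A:1", "A:2"), c("A:2", "A:1"))
  expect_length(same$lost, 0)
  expect_length(same$spurious, 0)
})

test_that("recall on uncorrupted synthetic notes is exactly 100%", {
  for (seed in 1:10) {
    terms <- with_seed_local(seed,
      sample(c("T:0000010", "T:0000011", "T:0000012", "T:0000020", "T:0000021"),
             sample(1:5, 1)))
    note <- synthesize_note(ont, terms, filler_seed = seed)
    rep <- compare_capture(terms, extract_terms(dict, note$text))
    expect_length(rep$lost, 0)
    expect_setequal(rep$retained, terms)
  }
})

test_that("corrupting k distinct mentions loses exactly k terms", {
  all5 <- c("T:0000010", "T:0000011", "T:0000012", "T:0000020", "T:0000021")
  for (seed in 1:10) {
    with_seed_local(seed, {
      note <- synthesize_note(ont, all5, filler_seed = seed + 100)
      k <- sample(1:3, 1)
      ops <- data.frame(kind = "truncate_suffix",
                        mention = sample(5, k), param = 1L)
      cor <- corrupt_text(note$text, note$mentions, ops, seed = seed)
      rep <- compare_capture(all5, extract_terms(dict, cor$text))
      expect_length(rep$lost, k)
      expect_length(rep$retained, 5 - k)
      expect_setequal(rep$lost, note$mentions$term_id[ops$mention])
    })
  }
})
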