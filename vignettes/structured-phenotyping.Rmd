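---
title: "Structured phenotype capture: models, contracts and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured phenotype capture: models, contracts and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocart)
```

`phenocart` models the full life cycle of structured clinical phenotyping:
browsing a phenotype ontology, assembling a per-patient annotation set,
persisting it as versioned records, rendering it for clinical notes, and
quantifying what the free-text alternative loses.  This vignette documents
the underlying models, the contracts the implementation commits to where the
domain leaves choices open, and what the synthetic-data generators do and do
not emulate.

## The ontology model

An ontology is parsed from OBO flat-file text into a term DAG.  Only the
term-level content that the workflow needs is interpreted: `id`, `name`,
`def`, `synonym` (with scope; a missing scope keyword defaults to `related`),
`is_a`, `alt_id`, `is_obsolete`, `replaced_by`, `consider`, and the header's
`data-version`.  Everything else (xrefs, creation metadata, non-`is_a`
relationship types, `[Typedef]` stanzas) is ignored, which is sufficient to
parse a full HPO release while keeping the grammar small.  Acyclicity of the
`is_a` graph over non-obsolete terms is verified once at parse time (Kahn's
algorithm, with one concrete cycle reported on failure), so every later
traversal may assume a DAG.

Identifier resolution is total and idempotent: primary ids resolve to
themselves, `alt_id`s to their host term, obsolete terms with exactly one
`replaced_by` to the replacement.  An obsolete term with zero or several
replacements resolves to *unreplaced* — a replacement is never guessed,
because silently substituting terms is precisely the class of error
structured capture exists to avoid.  Obsolete terms are likewise excluded
from search and from the extraction dictionary: surfacing out-of-use
vocabulary at the point of care reintroduces the outdated-term problem.

### Autocomplete ranking

The domain constraint is only that search should behave like autocomplete.
The concrete ranking here is a four-tier scheme chosen for determinism and
testability: name prefix, synonym prefix, name substring, synonym substring;
within a tier, shorter matched labels first, then term id.  Matching is
case-insensitive on whitespace-normalized labels (lowercase, internal runs of
whitespace collapsed; punctuation retained — the simplest reproducible
contract, shared verbatim with the extraction dictionary so the two views of
"surface form" can never drift apart).  Each term appears once, at its best
tier.  The whole ranking is validated against an independent linear-scan
oracle in the test suite.

## Cart and record semantics

The cart is a set keyed by term id with insertion order preserved.
Re-adding a term updates its negation/comment in place rather than erroring:
cart semantics, not ledger semantics — a clinician revising an entry should
not be blocked.  Negation is a structured boolean (so exports such as the
Phenopacket `excluded` flag are computable) while the comment stays free
text.  Each annotation snapshots the term name and ontology version at add
time; snapshots are immutable thereafter, which keeps old records
interpretable after ontology updates.

Validation flags unknown, obsolete and duplicate entries as blocking.  A
cart containing both a term and its proper ancestor gets a
`redundant_ancestor` *warning* only: choosing a less specific term alongside
a more specific one is a legitimate clinical decision, so the gate informs
rather than forbids.

The store is append-only: one directory per patient, one canonical-JSON file
per version, filename the zero-padded version number — inspectable with
`ls` and `cat`, append-only by construction.  Every save writes a full
snapshot at version `latest + 1`, never a delta.  Snapshot semantics make
the "all terms at once" view trivial (it is just the latest record) while
encounter-level changes remain recoverable as diffs between consecutive
versions.  Concurrency is optimistic: a writer may pass the version it
expects to create, and a collision is a conflict error; the last writer
never silently wins.

The canonical JSON payload (schema_version `"1.0"`) sorts keys
lexicographically and contains no insignificant whitespace, so byte equality
coincides with structural equality and `serialize ∘ parse` is a fixpoint —
both properties are tested over randomized records.  The record-level
`ontology_version` is taken from the most recently added annotation's
snapshot (the save operation deliberately takes no ontology argument, so the
record carries only what the cart knew); per-annotation versions are not
serialized separately.  Timestamps are UTC ISO 8601 at seconds precision and
injectable, for reproducibility.

## Exports

The RTF table is a minimal RTF 1.x document with a declared five-column
contract (HPO ID, Term Name, Negated, Comment, Date Added) — the production
table layouts in EHR integrations are vendor-specific and unpublished, so
the layout here is this package's own.  User text is escaped with RTF hex
escapes (`\'5c`, `\'7b`, `\'7d`) rather than doubled backslashes: a doubled
backslash followed by user text could form a spurious `\row` token, whereas
hex escapes make the `\row`-count-equals-rows-plus-one invariant and brace
balance robust against any comment content.  The Phenopacket export targets
structural validity of a minimal subset (subject id, `phenotypicFeatures`
with `type`/`excluded`, `metaData` with the ontology resource version), not
full Phenopackets v2 conformance.  Token expansion replaces every occurrence
of the configured token and never rescans rendered content, so expansion
cannot recurse.

## The extraction arm

The free-text comparison uses a deliberately *basic* dictionary matcher: an
Aho-Corasick automaton over the normalized names and exact-scope synonyms of
non-obsolete terms.  Broad/narrow/related synonyms are excluded to keep the
comparison conservative (near-synonymous matches would inflate the free-text
arm's apparent recall); there is no stemming, no abbreviation expansion, no
negation scope detection.  Matching runs on the normalized projection of the
text with offsets mapped back to the original; matches must sit on word
boundaries (adjacent characters, if any, non-alphanumeric — "lim" cannot
match inside "climb"); overlaps resolve longest-first, then leftmost; a form
shared by several terms emits one match per term over the same span.  The
matcher is verified against a quadratic naive-scan oracle implementing the
same contract independently.

Corruption operators model the observed copy-paste failure modes: suffix
truncation (the "limb" → "lim" class), single-character deletion, and
adjacent transposition.  Each operation edits exactly one ground-truth
mention span; operations apply right-to-left so recorded offsets stay valid;
given the seed and the operation list the result is deterministic.

## The gene ranker

The ranker is a transparent information-content baseline, not a
re-implementation of any production prioritizer with an external
knowledgebase.  Direct gene–term associations are propagated up the DAG
under the true-path rule; `IC(t) = −ln(n_t/N)` with the smoothing value
`−ln(1/(N+1))` for unannotated terms (more informative than any annotated
term, but finite); a gene's score is the sum of `IC` over the patient terms
it is propagated-associated with; ranks are assigned by descending score
with ties broken by gene symbol.  Two consequences matter for the
demonstration and are tested as properties: `IC` is monotone non-decreasing
from root to leaf, and removing a term can never increase any gene's score —
so losing terms can only hold or worsen the causal gene's rank.  The scorer
sits behind a small interface (`build_gene_corpus()` / `rank_genes()`), so a
heavier external ranker could be swapped in without touching the comparison
harness.

In `run_capture_demo()` the "causal" gene is defined as the top-ranked gene
under the structured arm — the gene the complete phenotype profile points
to.  On the built-in fixture this is a real degradation demonstration, not a
tautology: with all five non-root terms the top gene leads by a margin, and
losing one of its supporting terms can drop it behind a competitor.

## Synthetic data: what it does and does not emulate

The generators are pure functions of their parameters and seed (the caller's
RNG stream is saved and restored).  Defaults were chosen once, as follows:

* `run_capture_demo()` embeds **5 terms** and applies **1 corruption** —
  a realistic phenotype-profile size for a genetics encounter and the
  minimal corruption that demonstrates the effect.
* Corruptions default to suffix truncation of **1 character**: the smallest
  edit in the observed copy-paste error class.
* `random_ontology_obo()` uses 20–50 terms and edge probability ≈ 0.1 in the
  test suite: large enough for non-trivial DAG shapes (multiple parents,
  diamond inheritance), small enough that brute-force oracles run in
  seconds.  Terms may only point `is_a`-wise at lower indices, so the
  generator cannot emit a cycle; about 30% of terms get one exact synonym so
  search and dictionary code paths see synonym traffic.
* `synthesize_note()` separates mentions with sentences from a fixed neutral
  filler bank that contains no dictionary surface forms, so ground-truth
  recall is exact by construction.

What passing tests consequently *do* show: the traversal, search, matching,
persistence and ranking machinery obeys its contracts exactly, and the
capture-versus-extraction effect has the claimed direction and magnitude
at fixture scale.  What they do *not* show: performance or recall on real
clinical prose (ambiguity, abbreviations, negation phrases, OCR noise),
real HPO-scale ontologies' parse times, or the magnitudes any particular
external gene ranker would produce.  Synthetic notes are clean by design;
real notes are not.

## Numerical and degenerate-input choices

* Empty or whitespace-only search queries return zero hits, not an error.
* Removing an absent cart term is a warning, not an error; adding a known
  term twice is an update.
* An empty record renders as a header-only table (one `\row`), an empty
  `terms` array in JSON, and an empty Phenopacket feature list.
* A patient term set for ranking must be non-empty; an association table
  with no genes is an error.  An extraction arm that recovers nothing
  reports the worst possible rank for the causal gene.
* All set-valued outputs (ancestor sets, diff sets, gene lists) are sorted,
  and all rank ties are broken lexicographically, so every result is
  deterministic and directly comparable in tests.

## Command-line interface

The CLI (`cli_main()`, wrapped by `inst/scripts/phenocart`) is a thin layer:
each subcommand calls exactly the library functions documented above, prints
data to standard output and diagnostics to standard error, and exits 0 on
success, 1 on user error, 2 on environment error.  When no `--ontology` is
configured it falls back to the built-in toy ontology so every subcommand is
exercisable offline; a configured-but-unreadable path is a fatal environment
error with an instructive message.  The working cart is persisted as a JSON
session file under the store directory until `save` promotes it to an
immutable record version.

## Known limitations

* The OBO subset ignores non-`is_a` relationships; ontologies that encode
  hierarchy via `part_of` or other typedefs will appear flatter than they
  are.
* Dictionary extraction is exact-match by design; its measured recall is an
  upper bound for real free-text workflows, which makes the structured-arm
  comparison conservative in the package's favor only for the *corruption*
  effect, not for NLP sophistication.
* The IC ranker uses only the provided association table; it knows nothing
  of variant-level evidence, inheritance models or disease databases.
* The record store targets single-process use with optimistic conflict
  detection; it is not a database.
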