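---
title: "Models and methods: MeSH recognition, information content and semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: MeSH recognition, information content and semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshsimr)
```

## The data model

MeSH organizes biomedical knowledge as a forest of category trees whose
nodes are main headings (MHs). An MH is addressed by one or more dotted
*tree numbers* (`C10.574.945`); truncating components walks up the
hierarchy, and the first letter names the category (C diseases, F
psychiatry and psychology, ...). Because a heading may be placed at several
positions, the structure as a whole is a directed acyclic graph even though
each tree number is a path in a tree. Supplementary concept records (SCRs)
— rare diseases, specific substances — carry no tree number; they hang off
one or more *broader* MHs.

`mesh_dataset` keeps five tables: MH details, the UMLS-concept→MH map
(many concepts to one heading), SCR details (one concept per SCR), the
SCR↔MH broader links, and the MH parent/child pairs. Qualifier records and
MeSH entry-term synonym lists are deliberately out of scope: every stored
term is an MH or an SCR identified by its unique id, preferred name,
semantic types and UMLS concept ids. Two representational choices matter
downstream:

* **Two hierarchy encodings.** Tree numbers and the parent/child table
  encode the same hierarchy; the package navigates by tree-number prefixes
  and the test suite verifies on every generated dataset that the
  parent/child transitive closure agrees exactly. Keeping both makes
  prefix arithmetic cheap while preserving the graph form external tools
  expect.
* **SCR categories are inherited** from the broader MHs, since an SCR has
  no tree number of its own. This is what makes the cross-category rule
  (below) applicable to SCR comparisons.

An optional sixth table stores non-MeSH-synonymous UMLS concepts (id and
preferred name only). These are concepts the recognizer may encounter that
have no MeSH mapping; keeping their names in the dataset is what allows the
recursive normalization route.

## Information content

IC follows the corpus-frequency construction: `IC(d) = -log10(freq(D(d)) / N)`
with `freq` the per-term publication counts and `N` the total number of
publications indexed by MeSH. Choices a user should know:

* **`D(d)` includes `d` itself.** With a strictly-proper descendant set a
  leaf would have zero roll-up and undefined IC; the inclusive roll-up is
  the standard Resnik construction. The exclusive variant is available via
  `inclusive = FALSE` on the IC functions for sensitivity analyses.
* **Log base 10.** The Schlicker relevance factor is `1 - 10^(-IC(MICA))`;
  with base-10 logs that factor is exactly `1 - P(MICA)`, recovering the
  measure's published form. `ICTable` records the base.
* **Zero roll-up → pseudo-count 1**, making never-indexed terms maximally
  informative rather than infinite.
* **`N` always travels with the data** (counts-TSV manifest, fixture
  manifest, or the `n_total` argument); it is never hard-coded, and roll-ups
  never exceed it on coherent inputs, so IC is non-negative.

Counts come either from the dataset itself, a TSV, or
`fetch_publication_counts()`, whose transport is an injected function so
analyses replay recorded responses instead of querying a live service.

## The five similarity measures

Resnik, Lin, Jiang–Conrath and Schlicker are driven by the most informative
common ancestor. The package uses *inclusive* ancestor sets — each term is
its own ancestor — so `MICA(d, d) = d`, which is what makes the identity
boundary exact. Conventions on top of the raw formulas:

* **Cross-category zero, for all measures.** If the two category sets are
  disjoint there is no MICA and every measure returns exactly 0. The rule
  is applied to Jiang–Conrath explicitly: with two shallow terms of small
  IC the raw `1 - min(1, IC1 + IC2 - 2*0)` would be positive across
  categories, which contradicts the intended boundary behaviour; the
  short-circuit makes JC consistent with the other four.
* **Multiple tree numbers.** A term's ancestor set is the union over its
  tree numbers, and the full common-ancestor set is exactly the union of
  the per-tree-number-pair intersections. Because each IC measure is
  monotone in IC(MICA) given the endpoints, maximizing over tree-number
  pairings and taking the global-MICA value coincide; the package computes
  the global form. For Wang, the per-edge decay is taken as the *minimum*
  edge count over all tree-number paths, matching the same
  keep-the-best-pairing intent.
* **SCRs.** Each SCR endpoint is replaced by its broader-MH set and the
  maximum over cross pairs is returned; SCR-vs-SCR takes the cross product
  of both broader sets.
* **Identity.** `mesh_similarity()` returns exactly 1 for an identical
  resolved pair under every method. For Lin, JC and Wang this is the raw
  algebra; for Resnik (`IC(d)`) and Schlicker (`1 - P(d)`) it is a
  boundary convention applied by the dispatcher, so that "same term" reads
  as full similarity on every scale. The raw `sim_resnik()`/`sim_rel()`
  functions keep the formula values.
* **Degenerate ICs.** Two distinct terms whose ICs are both zero get Lin
  and Schlicker 0 (the 0/0 case); identity still scores 1.
* **Ties** for the MICA at equal IC break toward the lexicographically
  smaller id, so results are deterministic.

Wang's `omega` defaults to 0.6, the conventional weight for this measure
family; `seq(0.1, 1, 0.1)` sweeps are used in the tests to confirm the
boundary properties hold for any decay.

## Recognition and normalization

The built-in recognizer is a dictionary matcher over preferred names:
normalize, then scan token windows greedily left-to-right keeping the
longest match (ties prefer MH over SCR, then the smaller id). Normalization
lowercases, drops possessive `'s`, removes apostrophes and backticks (so
`Graves` disease` meets "Graves Disease"), maps other punctuation to spaces
and collapses whitespace; it is idempotent, and the same function is
applied to dictionary names and query text. There is no stemming and no
abbreviation expansion — phrases like "IgG levels" will not resolve, a
known limitation of dictionary matching.

Two normalization routes extend the plain scan:

* **SCR expansion** re-emits every SCR hit as its broader MHs
  (`route = "scr_expanded"`), the form the similarity layer consumes.
* **Recursive resolution**: when a matched window corresponds to a
  non-MeSH-synonymous concept, its preferred name is re-submitted as free
  text, up to `recursion_depth_limit` (default 2) with a visited-name set
  breaking cycles; results carry `route = "recursive"` and the triggering
  concept's id.

MetaMap is not reimplemented; its fielded (MMI) output is ingested by
`parse_mmi_output()`, resolving each row's concept id through the dataset
and falling back on the recursive route for unmapped ids. Scores are
rescaled from MetaMap's 0–1000 to [0, 1]. The default semantic-type filter
is the 33 disease-related UMLS type codes
(`mesh_disease_semantic_types`); an empty filter accepts everything.

## The synthetic generator

`generate_fixture()` emulates the structural features the algorithms
depend on, with deterministic output for a fixed seed:

* per-category full trees of configurable depth and branching, addressed
  by MeSH-style zero-padded tree numbers;
* **multi-parent placements**: with probability `multi_parent_rate` a node
  at depth ≥ 3 gains an extra same-category parent. The new placement is
  mirrored through the node's whole subtree under *every* placement of the
  new parent — exactly how real MeSH placements multiply — which keeps the
  tree-number encoding and the parent/child closure in perfect agreement;
* SCRs attached to one or two broader MHs; one or two concepts per MH
  (many-to-one mapping); a few non-MeSH concepts whose names embed an MH
  name, exercising the recursive route;
* per-term publication counts from a discrete power-law-like draw
  (`floor(count_min * u^(-1/(alpha-1)))`, alpha 2, capped), giving the
  many-rare/few-common profile of real indexing counts, with a 5% chance
  of a zero count to exercise the pseudo-count path;
* `N` defaults to the sum of all own counts, so with at least two
  populated categories every term — including category roots — keeps
  strictly positive IC.

Defaults (2 categories, depth 4, branching 3 → 80 headings, 6 SCRs) are
the conditions used throughout the tests and the acceptance script; the
Wang-oracle suite uses depth 5 / branching 3 (242 headings) and the IC
suite 3 categories × depth 5 × branching 4 (1023 headings). What the
generator does *not* emulate: realistic name morphology and synonymy,
abbreviations, the extreme size and depth imbalance of real MeSH, or
correlated placement of SCRs with term frequency. Passing tests therefore
demonstrate algorithmic correctness on MeSH-shaped structure, not
recognition performance on real clinical text.

## Numerical and engineering choices

* Exact identities (1 and 0 at the boundaries) are asserted with
  `identical()`, not tolerances; oracle comparisons (a shortest-path Wang
  reimplementation on the parent/child graph via igraph, a component-wise
  IC reimplementation, an exhaustive MICA enumeration) use 1e-12.
* On-disk storage is plain TSV plus a JSON manifest, byte-deterministic,
  with multi-valued fields pipe-joined — portable and diffable where a
  binary columnar store would not be.
* RRF parsing tolerates the trailing pipe, keeps genuinely empty fields,
  and reports malformed lines by number (error in strict mode, skip with a
  warning otherwise).
* Lookups are case-sensitive on ids and case-insensitive on names (names
  are compared after normalization).
* The concept map enforces many-to-one: a concept id mapping to two terms
  is a construction error, caught when the dataset is built.

## Known limitations

Only MHs and SCRs are modelled (no qualifiers, no entry-term synonyms), so
dictionary recall on real text depends entirely on preferred names; the
recognizer is greedy and does not backtrack, so a longest match can shadow
an alternative segmentation; similarity between annotation *sets*
(best-match-average) is out of scope; and live count fetching is
intentionally stubbed behind an injectable transport.
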