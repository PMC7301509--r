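#' Most informative common ancestor of two main headings
#'
#' Ancestor sets are inclusive: each term counts as its own ancestor, so
#' `mica(d, d)` is `d` itself. Two headings whose tree numbers share no
#' top-level category letter have no MICA by convention (IC reported as 0),
#' as do same-category headings under different roots. Ties on IC break
#' toward the lexicographically smaller ui.
#'
#' @param ds A [mesh_dataset].
#' @param ic_table A [build_ic_table()] result.
#' @param ui1,ui2 MH ids.
#' @return A list with `mica_ui` (MH id or `NA`) and `mica_ic` (0 when
#'   absent).
#' @export
mica <- function(ds, ic_table, ui1, ui2) {
  if (length(intersect(term_categories(ds, ui1), term_categories(ds, ui2))) == 0) {
    return(list(mica_ui = NA_character_, mica_ic = 0))
  }
  anc1 <- c(ancestor_terms(ds, ui1), ui1)
  anc2 <- c(ancestor_terms(ds, ui2), ui2)
  common <- intersect(anc1, anc2)
  if (length(common) == 0) {
    return(list(mica_ui = NA_character_, mica_ic = 0))
  }
  ic <- term_ic(ic_table, common)
  best <- sort(common[ic == max(ic)])[[1]]
  list(mica_ui = best, mica_ic = max(ic))
}

#' Pairwise semantic-similarity measures between main headings
#'
#' The four information-content measures are driven by the IC of the most
#' informative common ancestor ([mica()]):
#'
#' * **Resnik** `= IC(MICA)` — unnormalized; larger for more specific
#'   shared ancestors.
#' * **Lin** `= 2 IC(MICA) / (IC(d1) + IC(d2))` in `[0, 1]`.
#' * **Jiang-Conrath** `= 1 - min(1, IC(d1) + IC(d2) - 2 IC(MICA))`,
#'   the clamped complement of the JC distance.
#' * **Schlicker** `= Lin * (1 - 10^(-IC(MICA)))`, Lin damped by the
#'   relevance factor `1 - P(MICA)` so shallow ancestors count less.
#'
#' All four return 0 when the two headings' category sets are disjoint
#' (including Jiang-Conrath, whose raw formula could otherwise be positive
#' across categories). When both headings have zero IC, Lin and Schlicker
#' return 1 for an identical pair and 0 otherwise.
#'
#' These are the raw per-pair measures over main headings; use
#' [mesh_similarity()] for SCR handling and the identity convention.
#'
#' @inheritParams mica
#' @return A single numeric similarity.
#' @name ic_measures
NULL

#' @rdname ic_measures
#' @export
sim_resnik <- function(ds, ic_table, ui1, ui2) {
  mica(ds, ic_table, ui1, ui2)$mica_ic
}

#' @rdname ic_measures
#' @export
sim_lin <- function(ds, ic_table, ui1, ui2) {
  m <- mica(ds, ic_table, ui1, ui2)
  if (is.na(m$mica_ui)) return(0)
  denom <- sum(term_ic(ic_table, c(ui1, ui2)))
  if (denom == 0) return(if (ui1 == ui2) 1 else 0)
  2 * m$mica_ic / denom
}

#' @rdname ic_measures
#' @export
sim_jc <- function(ds, ic_table, ui1, ui2) {
  m <- mica(ds, ic_table, ui1, ui2)
  if (is.na(m$mica_ui)) return(0)
  dist <- sum(term_ic(ic_table, c(ui1, ui2))) - 2 * m$mica_ic
  1 - min(1, dist)
}

#' @rdname ic_measures
#' @export
sim_rel <- function(ds, ic_table, ui1, ui2) {
  m <- mica(ds, ic_table, ui1, ui2)
  if (is.na(m$mica_ui)) return(0)
  sim_lin(ds, ic_table, ui1, ui2) * (1 - 10^(-m$mica_ic))
}

#' Wang semantic-contribution values of a main heading
#'
#' Over the inclusive ancestor set of `ui`, each ancestor `a` contributes
#' `S(a) = omega^n_a` where `n_a` is the minimum number of hierarchy edges
#' from the term to `a` over all of its tree-number paths (the term itself
#' contributes `omega^0 = 1`). `SV` is the sum of all contributions.
#'
#' @inheritParams mica
#' @param ui MH id.
#' @param omega Edge-decay weight in `[0, 1]`.
#' @return A list with `s` (named numeric vector, ancestor ui ->
#'   contribution) and `sv` (their sum).
#' @export
wang_s_values <- function(ds, ui, omega = 0.6) {
  if (omega < 0 || omega > 1) abort("omega must lie in [0, 1]")
  tns <- term_tree_numbers(ds, ui)
  dist <- c(setNames(0L, ui))
  for (t in tns) {
    anc <- tn_ancestors(t)   # nearest-first: ancestor k is k edges away
    if (length(anc) == 0) next
    owners <- ds$tn_owner[anc]
    if (anyNA(owners)) {
      abort(paste0("Dangling tree-number prefix(es): ",
                   paste(anc[is.na(owners)], collapse = ", ")),
            class = "meshsimr_dangling_prefix")
    }
    for (k in seq_along(anc)) {
      a <- unname(owners[[k]])
      if (is.na(dist[a]) || k < dist[a]) dist[a] <- k
    }
  }
  # a term can re-appear among its own ancestors only through a malformed
  # dataset; self distance stays 0
  dist[ui] <- 0L
  s <- omega^dist
  list(s = s, sv = sum(s))
}

#' Wang graph-based similarity between two main headings
#'
#' The summed contributions of the common inclusive ancestors, normalized
#' by the two terms' total semantic values:
#' `sum_t (S1(t) + S2(t)) / (SV1 + SV2)`. Terms in disjoint categories
#' share no ancestors and score 0.
#'
#' @inheritParams wang_s_values
#' @param ui1,ui2 MH ids.
#' @return Similarity in `[0, 1]`.
#' @export
sim_wang <- function(ds, ui1, ui2, omega = 0.6) {
  w1 <- wang_s_values(ds, ui1, omega)
  w2 <- wang_s_values(ds, ui2, omega)
  common <- intersect(names(w1$s), names(w2$s))
  if (length(common) == 0) return(0)
  sum(w1$s[common] + w2$s[common]) / (w1$sv + w2$sv)
}

#' Semantic similarity between two MeSH terms
#'
#' The user-facing entry point implementing the full comparison rules:
#'
#' * An SCR endpoint is replaced by its set of broader main headings; the
#'   similarity is the maximum over all cross pairs (for two SCRs, over
#'   the cross product of both broader sets).
#' * An identical resolved pair scores exactly 1 under every method, the
#'   boundary convention for same-term comparisons.
#' * Multiple tree numbers are handled inside the measures (IC methods
#'   through the global inclusive-ancestor MICA, Wang through
#'   minimum-edge-count contributions), which realizes the
#'   maximal-similarity rule.
#'
#' @param ds A [mesh_dataset].
#' @param ui1,ui2 MeSH ids (MH or SCR).
#' @param method One of `"res"`, `"lin"`, `"jc"`, `"rel"`, `"wang"`.
#' @param ic_table A [build_ic_table()] result; required for the four IC
#'   methods and defaulted from the dataset's own counts.
#' @param omega Wang edge-decay weight, default 0.6.
#' @return A single numeric similarity, symmetric in `ui1`/`ui2`.
#' @examples
#' ds <- generate_fixture(mesh_fixture_spec(seed = 1))
#' ic <- build_ic_table(ds)
#' mesh_similarity(ds, "D000002", "D000003", method = "lin", ic_table = ic)
#' @export
mesh_similarity <- function(ds, ui1, ui2,
                            method = c("res", "lin", "jc", "rel", "wang"),
                            ic_table = NULL, omega = 0.6) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "mesh_dataset"), length(ui1) == 1L, length(ui2) == 1L)
  if (method != "wang" && is.null(ic_table)) ic_table <- build_ic_table(ds)
  resolve <- function(ui) {
    if (is_mh(ds, ui)) return(ui)
    if (is_scr(ds, ui)) return(scr_broader_mhs(ds, ui))
    abort(paste0("Unknown MeSH id: ", ui), class = "meshsimr_unknown_id")
  }
  set1 <- resolve(ui1)
  set2 <- resolve(ui2)
  pair_sim <- function(a, b) {
    if (a == b) return(1)
    switch(method,
           res = sim_resnik(ds, ic_table, a, b),
           lin = sim_lin(ds, ic_table, a, b),
           jc = sim_jc(ds, ic_table, a, b),
           rel = sim_rel(ds, ic_table, a, b),
           wang = sim_wang(ds, a, b, omega))
  }
  max(vapply(set1, function(a) {
    max(vapply(set2, function(b) pair_sim(a, b), numeric(1)))
  }, numeric(1)))
}

#' Batch semantic similarity over a table of term pairs
#'
#' @param pairs Data frame with columns `ui1`, `ui2`.
#' @inheritParams mesh_similarity
#' @param methods Character vector of methods to evaluate per pair.
#' @return `pairs` with one added column per method, pipe-friendly.
#' @export
mesh_similarity_pairs <- function(pairs, ds,
                                  methods = c("res", "lin", "jc", "rel", "wang"),
                                  ic_table = NULL, omega = 0.6) {
  stopifnot(is.data.frame(pairs), all(c("ui1", "ui2") %in% names(pairs)))
  if (any(methods != "wang") && is.null(ic_table)) ic_table <- build_ic_table(ds)
  out <- tibble::as_tibble(pairs)
  for (m in methods) {
    out[[m]] <- purrr::map2_dbl(out$ui1, out$ui2, function(a, b) {
      mesh_similarity(ds, a, b, method = m, ic_table = ic_table, omega = omega)
    })
  }
  out
}
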