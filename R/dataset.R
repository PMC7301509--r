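#' Construct a MeSH dataset
#'
#' The in-memory model mirrors the five-table MeSH store: main headings
#' (MHs) with their tree numbers, supplementary concept records (SCRs),
#' the UMLS-concept-to-MeSH mapping, the SCR narrower/broader links to MHs,
#' and the MH parent/child table. An optional sixth table holds
#' non-MeSH-synonymous UMLS concepts used by the recognizer's recursive
#' route.
#'
#' Every stored term carries at least one UMLS concept id (CUI). MHs have a
#' non-empty tree-number set; SCRs have none and are instead linked to one
#' or more broader MHs. A term's category set is the set of first letters of
#' its tree numbers; for an SCR it is inherited from its broader MHs.
#'
#' @param main_headings Tibble with columns `ui`, `name`, `tree_numbers`
#'   (list of character), `semantic_types` (list), `cuis` (list),
#'   `pub_count` (integer, `NA` allowed).
#' @param scrs Tibble with columns `ui`, `name`, `semantic_types` (list),
#'   `cuis` (list), `pub_count`.
#' @param scr_broader Tibble with columns `scr_ui`, `mh_ui`.
#' @param parent_child Tibble with columns `parent_ui`, `child_ui`.
#' @param non_mesh_concepts Optional tibble with columns `cui`, `name`:
#'   UMLS concepts with no MeSH mapping, kept so their preferred names can
#'   be re-parsed as free text.
#' @param manifest Named list of dataset metadata; `n_total` (total number
#'   of publications indexed by MeSH) and `schema_version` are recognised.
#' @return An object of class `mesh_dataset`.
#' @seealso [generate_fixture()], [build_mesh_dataset()],
#'   [read_mesh_dataset()]
#' @export
mesh_dataset <- function(main_headings, scrs = NULL, scr_broader = NULL,
                         parent_child = NULL, non_mesh_concepts = NULL,
                         manifest = list()) {
  empty_terms <- tibble::tibble(
    ui = character(), name = character(), tree_numbers = list(),
    semantic_types = list(), cuis = list(), pub_count = integer())
  scrs <- scrs %||% empty_terms[, setdiff(names(empty_terms), "tree_numbers")]
  scr_broader <- scr_broader %||%
    tibble::tibble(scr_ui = character(), mh_ui = character())
  parent_child <- parent_child %||%
    tibble::tibble(parent_ui = character(), child_ui = character())
  non_mesh_concepts <- non_mesh_concepts %||%
    tibble::tibble(cui = character(), name = character())

  main_headings <- tibble::as_tibble(main_headings)
  scrs <- tibble::as_tibble(scrs)
  if (!"tree_numbers" %in% names(scrs)) scrs$tree_numbers <- rep(list(character(0)), nrow(scrs))

  ds <- structure(
    list(
      main_headings = main_headings,
      scrs = scrs,
      scr_broader = tibble::as_tibble(scr_broader),
      parent_child = tibble::as_tibble(parent_child),
      non_mesh_concepts = tibble::as_tibble(non_mesh_concepts),
      manifest = manifest
    ),
    class = "mesh_dataset"
  )
  ds <- build_indexes(ds)
  validate_mesh_dataset(ds)
  ds
}

# lookup indexes recomputed on construction/load; never serialized
build_indexes <- function(ds) {
  mh <- ds$main_headings
  all_tns <- unlist(mh$tree_numbers, use.names = FALSE)
  owner <- rep(mh$ui, lengths(mh$tree_numbers))
  if (anyDuplicated(all_tns)) {
    dup <- unique(all_tns[duplicated(all_tns)])
    abort(paste0("Tree number owned by more than one main heading: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  ds$tn_owner <- setNames(owner, all_tns)

  concept_map <- dplyr::bind_rows(
    tibble::tibble(cui = unlist(mh$cuis, use.names = FALSE),
                   ui = rep(mh$ui, lengths(mh$cuis))),
    tibble::tibble(cui = unlist(ds$scrs$cuis, use.names = FALSE),
                   ui = rep(ds$scrs$ui, lengths(ds$scrs$cuis)))
  )
  if (anyDuplicated(concept_map$cui)) {
    dup <- unique(concept_map$cui[duplicated(concept_map$cui)])
    abort(paste0("CUI mapped to more than one MeSH term: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  ds$concept_map <- setNames(concept_map$ui, concept_map$cui)
  ds
}

validate_mesh_dataset <- function(ds) {
  mh <- ds$main_headings
  if (any(lengths(mh$tree_numbers) == 0)) {
    abort("Every main heading must carry at least one tree number")
  }
  assert_tn(unlist(mh$tree_numbers, use.names = FALSE))
  if (any(lengths(mh$cuis) == 0) || any(lengths(ds$scrs$cuis) == 0)) {
    abort("Every stored term must map to at least one UMLS concept")
  }
  if (anyDuplicated(c(mh$ui, ds$scrs$ui))) {
    abort("Duplicate term ids across main headings and SCRs")
  }
  missing_scr <- setdiff(ds$scr_broader$scr_ui, ds$scrs$ui)
  missing_mh <- setdiff(ds$scr_broader$mh_ui, mh$ui)
  if (length(missing_scr) || length(missing_mh)) {
    abort(paste0("scr_broader references unknown ids: ",
                 paste(c(missing_scr, missing_mh), collapse = ", ")))
  }
  orphans <- setdiff(ds$scrs$ui, ds$scr_broader$scr_ui)
  if (length(orphans)) {
    abort(paste0("SCR(s) with no broader main heading: ",
                 paste(orphans, collapse = ", ")),
          class = "meshsimr_empty_broader")
  }
  pc_ids <- unique(c(ds$parent_child$parent_ui, ds$parent_child$child_ui))
  dangling <- setdiff(pc_ids, mh$ui)
  if (length(dangling)) {
    abort(paste0("parent_child references unknown main headings: ",
                 paste(dangling, collapse = ", ")))
  }
  invisible(ds)
}

#' @export
print.mesh_dataset <- function(x, ...) {
  n_tot <- x$manifest$n_total
  cat("<mesh_dataset>\n")
  cat("  main headings: ", nrow(x$main_headings), "\n", sep = "")
  cat("  SCRs:          ", nrow(x$scrs), "\n", sep = "")
  cat("  CUI mappings:  ", length(x$concept_map), "\n", sep = "")
  cat("  parent/child:  ", nrow(x$parent_child), "\n", sep = "")
  if (!is.null(n_tot)) cat("  N_total:       ", n_tot, "\n", sep = "")
  invisible(x)
}

#' All terms of a dataset as one tidy table
#'
#' @param ds A [mesh_dataset].
#' @return A tibble with one row per term (MH and SCR), columns `ui`,
#'   `name`, `record_kind`, `tree_numbers`, `categories`, `semantic_types`,
#'   `cuis`, `pub_count`.
#' @export
mesh_terms <- function(ds) {
  stopifnot(inherits(ds, "mesh_dataset"))
  mh <- ds$main_headings
  mh$record_kind <- rep("MH", nrow(mh))
  mh$categories <- lapply(mh$tree_numbers, function(t) sort(unique(substr(t, 1, 1))))
  sc <- ds$scrs
  sc$record_kind <- rep("SCR", nrow(sc))
  sc$categories <- lapply(sc$ui, function(u) term_categories(ds, u))
  dplyr::bind_rows(mh, sc)[, c("ui", "name", "record_kind", "tree_numbers",
                               "categories", "semantic_types", "cuis",
                               "pub_count")]
}

is_mh <- function(ds, ui) ui %in% ds$main_headings$ui
is_scr <- function(ds, ui) ui %in% ds$scrs$ui

#' Look up one term by its MeSH unique id
#'
#' @param ds A [mesh_dataset].
#' @param ui MeSH unique id (case-sensitive).
#' @return A one-row tibble with columns `ui`, `name`, `record_kind`,
#'   `tree_numbers`, `categories`, `semantic_types`, `cuis`, `pub_count`.
#' @export
get_term <- function(ds, ui) {
  stopifnot(inherits(ds, "mesh_dataset"), length(ui) == 1L)
  if (is_mh(ds, ui)) {
    row <- ds$main_headings[ds$main_headings$ui == ui, ]
    row$record_kind <- "MH"
    row$categories <- list(sort(unique(substr(row$tree_numbers[[1]], 1, 1))))
  } else if (is_scr(ds, ui)) {
    row <- ds$scrs[ds$scrs$ui == ui, ]
    row$record_kind <- "SCR"
    row$categories <- list(term_categories(ds, ui))
  } else {
    abort(paste0("Unknown MeSH id: ", ui), class = "meshsimr_unknown_id")
  }
  row[, c("ui", "name", "record_kind", "tree_numbers", "categories",
          "semantic_types", "cuis", "pub_count")]
}

#' Resolve a UMLS concept id to its MeSH term
#'
#' Several CUIs may map to the same main heading; a MeSH-synonymous SCR
#' concept maps one-to-one. Concepts with no MeSH mapping raise a
#' `meshsimr_no_mapping` condition; callers may then fall back on the
#' recognizer's recursive route.
#'
#' @param ds A [mesh_dataset].
#' @param cui UMLS concept id.
#' @return The mapped term as a one-row tibble (see [get_term()]).
#' @export
umls_to_mesh <- function(ds, cui) {
  stopifnot(inherits(ds, "mesh_dataset"), length(cui) == 1L)
  ui <- unname(ds$concept_map[cui])
  if (is.na(ui)) {
    abort(paste0("No MeSH mapping for concept ", cui),
          class = "meshsimr_no_mapping")
  }
  get_term(ds, ui)
}

#' Broader main headings of a supplementary concept record
#'
#' SCRs carry no tree numbers; before any hierarchy computation they are
#' replaced by their broader main headings (one or more).
#'
#' @param ds A [mesh_dataset].
#' @param scr_ui MeSH id of an SCR.
#' @return Character vector of MH uis (sorted, non-empty).
#' @export
scr_broader_mhs <- function(ds, scr_ui) {
  stopifnot(inherits(ds, "mesh_dataset"), length(scr_ui) == 1L)
  if (is_mh(ds, scr_ui)) {
    abort(paste0(scr_ui, " is a main heading, not an SCR"),
          class = "meshsimr_not_scr")
  }
  if (!is_scr(ds, scr_ui)) {
    abort(paste0("Unknown MeSH id: ", scr_ui), class = "meshsimr_unknown_id")
  }
  out <- sort(unique(ds$scr_broader$mh_ui[ds$scr_broader$scr_ui == scr_ui]))
  if (length(out) == 0) {
    abort(paste0("SCR ", scr_ui, " has an empty broader set"),
          class = "meshsimr_empty_broader")
  }
  out
}

# category set of a term; SCR categories are inherited from broader MHs
term_categories <- function(ds, ui) {
  if (is_mh(ds, ui)) {
    tns <- ds$main_headings$tree_numbers[[match(ui, ds$main_headings$ui)]]
    return(sort(unique(substr(tns, 1, 1))))
  }
  broader <- scr_broader_mhs(ds, ui)
  sort(unique(unlist(lapply(broader, term_categories, ds = ds))))
}

term_tree_numbers <- function(ds, ui) {
  i <- match(ui, ds$main_headings$ui)
  if (is.na(i)) abort(paste0("Unknown main heading: ", ui),
                      class = "meshsimr_unknown_id")
  ds$main_headings$tree_numbers[[i]]
}

#' Ancestor main headings of a term
#'
#' The ancestors of an MH are the owners of every proper dotted prefix of
#' every tree number the term carries; the term itself is excluded. A
#' prefix with no owning main heading indicates a broken dataset and raises
#' an error.
#'
#' @param ds A [mesh_dataset].
#' @param ui MeSH id of a main heading.
#' @return Character vector of ancestor MH uis (sorted, possibly empty).
#' @export
ancestor_terms <- function(ds, ui) {
  tns <- term_tree_numbers(ds, ui)
  pref <- unique(unlist(lapply(tns, tn_ancestors), use.names = FALSE))
  if (length(pref) == 0) return(character(0))
  owners <- ds$tn_owner[pref]
  if (anyNA(owners)) {
    abort(paste0("Dangling tree-number prefix(es): ",
                 paste(pref[is.na(owners)], collapse = ", ")),
          class = "meshsimr_dangling_prefix")
  }
  sort(unique(setdiff(unname(owners), ui)))
}
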