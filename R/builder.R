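#' Build a MeSH dataset from RRF-style pipe-delimited tables
#'
#' Assembles the five-table model from three pipe-delimited inputs:
#'
#' * **concepts** — one row per UMLS-concept mapping, logical fields `cui`,
#'   `ui`, `name`, `kind` (`MH`, `SCR`, or `NON_MESH` with empty `ui`) and
#'   `tree_number` (may be empty on secondary rows; MHs accumulate the set
#'   of their tree numbers over rows).
#' * **relations** — fields `ui1`, `rel`, `ui2`; `rel = "PAR"` records that
#'   `ui1` is a hierarchy parent of main heading `ui2`, `rel = "RB"` that
#'   `ui2` is a broader main heading of the SCR `ui1`.
#' * **semantic types** — fields `cui`, `sty`; a term collects the semantic
#'   types of all its concepts.
#'
#' UMLS distributions split these columns over wide tables whose exact
#' layout varies; the `*_columns` arguments let callers point the logical
#' fields at whatever column order their extraction produced.
#'
#' Dangling references (relation rows naming unknown ids, semantic types
#' for unknown concepts are ignored silently) are collected and reported in
#' one error; an SCR left with zero broader headings fails the build.
#'
#' @param concepts_file,relations_file,sty_file Paths to the pipe-delimited
#'   inputs.
#' @param out_path Optional directory; when given the five tables are
#'   written there via [write_mesh_dataset()].
#' @param concept_columns,relation_columns,sty_columns Column-name vectors
#'   for [parse_rrf()]; must contain the logical field names above.
#' @param strict Passed to [parse_rrf()].
#' @param manifest Extra manifest entries (e.g. `n_total`).
#' @return The assembled [mesh_dataset].
#' @export
build_mesh_dataset <- function(concepts_file, relations_file, sty_file,
                               out_path = NULL,
                               concept_columns = c("cui", "ui", "name",
                                                   "kind", "tree_number"),
                               relation_columns = c("ui1", "rel", "ui2"),
                               sty_columns = c("cui", "sty"),
                               strict = TRUE, manifest = list()) {
  con <- parse_rrf(concepts_file, concept_columns, strict = strict)
  rel <- parse_rrf(relations_file, relation_columns, strict = strict)
  sty <- parse_rrf(sty_file, sty_columns, strict = strict)
  for (f in c("cui", "ui", "name", "kind", "tree_number")) {
    if (!f %in% names(con)) abort(paste0("concept columns lack field '", f, "'"))
  }

  cui_sty <- function(cuis) {
    sort(unique(sty$sty[sty$cui %in% cuis & nzchar(sty$sty)]))
  }
  assemble <- function(rows, with_tn) {
    uis <- unique(rows$ui)
    tibble::tibble(
      ui = uis,
      name = vapply(uis, function(u) {
        nm <- rows$name[rows$ui == u & nzchar(rows$name)]
        if (length(nm) == 0) abort(paste0("No name for term ", u))
        nm[[1]]
      }, character(1)),
      tree_numbers = lapply(uis, function(u) {
        if (!with_tn) return(character(0))
        sort(unique(rows$tree_number[rows$ui == u & nzchar(rows$tree_number)]))
      }),
      semantic_types = lapply(uis, function(u) cui_sty(rows$cui[rows$ui == u])),
      cuis = lapply(uis, function(u) sort(unique(rows$cui[rows$ui == u]))),
      pub_count = rep(NA_integer_, length(uis))
    )
  }

  mh_rows <- con[con$kind == "MH", ]
  scr_rows <- con[con$kind == "SCR", ]
  nm_rows <- con[con$kind == "NON_MESH", ]
  if (nrow(mh_rows) == 0) abort("No main-heading rows in the concept file")
  mh <- assemble(mh_rows, with_tn = TRUE)
  scr <- assemble(scr_rows, with_tn = FALSE)[, c("ui", "name",
                                                 "semantic_types", "cuis",
                                                 "pub_count")]

  known <- c(mh$ui, scr$ui)
  dangling <- unique(c(rel$ui1[!rel$ui1 %in% known], rel$ui2[!rel$ui2 %in% known]))
  if (length(dangling)) {
    abort(paste0("Relation rows reference unknown MeSH ids: ",
                 paste(sort(dangling), collapse = ", ")),
          class = "meshsimr_dangling_reference")
  }
  pc <- rel[rel$rel == "PAR", c("ui1", "ui2")]
  names(pc) <- c("parent_ui", "child_ui")
  rb <- rel[rel$rel == "RB", c("ui1", "ui2")]
  names(rb) <- c("scr_ui", "mh_ui")
  bad_rb <- unique(c(rb$scr_ui[!rb$scr_ui %in% scr$ui],
                     rb$mh_ui[!rb$mh_ui %in% mh$ui]))
  if (length(bad_rb)) {
    abort(paste0("Broader relations must link an SCR to a main heading; bad ids: ",
                 paste(sort(bad_rb), collapse = ", ")),
          class = "meshsimr_dangling_reference")
  }
  nmc <- tibble::tibble(cui = unique(nm_rows$cui),
                        name = vapply(unique(nm_rows$cui), function(c) {
                          nm_rows$name[match(c, nm_rows$cui)]
                        }, character(1)))
  ds <- mesh_dataset(mh, scr, scr_broader = rb, parent_child = pc,
                     non_mesh_concepts = nmc, manifest = manifest)
  if (!is.null(out_path)) write_mesh_dataset(ds, out_path)
  ds
}
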