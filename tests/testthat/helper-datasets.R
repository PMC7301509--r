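# Shared fixtures, built in code. fx() memoises generator output per spec.

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(seed = 1, ...) {
  key <- paste(deparse(c(seed = seed, list(...))), collapse = "")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixture(mesh_fixture_spec(seed = seed, ...))
  }
  .fixture_cache[[key]]
}

term_row <- function(ui, name, tns, cuis, count, sty = "dsyn") {
  tibble::tibble(ui = ui, name = name, tree_numbers = list(tns),
                 semantic_types = list(sty), cuis = list(cuis),
                 pub_count = as.integer(count))
}

# hand-built hierarchy with round-number ICs (N = 1000, log base 10):
#   C01 (root, own 200)          rollup 500  IC ~ 0.30103
#   +-- C01.100 (own 100)        rollup 100  IC = 1
#   |   +-- C01.100.500 (own 0)  rollup 0->1 IC = 3
#   +-- C01.200 (own 200)        rollup 200  IC ~ 0.69897
#   F03 (root, own 500)          rollup 500
# plus one SCR broader to {C01.100, C01.200}
tiny_sim_dataset <- function() {
  mh <- dplyr::bind_rows(
    term_row("D000100", "root heading", "C01", "C0900001", 200),
    term_row("D000101", "alpha heading", "C01.100", "C0900002", 100),
    term_row("D000102", "alpha leaf", "C01.100.500", "C0900003", 0),
    term_row("D000103", "beta heading", "C01.200", "C0900004", 200),
    term_row("D000104", "psych root", "F03", "C0900005", 500))
  scr <- tibble::tibble(ui = "C500100", name = "alpha variant",
                        semantic_types = list("dsyn"),
                        cuis = list("C0900006"), pub_count = NA_integer_)
  rb <- tibble::tibble(scr_ui = c("C500100", "C500100"),
                       mh_ui = c("D000101", "D000103"))
  pc <- tibble::tibble(parent_ui = c("D000100", "D000100", "D000101"),
                       child_ui = c("D000101", "D000103", "D000102"))
  mesh_dataset(mh, scr, rb, pc, manifest = list(n_total = 1000))
}

# encodes the Tauopathies / Schizophrenia tree numbers in two categories
tiny_mica_dataset <- function() {
  mh <- dplyr::bind_rows(
    term_row("D000200", "nervous system diseases", "C10", "C0910001", 50),
    term_row("D000201", "neurodegenerative diseases", "C10.574", "C0910002", 30),
    term_row("D000202", "tauopathies", "C10.574.945", "C0910003", 10),
    term_row("D000203", "mental disorders", "F03", "C0910004", 40),
    term_row("D000204", "psychotic disorders", "F03.700", "C0910005", 20),
    term_row("D000205", "schizophrenia", "F03.700.750", "C0910006", 15))
  pc <- tibble::tibble(
    parent_ui = c("D000200", "D000201", "D000203", "D000204"),
    child_ui = c("D000201", "D000202", "D000204", "D000205"))
  mesh_dataset(mh, parent_child = pc, manifest = list(n_total = 165))
}

# dictionary-recognizer fixture: nested names, an SCR, a backtick-style
# possessive name, and a non-MeSH concept whose name embeds an MH name
tiny_recog_dataset <- function() {
  mh <- dplyr::bind_rows(
    term_row("D008168", "Lung", "A04.411", "C0920001", 10, sty = "bpoc"),
    term_row("D008171", "Lung Diseases", "C08.381", "C0920002", 20),
    term_row("D006111", "Graves Disease", "C19.874.397", c("C0920003", "C0920004"), 5),
    term_row("D019958", "C19 root", "C19", "C0920005", 3),
    term_row("D019959", "C19 mid", "C19.874", "C0920006", 2),
    term_row("D019960", "A04 root", "A04", "C0920007", 1, sty = "anst"),
    term_row("D019961", "C08 root", "C08", "C0920008", 4))
  scr <- tibble::tibble(ui = "C537710", name = "Bardet-Biedl Syndrome 11",
                        semantic_types = list("dsyn"),
                        cuis = list("C0920100"), pub_count = NA_integer_)
  rb <- tibble::tibble(scr_ui = c("C537710", "C537710"),
                       mh_ui = c("D008171", "D006111"))
  pc <- tibble::tibble(parent_ui = c("D019958", "D019959", "D019960", "D019961"),
                       child_ui = c("D019959", "D006111", "D008168", "D008171"))
  nmc <- tibble::tibble(cui = "C0999001",
                        name = "Graves Disease type 1")
  mesh_dataset(mh, scr, rb, pc, nmc, manifest = list(n_total = 100))
}

# serialize a dataset back into the builder's RRF dialect (test inputs)
rrf_lines_from_dataset <- function(ds) {
  mh <- ds$main_headings
  con <- character(0)
  for (i in seq_len(nrow(mh))) {
    cuis <- mh$cuis[[i]]
    tns <- mh$tree_numbers[[i]]
    n <- max(length(cuis), length(tns))
    for (j in seq_len(n)) {
      con <- c(con, paste0(paste(c(if (j <= length(cuis)) cuis[[j]] else cuis[[1]],
                                   mh$ui[[i]], mh$name[[i]], "MH",
                                   if (j <= length(tns)) tns[[j]] else ""),
                                 collapse = "|"), "|"))
    }
  }
  for (i in seq_len(nrow(ds$scrs))) {
    con <- c(con, paste0(paste(c(ds$scrs$cuis[[i]][[1]], ds$scrs$ui[[i]],
                                 ds$scrs$name[[i]], "SCR", ""),
                               collapse = "|"), "|"))
  }
  for (i in seq_len(nrow(ds$non_mesh_concepts))) {
    con <- c(con, paste0(paste(c(ds$non_mesh_concepts$cui[[i]], "",
                                 ds$non_mesh_concepts$name[[i]], "NON_MESH", ""),
                               collapse = "|"), "|"))
  }
  rel <- c(paste(ds$parent_child$parent_ui, "PAR", ds$parent_child$child_ui,
                 sep = "|"),
           paste(ds$scr_broader$scr_ui, "RB", ds$scr_broader$mh_ui, sep = "|"))
  sty <- unlist(lapply(seq_len(nrow(mh)), function(i) {
    paste(mh$cuis[[i]][[1]], mh$semantic_types[[i]], sep = "|")
  }))
  sty <- c(sty, unlist(lapply(seq_len(nrow(ds$scrs)), function(i) {
    paste(ds$scrs$cuis[[i]][[1]], ds$scrs$semantic_types[[i]], sep = "|")
  })))
  list(concepts = con, relations = rel, sty = sty)
}

write_rrf_fixture <- function(ds, dir) {
  lines <- rrf_lines_from_dataset(ds)
  paths <- list(concepts = file.path(dir, "concepts.rrf"),
                relations = file.path(dir, "relations.rrf"),
                sty = file.path(dir, "sty.rrf"))
  writeLines(lines$concepts, paths$concepts)
  writeLines(lines$relations, paths$relations)
  writeLines(lines$sty, paths$sty)
  paths
}
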