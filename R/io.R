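MESH_SCHEMA_VERSION <- "1.0"

join_multi <- function(x) vapply(x, function(v) paste(v, collapse = "|"), character(1))
split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1]]
  })
}

#' Write a MeSH dataset to a directory of TSV tables
#'
#' Five tab-separated tables plus a JSON manifest (schema version, column
#' names, `n_total`). Multi-valued fields (tree numbers, CUIs, semantic
#' types) are serialized as `"|"`-joined strings. The optional
#' `NonMeshConcepts` table is written only when non-empty. Output is
#' byte-deterministic for a given dataset.
#'
#' @param ds A [mesh_dataset].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_mesh_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mesh_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mh <- tibble::tibble(
    ui = ds$main_headings$ui,
    name = ds$main_headings$name,
    tree_numbers = join_multi(ds$main_headings$tree_numbers),
    semantic_types = join_multi(ds$main_headings$semantic_types),
    cuis = join_multi(ds$main_headings$cuis),
    pub_count = ds$main_headings$pub_count
  )
  scr <- tibble::tibble(
    ui = ds$scrs$ui,
    name = ds$scrs$name,
    semantic_types = join_multi(ds$scrs$semantic_types),
    cuis = join_multi(ds$scrs$cuis),
    pub_count = ds$scrs$pub_count
  )
  readr::write_tsv(mh, file.path(path, "MainHeadingDetailData.tsv"))
  cm <- tibble::tibble(cui = names(ds$concept_map), mh_ui = unname(ds$concept_map))
  cm <- cm[cm$mh_ui %in% ds$main_headings$ui, ]
  cm <- cm[order(cm$cui), ]
  readr::write_tsv(cm, file.path(path, "SupplementMainHeading.tsv"))
  readr::write_tsv(scr, file.path(path, "RNDetailData.tsv"))
  readr::write_tsv(ds$scr_broader, file.path(path, "RNandRBRel.tsv"))
  readr::write_tsv(ds$parent_child, file.path(path, "ParentChildRel.tsv"))
  if (nrow(ds$non_mesh_concepts) > 0) {
    readr::write_tsv(ds$non_mesh_concepts, file.path(path, "NonMeshConcepts.tsv"))
  }
  manifest <- ds$manifest
  manifest$schema_version <- MESH_SCHEMA_VERSION
  manifest$tables <- list(
    MainHeadingDetailData = nrow(mh), SupplementMainHeading = nrow(cm),
    RNDetailData = nrow(scr), RNandRBRel = nrow(ds$scr_broader),
    ParentChildRel = nrow(ds$parent_child)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a MeSH dataset from a directory written by [write_mesh_dataset()]
#'
#' @param path Dataset directory.
#' @return A [mesh_dataset].
#' @export
read_mesh_dataset <- function(path) {
  need <- c("MainHeadingDetailData.tsv", "SupplementMainHeading.tsv",
            "RNDetailData.tsv", "RNandRBRel.tsv", "ParentChildRel.tsv",
            "manifest.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(paste0("Not a MeSH dataset directory (missing ",
                 paste(missing, collapse = ", "), "): ", path))
  }
  rd <- function(f, types) readr::read_tsv(file.path(path, f), col_types = types,
                                           progress = FALSE)
  mh_raw <- rd("MainHeadingDetailData.tsv", "ccccci")
  cm <- rd("SupplementMainHeading.tsv", "cc")
  scr_raw <- rd("RNDetailData.tsv", "cccci")
  rel <- rd("RNandRBRel.tsv", "cc")
  pc <- rd("ParentChildRel.tsv", "cc")
  nm_path <- file.path(path, "NonMeshConcepts.tsv")
  nm <- if (file.exists(nm_path)) readr::read_tsv(nm_path, col_types = "cc",
                                                  progress = FALSE) else NULL
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)

  mh <- tibble::tibble(
    ui = mh_raw$ui, name = mh_raw$name,
    tree_numbers = split_multi(mh_raw$tree_numbers),
    semantic_types = split_multi(mh_raw$semantic_types),
    cuis = split_multi(mh_raw$cuis),
    pub_count = mh_raw$pub_count
  )
  # MH cuis in MainHeadingDetailData and SupplementMainHeading must agree;
  # the relation table is authoritative on load
  mh$cuis <- lapply(mh$ui, function(u) sort(cm$cui[cm$mh_ui == u]))
  scr <- tibble::tibble(
    ui = scr_raw$ui, name = scr_raw$name,
    semantic_types = split_multi(scr_raw$semantic_types),
    cuis = split_multi(scr_raw$cuis),
    pub_count = scr_raw$pub_count
  )
  mesh_dataset(mh, scr, rel, pc, nm, manifest = as.list(manifest))
}

#' Parse a UMLS RRF-style pipe-delimited file
#'
#' Rich Release Format: fields separated by `"|"`, a trailing separator
#' tolerated, no quoting, UTF-8. Rows whose field count disagrees with the
#' column map are an error in strict mode and are skipped with a warning
#' (carrying line numbers) in lenient mode.
#'
#' @param path File path.
#' @param columns Character vector of column names; its length fixes the
#'   expected field count.
#' @param strict Error on a malformed line (default) instead of skipping it.
#' @return A tibble with the named columns plus `line` (source line number).
#' @export
parse_rrf <- function(path, columns, strict = TRUE) {
  stopifnot(is.character(columns), length(columns) > 0)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(character(0)), length(columns)),
                                      columns))
    out$line <- integer(0)
    return(out)
  }
  # a trailing "|" terminates the last field; strip exactly one
  stripped <- sub("\\|$", "", lines)
  fields <- stringr::str_split(stripped, stringr::fixed("|"))
  n <- lengths(fields)
  bad <- which(n != length(columns))
  if (length(bad)) {
    msg <- paste0("RRF line(s) with wrong field count (expected ",
                  length(columns), "): ",
                  paste(head(bad, 5), collapse = ", "))
    if (strict) abort(msg, class = "meshsimr_rrf_parse_error")
    warn(paste0(msg, " - skipped"))
    fields <- fields[-bad]
  }
  keep <- setdiff(seq_along(n), bad)
  if (length(fields) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(character(0)), length(columns)),
                                      columns))
    out$line <- integer(0)
    return(out)
  }
  mat <- do.call(rbind, fields)
  out <- tibble::as_tibble(setNames(lapply(seq_along(columns),
                                           function(j) mat[, j]), columns))
  out$line <- keep
  out
}
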