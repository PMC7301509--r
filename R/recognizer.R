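#' Disease-related UMLS semantic types
#'
#' The default semantic-type filter of the recognizer: the 33 UMLS type
#' codes covering diseases, findings, anatomy and related categories that
#' biomedical phenotype phrases most often map to.
#'
#' @format Character vector of 33 type codes.
#' @export
mesh_disease_semantic_types <- c(
  "inpo", "dsyn", "phpr", "anab", "orgf", "clna", "hlca", "genf", "orga",
  "neop", "emod", "inbe", "lbtr", "anst", "npop", "celc", "cell", "bpoc",
  "acty", "mobd", "celf", "evnt", "sosy", "patf", "tisu", "moft", "fndg",
  "bdsu", "ortf", "menp", "acab", "comd", "sbst", "cgab")

#' Normalize a free-text phrase
#'
#' Deterministic, idempotent normalization applied both to dictionary
#' names and to query text: lowercasing; optional removal of possessive
#' `'s`; removal of ASCII and Unicode apostrophes and backticks (so
#' "Graves` disease" meets "Graves Disease"); all other punctuation
#' replaced by spaces; whitespace collapsed.
#'
#' @param text Character vector.
#' @param strip_possessives Drop a possessive `'s` before removing the
#'   apostrophe itself.
#' @return Normalized character vector (empty in, empty out).
#' @examples
#' normalize_phrase("Graves` disease")
#' normalize_phrase("Alzheimer's  Disease")
#' @export
normalize_phrase <- function(text, strip_possessives = TRUE) {
  out <- stringr::str_to_lower(text)
  if (strip_possessives) {
    out <- stringr::str_replace_all(out, "['‘’`´]s(?=\\s|$|[^a-z0-9])", "")
  }
  out <- stringr::str_replace_all(out, "['‘’`´]", "")
  out <- stringr::str_replace_all(out, "[^a-z0-9]+", " ")
  stringr::str_squish(out)
}

#' Recognizer configuration
#'
#' @param semantic_type_filter Set of UMLS semantic-type codes a match must
#'   carry at least one of; empty accepts everything. Defaults to
#'   [mesh_disease_semantic_types].
#' @param expand_scr Also emit, for every SCR match, one annotation per
#'   broader main heading (route `"scr_expanded"`).
#' @param recursion_depth_limit How many times the preferred name of a
#'   matched non-MeSH-synonymous concept may be re-submitted as free text
#'   (0 disables the recursive route).
#' @param strip_possessives Passed to [normalize_phrase()].
#' @param max_window Longest candidate match, in tokens.
#' @return A `mesh_recognizer_config` list.
#' @export
recognizer_config <- function(semantic_type_filter = mesh_disease_semantic_types,
                              expand_scr = FALSE, recursion_depth_limit = 2L,
                              strip_possessives = TRUE, max_window = 8L) {
  if (recursion_depth_limit < 0) abort("recursion_depth_limit must be >= 0")
  structure(list(semantic_type_filter = semantic_type_filter,
                 expand_scr = isTRUE(expand_scr),
                 recursion_depth_limit = as.integer(recursion_depth_limit),
                 strip_possessives = isTRUE(strip_possessives),
                 max_window = as.integer(max_window)),
            class = "mesh_recognizer_config")
}

empty_annotation <- function() {
  tibble::tibble(source_text = character(0), start = integer(0),
                 end = integer(0), cui = character(0), mesh_ui = character(0),
                 mesh_name = character(0), record_kind = character(0),
                 route = character(0), score = numeric(0))
}

# dictionary over normalized preferred names; kind CONCEPT rows are the
# non-MeSH-synonymous UMLS concepts (recursive route only)
name_index <- function(ds, cfg) {
  idx <- dplyr::bind_rows(
    tibble::tibble(name = ds$main_headings$name, ui = ds$main_headings$ui,
                   kind = "MH",
                   cui = vapply(ds$main_headings$cuis, `[[`, character(1), 1),
                   sty = ds$main_headings$semantic_types),
    tibble::tibble(name = ds$scrs$name, ui = ds$scrs$ui, kind = "SCR",
                   cui = vapply(ds$scrs$cuis, `[[`, character(1), 1),
                   sty = ds$scrs$semantic_types),
    tibble::tibble(name = ds$non_mesh_concepts$name,
                   ui = NA_character_, kind = "CONCEPT",
                   cui = ds$non_mesh_concepts$cui,
                   sty = rep(list(character(0)),
                             nrow(ds$non_mesh_concepts)))
  )
  idx$key <- normalize_phrase(idx$name, cfg$strip_possessives)
  flt <- cfg$semantic_type_filter
  if (length(flt) > 0) {
    keep <- vapply(seq_len(nrow(idx)), function(i) {
      idx$kind[[i]] == "CONCEPT" || length(idx$sty[[i]]) == 0 ||
        length(intersect(idx$sty[[i]], flt)) > 0
    }, logical(1))
    idx <- idx[keep, ]
  }
  idx[nzchar(idx$key), ]
}

# greedy left-to-right longest-match scan over normalized token windows;
# ties at one start: longer window, then MH > SCR > CONCEPT, then smaller ui
scan_text <- function(ds, text, cfg, idx, include_concepts) {
  if (!include_concepts) idx <- idx[idx$kind != "CONCEPT", ]
  if (nrow(idx) == 0 || is.na(text) || !nzchar(text)) return(empty_annotation())
  loc <- stringr::str_locate_all(text, "\\S+")[[1]]
  if (nrow(loc) == 0) return(empty_annotation())
  toks <- stringr::str_sub(text, loc[, 1], loc[, 2])
  norm <- normalize_phrase(toks, cfg$strip_possessives)
  n <- length(toks)
  maxw <- min(cfg$max_window, n)
  out <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (w in seq(min(maxw, n - i + 1L), 1L)) {
      parts <- norm[i:(i + w - 1L)]
      key <- paste(parts[nzchar(parts)], collapse = " ")
      if (!nzchar(key)) next
      hits <- idx[idx$key == key, ]
      if (nrow(hits) == 0) next
      rank <- match(hits$kind, c("MH", "SCR", "CONCEPT"))
      ord <- order(rank, hits$ui, hits$cui)
      hit <- hits[ord[[1]], ]
      out[[length(out) + 1L]] <- tibble::tibble(
        source_text = text,
        start = unname(loc[i, 1]) - 1L, end = unname(loc[i + w - 1L, 2]),
        cui = hit$cui,
        mesh_ui = hit$ui, mesh_name = hit$name,
        record_kind = if (hit$kind == "CONCEPT") "CONCEPT" else hit$kind,
        route = switch(hit$kind, MH = "direct", SCR = "scr",
                       CONCEPT = "concept"),
        score = 1)
      i <- i + w
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  if (length(out) == 0) return(empty_annotation())
  dplyr::bind_rows(out)
}

#' Match MeSH terms in free text by longest dictionary match
#'
#' Greedy left-to-right scan over normalized token windows against the
#' dataset vocabulary of preferred names. Matches never overlap and are
#' returned in ascending span order; spans are 0-based half-open character
#' offsets into the original text.
#'
#' @param ds A [mesh_dataset].
#' @param text One character string.
#' @param cfg A [recognizer_config()].
#' @return Annotation tibble with columns `source_text`, `start`, `end`,
#'   `cui`, `mesh_ui`, `mesh_name`, `record_kind` (`MH`/`SCR`), `route`
#'   (`direct`/`scr`) and `score`.
#' @export
match_concepts <- function(ds, text, cfg = recognizer_config()) {
  stopifnot(inherits(ds, "mesh_dataset"), length(text) == 1L)
  scan_text(ds, text, cfg, name_index(ds, cfg), include_concepts = FALSE)
}

# re-submit the preferred names of matched non-MeSH concepts as free text
resolve_recursive <- function(ds, ann, cfg, idx, depth, visited) {
  if (nrow(ann) == 0) return(empty_annotation())
  keep <- ann[ann$record_kind != "CONCEPT", ]
  concepts <- ann[ann$record_kind == "CONCEPT", ]
  resolved <- list()
  for (j in seq_len(nrow(concepts))) {
    nm <- normalize_phrase(concepts$mesh_name[[j]], cfg$strip_possessives)
    if (depth >= cfg$recursion_depth_limit || nm %in% visited) next
    # drop already-visited concept names so a concept cannot re-match itself
    idx_j <- idx[!(idx$kind == "CONCEPT" & idx$key %in% c(visited, nm)), ]
    inner <- scan_text(ds, concepts$mesh_name[[j]], cfg, idx_j,
                       include_concepts = TRUE)
    inner <- resolve_recursive(ds, inner, cfg, idx_j, depth + 1L,
                               c(visited, nm))
    if (nrow(inner) == 0) next
    inner$source_text <- concepts$source_text[[j]]
    inner$start <- concepts$start[[j]]
    inner$end <- concepts$end[[j]]
    inner$cui <- concepts$cui[[j]]
    inner$route <- "recursive"
    resolved[[length(resolved) + 1L]] <- inner
  }
  dplyr::bind_rows(c(list(keep), resolved))
}

expand_scr_annotations <- function(ds, ann) {
  scr_rows <- ann[ann$record_kind == "SCR", ]
  if (nrow(scr_rows) == 0) return(ann)
  extra <- lapply(seq_len(nrow(scr_rows)), function(j) {
    broader <- scr_broader_mhs(ds, scr_rows$mesh_ui[[j]])
    tibble::tibble(
      source_text = scr_rows$source_text[[j]],
      start = scr_rows$start[[j]], end = scr_rows$end[[j]],
      cui = scr_rows$cui[[j]],
      mesh_ui = broader,
      mesh_name = ds$main_headings$name[match(broader, ds$main_headings$ui)],
      record_kind = "MH", route = "scr_expanded",
      score = scr_rows$score[[j]])
  })
  dplyr::bind_rows(c(list(ann), extra))
}

order_annotations <- function(ann) {
  route_rank <- match(ann$route, c("direct", "scr", "recursive", "scr_expanded"))
  ann[order(ann$start, ann$end, route_rank, ann$mesh_ui), ]
}

#' Parse free text into MeSH annotations
#'
#' [match_concepts()] plus the two normalization routes:
#' matched non-MeSH-synonymous concepts have their preferred names
#' re-submitted as free text (route `"recursive"`, bounded by
#' `recursion_depth_limit` with cycle detection), and with
#' `expand_scr` every SCR match additionally emits one annotation per
#' broader main heading (route `"scr_expanded"`).
#'
#' @inheritParams match_concepts
#' @return Annotation tibble (see [match_concepts()]); `route` gains the
#'   values `"recursive"` and `"scr_expanded"`.
#' @export
parse_text <- function(ds, text, cfg = recognizer_config()) {
  stopifnot(inherits(ds, "mesh_dataset"), length(text) == 1L)
  idx <- name_index(ds, cfg)
  ann <- scan_text(ds, text, cfg, idx,
                   include_concepts = cfg$recursion_depth_limit > 0)
  ann <- resolve_recursive(ds, ann, cfg, idx, depth = 0L, visited = character(0))
  if (cfg$expand_scr) ann <- expand_scr_annotations(ds, ann)
  order_annotations(ann)
}

#' Annotate a table of phrases
#'
#' Pipe-friendly wrapper running [parse_text()] over every row of a phrase
#' table.
#'
#' @param phrases Data frame with a text column.
#' @param ds A [mesh_dataset].
#' @param cfg A [recognizer_config()].
#' @param text_col Name of the text column (default `"text"`).
#' @return One annotation tibble with a leading `phrase_id` column (row
#'   number in `phrases`).
#' @export
annotate_phrases <- function(phrases, ds, cfg = recognizer_config(),
                             text_col = "text") {
  stopifnot(is.data.frame(phrases), text_col %in% names(phrases))
  out <- lapply(seq_len(nrow(phrases)), function(i) {
    ann <- parse_text(ds, phrases[[text_col]][[i]], cfg)
    if (nrow(ann) > 0) ann <- tibble::add_column(ann, phrase_id = i,
                                                 .before = 1)
    ann
  })
  dplyr::bind_rows(out)
}

#' Ingest MetaMap fielded (MMI) output
#'
#' Parses the pipe-delimited MMI stream (fields: id, record type, score,
#' preferred name, CUI, semantic types, trigger, location, positional
#' info). Only `MMI` records are used; other record types (e.g. `AA`
#' abbreviation lines) are ignored. Each row's CUI is resolved through the
#' concept map; CUIs unknown to the dataset are routed through the
#' recursive path on the row's preferred name. Scores are rescaled from
#' MetaMap's 0-1000 range to `[0, 1]`. Positional info `start/length` is
#' taken as a 1-based offset and converted to a 0-based half-open span.
#'
#' @param ds A [mesh_dataset].
#' @param lines Character vector of MMI lines (or a connection/file path
#'   readable by [readr::read_lines()]).
#' @param cfg A [recognizer_config()].
#' @return Annotation tibble (see [match_concepts()]).
#' @export
parse_mmi_output <- function(ds, lines, cfg = recognizer_config()) {
  stopifnot(inherits(ds, "mesh_dataset"))
  if (length(lines) == 1L && file.exists(lines)) {
    lines <- readr::read_lines(lines, progress = FALSE)
  }
  idx <- name_index(ds, cfg)
  out <- list()
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (!nzchar(ln)) next
    f <- strsplit(sub("\\|$", "", ln), "|", fixed = TRUE)[[1]]
    if (length(f) < 2 || f[[2]] != "MMI") next
    if (length(f) < 9) {
      warn(paste0("Malformed MMI line ", k, " skipped"))
      next
    }
    score <- suppressWarnings(as.numeric(f[[3]]))
    if (is.na(score)) {
      warn(paste0("Malformed MMI line ", k, " skipped"))
      next
    }
    score <- min(1, max(0, score / 1000))
    pref_name <- f[[4]]
    cui <- f[[5]]
    stys <- strsplit(gsub("\\[|\\]", "", f[[6]]), ",", fixed = TRUE)[[1]]
    stys <- stringr::str_squish(stys)
    flt <- cfg$semantic_type_filter
    if (length(flt) > 0 && length(stys) > 0 &&
        length(intersect(stys, flt)) == 0) next
    pos <- stringr::str_match(f[[9]], "([0-9]+)/([0-9]+)")
    start <- if (is.na(pos[1, 2])) 0L else as.integer(pos[1, 2]) - 1L
    len <- if (is.na(pos[1, 3])) nchar(pref_name) else as.integer(pos[1, 3])

    ui <- unname(ds$concept_map[cui])
    if (!is.na(ui)) {
      term <- get_term(ds, ui)
      out[[length(out) + 1L]] <- tibble::tibble(
        source_text = pref_name, start = start, end = start + len,
        cui = cui, mesh_ui = ui, mesh_name = term$name,
        record_kind = term$record_kind,
        route = if (term$record_kind == "SCR") "scr" else "direct",
        score = score)
    } else if (cfg$recursion_depth_limit > 0) {
      nm <- normalize_phrase(pref_name, cfg$strip_possessives)
      idx_r <- idx[!(idx$kind == "CONCEPT" & idx$key == nm), ]
      inner <- scan_text(ds, pref_name, cfg, idx_r, include_concepts = TRUE)
      inner <- resolve_recursive(ds, inner, cfg, idx_r, depth = 1L,
                                 visited = nm)
      if (nrow(inner) > 0) {
        inner$source_text <- pref_name
        inner$start <- start
        inner$end <- start + len
        inner$cui <- cui
        inner$route <- "recursive"
        inner$score <- score
        out[[length(out) + 1L]] <- inner
      }
    }
  }
  ann <- dplyr::bind_rows(c(list(empty_annotation()), out))
  if (cfg$expand_scr) ann <- expand_scr_annotations(ds, ann)
  order_annotations(ann)
}
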