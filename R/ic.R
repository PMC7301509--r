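#' Publication-count frequency table
#'
#' Holds the per-main-heading publication counts and the total number of
#' publications indexed by MeSH (`N`), the two quantities information
#' content is estimated from.
#'
#' @param counts Either a named integer vector (names = MH uis) or a data
#'   frame with columns `ui` (or `mesh_ui`) and `count`.
#' @param n_total Total number of publications indexed by MeSH; must be
#'   positive.
#' @return A `mesh_freq_table`: tibble with columns `ui`, `count` and
#'   attribute `n_total`.
#' @export
frequency_table <- function(counts, n_total) {
  if (is.data.frame(counts)) {
    nm <- if ("ui" %in% names(counts)) "ui" else "mesh_ui"
    tbl <- tibble::tibble(ui = as.character(counts[[nm]]),
                          count = as.integer(counts$count))
  } else {
    tbl <- tibble::tibble(ui = names(counts), count = as.integer(counts))
  }
  if (any(tbl$count < 0, na.rm = TRUE)) abort("Counts must be non-negative")
  if (!is.numeric(n_total) || n_total <= 0) {
    abort("n_total must be a positive number", class = "meshsimr_bad_n")
  }
  structure(tbl, n_total = as.numeric(n_total),
            class = c("mesh_freq_table", class(tbl)))
}

#' Frequency table carried by a dataset
#'
#' Reads the per-term `pub_count` column and the manifest's `n_total`.
#'
#' @param ds A [mesh_dataset].
#' @return A [frequency_table()].
#' @export
dataset_frequency_table <- function(ds) {
  stopifnot(inherits(ds, "mesh_dataset"))
  if (is.null(ds$manifest$n_total)) {
    abort("Dataset manifest has no n_total; supply a frequency table")
  }
  cnt <- ds$main_headings$pub_count
  keep <- !is.na(cnt)
  frequency_table(setNames(cnt[keep], ds$main_headings$ui[keep]),
                  ds$manifest$n_total)
}

#' Read / write a publication-count TSV
#'
#' Columns `mesh_ui`, `name`, `count`; the total is carried in a sibling
#' JSON manifest under key `N_total`.
#'
#' @param path TSV path; the manifest is `<path>.manifest.json`.
#' @param ds Optional dataset used to fill the `name` column on write.
#' @param ft A [frequency_table()].
#' @return `read_counts_tsv()` a [frequency_table()].
#' @export
read_counts_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
  man <- paste0(path, ".manifest.json")
  if (!file.exists(man)) abort(paste0("Missing counts manifest: ", man))
  n_total <- jsonlite::read_json(man, simplifyVector = TRUE)$N_total
  frequency_table(setNames(tbl$count, tbl$mesh_ui), n_total)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(ft, path, ds = NULL) {
  stopifnot(inherits(ft, "mesh_freq_table"))
  nm <- if (!is.null(ds)) {
    ds$main_headings$name[match(ft$ui, ds$main_headings$ui)]
  } else NA_character_
  readr::write_tsv(tibble::tibble(mesh_ui = ft$ui, name = nm, count = ft$count),
                   path)
  jsonlite::write_json(list(N_total = attr(ft, "n_total")),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Descendant closure of a main heading
#'
#' All main headings owning a tree number that properly extends any tree
#' number of `ui`. The closure is inclusive by default (the term counts as
#' its own descendant), which is the standard construction for
#' corpus-frequency information content: without it a leaf's rolled-up
#' frequency would be zero.
#'
#' @param ds A [mesh_dataset].
#' @param ui MH id.
#' @param inclusive Include `ui` itself (default `TRUE`).
#' @return Character vector of MH uis (sorted).
#' @export
descendant_closure <- function(ds, ui, inclusive = TRUE) {
  tns <- term_tree_numbers(ds, ui)
  all_tn <- names(ds$tn_owner)
  hit <- rep(FALSE, length(all_tn))
  for (t in tns) hit <- hit | startsWith(all_tn, paste0(t, "."))
  out <- unique(unname(ds$tn_owner[hit]))
  out <- setdiff(out, ui)
  if (inclusive) out <- c(out, ui)
  sort(out)
}

#' Rolled-up publication frequency of a term
#'
#' Sum of the publication counts over the term's descendant closure;
#' headings absent from the frequency table contribute zero.
#'
#' @inheritParams descendant_closure
#' @param ft A [frequency_table()].
#' @return A single non-negative number.
#' @export
rollup_frequency <- function(ds, ui, ft, inclusive = TRUE) {
  dc <- descendant_closure(ds, ui, inclusive = inclusive)
  sum(ft$count[ft$ui %in% dc], na.rm = TRUE)
}

#' Information content of a main heading
#'
#' `IC(d) = -log10(freq(D(d)) / N)` where `D(d)` is the descendant closure
#' and `N` the total number of publications indexed by MeSH. A zero
#' roll-up is replaced by a pseudo-count of 1, so unindexed terms are
#' maximally informative rather than undefined.
#'
#' @inheritParams rollup_frequency
#' @return IC value (>= 0 whenever roll-ups never exceed `N`).
#' @export
information_content <- function(ds, ui, ft, inclusive = TRUE) {
  n_total <- attr(ft, "n_total")
  if (is.null(n_total) || n_total <= 0) {
    abort("Frequency table has no positive n_total", class = "meshsimr_bad_n")
  }
  freq <- rollup_frequency(ds, ui, ft, inclusive = inclusive)
  if (freq == 0) freq <- 1
  -log10(freq / n_total)
}

#' Information-content table for every main heading
#'
#' @inheritParams rollup_frequency
#' @param ft A [frequency_table()]; defaults to the counts carried by the
#'   dataset itself.
#' @return A `mesh_ic_table`: tibble with columns `ui`, `rollup`, `ic`,
#'   attributes `n_total`, `log_base` (10) and `inclusive`.
#' @export
build_ic_table <- function(ds, ft = dataset_frequency_table(ds),
                           inclusive = TRUE) {
  stopifnot(inherits(ds, "mesh_dataset"))
  n_total <- attr(ft, "n_total")
  if (is.null(n_total) || n_total <= 0) {
    abort("Frequency table has no positive n_total", class = "meshsimr_bad_n")
  }
  uis <- ds$main_headings$ui
  rollup <- vapply(uis, rollup_frequency, numeric(1), ds = ds, ft = ft,
                   inclusive = inclusive)
  ic <- -log10(pmax(rollup, 1) / n_total)
  structure(tibble::tibble(ui = uis, rollup = unname(rollup), ic = unname(ic)),
            n_total = n_total, log_base = 10, inclusive = inclusive,
            class = c("mesh_ic_table", "tbl_df", "tbl", "data.frame"))
}

term_ic <- function(ic_table, ui) {
  v <- ic_table$ic[match(ui, ic_table$ui)]
  if (anyNA(v)) {
    abort(paste0("No IC value for: ", paste(ui[is.na(v)], collapse = ", ")),
          class = "meshsimr_unknown_id")
  }
  v
}
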