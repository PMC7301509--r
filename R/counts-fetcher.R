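#' Fetch per-term publication counts through an injectable fetcher
#'
#' Publication counts per MeSH term normally come from a MeSH-field search
#' of PubMed (one record count per term name). To keep every run
#' reproducible and offline-safe the transport is injected: `fetcher` is
#' any function taking one term name and returning the raw response body.
#' Responses in either E-utilities XML style (`<Count>42</Count>`) or
#' simple `count=42` form are parsed; anything else raises a transport
#' error after `retries` further attempts. Results are cached in a TSV so
#' repeated calls never re-query.
#'
#' @param terms Tibble with columns `ui`, `name` (e.g. from
#'   [mesh_terms()]), or a named character vector `ui -> name`.
#' @param fetcher `function(name) -> character` response body. May also be
#'   a named character vector of recorded responses keyed by term name.
#' @param n_total Total publication count for the resulting
#'   [frequency_table()].
#' @param cache_path Optional TSV path; hits are served from it without
#'   calling `fetcher`, and new results are appended.
#' @param retries Extra attempts per term after a failure.
#' @return A [frequency_table()]. Failed terms abort with a partial-results
#'   report naming them.
#' @export
fetch_publication_counts <- function(terms, fetcher, n_total,
                                     cache_path = NULL, retries = 1L) {
  if (!is.data.frame(terms)) {
    terms <- tibble::tibble(ui = names(terms), name = unname(terms))
  }
  if (is.character(fetcher)) {
    recorded <- fetcher
    fetcher <- function(name) {
      if (!name %in% names(recorded)) stop("no recorded response for ", name)
      recorded[[name]]
    }
  }
  cache <- if (!is.null(cache_path) && file.exists(cache_path)) {
    readr::read_tsv(cache_path, col_types = "ci", progress = FALSE)
  } else tibble::tibble(name = character(0), count = integer(0))

  counts <- integer(nrow(terms))
  failed <- character(0)
  for (i in seq_len(nrow(terms))) {
    nm <- terms$name[[i]]
    hit <- match(nm, cache$name)
    if (!is.na(hit)) {
      counts[[i]] <- cache$count[[hit]]
      next
    }
    val <- NA_integer_
    for (attempt in seq_len(1L + retries)) {
      body <- tryCatch(fetcher(nm), error = function(e) NULL)
      if (!is.null(body)) {
        val <- parse_count_response(body)
        if (!is.na(val)) break
      }
    }
    if (is.na(val)) {
      failed <- c(failed, nm)
      next
    }
    counts[[i]] <- val
    cache <- dplyr::bind_rows(cache, tibble::tibble(name = nm, count = val))
  }
  if (!is.null(cache_path)) readr::write_tsv(cache, cache_path)
  if (length(failed)) {
    abort(paste0("Count fetch failed for ", length(failed), " term(s): ",
                 paste(head(failed, 10), collapse = ", "),
                 "; ", nrow(terms) - length(failed), " succeeded"),
          class = "meshsimr_transport_error")
  }
  frequency_table(setNames(counts, terms$ui), n_total)
}

parse_count_response <- function(body) {
  body <- paste(body, collapse = "\n")
  m <- stringr::str_match(body, "<Count>\\s*([0-9]+)\\s*</Count>")[, 2]
  if (is.na(m)) m <- stringr::str_match(body, "count\\s*=\\s*([0-9]+)")[, 2]
  if (is.na(m)) return(NA_integer_)
  as.integer(m)
}
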