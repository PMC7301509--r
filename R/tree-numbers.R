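#' Tree numbers
#'
#' A MeSH tree number is the dotted hierarchical address of a main heading,
#' e.g. `"C10.574.945"`. The first component starts with a single uppercase
#' letter naming the MeSH category ("C" diseases, "F" psychiatry and
#' psychology, ...); every proper dotted prefix addresses an ancestor.
#'
#' @param tn Character vector of tree numbers.
#' @return `tn_valid()` a logical vector; `tn_category()` the single-letter
#'   category of each tree number; `tn_depth()` the number of dotted
#'   components; `tn_ancestors()` a character vector of all proper prefixes
#'   of one tree number, nearest ancestor first (empty for a top-level
#'   node).
#' @examples
#' tn_ancestors("C10.574.945")
#' tn_category("F03.700.750")
#' @name tree_numbers
NULL

#' @rdname tree_numbers
#' @export
tn_valid <- function(tn) {
  !is.na(tn) & stringr::str_detect(tn, "^[A-Z][0-9A-Za-z]*(\\.[0-9A-Za-z]+)*$")
}

assert_tn <- function(tn) {
  bad <- tn[!tn_valid(tn)]
  if (length(bad) > 0) {
    abort(paste0("Malformed tree number(s): ", paste(bad, collapse = ", ")),
          class = "meshsimr_bad_tree_number")
  }
  invisible(tn)
}

#' @rdname tree_numbers
#' @export
tn_category <- function(tn) {
  assert_tn(tn)
  substr(tn, 1L, 1L)
}

#' @rdname tree_numbers
#' @export
tn_depth <- function(tn) {
  assert_tn(tn)
  stringr::str_count(tn, stringr::fixed(".")) + 1L
}

#' @rdname tree_numbers
#' @export
tn_ancestors <- function(tn) {
  stopifnot(length(tn) == 1L)
  assert_tn(tn)
  parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
  n <- length(parts)
  if (n == 1L) return(character(0))
  # nearest-first: drop one trailing component at a time
  vapply(seq(n - 1L, 1L), function(k) paste(parts[seq_len(k)], collapse = "."),
         character(1))
}

# parent tree number (one component shorter), NA for top-level nodes
tn_parent <- function(tn) {
  anc <- lapply(tn, tn_ancestors)
  vapply(anc, function(a) if (length(a)) a[[1]] else NA_character_, character(1))
}
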