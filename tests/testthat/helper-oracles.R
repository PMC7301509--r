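# Independent oracles. These deliberately avoid the package's prefix-string
# machinery: ancestry is recomputed from split components, Wang distances
# from shortest paths on the ParentChildRel graph.

split_tn <- function(tn) strsplit(tn, ".", fixed = TRUE)[[1]]

# all proper prefixes of a tree number, by explicit component enumeration
oracle_prefixes <- function(tn) {
  parts <- split_tn(tn)
  if (length(parts) < 2) return(character(0))
  out <- character(0)
  acc <- parts[[1]]
  for (k in 2:length(parts)) {
    out <- c(out, acc)
    acc <- paste(acc, parts[[k]], sep = ".")
  }
  out
}

# inclusive ancestor set of a heading by brute component comparison
oracle_ancestor_set <- function(ds, ui) {
  tns <- ds$main_headings$tree_numbers[[match(ui, ds$main_headings$ui)]]
  pref <- unique(unlist(lapply(tns, oracle_prefixes)))
  owners <- vapply(seq_len(nrow(ds$main_headings)), function(i) {
    any(ds$main_headings$tree_numbers[[i]] %in% pref)
  }, logical(1))
  unique(c(ds$main_headings$ui[owners], ui))
}

# inclusive descendant set: component-wise proper-extension test
oracle_descendant_set <- function(ds, ui) {
  tns <- ds$main_headings$tree_numbers[[match(ui, ds$main_headings$ui)]]
  is_ext <- function(long, short) {
    a <- split_tn(long); b <- split_tn(short)
    length(a) > length(b) && identical(a[seq_along(b)], b)
  }
  hit <- vapply(seq_len(nrow(ds$main_headings)), function(i) {
    any(vapply(ds$main_headings$tree_numbers[[i]], function(l) {
      any(vapply(tns, function(s) is_ext(l, s), logical(1)))
    }, logical(1)))
  }, logical(1))
  unique(c(ds$main_headings$ui[hit], ui))
}

oracle_ic <- function(ds, ui, ft) {
  dc <- oracle_descendant_set(ds, ui)
  freq <- sum(ft$count[ft$ui %in% dc], na.rm = TRUE)
  -log10(max(freq, 1) / attr(ft, "n_total"))
}

oracle_mica_ic <- function(ds, ic_table, ui1, ui2) {
  cat1 <- unique(substr(unlist(ds$main_headings$tree_numbers[
    match(ui1, ds$main_headings$ui)]), 1, 1))
  cat2 <- unique(substr(unlist(ds$main_headings$tree_numbers[
    match(ui2, ds$main_headings$ui)]), 1, 1))
  if (length(intersect(cat1, cat2)) == 0) return(0)
  common <- intersect(oracle_ancestor_set(ds, ui1), oracle_ancestor_set(ds, ui2))
  if (length(common) == 0) return(0)
  max(ic_table$ic[match(common, ic_table$ui)])
}

# Wang by shortest-path distances on the parent/child graph (igraph)
oracle_wang_s <- function(g, all_uis, ui, omega) {
  d <- igraph::distances(g, v = ui, to = all_uis, mode = "out")[1, ]
  d <- d[is.finite(d)]
  omega^d
}

oracle_wang <- function(ds, ui1, ui2, omega) {
  g <- parent_child_graph(ds)
  uis <- ds$main_headings$ui
  s1 <- oracle_wang_s(g, uis, ui1, omega)
  s2 <- oracle_wang_s(g, uis, ui2, omega)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

.graph_cache <- new.env(parent = emptyenv())
parent_child_graph <- function(ds) {
  key <- digest_ds(ds)
  if (is.null(.graph_cache[[key]])) {
    edges <- rbind(ds$parent_child$child_ui, ds$parent_child$parent_ui)
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, nrow(ds$main_headings),
                              name = ds$main_headings$ui)
    g <- igraph::add_edges(g, as.vector(edges))
    .graph_cache[[key]] <- g
  }
  .graph_cache[[key]]
}

digest_ds <- function(ds) {
  paste0(nrow(ds$main_headings), "-", nrow(ds$parent_child), "-",
         ds$main_headings$ui[[1]], "-",
         ds$main_headings$ui[[nrow(ds$main_headings)]])
}

# transitive closure of parent_child above a node (BFS over edges)
oracle_pc_ancestors <- function(ds, ui) {
  out <- character(0)
  frontier <- ui
  while (length(frontier) > 0) {
    parents <- unique(ds$parent_child$parent_ui[
      ds$parent_child$child_ui %in% frontier])
    parents <- setdiff(parents, out)
    out <- c(out, parents)
    frontier <- parents
  }
  sort(setdiff(out, ui))
}
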