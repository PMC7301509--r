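#' Specify a synthetic MeSH fixture
#'
#' The generator emulates the structural features of MeSH that the rest of
#' the toolkit depends on: per-category rooted hierarchies addressed by
#' dotted tree numbers, occasional multi-parent placements (a second tree
#' number mirrored through the whole subtree, as real MeSH placements are),
#' SCRs attached to one or more broader main headings, many-to-one
#' CUI-to-MH mappings, and a heavy-tailed distribution of per-term
#' publication counts (many rare terms, few common ones).
#'
#' @param seed Integer RNG seed; the same spec and seed reproduce
#'   byte-identical tables.
#' @param n_categories Number of top-level MeSH categories (letters drawn
#'   from C, F, A, B, D, E, G, H in that order).
#' @param max_depth Levels per category tree (root = level 1).
#' @param branching Children per internal node.
#' @param n_scrs Number of supplementary concept records.
#' @param multi_parent_rate Probability that a node at depth >= 3 receives
#'   an extra parent (and hence an extra tree number) within its category.
#' @param n_non_mesh Number of non-MeSH-synonymous UMLS concepts whose
#'   names embed a main-heading name (feeds the recognizer's recursive
#'   route).
#' @param count_alpha,count_min,count_max Parameters of the discrete
#'   power-law-like publication-count draw
#'   `min(count_max, floor(count_min * u^(-1/(count_alpha - 1))))`.
#' @param zero_count_rate Probability that a term has no indexed
#'   publications of its own.
#' @param extra_cui_rate Probability that a main heading carries a second
#'   UMLS concept.
#' @param n_total Total number of publications indexed by MeSH; defaults to
#'   the sum of all per-term counts, so with two or more populated
#'   categories every term keeps strictly positive information content.
#' @return A `mesh_fixture_spec` list.
#' @export
mesh_fixture_spec <- function(seed = 1L, n_categories = 2L, max_depth = 4L,
                              branching = 3L, n_scrs = 6L,
                              multi_parent_rate = 0.1, n_non_mesh = 3L,
                              count_alpha = 2, count_min = 1,
                              count_max = 10000, zero_count_rate = 0.05,
                              extra_cui_rate = 0.3, n_total = NULL) {
  spec <- list(seed = as.integer(seed), n_categories = as.integer(n_categories),
               max_depth = as.integer(max_depth), branching = as.integer(branching),
               n_scrs = as.integer(n_scrs), multi_parent_rate = multi_parent_rate,
               n_non_mesh = as.integer(n_non_mesh), count_alpha = count_alpha,
               count_min = count_min, count_max = count_max,
               zero_count_rate = zero_count_rate, extra_cui_rate = extra_cui_rate,
               n_total = n_total)
  if (spec$n_categories < 1 || spec$n_categories > 8) {
    abort("n_categories must be between 1 and 8")
  }
  if (spec$max_depth < 1) abort("max_depth must be >= 1")
  if (spec$branching < 1 && spec$max_depth > 1) {
    abort("Infeasible spec: branching 0 with max_depth > 1")
  }
  for (r in c("multi_parent_rate", "zero_count_rate", "extra_cui_rate")) {
    if (spec[[r]] < 0 || spec[[r]] > 1) abort(paste0(r, " must lie in [0, 1]"))
  }
  if (spec$count_alpha <= 1) abort("count_alpha must exceed 1")
  if (spec$n_scrs < 0 || spec$n_non_mesh < 0) abort("Counts must be non-negative")
  structure(spec, class = "mesh_fixture_spec")
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a deterministic synthetic MeSH dataset
#'
#' @param spec A [mesh_fixture_spec()].
#' @param out_path Optional directory; when given the dataset is also
#'   written there via [write_mesh_dataset()].
#' @return A [mesh_dataset] whose manifest records the spec and `n_total`.
#' @examples
#' ds <- generate_fixture(mesh_fixture_spec(seed = 1))
#' ds
#' @export
generate_fixture <- function(spec = mesh_fixture_spec(), out_path = NULL) {
  stopifnot(inherits(spec, "mesh_fixture_spec"))
  ds <- with_preserved_seed(spec$seed, generate_fixture_impl(spec))
  if (!is.null(out_path)) write_mesh_dataset(ds, out_path)
  ds
}

generate_fixture_impl <- function(spec) {
  cats <- c("C", "F", "A", "B", "D", "E", "G", "H")[seq_len(spec$n_categories)]
  nouns <- c("syndrome", "disease", "disorder", "condition")

  ui_n <- 0L
  next_ui <- function() {
    ui_n <<- ui_n + 1L
    sprintf("D%06d", ui_n)
  }

  nodes <- list()   # per node: ui, level, category, primary_tn, parents
  for (cat in cats) {
    level_nodes <- list(list(ui = next_ui(), level = 1L, category = cat,
                             primary_tn = paste0(cat, "01"),
                             parents = character(0)))
    nodes <- c(nodes, level_nodes)
    if (spec$max_depth > 1) {
      for (lev in 2:spec$max_depth) {
        new_level <- list()
        for (p in level_nodes) {
          for (b in seq_len(spec$branching)) {
            nd <- list(ui = next_ui(), level = lev, category = cat,
                       primary_tn = paste0(p$primary_tn, ".",
                                           sprintf("%03d", b)),
                       parents = p$ui)
            new_level <- c(new_level, list(nd))
          }
        }
        nodes <- c(nodes, new_level)
        level_nodes <- new_level
      }
    }
  }

  ui <- vapply(nodes, `[[`, character(1), "ui")
  level <- vapply(nodes, `[[`, integer(1), "level")
  category <- vapply(nodes, `[[`, character(1), "category")
  primary_tn <- vapply(nodes, `[[`, character(1), "primary_tn")
  tns <- as.list(primary_tn)
  names(tns) <- ui
  pc <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$parents) == 0) return(NULL)
    data.frame(parent_ui = nd$parents, child_ui = nd$ui)
  }))
  pc <- if (is.null(pc)) tibble::tibble(parent_ui = character(0),
                                        child_ui = character(0)) else
    tibble::as_tibble(pc)

  # extra parents: mirror the relinked node's tree-number suffixes under the
  # new parent so tree numbers and parent/child stay in exact agreement
  extra_comp <- integer(0)  # per-parent counter for fresh 9xx components
  candidates <- which(level >= 3)
  for (i in candidates) {
    if (spec$multi_parent_rate <= 0 || runif(1) >= spec$multi_parent_rate) next
    cur_parents <- pc$parent_ui[pc$child_ui == ui[i]]
    pool <- which(level == level[i] - 1L & category == category[i] &
                    !(ui %in% cur_parents))
    if (length(pool) == 0) next
    p2 <- if (length(pool) == 1) pool else sample(pool, 1)
    p2_ui <- ui[p2]
    prev <- extra_comp[p2_ui]
    k <- (if (length(prev) == 0 || is.na(prev)) 900L else prev) + 1L
    extra_comp[p2_ui] <- k
    # mirror under every placement of the new parent, so the tree-number
    # encoding keeps agreeing with the parent/child graph (links are
    # processed shallow-first, so p2's tree numbers are already complete)
    new_prefixes <- paste0(tns[[p2_ui]], ".", sprintf("%03d", k))
    x_tn <- primary_tn[i]
    snapshot <- tns
    for (u in names(snapshot)) {
      for (s in snapshot[[u]]) {
        suffix <- if (s == x_tn) "" else if (startsWith(s, paste0(x_tn, "."))) {
          substring(s, nchar(x_tn) + 1L)
        } else NULL
        if (!is.null(suffix)) {
          tns[[u]] <- c(tns[[u]], paste0(new_prefixes, suffix))
        }
      }
    }
    pc <- dplyr::bind_rows(pc, tibble::tibble(parent_ui = p2_ui,
                                              child_ui = ui[i]))
  }

  n_mh <- length(ui)
  counts <- integer(n_mh)
  for (j in seq_len(n_mh)) {
    if (runif(1) < spec$zero_count_rate) {
      counts[j] <- 0L
    } else {
      u <- runif(1)
      counts[j] <- as.integer(min(spec$count_max,
                                  floor(spec$count_min *
                                          u^(-1 / (spec$count_alpha - 1)))))
    }
  }

  cui_n <- 0L
  next_cui <- function() {
    cui_n <<- cui_n + 1L
    sprintf("C0%06d", cui_n)
  }
  stys <- c("dsyn", "neop", "sosy", "fndg")
  mh <- tibble::tibble(
    ui = ui,
    name = paste(nouns[1 + (seq_len(n_mh) - 1) %% length(nouns)], tolower(ui)),
    tree_numbers = unname(lapply(tns, function(x) sort(unique(x)))[ui]),
    semantic_types = lapply(seq_len(n_mh), function(j) sample(stys, 1)),
    cuis = lapply(seq_len(n_mh), function(j) {
      c(next_cui(), if (runif(1) < spec$extra_cui_rate) next_cui())
    }),
    pub_count = counts
  )

  scr <- tibble::tibble(ui = character(0), name = character(0),
                        semantic_types = list(), cuis = list(),
                        pub_count = integer(0))
  rb <- tibble::tibble(scr_ui = character(0), mh_ui = character(0))
  if (spec$n_scrs > 0) {
    scr_ui <- sprintf("C5%05d", seq_len(spec$n_scrs))
    broader <- lapply(seq_len(spec$n_scrs), function(j) {
      n_b <- 1L + rbinom(1, 1, 0.3)
      sample(ui, min(n_b, n_mh))
    })
    scr <- tibble::tibble(
      ui = scr_ui,
      name = paste("variant", tolower(scr_ui)),
      semantic_types = lapply(seq_len(spec$n_scrs), function(j) sample(stys, 1)),
      cuis = lapply(seq_len(spec$n_scrs), function(j) next_cui()),
      pub_count = rep(NA_integer_, spec$n_scrs)
    )
    rb <- tibble::tibble(scr_ui = rep(scr_ui, lengths(broader)),
                         mh_ui = unlist(broader))
  }

  nmc <- tibble::tibble(cui = character(0), name = character(0))
  if (spec$n_non_mesh > 0) {
    host <- sample(seq_len(n_mh), spec$n_non_mesh, replace = spec$n_non_mesh > n_mh)
    nmc <- tibble::tibble(
      cui = vapply(seq_len(spec$n_non_mesh), function(j) next_cui(), character(1)),
      name = paste(mh$name[host], "type", seq_len(spec$n_non_mesh))
    )
  }

  n_total <- spec$n_total %||% sum(counts)
  manifest <- list(generator = "meshsimr-fixture", seed = spec$seed,
                   n_total = n_total,
                   fixture = spec[c("n_categories", "max_depth", "branching",
                                    "n_scrs", "multi_parent_rate",
                                    "n_non_mesh")])
  mesh_dataset(mh, scr, rb, pc, nmc, manifest = manifest)
}
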