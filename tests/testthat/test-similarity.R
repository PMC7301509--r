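ic_of <- function(ds) build_ic_table(ds)

test_that("MICA is absent across categories and self-resolving on identity", {
  ds <- tiny_mica_dataset()
  ic <- ic_of(ds)
  # the printed Tauopathies / Schizophrenia tree numbers live in C vs F
  m <- mica(ds, ic, "D000202", "D000205")
  expect_true(is.na(m$mica_ui))
  expect_identical(m$mica_ic, 0)
  m2 <- mica(ds, ic, "D000202", "D000202")
  expect_equal(m2$mica_ui, "D000202")
  expect_equal(m2$mica_ic, ic$ic[ic$ui == "D000202"])
})

test_that("sibling headings meet at their parent", {
  ds <- tiny_sim_dataset()
  ic <- ic_of(ds)
  m <- mica(ds, ic, "D000101", "D000103")
  expect_equal(m$mica_ui, "D000100")
  expect_equal(m$mica_ic, ic$ic[ic$ui == "D000100"])
  expect_equal(oracle_mica_ic(ds, ic, "D000101", "D000103"), m$mica_ic)
})

test_that("the four IC measures reproduce hand-computed values", {
  ds <- tiny_sim_dataset()
  ic <- ic_of(ds)
  # IC(d1) = 1, IC(d2) = log10(5) ~ 0.69897, IC(MICA) = log10(2) ~ 0.30103
  expect_equal(sim_resnik(ds, ic, "D000101", "D000103"), log10(2))
  expect_equal(sim_lin(ds, ic, "D000101", "D000103"),
               2 * log10(2) / (1 + log10(5)), tolerance = 1e-12)
  expect_equal(round(sim_lin(ds, ic, "D000101", "D000103"), 5), 0.35437)
  expect_equal(sim_jc(ds, ic, "D000101", "D000103"), 0)  # distance clamps at 1
  expect_equal(round(sim_rel(ds, ic, "D000101", "D000103"), 5), 0.17718)
  # Schlicker damps Lin by exactly 1 - P(MICA); 10^(-log10(2)) = 0.5
  expect_equal(sim_rel(ds, ic, "D000101", "D000103"),
               sim_lin(ds, ic, "D000101", "D000103") * 0.5, tolerance = 1e-12)
})

test_that("raw measures satisfy their identity algebra", {
  ds <- tiny_sim_dataset()
  ic <- ic_of(ds)
  d <- "D000101"
  expect_equal(sim_resnik(ds, ic, d, d), 1)            # IC(d) = 1 here
  expect_equal(sim_lin(ds, ic, d, d), 1)
  expect_equal(sim_jc(ds, ic, d, d), 1)
  expect_equal(sim_rel(ds, ic, d, d), 1 - 10^(-1))     # 1 - P(d)
  expect_equal(sim_wang(ds, d, d), 1)
})

test_that("all measures are exactly zero across disjoint categories", {
  ds <- tiny_sim_dataset()
  ic <- ic_of(ds)
  for (m in c("res", "lin", "jc", "rel", "wang")) {
    expect_identical(mesh_similarity(ds, "D000101", "D000104", method = m,
                                     ic_table = ic), 0)
  }
})

test_that("Jiang-Conrath is short-circuited across categories", {
  # both roots are common enough that the raw JC distance stays below 1,
  # so without the category rule the score would be spuriously positive
  ds <- tiny_mica_dataset()
  ic <- ic_of(ds)
  ic1 <- ic$ic[ic$ui == "D000200"]
  ic2 <- ic$ic[ic$ui == "D000203"]
  expect_lt(ic1 + ic2, 1)
  expect_identical(sim_jc(ds, ic, "D000200", "D000203"), 0)
})

test_that("Lin and Schlicker handle the zero-IC boundary cases", {
  # one category, one root with all the mass: IC(root) = 0
  mh <- dplyr::bind_rows(
    term_row("D000300", "root a", "C01", "C0940001", 0),
    term_row("D000301", "leaf a", "C01.100", "C0940002", 100))
  ds <- mesh_dataset(mh, parent_child = tibble::tibble(
    parent_ui = "D000300", child_ui = "D000301"),
    manifest = list(n_total = 100))
  ic <- ic_of(ds)
  expect_equal(ic$ic[ic$ui == "D000300"], 0)
  expect_equal(sim_lin(ds, ic, "D000300", "D000300"), 1)
  expect_identical(mesh_similarity(ds, "D000300", "D000300", "rel",
                                   ic_table = ic), 1)
})

test_that("Wang contributions decay by omega per edge with min-path tie-break", {
  ds <- tiny_sim_dataset()
  w <- wang_s_values(ds, "D000102", omega = 0.6)   # tn C01.100.500
  expect_equal(sort(names(w$s)), c("D000100", "D000101", "D000102"))
  expect_equal(unname(w$s["D000102"]), 1)
  expect_equal(unname(w$s["D000101"]), 0.6)
  expect_equal(unname(w$s["D000100"]), 0.36)
  expect_equal(w$sv, 1.96)
  expect_equal(unname(wang_s_values(ds, "D000102", omega = 0)$s["D000102"]), 1)
})

test_that("Wang similarity matches the published worked pairing", {
  ds <- tiny_sim_dataset()
  # C01.100.500 vs C01.200: (0.36 + 0.6) / (1.96 + 1.6)
  expect_equal(sim_wang(ds, "D000102", "D000103", omega = 0.6),
               (0.36 + 0.6) / (1.96 + 1.6), tolerance = 1e-15)
  expect_equal(round(sim_wang(ds, "D000102", "D000103", omega = 0.6), 5),
               0.26966)
})

test_that("a term reached by paths of different lengths keeps the shortest", {
  mh <- dplyr::bind_rows(
    term_row("D000400", "root", "C01", "C0950001", 10),
    term_row("D000401", "mid a", "C01.100", "C0950002", 5),
    term_row("D000402", "mid b", c("C01.200", "C01.100.150"), "C0950003", 5),
    term_row("D000403", "leaf", c("C01.200.100", "C01.100.150.100"),
             "C0950004", 2))
  pc <- tibble::tibble(parent_ui = c("D000400", "D000400", "D000401",
                                     "D000402"),
                       child_ui = c("D000401", "D000402", "D000402",
                                    "D000403"))
  ds <- mesh_dataset(mh, parent_child = pc, manifest = list(n_total = 22))
  w <- wang_s_values(ds, "D000403", omega = 0.6)
  # root reachable in 2 edges (via C01.200.100) and 3 (via C01.100.150.100)
  expect_equal(unname(w$s["D000400"]), 0.6^2)
  expect_equal(oracle_wang(ds, "D000403", "D000401", 0.6),
               sim_wang(ds, "D000403", "D000401", 0.6), tolerance = 1e-12)
})

test_that("Wang equals the shortest-path oracle on a generated DAG", {
  skip_if_not_installed("igraph")
  set.seed(11)
  ds <- fx(2, multi_parent_rate = 0.3)
  uis <- ds$main_headings$ui
  pairs <- cbind(sample(uis, 60, replace = TRUE),
                 sample(uis, 60, replace = TRUE))
  for (omega in c(0.1, 0.6, 1.0)) {
    for (k in seq_len(nrow(pairs))) {
      expect_equal(sim_wang(ds, pairs[k, 1], pairs[k, 2], omega),
                   oracle_wang(ds, pairs[k, 1], pairs[k, 2], omega),
                   tolerance = 1e-12,
                   info = paste(pairs[k, 1], pairs[k, 2], omega))
    }
  }
})

test_that("IC measures match direct evaluation with the exhaustive MICA oracle", {
  set.seed(12)
  ds <- fx(1)
  ic <- ic_of(ds)
  uis <- ds$main_headings$ui
  pairs <- cbind(sample(uis, 80, replace = TRUE),
                 sample(uis, 80, replace = TRUE))
  icv <- function(u) ic$ic[match(u, ic$ui)]
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    m <- oracle_mica_ic(ds, ic, a, b)
    no_common <- m == 0 &&
      length(intersect(oracle_ancestor_set(ds, a),
                       oracle_ancestor_set(ds, b))) == 0
    expect_equal(sim_resnik(ds, ic, a, b), m, tolerance = 1e-12)
    lin_exp <- if (no_common) 0 else 2 * m / (icv(a) + icv(b))
    expect_equal(sim_lin(ds, ic, a, b), lin_exp, tolerance = 1e-12)
    jc_exp <- if (no_common) 0 else 1 - min(1, icv(a) + icv(b) - 2 * m)
    expect_equal(sim_jc(ds, ic, a, b), jc_exp, tolerance = 1e-12)
    rel_exp <- lin_exp * (1 - 10^(-m))
    expect_equal(sim_rel(ds, ic, a, b), rel_exp, tolerance = 1e-12)
  }
})

test_that("the dispatcher is symmetric for every method", {
  set.seed(13)
  ds <- fx(1)
  ic <- ic_of(ds)
  all_ids <- c(ds$main_headings$ui, ds$scrs$ui)
  pairs <- cbind(sample(all_ids, 50, replace = TRUE),
                 sample(all_ids, 50, replace = TRUE))
  for (m in c("res", "lin", "jc", "rel", "wang")) {
    for (k in seq_len(nrow(pairs))) {
      expect_identical(
        mesh_similarity(ds, pairs[k, 1], pairs[k, 2], m, ic_table = ic),
        mesh_similarity(ds, pairs[k, 2], pairs[k, 1], m, ic_table = ic),
        info = paste(m, pairs[k, 1], pairs[k, 2]))
    }
  }
})

test_that("normalized measures stay inside [0, 1] and Resnik below max IC", {
  set.seed(14)
  ds <- fx(1)
  ic <- ic_of(ds)
  uis <- ds$main_headings$ui
  pairs <- cbind(sample(uis, 60, replace = TRUE),
                 sample(uis, 60, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    for (m in c("lin", "jc", "rel", "wang")) {
      v <- mesh_similarity(ds, pairs[k, 1], pairs[k, 2], m, ic_table = ic)
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
    r <- mesh_similarity(ds, pairs[k, 1], pairs[k, 2], "res", ic_table = ic)
    expect_lte(r, max(ic$ic) + 1e-12)
  }
})

test_that("SCR endpoints resolve through their broader headings", {
  ds <- tiny_sim_dataset()
  ic <- ic_of(ds)
  # SCR vs one of its own broader headings reduces to identity
  for (m in c("res", "lin", "jc", "rel", "wang")) {
    expect_identical(mesh_similarity(ds, "C500100", "D000101", m,
                                     ic_table = ic), 1)
  }
  # SCR vs an unrelated heading takes the best broader pairing
  direct <- max(sim_lin(ds, ic, "D000101", "D000102"),
                sim_lin(ds, ic, "D000103", "D000102"))
  expect_equal(mesh_similarity(ds, "C500100", "D000102", "lin",
                               ic_table = ic), direct)
})

test_that("multi-category terms score by the best tree-number pairing", {
  mh <- dplyr::bind_rows(
    term_row("D000500", "c root", "C01", "C0960001", 100),
    term_row("D000501", "f root", "F01", "C0960002", 100),
    term_row("D000502", "bridge", c("C01.100", "F01.100"), "C0960003", 10),
    term_row("D000503", "c leaf", "C01.200", "C0960004", 10))
  pc <- tibble::tibble(parent_ui = c("D000500", "D000501", "D000500"),
                       child_ui = c("D000502", "D000502", "D000503"))
  ds <- mesh_dataset(mh, parent_child = pc, manifest = list(n_total = 220))
  ic <- ic_of(ds)
  # bridge shares the C category with the leaf; pairing through C01 wins
  expect_equal(sim_resnik(ds, ic, "D000502", "D000503"),
               ic$ic[ic$ui == "D000500"])
  expect_gt(mesh_similarity(ds, "D000502", "D000503", "lin", ic_table = ic), 0)
})

test_that("moving to a deeper divergence point never increases similarity", {
  set.seed(15)
  ds <- fx(1)
  ic <- ic_of(ds)
  pc <- ds$parent_child
  # pick terms with a sibling (same parent) and a cousin (same grandparent)
  checked <- 0
  for (d1 in sample(pc$child_ui, 40)) {
    parent <- pc$parent_ui[pc$child_ui == d1][[1]]
    sibs <- setdiff(pc$child_ui[pc$parent_ui == parent], d1)
    gp <- pc$parent_ui[pc$child_ui == parent]
    if (length(sibs) == 0 || length(gp) == 0) next
    uncles <- setdiff(pc$child_ui[pc$parent_ui %in% gp], c(parent, d1))
    cousins <- setdiff(pc$child_ui[pc$parent_ui %in% uncles], sibs)
    if (length(cousins) == 0) next
    sib <- sibs[[1]]; cousin <- cousins[[1]]
    expect_gte(sim_lin(ds, ic, d1, sib) + 1e-12, sim_lin(ds, ic, d1, cousin))
    expect_gte(sim_wang(ds, d1, sib) + 1e-12, sim_wang(ds, d1, cousin))
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})
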