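test_that("RRF lines split on pipes with a trailing separator tolerated", {
  f <- withr::local_tempfile(lines = c("C0002395|MSH|D000544|",
                                       "C0011860|MSH|D003924"))
  rows <- parse_rrf(f, c("cui", "sab", "ui"))
  expect_equal(rows$cui, c("C0002395", "C0011860"))
  expect_equal(rows$ui, c("D000544", "D003924"))
  expect_equal(rows$line, 1:2)
})

test_that("empty files yield empty streams and bad arity is reported by line", {
  f <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(parse_rrf(f, c("a", "b"))), 0)
  g <- withr::local_tempfile(lines = c("x|y|", "x|y|z|"))
  expect_error(parse_rrf(g, c("a", "b")), class = "meshsimr_rrf_parse_error")
  expect_error(parse_rrf(g, c("a", "b")), "2")
  expect_warning(rows <- parse_rrf(g, c("a", "b"), strict = FALSE), "skipped")
  expect_equal(nrow(rows), 1)
})

test_that("a minimal RRF triple builds one MH, one SCR and one broader link", {
  dir <- withr::local_tempdir()
  writeLines(c("C0000001|D000001|some disease|MH|C01",
               "C0000002|S000001|some variant|SCR||"),
             file.path(dir, "con.rrf"))
  writeLines("S000001|RB|D000001", file.path(dir, "rel.rrf"))
  writeLines(c("C0000001|dsyn", "C0000002|dsyn"), file.path(dir, "sty.rrf"))
  ds <- build_mesh_dataset(file.path(dir, "con.rrf"), file.path(dir, "rel.rrf"),
                           file.path(dir, "sty.rrf"))
  expect_equal(nrow(ds$main_headings), 1)
  expect_equal(nrow(ds$scrs), 1)
  expect_equal(nrow(ds$scr_broader), 1)
  expect_equal(get_term(ds, "S000001")$record_kind, "SCR")
  expect_equal(ds$main_headings$semantic_types[[1]], "dsyn")
})

test_that("several concept rows accumulate onto one heading", {
  dir <- withr::local_tempdir()
  cuis <- sprintf("C000000%d", 1:7)
  writeLines(c(paste0(cuis[1], "|D000544|Alzheimer Disease|MH|C10.228"),
               paste0(cuis[-1], "|D000544|Alzheimer Disease|MH||")),
             file.path(dir, "con.rrf"))
  writeLines(character(0), file.path(dir, "rel.rrf"))
  writeLines(paste0(cuis, "|dsyn"), file.path(dir, "sty.rrf"))
  ds <- build_mesh_dataset(file.path(dir, "con.rrf"), file.path(dir, "rel.rrf"),
                           file.path(dir, "sty.rrf"))
  expect_equal(nrow(ds$main_headings), 1)
  expect_equal(length(ds$concept_map), 7)
  expect_setequal(ds$main_headings$cuis[[1]], cuis)
})

test_that("dangling relation references fail the build and name the id", {
  dir <- withr::local_tempdir()
  writeLines("C0000001|D000001|thing|MH|C01", file.path(dir, "con.rrf"))
  writeLines("D000001|PAR|D999999", file.path(dir, "rel.rrf"))
  writeLines("C0000001|dsyn", file.path(dir, "sty.rrf"))
  expect_error(
    build_mesh_dataset(file.path(dir, "con.rrf"), file.path(dir, "rel.rrf"),
                       file.path(dir, "sty.rrf")),
    "D999999", class = "meshsimr_dangling_reference")
})

test_that("an SCR with no broader heading fails the build", {
  dir <- withr::local_tempdir()
  writeLines(c("C0000001|D000001|thing|MH|C01",
               "C0000002|S000001|variant|SCR||"), file.path(dir, "con.rrf"))
  writeLines(character(0), file.path(dir, "rel.rrf"))
  writeLines("C0000001|dsyn", file.path(dir, "sty.rrf"))
  expect_error(
    build_mesh_dataset(file.path(dir, "con.rrf"), file.path(dir, "rel.rrf"),
                       file.path(dir, "sty.rrf")),
    class = "meshsimr_empty_broader")
})

test_that("full trees have the predicted node count", {
  ds <- generate_fixture(mesh_fixture_spec(seed = 1, n_categories = 2,
                                           max_depth = 3, branching = 2,
                                           n_scrs = 2, multi_parent_rate = 0))
  expect_equal(nrow(ds$main_headings), 2 * (1 + 2 + 4))
  expect_equal(nrow(ds$parent_child), 2 * 6)
})

test_that("the generator is byte-deterministic for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- mesh_fixture_spec(seed = 7, multi_parent_rate = 0.4)
  generate_fixture(spec, out_path = d1)
  generate_fixture(spec, out_path = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("extra parents appear in both a second tree number and parent_child", {
  ds <- generate_fixture(mesh_fixture_spec(seed = 3, multi_parent_rate = 0.5,
                                           max_depth = 3, branching = 3))
  pc <- ds$parent_child
  dup_children <- unique(pc$child_ui[duplicated(pc$child_ui)])
  expect_gt(length(dup_children), 0)
  for (ch in dup_children) {
    parents <- pc$parent_ui[pc$child_ui == ch]
    child_tns <- ds$main_headings$tree_numbers[[match(ch, ds$main_headings$ui)]]
    for (p in parents) {
      p_tns <- ds$main_headings$tree_numbers[[match(p, ds$main_headings$ui)]]
      # some tree number of the child is one component below some tn of p
      expect_true(any(tn_parent(child_tns) %in% p_tns),
                  info = paste(p, "->", ch))
    }
  }
})

test_that("infeasible fixture specs are rejected", {
  expect_error(mesh_fixture_spec(branching = 0, max_depth = 2), "Infeasible")
  expect_error(mesh_fixture_spec(multi_parent_rate = 1.5), "\\[0, 1\\]")
  expect_error(mesh_fixture_spec(n_scrs = -1), "non-negative")
})

test_that("datasets serialize and load back identically", {
  ds <- fx(1)
  dir <- withr::local_tempdir()
  write_mesh_dataset(ds, dir)
  ds2 <- read_mesh_dataset(dir)
  for (tab in c("main_headings", "scrs", "scr_broader", "parent_child",
                "non_mesh_concepts")) {
    expect_equal(as.data.frame(ds2[[tab]]), as.data.frame(ds[[tab]]),
                 info = tab)
  }
  expect_identical(ds2$concept_map, ds$concept_map)
  expect_equal(ds2$manifest$n_total, ds$manifest$n_total)
  # writing the loaded dataset reproduces the files byte for byte
  dir2 <- withr::local_tempdir()
  write_mesh_dataset(ds2, dir2)
  for (f in setdiff(list.files(dir), "manifest.json")) {
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)),
                     info = f)
  }
})

test_that("an RRF encoding of a fixture rebuilds the same vocabulary", {
  ds <- generate_fixture(mesh_fixture_spec(seed = 5, max_depth = 3,
                                           branching = 2, n_scrs = 3))
  dir <- withr::local_tempdir()
  paths <- write_rrf_fixture(ds, dir)
  built <- build_mesh_dataset(paths$concepts, paths$relations, paths$sty)
  expect_equal(built$main_headings$ui, ds$main_headings$ui)
  expect_equal(built$scrs$ui, ds$scrs$ui)
  expect_equal(length(built$concept_map), length(ds$concept_map))
  expect_equal(built$main_headings$tree_numbers, ds$main_headings$tree_numbers,
               ignore_attr = TRUE)
  expect_setequal(paste(built$parent_child$parent_ui, built$parent_child$child_ui),
                  paste(ds$parent_child$parent_ui, ds$parent_child$child_ui))
})
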