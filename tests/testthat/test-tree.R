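test_that("validate_tree reports structural violations without raising", {
  one <- airway_tree(data.frame(id = 1, x = 0, y = 0, z = 0, parent = -1))
  expect_length(validate_tree(one), 0L)

  two_roots <- data.frame(id = 1:2, x = 0, y = 0, z = 0:1, parent = c(-1, -1))
  v <- validate_tree(structure(two_roots, class = c("airway_tree", "data.frame")))
  expect_true(any(grepl("multiple roots", v)))

  # 1 -> 2 -> 3 -> 1 cycle next to a legitimate root
  cyc <- data.frame(id = 1:4, x = 0, y = 0, z = 0:3,
                    parent = c(3, 1, 2, -1))
  v <- validate_tree(structure(cyc, class = c("airway_tree", "data.frame")))
  expect_true(any(grepl("cycle", v)))

  dangle <- data.frame(id = 1:2, x = 0, y = 0, z = 0:1, parent = c(-1, 99))
  v <- validate_tree(structure(dangle, class = c("airway_tree", "data.frame")))
  expect_true(any(grepl("dangling", v)))
})

test_that("branch decomposition partitions nodes with +1 generations", {
  # 5-node chain into a perfect binary tree of depth 3: 15 branches
  tr <- make_binary_tree(chain = 5L, depth = 3L)
  br <- branch_decomposition(tr)
  expect_length(br, 15L)
  expect_equal(sort(unique(vapply(br, `[[`, integer(1), "generation"))), 0:3)
  expect_equal(as.integer(table(vapply(br, `[[`, integer(1), "generation"))),
               c(1L, 2L, 4L, 8L))
  # every node in exactly one branch
  all_ids <- unlist(lapply(br, `[[`, "node_ids"))
  expect_equal(sort(all_ids), sort(tr$id))
  expect_false(anyDuplicated(all_ids) > 0)

  chain <- airway_tree(data.frame(id = 1:4, x = 0, y = 0, z = 0:3,
                                  parent = c(-1, 1, 2, 3)))
  bc <- branch_decomposition(chain)
  expect_length(bc, 1L)
  expect_equal(bc[[1]]$generation, 0L)
})

test_that("main bronchi sit at generation 1 and segmental candidates at 3", {
  tr <- make_binary_tree(chain = 5L, depth = 4L)
  br <- branch_decomposition(tr)
  # children of the first bifurcation are generation 1
  gen1 <- Filter(function(b) b$generation == 1L, br)
  expect_length(gen1, 2L)
  expect_length(segmental_candidates(tr), 8L)

  chain <- airway_tree(data.frame(id = 1:3, x = 0, y = 0, z = 0:2,
                                  parent = c(-1, 1, 2)))
  expect_length(segmental_candidates(chain), 0L)

  ph <- get_phantom(42)
  cands <- segmental_candidates(ph$tree)
  expect_length(cands, 18L)
  # ordered by first node id
  firsts <- vapply(cands, function(b) b$node_ids[1L], integer(1))
  expect_equal(firsts, sort(firsts))
})

test_that("label propagation covers branch and downstream subtree only", {
  tr <- make_binary_tree(chain = 3L, depth = 4L)
  cands <- segmental_candidates(tr)
  # annotate one generation-3 branch
  n0 <- cands[[1]]$node_ids[1L]
  lab <- propagate_labels(tr, segmental_annotation(n0, 7L))
  labeled <- lab$id[!is.na(lab$label)]
  # the branch plus its whole downstream subtree
  desc <- n0
  repeat {
    more <- lab$id[lab$parent %in% desc & !(lab$id %in% desc)]
    if (!length(more)) break
    desc <- c(desc, more)
  }
  expect_setequal(labeled, desc)
  expect_true(all(lab$label[match(labeled, lab$id)] == 7L))
  # idempotent
  expect_identical(propagate_labels(lab, segmental_annotation(n0, 7L)), lab)
})

test_that("propagation flags conflicts, missing nodes, and odd generations", {
  tr <- make_binary_tree(chain = 3L, depth = 4L)
  cands <- segmental_candidates(tr)
  g3 <- cands[[1]]$node_ids[1L]
  # a node strictly downstream of g3 (generation 4)
  down <- tr$id[tr$parent == g3][1L]
  expect_warning(
    expect_error(propagate_labels(tr, segmental_annotation(c(g3, down), c(1L, 2L))),
                 "conflicting annotation"),
    "generation")
  expect_error(propagate_labels(tr, segmental_annotation(999L, 1L)),
               "not in tree")
  expect_warning(propagate_labels(tr, segmental_annotation(down, 2L)),
                 "generation-4")
})

test_that("18 phantom annotations label exactly the generation >= 3 subtree", {
  ph <- get_phantom(42)
  lab <- ph$tree
  expect_setequal(unique(stats::na.omit(lab$label)), 1:18)
  br <- branch_decomposition(lab)
  for (b in br) {
    rows <- match(b$node_ids, lab$id)
    if (b$generation < 3L) {
      expect_true(all(is.na(lab$label[rows])))
    } else {
      expect_true(all(!is.na(lab$label[rows])))
    }
  }
})

test_that("SWC round trip preserves geometry, labels, and topology", {
  ph <- get_phantom(42)
  f <- tempfile(fileext = ".swc")
  write_swc(ph$tree, f)
  back <- read_swc(f)
  expect_equal(back$id, ph$tree$id)
  expect_equal(back$parent, ph$tree$parent)
  expect_equal(back$label, ph$tree$label)
  expect_lt(max(abs(back$x - ph$tree$x), abs(back$y - ph$tree$y),
                abs(back$z - ph$tree$z)), 1e-6)
  expect_lt(max(abs(back$radius - ph$tree$radius)), 1e-6)
})

test_that("SWC reader accepts forward parent references and flags defects", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# forward reference: child defined before its parent",
               "2 1 0 0 1 1 1",
               "1 1 0 0 0 1 -1"), f)
  tr <- read_swc(f)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$parent[tr$id == 2L], 1L)

  writeLines(c("1 1 0 0 0 1 -1", "2 1 oops 0 1 1 1"), f)
  expect_error(read_swc(f), "line 2")

  writeLines(c("1 1 0 0 0 1 -1", "2 1 0 0 1 1 5"), f)
  expect_error(read_swc(f), "dangling")

  writeLines(c("1 1 0 0 0 1 -1", "2 1 0 0 1 1 -1"), f)
  expect_error(read_swc(f), "multiple roots")
})

test_that("annotation JSON round-trips and rejects duplicates", {
  ann <- segmental_annotation(c(10L, 20L), c(1L, 4L))
  f <- tempfile(fileext = ".json")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_error(segmental_annotation(c(1L, 2L), c(3L, 3L)), "duplicate segment")
  expect_error(segmental_annotation(c(1L, 1L), c(3L, 4L)), "duplicate node")
})

test_that("branch decomposition partitions nodes on random phantoms", {
  for (s in c(11, 12)) {
    ph <- get_phantom(s)
    br <- branch_decomposition(ph$tree)
    all_ids <- unlist(lapply(br, `[[`, "node_ids"))
    expect_equal(sort(all_ids), sort(ph$tree$id))
  }
})
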