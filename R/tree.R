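#' Rooted airway centerline trees
#'
#' An `airway_tree` is a data frame of centerline nodes with columns `id`
#' (unique positive integers), `x`, `y`, `z` (world mm), `radius` (mm),
#' `parent` (id of the parent node, -1 for the root) and `label` (segment
#' code 1-18, or `NA` when unlabeled). A valid tree has exactly one root and
#' is connected and acyclic.
#'
#' @param nodes a data frame with at least `id`, `x`, `y`, `z`, `parent`;
#'   `radius` defaults to 1 mm and `label` to `NA`.
#' @param validate check invariants and fail on violations (default `TRUE`).
#' @return An object of class `airway_tree` (also a data frame).
#' @examples
#' tr <- airway_tree(data.frame(id = 1:3, x = 0, y = 0, z = c(0, 2, 4),
#'                              parent = c(-1, 1, 2)))
#' validate_tree(tr)
#' @export
airway_tree <- function(nodes, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  if (nrow(nodes) == 0L) stop("tree has no nodes")
  required <- c("id", "x", "y", "z", "parent")
  missing <- setdiff(required, names(nodes))
  if (length(missing)) stop("missing node columns: ", paste(missing, collapse = ", "))
  if (is.null(nodes$radius)) nodes$radius <- 1.0
  if (is.null(nodes$label)) nodes$label <- NA_integer_
  nodes <- nodes[, c("id", "x", "y", "z", "radius", "parent", "label")]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$label <- as.integer(nodes$label)
  tr <- structure(nodes, class = c("airway_tree", "data.frame"))
  if (validate) {
    v <- validate_tree(tr)
    if (length(v)) stop("invalid airway tree:\n  ", paste(v, collapse = "\n  "))
  }
  tr
}

#' @export
print.airway_tree <- function(x, ...) {
  nlab <- sum(!is.na(x$label))
  cat(sprintf("<airway_tree> %d nodes, root id %s, %d labeled node%s (%d segment%s)\n",
              nrow(x), paste(x$id[x$parent == -1L], collapse = ","),
              nlab, if (nlab == 1) "" else "s",
              length(unique(stats::na.omit(x$label))),
              if (length(unique(stats::na.omit(x$label))) == 1) "" else "s"))
  invisible(x)
}

#' Check airway-tree invariants
#'
#' Reports violations instead of raising: duplicate ids, dangling or
#' self-referencing parents, multiple roots, no root, cycles, and
#' disconnected components. An empty character vector means the tree is
#' valid.
#'
#' @param tree an [airway_tree] (or bare data frame of nodes).
#' @return Character vector of human-readable violations (empty if valid).
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  if (nrow(tree) == 0L) return("tree has no nodes")
  if (anyDuplicated(tree$id))
    v <- c(v, paste0("duplicate node ids: ",
                     paste(unique(tree$id[duplicated(tree$id)]), collapse = ", ")))
  roots <- tree$id[tree$parent == -1L]
  if (length(roots) == 0L) v <- c(v, "no root (no node with parent -1)")
  if (length(roots) > 1L)
    v <- c(v, paste0("multiple roots: nodes ", paste(roots, collapse = ", ")))
  self <- tree$id[tree$id == tree$parent]
  if (length(self)) v <- c(v, paste0("self-parenting nodes: ", paste(self, collapse = ", ")))
  dangling <- tree$id[tree$parent != -1L & !(tree$parent %in% tree$id)]
  if (length(dangling))
    v <- c(v, paste0("dangling parent for nodes: ", paste(dangling, collapse = ", ")))
  if (length(v)) return(v)  # structure too broken for traversal checks
  # every node has one parent, so any node unreachable from the root lies on
  # a cycle or in a detached component; one BFS over children finds them
  pos <- match(tree$parent, tree$id)        # parent row per node (NA at root)
  reached <- logical(nrow(tree))
  frontier <- which(tree$parent == -1L)
  reached[frontier] <- TRUE
  while (length(frontier)) {
    frontier <- which(!reached & pos %in% frontier)
    reached[frontier] <- TRUE
  }
  if (!all(reached))
    v <- c(v, paste0("cycle or disconnected component involving nodes: ",
                     paste(tree$id[!reached], collapse = ", ")))
  v
}

tree_root <- function(tree) tree$id[tree$parent == -1L]

# children list keyed by node id (character)
children_map <- function(tree) {
  kids <- split(tree$id[tree$parent != -1L], tree$parent[tree$parent != -1L])
  kids
}

#' Decompose a tree into branches with generation levels
#'
#' A branch is the maximal chain of nodes between consecutive branch points
#' (or between the root / a leaf and the nearest branch point); the branch
#' point itself terminates the upstream branch. The trachea chain is
#' generation 0, so the left and right main bronchi are generation 1 and
#' tertiary (segmental) bronchi are generation 3. Trifurcations are allowed;
#' every child branch is one generation deeper than its parent.
#'
#' @param tree a valid [airway_tree].
#' @return A list of branches, each a list with `node_ids` (ordered from the
#'   root side towards the periphery) and `generation` (integer, trachea =
#'   0).
#' @export
branch_decomposition <- function(tree) {
  v <- validate_tree(tree)
  if (length(v)) stop("invalid airway tree:\n  ", paste(v, collapse = "\n  "))
  kids <- children_map(tree)
  nk <- function(id) {
    k <- kids[[as.character(id)]]
    if (is.null(k)) integer(0) else sort(k)
  }
  branches <- list()
  # (start node, generation) worklist; deterministic order via sorted children
  work <- list(list(start = tree_root(tree), gen = 0L))
  while (length(work)) {
    item <- work[[1L]]
    work <- work[-1L]
    chain <- item$start
    cur <- item$start
    repeat {
      k <- nk(cur)
      if (length(k) == 1L) {
        cur <- k
        chain <- c(chain, cur)
      } else break
    }
    branches[[length(branches) + 1L]] <- list(node_ids = chain, generation = item$gen)
    for (child in nk(cur))
      work[[length(work) + 1L]] <- list(start = child, gen = item$gen + 1L)
  }
  branches
}

#' Tertiary (segmental) bronchus candidates
#'
#' Returns the generation-3 branches of the tree — the level at which
#' segmental bronchi sit when the main bronchi are counted as generation 1 —
#' ordered by their first node id.
#'
#' @param tree a valid [airway_tree].
#' @return List of branches (see [branch_decomposition]) at generation 3.
#' @export
segmental_candidates <- function(tree) {
  br <- branch_decomposition(tree)
  g3 <- Filter(function(b) b$generation == 3L, br)
  first <- vapply(g3, function(b) b$node_ids[1L], integer(1))
  g3[order(first)]
}

#' Single-point segmental annotations
#'
#' One clicked centerline point per segmental bronchus: a mapping from node
#' id to segment code. At most one annotation per segment code is allowed.
#'
#' @param node_id integer node ids.
#' @param segment integer segment codes (1-18), same length.
#' @return An object of class `segmental_annotation` (a data frame).
#' @export
segmental_annotation <- function(node_id, segment) {
  node_id <- as.integer(node_id)
  segment <- as.integer(segment)
  if (length(node_id) != length(segment))
    stop("node_id and segment must have the same length")
  if (anyDuplicated(segment))
    stop("duplicate segment code in annotation: ",
         paste(unique(segment[duplicated(segment)]), collapse = ", "))
  if (anyDuplicated(node_id))
    stop("duplicate node id in annotation: ",
         paste(unique(node_id[duplicated(node_id)]), collapse = ", "))
  structure(data.frame(node_id = node_id, segment = segment),
            class = c("segmental_annotation", "data.frame"))
}

#' Read/write annotations as JSON
#'
#' Format: a JSON array of objects `{"node_id": <int>, "segment": <int>}`.
#'
#' @param path file path.
#' @param ann a [segmental_annotation].
#' @return `read_annotations` returns a `segmental_annotation`;
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  d <- jsonlite::fromJSON(path)
  if (!is.data.frame(d) || !all(c("node_id", "segment") %in% names(d)))
    stop("annotation JSON must be an array of {node_id, segment} objects: ", path)
  segmental_annotation(d$node_id, d$segment)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  jsonlite::write_json(as.data.frame(ann), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Propagate segmental labels through downstream sub-branches
#'
#' Each annotated point labels the entire branch it sits on plus every
#' downstream sub-branch, mirroring the single-click annotation workflow:
#' the annotator marks one centerline point per segmental bronchus and the
#' label flows to the periphery. Nodes upstream of the annotated branch are
#' left unlabeled. Overlapping propagation regions are an error (each
#' bronchus must carry a unique label); annotating a branch whose generation
#' is not 3 produces a warning but still propagates.
#'
#' @param tree a valid [airway_tree].
#' @param ann a [segmental_annotation].
#' @return The tree with `label` filled in over the annotated subtrees.
#' @export
propagate_labels <- function(tree, ann) {
  stopifnot(inherits(ann, "segmental_annotation"))
  v <- validate_tree(tree)
  if (length(v)) stop("invalid airway tree:\n  ", paste(v, collapse = "\n  "))
  missing <- setdiff(ann$node_id, tree$id)
  if (length(missing))
    stop("annotated node(s) not in tree: ", paste(missing, collapse = ", "))
  br <- branch_decomposition(tree)
  kids <- children_map(tree)
  node_branch <- integer(0)
  for (bi in seq_along(br)) node_branch[as.character(br[[bi]]$node_ids)] <- bi
  labels <- stats::setNames(rep(NA_integer_, nrow(tree)), as.character(tree$id))
  owner <- stats::setNames(rep(NA_integer_, nrow(tree)), as.character(tree$id))
  for (r in seq_len(nrow(ann))) {
    nid <- ann$node_id[r]
    code <- ann$segment[r]
    bi <- node_branch[[as.character(nid)]]
    gen <- br[[bi]]$generation
    if (gen != 3L)
      warning(sprintf("annotation for segment %d sits on a generation-%d branch (expected 3)",
                      code, gen))
    # whole branch, then the subtree below its terminal node
    region <- br[[bi]]$node_ids
    stack <- kids[[as.character(region[length(region)])]]
    while (length(stack)) {
      cur <- stack[1L]
      stack <- stack[-1L]
      region <- c(region, cur)
      k <- kids[[as.character(cur)]]
      if (!is.null(k)) stack <- c(stack, k)
    }
    keys <- as.character(region)
    clash <- !is.na(labels[keys]) & labels[keys] != code
    if (any(clash)) {
      other <- unique(labels[keys][clash])
      stop(sprintf("conflicting annotation: segments %s and %d propagate to the same nodes",
                   paste(other, collapse = ","), code))
    }
    labels[keys] <- code
    owner[keys] <- code
  }
  out <- tree
  out$label <- unname(labels[as.character(out$id)])
  out
}

#' Read and write centerline trees as SWC
#'
#' SWC columns: `id type x y z radius parent`. Whitespace separated, `#`
#' comments, ids need not be contiguous, and a parent may reference an id
#' defined later in the file (two-pass read). Segment labels are stored in
#' the type column as `100 + code`; types 0/1 mean unlabeled. Positions
#' round-trip to 1e-6 mm.
#'
#' @param path SWC file path.
#' @param tree an [airway_tree].
#' @return `read_swc` returns an [airway_tree]; `write_swc` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("SWC file has no data lines: ", path)
  rows <- vector("list", length(keep))
  for (m in seq_along(keep)) {
    ln <- keep[m]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) != 7L)
      stop(sprintf("malformed SWC line %d in '%s': expected 7 fields, got %d",
                   ln, path, length(tok)))
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num))
      stop(sprintf("malformed SWC line %d in '%s': non-numeric field", ln, path))
    rows[[m]] <- num
  }
  m <- do.call(rbind, rows)
  type <- as.integer(m[, 2])
  label <- ifelse(type >= 101L & type <= 118L, type - 100L, NA_integer_)
  nodes <- data.frame(id = as.integer(m[, 1]), x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]),
                      label = as.integer(label))
  dangling <- nodes$id[nodes$parent != -1L & !(nodes$parent %in% nodes$id)]
  if (length(dangling))
    stop("SWC dangling parent reference for node(s): ",
         paste(dangling, collapse = ", "))
  airway_tree(nodes)
}

#' @rdname read_swc
#' @export
write_swc <- function(tree, path) {
  type <- ifelse(is.na(tree$label), 1L, 100L + tree$label)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   tree$id, type, tree$x, tree$y, tree$z, tree$radius, tree$parent)
  writeLines(c("# SWC airway centerline (type = 100 + segment code; 1 = unlabeled)",
               lines), path)
  invisible(path)
}

# ---- internal helpers shared by probmap / parcellate / metrics ----

# Labeled centerline point set: labeled nodes plus points interpolated along
# edges whose two endpoints carry the same label, at steps <= `step` mm.
labeled_centerline_points <- function(tree, step) {
  idx <- stats::setNames(seq_len(nrow(tree)), as.character(tree$id))
  pts <- list()
  lab <- list()
  li <- which(!is.na(tree$label))
  if (length(li)) {
    pts[[1L]] <- cbind(tree$x[li], tree$y[li], tree$z[li])
    lab[[1L]] <- tree$label[li]
  }
  for (i in which(tree$parent != -1L)) {
    p <- idx[[as.character(tree$parent[i])]]
    if (is.na(tree$label[i]) || is.na(tree$label[p])) next
    if (tree$label[i] != tree$label[p]) next
    a <- c(tree$x[p], tree$y[p], tree$z[p])
    b <- c(tree$x[i], tree$y[i], tree$z[i])
    len <- sqrt(sum((b - a)^2))
    ns <- max(1L, ceiling(len / step))
    if (ns > 1L) {
      t <- seq_len(ns - 1L) / ns
      pts[[length(pts) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                       a[2] + t * (b[2] - a[2]),
                                       a[3] + t * (b[3] - a[3]))
      lab[[length(lab) + 1L]] <- rep(tree$label[i], ns - 1L)
    }
  }
  if (!length(pts)) return(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), label = integer(0)))
  m <- do.call(rbind, pts)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], label = unlist(lab))
}

#' Count branching sites of a tree
#'
#' With `merge_radius_mm = 0` this is the number of nodes with two or more
#' children. With a positive radius, branch points closer together than the
#' radius (single linkage) are merged into one anatomical branching site:
#' a traced trifurcation typically appears as two binary splits a couple of
#' millimetres apart, which is still one site.
#'
#' @param tree an [airway_tree].
#' @param merge_radius_mm merge distance in mm (default 0: raw count).
#' @return Integer number of branch points / branching sites.
#' @export
count_branch_points <- function(tree, merge_radius_mm = 0) {
  if (nrow(tree) == 0L) return(0L)
  tab <- table(tree$parent[tree$parent != -1L])
  bp_ids <- as.integer(names(tab)[tab >= 2L])
  n <- length(bp_ids)
  if (n == 0L || merge_radius_mm <= 0) return(n)
  rows <- match(bp_ids, tree$id)
  p <- cbind(tree$x[rows], tree$y[rows], tree$z[rows])
  # single-linkage clusters within the merge radius (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d2 <- as.matrix(stats::dist(p))^2
  r2 <- merge_radius_mm^2
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d2[i, j] <= r2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Total centerline length (mm): sum of parent-child edge lengths.
tree_length <- function(tree) {
  idx <- stats::setNames(seq_len(nrow(tree)), as.character(tree$id))
  i <- which(tree$parent != -1L)
  if (!length(i)) return(0)
  p <- idx[as.character(tree$parent[i])]
  sum(sqrt((tree$x[i] - tree$x[p])^2 + (tree$y[i] - tree$y[p])^2 +
             (tree$z[i] - tree$z[p])^2))
}
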