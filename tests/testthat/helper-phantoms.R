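# full phantoms are a couple of seconds each; cache them across test files
.phantom_cache <- new.env(parent = emptyenv())

get_phantom <- function(seed) {
  key <- as.character(seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(seed = seed))
  .phantom_cache[[key]]
}

# a small binary tree: `chain` nodes of trachea, then `depth` perfect binary
# levels with 2-node branches
make_binary_tree <- function(chain = 5L, depth = 3L, step = 2) {
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0, parent = -1L)
  nid <- 1L
  add <- function(x, y, z, parent) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = nid, x = x, y = y, z = z,
                                      parent = parent))
    nid
  }
  last <- 1L
  for (i in seq_len(chain - 1L)) last <- add(0, 0, i * step, last)
  grow <- function(parent, x, y, z, level, span) {
    if (level > depth) return(invisible())
    for (s in c(-1, 1)) {
      n1 <- add(x + s * span, y, z + step, parent)
      grow(n1, x + s * span, y, z + step, level + 1L, span / 2)
    }
  }
  grow(last, 0, 0, (chain - 1L) * step, 1L, 8)
  airway_tree(nodes)
}
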