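#' Build the tree-structured scale index model
#'
#' The scale tree is the depth-2 structure that drives adaptive
#' administration: a sentinel root, one child per comprehensive symptom
#' block (in optimized label order), and below each block the leaf holding
#' that symptom's single-assessment scale. Labels without a confirmation
#' scale get a childless block node.
#'
#' @param optimized an `optimized_scale_system`.
#' @return object of class `scale_tree` with `root`, `label_order`,
#'   `input_label_order`, `blocks` (label -> comprehensive item ids),
#'   `singles` / `singles_input` (label -> single item ids, optimized /
#'   input order) and `edges` (data.frame `parent`, `child` of node ids
#'   `D'`, `T_<label>`, `S_<label>`).
#' @export
build_scale_tree <- function(optimized) {
  stopifnot(inherits(optimized, "optimized_scale_system"))
  blocks <- optimized$comp_blocks
  singles <- optimized$single_orders
  orphan <- setdiff(names(singles), names(blocks))
  if (length(orphan))
    stop("single-assessment scale(s) whose label has no comprehensive block: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  labs <- optimized$label_order
  block_ids <- paste0("T_", labs)
  e_root <- data.frame(parent = "D'", child = block_ids,
                       stringsAsFactors = FALSE)
  with_leaf <- labs[labs %in% names(singles)]
  e_leaf <- data.frame(parent = paste0("T_", with_leaf, recycle0 = TRUE),
                       child = paste0("S_", with_leaf, recycle0 = TRUE),
                       stringsAsFactors = FALSE)
  structure(list(root = "D'",
                 label_order = labs,
                 input_label_order = optimized$input_label_order,
                 blocks = blocks,
                 singles = singles,
                 singles_input = optimized$single_input_orders,
                 edges = rbind(e_root, e_leaf)),
            class = "scale_tree")
}

#' @export
print.scale_tree <- function(x, ...) {
  cat("<scale_tree> root D' ->", length(x$label_order), "symptom blocks,",
      length(x$singles), "single-assessment leaves\n")
  invisible(x)
}

#' Successor of a symptom label in traversal order
#'
#' Iterates the root's children in optimized label order. `current = NULL`
#' is the start sentinel (returns the first label); after the final label
#' the end sentinel `NA_character_` is returned.
#'
#' @param tree a `scale_tree`.
#' @param current `NULL` (start), or a label in the tree.
#' @return the next label, or `NA_character_` when traversal is complete.
#' @export
next_label <- function(tree, current = NULL) {
  labs <- tree$label_order
  if (is.null(current)) {
    return(if (length(labs)) labs[[1L]] else NA_character_)
  }
  pos <- match(current, labs)
  if (is.na(pos)) stop("unknown label: ", current, call. = FALSE)
  if (pos == length(labs)) NA_character_ else labs[[pos + 1L]]
}

#' Flatten a scale tree back to its block and item orders
#'
#' Inverse of `build_scale_tree()` up to the ordering information: returns
#' the comprehensive blocks (in label order) and single-scale item orders
#' the tree was built from.
#'
#' @param tree a `scale_tree`.
#' @return list with `label_order`, `comp_blocks`, `single_orders`.
#' @export
flatten_tree <- function(tree) {
  list(label_order = tree$label_order,
       comp_blocks = tree$blocks[tree$label_order],
       single_orders = tree$singles)
}

#' Export a scale tree
#'
#' `tree_to_adjacency()` returns a plain list (JSON-ready) of node ids and
#' edges; `tree_to_dot()` renders Graphviz DOT text.
#'
#' @param tree a `scale_tree`.
#' @return a list, or a character scalar of DOT source.
#' @export
tree_to_adjacency <- function(tree) {
  nodes <- c(tree$root, paste0("T_", tree$label_order),
             paste0("S_", names(tree$singles)))
  list(nodes = nodes,
       edges = Map(function(p, c) list(parent = p, child = c),
                   tree$edges$parent, tree$edges$child, USE.NAMES = FALSE),
       label_order = tree$label_order)
}

#' @rdname tree_to_adjacency
#' @export
tree_to_dot <- function(tree) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph scale_tree {",
             '  "D\'" [shape=box];',
             sprintf('  "%s" -> "%s";', esc(tree$edges$parent),
                     esc(tree$edges$child)),
             "}")
  paste(lines, collapse = "\n")
}
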