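#' Read and validate a rooted Newick tree
#'
#' Parses a Newick string (or file) into an [ape::phylo] object and enforces
#' the invariants the downstream likelihood machinery relies on: a single
#' root, unique non-empty leaf labels, non-negative branch lengths on every
#' non-root edge, and a full set of internal-node labels. Internal nodes
#' without a label receive stable identifiers `"N1".."Nk"` assigned in
#' postorder.
#'
#' Branch lengths are required by default because both likelihood tracks
#' interpret them as substitutions/site; `missing_length = "zero"` substitutes
#' 0 instead of failing. Quoted labels are rejected: inputs here are
#' program-generated. Polytomies are allowed.
#'
#' @param x a Newick string, or the path of a file containing one.
#' @param missing_length what to do when an edge has no branch length:
#'   `"error"` (default) or `"zero"`.
#' @return a rooted `phylo` object with `node.label` set on every internal
#'   node.
#' @export
read_newick <- function(x, missing_length = c("error", "zero")) {
  missing_length <- match.arg(missing_length)
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl(";", x, fixed = TRUE) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  if (grepl("'", x, fixed = TRUE) || grepl('"', x, fixed = TRUE)) {
    stop("quoted labels are not supported: ", x)
  }
  n_open <- lengths(regmatches(x, gregexpr("(", x, fixed = TRUE)))
  n_close <- lengths(regmatches(x, gregexpr(")", x, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- tryCatch(ape::read.tree(text = x),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not parse '", x, "'")
  validate_tree(tree, missing_length = missing_length)
}

#' Validate a phylo object against the package's tree contract
#'
#' @param tree a `phylo` object.
#' @param missing_length see [read_newick()].
#' @return the validated tree, with internal labels filled in.
#' @export
validate_tree <- function(tree, missing_length = c("error", "zero")) {
  missing_length <- match.arg(missing_length)
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) {
    if (missing_length == "error") {
      stop("tree has no branch lengths (substitutions/site are required; ",
           "use missing_length = \"zero\" to default them)")
    }
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (missing_length == "error") stop("tree has edges with missing lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    bad <- min(tree$edge.length)
    stop("negative branch length in tree: ", format(bad))
  }
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label")
  if (anyDuplicated(labs)) {
    stop("duplicate leaf label: ", labs[duplicated(labs)][1L])
  }
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  tree <- name_internal_nodes(tree)
  tree
}

## Stable ids N1..Nk for unlabeled internals, assigned in postorder so the
## numbering is reproducible for a given topology.
name_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", n_int)
  labs[is.na(labs)] <- ""
  po <- ape::reorder.phylo(tree, "postorder")$edge
  int_order <- unique(po[, 1L])            # parents in postorder
  if (!(n_tip + 1L) %in% int_order) int_order <- c(int_order, n_tip + 1L)
  k <- 0L
  for (node in int_order) {
    i <- node - n_tip
    if (!nzchar(labs[i])) {
      k <- k + 1L
      labs[i] <- paste0("N", k)
    }
  }
  if (anyDuplicated(c(tree$tip.label, labs))) {
    stop("node labels are not unique after internal naming")
  }
  tree$node.label <- labs
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is written there.
#' @param digits number of significant digits for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Node label of every node, tips then internals
#'
#' @param tree a validated `phylo`.
#' @return character vector indexed by the internal node numbering of `phylo`
#'   (1..Ntip are tips, Ntip+1.. are internal nodes).
#' @export
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

#' Branch table of a tree
#'
#' One row per non-root node, giving its parent, the connecting branch length
#' and whether the child is a leaf.
#'
#' @param tree a validated `phylo`.
#' @return a `data.frame` with columns `parent_id`, `child_id`,
#'   `branch_length`, `child_is_leaf`.
#' @export
branch_table <- function(tree) {
  tree <- validate_tree(tree)
  labs <- node_labels(tree)
  data.frame(
    parent_id = labs[tree$edge[, 1L]],
    child_id = labs[tree$edge[, 2L]],
    branch_length = tree$edge.length,
    child_is_leaf = tree$edge[, 2L] <= length(tree$tip.label),
    stringsAsFactors = FALSE
  )
}

#' Prune a tree to a subset of leaves
#'
#' Removes all leaves not in `keep`, suppressing the resulting unary nodes
#' and summing their branch lengths, so every kept leaf keeps its original
#' root-to-leaf path length. When every kept leaf lies inside one clade,
#' the branch chain between the original root and that clade's ancestor is
#' retained as the pruned tree's `root.edge`, which [root_to_tip()]
#' includes in path lengths.
#'
#' @param tree a validated `phylo`.
#' @param keep character vector of leaf labels to retain (at least 2).
#' @return the pruned, re-validated tree.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 leaves to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL
  out <- validate_tree(out, missing_length = "zero")
  ## distance from the original root down to the pruned tree's root: the
  ## per-leaf depth deficit, identical for every kept leaf
  stem <- root_to_tip(tree)[out$tip.label] - root_to_tip(out)
  stopifnot(diff(range(stem)) < 1e-9)
  if (stem[1L] > 0) out$root.edge <- unname(stem[1L])
  out
}

#' Root-to-leaf path lengths
#'
#' Includes the tree's `root.edge`, if any (see [prune_to_taxa()]).
#'
#' @param tree a validated `phylo`.
#' @return named numeric vector of root-to-tip distances.
#' @export
root_to_tip <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- node_depths(tree)
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  stats::setNames(depth[seq_len(n_tip)] + stem, tree$tip.label)
}

## Depth (distance from root) of every node, preorder accumulation.
node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  len <- ape::reorder.phylo(tree, "postorder")$edge.length
  depth <- numeric(n_node)
  for (i in rev(seq_len(nrow(edge)))) {           # preorder
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + len[i]
  }
  depth
}

#' Attach labels to ancestors identified by their descendant leaf sets
#'
#' Ancestor naming follows the convention of naming internal nodes after the
#' clade they subtend (e.g. the last common ancestor of a lineage). The map
#' is keyed by the exact set of leaf labels descending from the node.
#'
#' @param tree a validated `phylo`.
#' @param label_map named character vector: names are comma-separated leaf
#'   sets (order-insensitive), values the labels to attach.
#' @return the relabelled tree.
#' @export
label_ancestors <- function(tree, label_map) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  clades <- clade_leafsets(tree)
  keys <- vapply(strsplit(names(label_map), ","), function(s)
    paste(sort(trimws(s)), collapse = ","), character(1))
  for (j in seq_along(keys)) {
    hit <- which(clades == keys[j])
    if (!length(hit)) stop("no internal node has leaf set {", keys[j], "}")
    tree$node.label[hit] <- unname(label_map[j])
  }
  tree
}

## Canonical sorted comma-joined leaf set under each internal node.
clade_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  vapply(sets[(n_tip + 1L):(n_tip + tree$Nnode)],
         function(s) paste(sort(s), collapse = ","), character(1))
}

#' Read a node-label map from a two-column TSV
#'
#' @param path TSV with columns: comma-separated leaf set, label.
#' @return named character vector suitable for [label_ancestors()].
#' @export
read_node_label_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("node-label map needs 2 columns: leafset, label")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}
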