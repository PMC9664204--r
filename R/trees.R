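#' Parse a rooted tree from Newick text
#'
#' Wraps [ape::read.tree()] with the validation and labelling conventions
#' used throughout the package: leaf labels must be unique, internal labels
#' (where present) must be unique, and unlabelled internal nodes receive
#' deterministic auto-labels `N<k>` where `k` is the node's preorder index
#' (root = 1). Branch lengths are parsed but ignored by all downstream
#' algorithms. A branch is always identified by the label of its child node;
#' the root branch is addressable by the root label.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `phylo` with complete, unique node labels.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_parens(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree))
    stop("Newick parse error: no tree could be read from the input",
         call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  tree <- .autolabel(tree)
  lab <- tree$node.label
  dupn <- lab[nzchar(lab) & duplicated(lab)]
  if (length(dupn))
    stop("duplicate internal label(s): ", paste(unique(dupn), collapse = ", "),
         call. = FALSE)
  clash <- intersect(tree$node.label, tree$tip.label)
  if (length(clash))
    stop("label(s) used for both a leaf and an internal node: ",
         paste(clash, collapse = ", "), call. = FALSE)
  tree
}

#' Write a tree to Newick text
#'
#' Inverse of [parse_newick()]; `parse_newick(write_newick(x))` reproduces
#' the topology and labels exactly.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

.check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses: unexpected ')' at character ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("unbalanced parentheses: ", depth, " unclosed '(' in input",
         call. = FALSE)
  invisible(TRUE)
}

# Fill missing internal labels with N<preorder index>.
.autolabel <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  ord <- preorder_nodes(tree)
  pre_index <- integer(max(ord))
  pre_index[ord] <- seq_along(ord)
  ntip <- length(tree$tip.label)
  for (i in seq_len(n_int)) {
    if (!nzchar(lab[i])) {
      cand <- paste0("N", pre_index[ntip + i])
      while (cand %in% c(tree$tip.label, lab)) cand <- paste0(cand, "_")
      lab[i] <- cand
    }
  }
  tree$node.label <- lab
  tree
}

## ---- internal tree utilities (node numbers follow ape conventions) ----

tree_root <- function(tree) {
  unique(tree$edge[, 1][!tree$edge[, 1] %in% tree$edge[, 2]])
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- character(length(node))
  tip <- node <= ntip
  out[tip] <- tree$tip.label[node[tip]]
  out[!tip] <- tree$node.label[node[!tip] - ntip]
  out
}

node_id <- function(tree, label) {
  all_lab <- c(tree$tip.label, tree$node.label)
  idx <- match(label, all_lab)
  if (anyNA(idx))
    stop("unknown node label(s): ", paste(label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

has_label <- function(tree, label) {
  label %in% c(tree$tip.label, tree$node.label)
}

tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

tree_parents <- function(tree) {
  par <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

preorder_nodes <- function(tree) {
  root <- tree_root(tree)
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[1]
    stack <- stack[-1]
    out <- c(out, node)
    kids <- tree_children(tree, node)
    if (length(kids)) stack <- c(kids, stack)
  }
  out
}

# Leaf indices under (and including) a node.
leaves_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]
    stack <- stack[-1]
    if (nd <= ntip) out <- c(out, nd) else
      stack <- c(tree_children(tree, nd), stack)
  }
  out
}

# All nodes (internal + leaves) under and including `node`.
nodes_under <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]
    stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(tree_children(tree, nd), stack)
  }
  out
}

node_depths <- function(tree) {
  par <- tree_parents(tree)
  d <- rep(NA_integer_, length(par))
  root <- tree_root(tree)
  d[root] <- 0L
  for (nd in preorder_nodes(tree)) {
    if (nd == root) next
    d[nd] <- d[par[nd]] + 1L
  }
  d
}

# MRCA by labels; accepts leaves and internal labels; length-1 input returns
# the node itself.
mrca_node <- function(tree, labels) {
  ids <- node_id(tree, unique(labels))
  if (length(ids) == 1L) return(ids)
  par <- tree_parents(tree)
  anc_path <- function(n) {
    p <- n
    while (!is.na(par[n])) { n <- par[n]; p <- c(p, n) }
    p
  }
  common <- Reduce(intersect, lapply(ids, anc_path))
  common[1]
}

mrca_label <- function(tree, labels) node_label(tree, mrca_node(tree, labels))

# Is node `a` an ancestor of (or equal to) node `b`?
is_ancestor <- function(tree, a, b) {
  par <- tree_parents(tree)
  while (!is.na(b)) {
    if (a == b) return(TRUE)
    b <- par[b]
  }
  FALSE
}

is_binary_rooted <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  all(tab[tab > 0] == 2L)
}
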