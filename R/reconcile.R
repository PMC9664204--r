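#' LCA reconciliation of a gene tree with a species tree
#'
#' Standard lowest-common-ancestor reconciliation: each gene-tree leaf
#' (labelled `species|gene_id`) maps to its species; each internal node
#' maps to the species-tree MRCA of its children's images. An internal node
#' is a duplication if and only if its image equals the image of at least
#' one child; otherwise it is a speciation. Losses are counted by standard
#' duplication-loss accounting: along a gene-tree edge whose endpoints map
#' `d` species-tree edges apart, `d - 1` species-tree edges are skipped
#' under a speciation (each skip is a loss) and `d` under a duplication.
#'
#' @param gene_tree Rooted binary `phylo` with `species|gene_id` leaf labels.
#' @param species_tree Rooted binary `phylo` with unique labels.
#' @return A `reconciliation` list: `node_map` (gene node -> species label,
#'   named `g<node>`), `node_events` (internal nodes, `speciation` or
#'   `duplication`), `n_duplications`, `n_losses`,
#'   `duplication_assignments` (duplication node -> species branch label).
#' @export
lca_reconcile <- function(gene_tree, species_tree) {
  if (!ape::is.rooted(gene_tree))
    stop("gene tree must be rooted; refusing to root it silently",
         call. = FALSE)
  if (!is_binary_rooted(gene_tree))
    stop("gene tree must be binary", call. = FALSE)
  if (!is_binary_rooted(species_tree))
    stop("species tree must be binary for LCA reconciliation",
         call. = FALSE)
  sp_of_leaf <- sub("\\|.*$", "", gene_tree$tip.label)
  unknown <- setdiff(sp_of_leaf, species_tree$tip.label)
  if (length(unknown))
    stop("gene tree species absent from species tree: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)

  ngt <- length(gene_tree$tip.label)
  n_nodes <- ngt + gene_tree$Nnode
  M <- integer(n_nodes)            # gene node -> species node id
  events <- rep(NA_character_, n_nodes)
  par <- tree_parents(species_tree)
  depth <- node_depths(species_tree)
  post <- rev(preorder_nodes(gene_tree))
  for (nd in post) {
    if (nd <= ngt) {
      M[nd] <- node_id(species_tree, sp_of_leaf[nd])
    } else {
      kids <- tree_children(gene_tree, nd)
      M[nd] <- mrca_node(species_tree,
                         node_label(species_tree, M[kids]))
      events[nd] <- if (any(M[kids] == M[nd])) "duplication" else "speciation"
    }
  }
  # loss accounting
  n_losses <- 0L
  for (nd in preorder_nodes(gene_tree)) {
    if (nd <= ngt) next
    kids <- tree_children(gene_tree, nd)
    for (k in kids) {
      d <- depth[M[k]] - depth[M[nd]]
      n_losses <- n_losses +
        if (events[nd] == "duplication") d else max(d - 1L, 0L)
    }
  }
  internal <- (ngt + 1L):n_nodes
  dup_nodes <- internal[events[internal] == "duplication"]
  gname <- function(ids) sprintf("g%d", ids)   # length-0 safe
  node_map <- stats::setNames(node_label(species_tree, M),
                              gname(seq_len(n_nodes)))
  structure(list(
    node_map = node_map,
    node_events = stats::setNames(events[internal], gname(internal)),
    n_duplications = length(dup_nodes),
    n_losses = n_losses,
    duplication_assignments = stats::setNames(
      node_label(species_tree, M[dup_nodes]), gname(dup_nodes)),
    gene_tree = gene_tree, species_tree = species_tree),
    class = "reconciliation")
}

#' Classify duplications into WGD windows or local events
#'
#' A duplication mapping to a branch carrying a WGD tag is a candidate
#' ohnolog-producing duplication and gets the label `WGD:<tag>`; when a
#' branch carries several tags (the two basal vertebrate rounds are
#' typically indistinguishable on a single stem branch) the tags are
#' joined, e.g. `WGD:1R/2R`. Duplications on untagged terminal branches are
#' `lineage_specific`; on untagged internal branches `local_prewindow`
#' (a local duplication predating the tagged windows below it or simply
#' outside any window). Synteny corroboration of ohnolog status is a
#' separate step (see [detect_paralogon()]).
#'
#' @param recon A [lca_reconcile()] result.
#' @param wgd_tags Named character vector, tag -> branch label (branch =
#'   child-node label).
#' @return Named character vector, duplication node -> timing label.
#' @export
classify_duplications <- function(recon, wgd_tags) {
  sp <- recon$species_tree
  vapply(recon$duplication_assignments, function(branch) {
    tags <- names(wgd_tags)[wgd_tags == branch]
    if (length(tags))
      paste0("WGD:", paste(tags, collapse = "/"))
    else if (branch %in% sp$tip.label)
      "lineage_specific"
    else
      "local_prewindow"
  }, character(1))
}

#' Derive a Dollo gain constraint from a two-subtype gene tree
#'
#' When a gene tree joins two subtypes (e.g. a narrowly retained subtype
#' sister to a widely retained one), the species-tree node where their
#' split maps is the latest possible origin of both subtypes — older than
#' the narrow subtype's present-day distribution suggests. That node can be
#' fed to [dollo_reconstruct()] as `gain_constraint`, keeping the tree
#' evidence and the presence evidence in separate, explicit steps.
#'
#' @param recon A [lca_reconcile()] result.
#' @param subtypes Named character vector mapping each gene-tree leaf label
#'   to its subtype.
#' @return Species-tree node label of the subtype split.
#' @export
infer_gain_constraint <- function(recon, subtypes) {
  gt <- recon$gene_tree
  missing <- setdiff(gt$tip.label, names(subtypes))
  if (length(missing))
    stop("subtype missing for leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(unique(subtypes[gt$tip.label])) < 2L)
    stop("gene tree contains a single subtype; no split to time",
         call. = FALSE)
  split_node <- mrca_node(gt, gt$tip.label)
  unname(recon$node_map[paste0("g", split_node)])
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("LCA reconciliation:", x$n_duplications, "duplication(s),",
      x$n_losses, "loss(es)\n")
  if (length(x$duplication_assignments)) {
    cat("  duplications on branches:",
        paste(unique(x$duplication_assignments), collapse = ", "), "\n")
  }
  invisible(x)
}
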