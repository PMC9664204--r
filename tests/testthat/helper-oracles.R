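# Independent oracles and small generators shared across tests. These
# deliberately avoid the package's own tree utilities: they use ape /
# phangorn primitives and plain recursions so they can disagree with the
# implementation under test.

rand_labelled_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- ape::rtree(n, tip.label = paste0("s", seq_len(n)))
  t$edge.length <- NULL
  t$node.label <- NULL
  parse_newick(ape::write.tree(t))
}

all_labels <- function(tree) c(tree$tip.label, tree$node.label)

# Exhaustive-minimum Dollo oracle: smallest set of loss branches (all of
# which must be present-free) covering every absent leaf under the gain
# node. Enumerates subsets by increasing size.
oracle_dollo_losses <- function(tree, states, gain_constraint = NULL) {
  st <- states[tree$tip.label]
  ntip <- length(tree$tip.label)
  present <- which(st %in% c("1", "P", "present", "pseudogene"))
  absent <- which(st %in% c("0", "absent"))
  tipsets <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  gain <- if (!is.null(gain_constraint)) {
    match(gain_constraint, all_labels(tree))
  } else if (length(present) == 1L) present else ape::getMRCA(tree, present)
  under_gain <- if (gain <= ntip) integer(0) else
    unlist(phangorn::Descendants(tree, gain, "all"))
  absent_to_cover <- intersect(absent, tipsets[[gain]])
  if (!length(absent_to_cover)) return(0L)
  cands <- under_gain[vapply(under_gain, function(nd)
    !any(tipsets[[nd]] %in% present), logical(1))]
  for (k in seq_len(length(cands))) {
    for (cs in utils::combn(cands, k, simplify = FALSE)) {
      covered <- unique(unlist(tipsets[cs]))
      if (all(absent_to_cover %in% covered)) return(k)
    }
  }
  stop("oracle found no covering loss set")
}

# Pedigree-walk reconciliation oracle. For each realized duplication event
# of a family, computes the extant species reachable from the two copies
# ("threads") by replaying the recorded events along the species tree.
# A duplication is observable when both sides retain descendants; its
# expected LCA placement is the species-tree MRCA of the union.
oracle_observable_dups <- function(sim, family, tree) {
  ev <- sim$truth$events
  ev <- ev[ev$family_id %in% family, , drop = FALSE]
  extant <- lapply(sim$tables, function(tb) unname(attr(tb, "lineage")))
  labels <- all_labels(tree)
  lab_of <- function(node) labels[node]
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]

  thread_species <- function(l, node, after) {
    evs <- ev[ev$branch == lab_of(node) & ev$order > after, , drop = FALSE]
    evs <- evs[order(evs$order), , drop = FALSE]
    out <- character(0)
    alive <- TRUE
    for (i in seq_len(nrow(evs))) {
      e <- evs[i, ]
      if (e$kind %in% c("wgd", "local_duplication") &&
          !is.na(e$parent) && e$parent == l) {
        out <- c(out, thread_species(e$child, node, e$order))
      } else if (e$kind == "loss" && !is.na(e$lineage) && e$lineage == l) {
        alive <- FALSE
        break
      }
    }
    if (alive) {
      kk <- kids_of(node)
      if (!length(kk)) {
        sp <- tree$tip.label[node]
        if (l %in% extant[[sp]]) out <- c(out, sp)
      } else {
        for (k in kk) out <- c(out, thread_species(l, k, 0))
      }
    }
    unique(out)
  }

  dups <- ev[ev$kind %in% c("wgd", "local_duplication"), , drop = FALSE]
  placements <- character(0)
  true_branches <- character(0)
  for (i in seq_len(nrow(dups))) {
    e <- dups[i, ]
    node <- match(e$branch, labels)
    a <- thread_species(e$parent, node, e$order)
    b <- thread_species(e$child, node, e$order)
    if (!length(a) || !length(b)) next
    sp <- union(a, b)
    pl <- if (length(sp) == 1L) sp else labels[ape::getMRCA(tree, sp)]
    placements <- c(placements, pl)
    true_branches <- c(true_branches, e$branch)
  }
  list(placements = placements, true_branches = true_branches)
}

# Fixture pipeline shared by scenario and acceptance tests.
fixture_repertoires <- function() {
  tree <- trpv_species_tree()
  apply_nomenclature(propagate_history(tree, trpv_event_history()))
}
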