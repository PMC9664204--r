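#' Dollo parsimony reconstruction of a gene subtype's gains and losses
#'
#' Under Dollo parsimony a character can be gained exactly once and lost
#' any number of times. Given the per-species state of one gene subtype
#' (present / pseudogene / absent / unknown), the gain is placed at the
#' MRCA of all non-absent species (a pseudogene proves the lineage
#' persisted, so it counts as present), unless `gain_constraint` forces an
#' earlier node — typically supplied from reconciliation evidence when the
#' gene tree shows the subtype is older than its current species
#' distribution. Losses are the minimal set of branches whose removal
#' explains every absent species; unknown states are resolved to minimize
#' losses.
#'
#' The minimal loss set is found by collecting, inside the gain subtree,
#' the maximal subtrees containing no (required-)present leaf; each such
#' subtree holding at least one absent leaf receives exactly one loss.
#' Ties among equally minimal placements (which arise only through unknown
#' states) are broken toward the deepest (leafward) placement: the loss is
#' put at the MRCA of the absent leaves of the subtree. When unknown leaves
#' fall between that MRCA and the subtree root, other equally minimal
#' placements exist and `ambiguous` is set.
#'
#' @param tree Species tree (`phylo`; multifurcations allowed).
#' @param states Named character vector, species -> state. Both the compact
#'   tokens (`1`, `P`, `0`, `?`) and long names are accepted.
#' @param gain_constraint Optional node label at (or above) which the gain
#'   is forced; must be an ancestor of all non-absent species.
#' @param subtype Optional label stored in the result.
#' @return A `dollo_result` list: `subtype`, `gain_branch`, `loss_branches`
#'   (character vector), `n_losses`, `ambiguous`.
#' @export
dollo_reconstruct <- function(tree, states, gain_constraint = NULL,
                              subtype = NA_character_) {
  states <- .norm_states(states, tree)
  non_absent <- names(states)[states %in% c("present", "pseudogene")]
  if (!length(non_absent))
    stop("Dollo reconstruction needs at least one non-absent species",
         call. = FALSE)
  gain_node <- mrca_node(tree, non_absent)
  if (!is.null(gain_constraint)) {
    cn <- node_id(tree, gain_constraint)
    if (!is_ancestor(tree, cn, gain_node))
      stop("gain_constraint '", gain_constraint,
           "' is not an ancestor of all non-absent species", call. = FALSE)
    gain_node <- cn
  }

  ntip <- length(tree$tip.label)
  state_of_leaf <- function(leaf) states[tree$tip.label[leaf]]
  sub_nodes <- nodes_under(tree, gain_node)
  # present-free: subtree contains no present/pseudogene leaf
  present_free <- vapply(sub_nodes, function(nd) {
    lv <- tree$tip.label[leaves_under(tree, nd)]
    !any(states[lv] %in% c("present", "pseudogene"))
  }, logical(1))
  names(present_free) <- sub_nodes
  par <- tree_parents(tree)
  is_pf <- function(nd) isTRUE(present_free[as.character(nd)])
  maximal <- sub_nodes[vapply(sub_nodes, function(nd) {
    if (!is_pf(nd)) return(FALSE)
    p <- par[nd]
    if (is.na(p) || !(p %in% sub_nodes)) return(TRUE)
    !is_pf(p)
  }, logical(1))]

  loss_branches <- character(0)
  ambiguous <- FALSE
  for (nd in maximal) {
    lv <- leaves_under(tree, nd)
    absent_lv <- lv[vapply(lv, function(l) state_of_leaf(l) == "absent",
                           logical(1))]
    if (!length(absent_lv)) next  # only unknowns: resolved present, no loss
    loss_node <- mrca_node(tree, tree$tip.label[absent_lv])
    loss_branches <- c(loss_branches, node_label(tree, loss_node))
    if (loss_node != nd) {
      gap <- setdiff(leaves_under(tree, nd), leaves_under(tree, loss_node))
      if (any(vapply(gap, function(l) state_of_leaf(l) == "unknown",
                     logical(1))))
        ambiguous <- TRUE
    }
  }
  loss_branches <- sort(loss_branches)
  structure(list(subtype = subtype,
                 gain_branch = node_label(tree, gain_node),
                 loss_branches = loss_branches,
                 n_losses = length(loss_branches),
                 ambiguous = ambiguous),
            class = "dollo_result")
}

.norm_states <- function(states, tree) {
  map <- c("1" = "present", "P" = "pseudogene", "0" = "absent",
           "?" = "unknown", present = "present", pseudogene = "pseudogene",
           absent = "absent", unknown = "unknown")
  bad <- !states %in% names(map)
  if (any(bad))
    stop("unknown state token(s): ", paste(unique(states[bad]), collapse = ", "),
         call. = FALSE)
  out <- unname(map[states])
  names(out) <- names(states)
  missing <- setdiff(tree$tip.label, names(out))
  if (length(missing))
    stop("states missing for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out[tree$tip.label]
}

#' Number of independent losses of a subtype
#'
#' Convenience wrapper around [dollo_reconstruct()] returning only the
#' minimal loss count.
#'
#' @inheritParams dollo_reconstruct
#' @return Integer.
#' @export
count_independent_losses <- function(tree, states, gain_constraint = NULL) {
  dollo_reconstruct(tree, states, gain_constraint)$n_losses
}

#' Dollo reconstruction of every row of a presence matrix
#'
#' Applies [dollo_reconstruct()] per matrix row. Row-level errors are
#' captured in the `error` column and the run continues.
#'
#' @param tree Species tree.
#' @param matrix A `presence_matrix`.
#' @param constraints Optional named character vector, subtype -> node label
#'   used as gain constraint for that row.
#' @return data.frame with one row per subtype: `subtype`, `gain_branch`,
#'   `loss_branches` (`;`-joined), `n_losses`, `ambiguous`, `error`.
#' @export
dollo_all <- function(tree, matrix, constraints = NULL) {
  rows <- lapply(rownames(matrix), function(st) {
    cons <- if (!is.null(constraints) && st %in% names(constraints))
      constraints[[st]] else NULL
    res <- tryCatch(
      dollo_reconstruct(tree, matrix[st, ], gain_constraint = cons,
                        subtype = st),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(subtype = st, gain_branch = NA_character_,
                 loss_branches = NA_character_, n_losses = NA_integer_,
                 ambiguous = NA, error = conditionMessage(res))
    } else {
      data.frame(subtype = st, gain_branch = res$gain_branch,
                 loss_branches = paste(res$loss_branches, collapse = ";"),
                 n_losses = res$n_losses, ambiguous = res$ambiguous,
                 error = NA_character_)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.dollo_result <- function(x, ...) {
  cat("Dollo reconstruction",
      if (!is.na(x$subtype)) paste0("of ", x$subtype) else "", "\n")
  cat("  gain at:", x$gain_branch, "\n")
  cat("  losses (", x$n_losses, "):",
      paste(x$loss_branches, collapse = ", "), "\n")
  if (x$ambiguous) cat("  (multiple equally minimal placements exist)\n")
  invisible(x)
}
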