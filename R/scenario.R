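#' Default nomenclature scheme for WGD and serial duplicates
#'
#' Encodes the naming conventions used in the vertebrate gene-duplication
#' literature: teleost-WGD (3R) ohnolog pairs take suffixes `a`/`b` (Zfin
#' convention), salmonid-WGD (4R) pairs take suffixes \eqn{\alpha}/\eqn{\beta},
#' and lineage-specific serial duplicates take a lineage prefix plus serial
#' index (`m` mammal, `sau` sauropsid, `am` amphibian, `ch` chondrichthyan,
#' `po` Polypteridae, `cy` cyclostome). Aliases map package-internal serial
#' names to their historical names (e.g. the second mammalian TRPV5 copy is
#' universally known as TRPV6).
#'
#' @param aliases Named character vector, canonical name -> alias.
#' @return A `nomenclature_scheme` list.
#' @export
nomenclature_scheme <- function(aliases = c("mTRPV5-2" = "TRPV6")) {
  structure(list(
    wgd_suffixes = list("3R" = c("a", "b"),
                        "4R" = c("\u03b1", "\u03b2")),
    prefixes = c(m = "mammal", sau = "sauropsid", am = "amphibian",
                 ch = "chondrichthyan", po = "Polypteridae",
                 cy = "cyclostome"),
    aliases = aliases),
    class = "nomenclature_scheme")
}

.empty_repertoire <- function() {
  data.frame(name = character(), subtype = character(), status = character(),
             parent_name = character(), origin_kind = character(),
             origin_tag = character(), copy_index = integer(),
             stringsAsFactors = FALSE)
}

.as_repertoire <- function(df) {
  out <- .empty_repertoire()
  for (col in names(out)) {
    if (is.null(df[[col]]))
      df[[col]] <- if (col == "copy_index") NA_integer_ else NA_character_
  }
  df <- df[names(out)]
  if (nrow(df) == 0) return(out)
  df
}

#' Propagate an event history along a species tree
#'
#' The core scenario engine: starting from the root repertoire, the tree is
#' traversed in preorder and the events placed on each branch are applied in
#' listed order. A `wgd` event duplicates every coding lineage present on
#' the branch (pseudogenes are not re-duplicated); a `local_duplication`
#' inserts extra copies of its target; a `loss` removes a lineage from the
#' branch's subtree only; a `pseudogenization` flips a lineage's status.
#' Children inherit the parent's post-event repertoire, so an event on
#' branch *b* can affect only nodes inside *b*'s subtree.
#'
#' Copy names are assigned during propagation from each event's `name_rule`
#' and the `scheme` (see [read_event_history()] and
#' [nomenclature_scheme()]); [apply_nomenclature()] finalizes aliases and
#' verifies injectivity.
#'
#' @param tree Species tree (`phylo`, labelled as by [parse_newick()]).
#' @param history An [event_history()].
#' @param root_repertoire Optional data.frame (`name`, `subtype`, `status`)
#'   overriding the history's own root repertoire.
#' @param scheme A [nomenclature_scheme()].
#' @return A `repertoire_set`: named list (node label -> repertoire
#'   data.frame) with the tree attached as an attribute.
#' @export
propagate_history <- function(tree, history, root_repertoire = NULL,
                              scheme = nomenclature_scheme()) {
  rep0 <- root_repertoire %||% history$root_repertoire
  if (is.null(rep0) || nrow(rep0) == 0)
    stop("root repertoire is empty", call. = FALSE)
  rep0 <- .as_repertoire(rep0)
  rep0$origin_kind[is.na(rep0$origin_kind)] <- "root"
  events <- history$events
  ev_branch <- vapply(events, function(e) e$branch, character(1))

  out <- list()
  walk <- function(node, incoming) {
    lab <- node_label(tree, node)
    rep <- incoming
    for (ev in events[ev_branch == lab]) {
      rep <- .apply_event(rep, ev, lab, scheme)
    }
    out[[lab]] <<- rep
    for (kid in tree_children(tree, node)) walk(kid, rep)
  }
  walk(tree_root(tree), rep0)
  structure(out, class = "repertoire_set", tree = tree)
}

.apply_event <- function(rep, ev, branch, scheme) {
  find_target <- function(target) {
    idx <- which(rep$name == target)
    if (!length(idx))
      stop(ev$kind, " event on branch '", branch, "' targets lineage '",
           target, "' which does not exist there", call. = FALSE)
    idx
  }
  switch(ev$kind,
    wgd = {
      coding <- which(rep$status == "coding")
      new_rows <- rep[0, ]
      keep <- rep
      for (i in coding) {
        old <- rep$name[i]
        nm <- .wgd_copy_names(old, ev, scheme)
        subty <- rep(rep$subtype[i], 2)
        if (!is.null(ev$subtypes)) {
          st <- unlist(ev$subtypes)
          subty <- ifelse(nm %in% names(st), st[nm], subty)
        }
        keep$name[i] <- nm[1]
        keep$subtype[i] <- subty[1]
        keep$parent_name[i] <- old
        keep$origin_kind[i] <- "wgd"
        keep$origin_tag[i] <- ev$tag
        keep$copy_index[i] <- 1L
        new_rows <- rbind(new_rows, data.frame(
          name = nm[2], subtype = subty[2], status = "coding",
          parent_name = old, origin_kind = "wgd", origin_tag = ev$tag,
          copy_index = 2L, stringsAsFactors = FALSE))
      }
      rbind(keep, new_rows)
    },
    local_duplication = {
      i <- find_target(ev$target)[1]
      copies <- ev$copies %||% 1L
      rule <- ev$name_rule %||% "serial"
      old <- rep$name[i]
      if (rule == "serial") {
        prefix <- ev$prefix %||% ""
        base <- paste0(prefix, old)
        new_names <- paste0(base, "-", seq_len(copies) + 1L)
        rep$name[i] <- paste0(base, "-1")
        new_subtypes <- rep(rep$subtype[i], copies)
      } else {
        new_names <- unlist(ev$names)
        if (length(new_names) != copies)
          stop("local_duplication on branch '", branch,
               "': names must match copies", call. = FALSE)
        new_subtypes <- if (!is.null(ev$subtypes)) unlist(ev$subtypes)
                        else rep(rep$subtype[i], copies)
      }
      rbind(rep, data.frame(
        name = new_names, subtype = new_subtypes, status = "coding",
        parent_name = old, origin_kind = "local_duplication",
        origin_tag = NA_character_, copy_index = seq_len(copies) + 1L,
        stringsAsFactors = FALSE))
    },
    loss = {
      i <- find_target(ev$target)
      rep[-i, , drop = FALSE]
    },
    pseudogenization = {
      i <- find_target(ev$target)
      rep$status[i] <- "pseudogene"
      rep
    },
    stop("unknown event kind: ", ev$kind, call. = FALSE))
}

.wgd_copy_names <- function(old, ev, scheme) {
  rule <- ev$name_rule %||% "suffix_ab"
  if (rule == "explicit") {
    nm <- ev$names[[old]]
    if (is.null(nm) || length(unlist(nm)) != 2)
      stop("wgd event with explicit names lacks a 2-name entry for lineage '",
           old, "'", call. = FALSE)
    return(unlist(nm))
  }
  suffixes <- switch(rule,
    suffix_ab = scheme$wgd_suffixes[["3R"]],
    suffix_alphabeta = scheme$wgd_suffixes[["4R"]],
    stop("unknown wgd name_rule: ", rule, call. = FALSE))
  paste0(old, suffixes)
}

#' Count gene lineages at a node
#'
#' Gene counts follow the field's convention of excluding pseudogenes
#' unless explicitly requested, since published per-species totals count
#' functional genes and discuss pseudogenes separately.
#'
#' @param repertoires A `repertoire_set` from [propagate_history()].
#' @param node Node label (leaf or internal).
#' @param subtype Optional subtype filter (matched against the lineage
#'   subtype column); `NULL` counts all subtypes.
#' @param include_pseudogenes Count pseudogene lineages too?
#' @return Integer count.
#' @export
count_by_subtype <- function(repertoires, node, subtype = NULL,
                             include_pseudogenes = FALSE) {
  if (!node %in% names(repertoires))
    stop("unknown node: ", node, call. = FALSE)
  rep <- repertoires[[node]]
  if (!is.null(subtype)) rep <- rep[rep$subtype %in% subtype, , drop = FALSE]
  if (!include_pseudogenes) rep <- rep[rep$status == "coding", , drop = FALSE]
  nrow(rep)
}

#' Finalize nomenclature of a propagated repertoire set
#'
#' Verifies that the naming rules produced injective names within every
#' node's repertoire (a rule collision is an error, not a warning) and
#' attaches the scheme's aliases (e.g. the second mammalian TRPV5 serial
#' duplicate carries the alias TRPV6) as an `alias` column.
#'
#' @param repertoires A `repertoire_set`.
#' @param scheme A [nomenclature_scheme()].
#' @return The repertoire set with alias columns added.
#' @export
apply_nomenclature <- function(repertoires, scheme = nomenclature_scheme()) {
  for (node in names(repertoires)) {
    rep <- repertoires[[node]]
    dup <- rep$name[duplicated(rep$name)]
    if (length(dup))
      stop("nomenclature collision at node '", node, "': ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    rep$alias <- unname(scheme$aliases[rep$name])
    repertoires[[node]] <- rep
  }
  repertoires
}

#' Compare a predicted repertoire set against an observed presence matrix
#'
#' For every matrix row and species, the predicted state is derived from
#' the repertoire at that species' leaf: a row labelled with a subtype
#' aggregates all lineages of that subtype (coding beats pseudogene);
#' a row labelled with a specific lineage name is matched by name. Cells
#' where either side is `unknown` are treated as matches, since the
#' scenario takes no position on them. Species present in the matrix but
#' absent from the repertoire set are reported as `uncovered`, not errors.
#'
#' @param predicted A `repertoire_set`.
#' @param observed A `presence_matrix`.
#' @return data.frame with columns `subtype`, `species`, `predicted`,
#'   `observed`, `outcome` (one of `match`, `predicted_only`,
#'   `observed_only`, `status_mismatch`, `uncovered`); the number of
#'   discrepancies is attached as attribute `n_discrepancies`.
#' @export
diff_vs_observed <- function(predicted, observed) {
  subtypes_known <- unique(unlist(lapply(predicted, function(r) r$subtype)))
  rows <- list()
  for (sp in colnames(observed)) {
    covered <- sp %in% names(predicted)
    for (rl in rownames(observed)) {
      obs <- observed[rl, sp]
      if (!covered) {
        rows[[length(rows) + 1L]] <- data.frame(
          subtype = rl, species = sp, predicted = NA_character_,
          observed = obs, outcome = "uncovered")
        next
      }
      rep <- predicted[[sp]]
      if (rl %in% subtypes_known) {
        hit <- rep[rep$subtype == rl, , drop = FALSE]
      } else {
        hit <- rep[rep$name == rl, , drop = FALSE]
      }
      pred <- if (any(hit$status == "coding")) "present"
              else if (nrow(hit)) "pseudogene" else "absent"
      outcome <- if (obs == "unknown") "match"
        else if (pred == obs) "match"
        else if (pred == "absent") "observed_only"
        else if (obs == "absent") "predicted_only"
        else "status_mismatch"
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = rl, species = sp, predicted = pred, observed = obs,
        outcome = outcome)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_discrepancies") <-
    sum(!out$outcome %in% c("match", "uncovered"))
  out
}

#' @export
print.repertoire_set <- function(x, ...) {
  tree <- attr(x, "tree")
  leaves <- tree$tip.label
  counts <- vapply(leaves, function(l)
    sum(x[[l]]$status == "coding"), integer(1))
  cat("Repertoire set over", length(x), "nodes; per-species coding counts:\n")
  print(counts)
  invisible(x)
}
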