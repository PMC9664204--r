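#' Read an event history from a JSON file
#'
#' An event history is the machine-readable form of a per-branch
#' evolutionary scenario: an ordered list of events (whole-genome
#' duplication, local duplication, loss, pseudogenization), each placed on a
#' species-tree branch identified by the label of the branch's child node
#' (the root branch is addressable by the root label). Events sharing a
#' branch are applied in listed order during propagation.
#'
#' The JSON document has three members:
#' \describe{
#'   \item{`wgd_tags`}{object mapping WGD tag (e.g. `"3R"`) to branch label.}
#'   \item{`root_repertoire`}{array of `{name, subtype, status}` objects
#'     describing the gene lineages present above the root branch.}
#'   \item{`events`}{array of event objects, see Details.}
#' }
#'
#' Event objects carry `branch`, `kind` and kind-specific fields:
#' `wgd` events carry `tag` and a `name_rule` (`"explicit"` with a
#' `names` map from old lineage name to the two copy names, `"suffix_ab"`
#' for teleost-style a/b naming, or `"suffix_alphabeta"` for salmonid-style
#' \eqn{\alpha}/\eqn{\beta} naming); `local_duplication` events carry
#' `target`, `copies` and either explicit `names` (and optional `subtypes`)
#' or a `"serial"` rule with a lineage `prefix` (the target is renamed
#' `<prefix><target>-1` and the copies `<prefix><target>-2` onward);
#' `loss` and `pseudogenization` carry a `target` lineage name.
#'
#' @param path JSON file path.
#' @param tree Species tree (`phylo`) the branches must belong to.
#' @return An `event_history` list with members `events`, `wgd_tags` and
#'   `root_repertoire`.
#' @export
read_event_history <- function(path, tree) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rr <- doc$root_repertoire
  root_rep <- data.frame(
    name = vapply(rr, function(x) x$name, character(1)),
    subtype = vapply(rr, function(x) x$subtype, character(1)),
    status = vapply(rr, function(x) x$status %||% "coding", character(1)),
    stringsAsFactors = FALSE)
  wgd_tags <- vapply(doc$wgd_tags, identity, character(1))
  event_history(doc$events, tree, wgd_tags = wgd_tags,
                root_repertoire = root_rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build and validate an event history
#'
#' @param events List of event lists (see [read_event_history()]).
#' @param tree Species tree (`phylo`).
#' @param wgd_tags Named character vector, tag -> branch label.
#' @param root_repertoire data.frame with `name`, `subtype`, `status`.
#' @return An `event_history`.
#' @export
event_history <- function(events, tree, wgd_tags = character(),
                          root_repertoire = NULL) {
  kinds <- c("wgd", "local_duplication", "loss", "pseudogenization")
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (is.null(ev$branch) || !has_label(tree, ev$branch))
      stop("event ", i, " references branch absent from the tree: ",
           ev$branch %||% "<missing>", call. = FALSE)
    if (is.null(ev$kind) || !ev$kind %in% kinds)
      stop("event ", i, " has unknown kind: ", ev$kind %||% "<missing>",
           call. = FALSE)
    if (ev$kind == "wgd" && is.null(ev$tag))
      stop("event ", i, " (wgd) is missing its tag", call. = FALSE)
    if (ev$kind == "local_duplication") {
      copies <- ev$copies %||% 1L
      if (copies < 1)
        stop("event ", i, " (local_duplication) has copies < 1",
             call. = FALSE)
      events[[i]]$copies <- as.integer(copies)
    }
    if (ev$kind %in% c("loss", "pseudogenization") && is.null(ev$target))
      stop("event ", i, " (", ev$kind, ") is missing its target",
           call. = FALSE)
  }
  if (length(wgd_tags)) {
    bad <- !vapply(wgd_tags, has_label, logical(1), tree = tree)
    if (any(bad))
      stop("wgd tag(s) on unknown branch: ",
           paste(wgd_tags[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(events = events, wgd_tags = wgd_tags,
                 root_repertoire = root_repertoire),
            class = "event_history")
}

#' Write an event history to JSON
#' @param history An `event_history`.
#' @param path Output path.
#' @export
write_event_history <- function(history, path) {
  rr <- history$root_repertoire
  doc <- list(
    wgd_tags = as.list(history$wgd_tags),
    root_repertoire = lapply(seq_len(nrow(rr)), function(i)
      list(name = rr$name[i], subtype = rr$subtype[i], status = rr$status[i])),
    events = history$events)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.event_history <- function(x, ...) {
  kinds <- vapply(x$events, function(e) e$kind, character(1))
  cat("Event history:", length(x$events), "events (",
      paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
            collapse = ", "), ")\n")
  if (length(x$wgd_tags))
    cat("WGD rounds:", paste(names(x$wgd_tags), "on", x$wgd_tags,
                             collapse = "; "), "\n")
  invisible(x)
}
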