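#' Read a presence/absence matrix
#'
#' The matrix records the state of each gene subtype (row) in each species
#' (column). File cells use the compact tokens `1` (present), `P`
#' (pseudogene), `0` (absent) and `?` (unknown); internally the long state
#' names are used. Pseudogene cells count as "lineage present" for all
#' gain/loss reconstruction, because a recognizable pseudogene proves the
#' lineage persisted.
#'
#' @param path TSV path; first column holds row (subtype) labels, header
#'   holds species names.
#' @param tree Optional species tree (`phylo`); when given, every column
#'   species must be a leaf of the tree.
#' @return Character matrix of class `presence_matrix` with values in
#'   `present`, `pseudogene`, `absent`, `unknown`.
#' @export
read_presence_matrix <- function(path, tree = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty presence matrix: ", path, call. = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  presence_matrix(m, tree = tree)
}

#' Validate a presence/absence matrix
#'
#' @param m Character matrix with subtype rownames and species colnames;
#'   cells may use either the compact (`1/P/0/?`) or long state names.
#' @param tree Optional species tree used to validate column names.
#' @return A validated `presence_matrix`.
#' @export
presence_matrix <- function(m, tree = NULL) {
  map <- c("1" = "present", "P" = "pseudogene", "0" = "absent",
           "?" = "unknown", present = "present", pseudogene = "pseudogene",
           absent = "absent", unknown = "unknown")
  bad <- !m %in% names(map)
  if (any(bad))
    stop("unknown state token(s): ", paste(unique(m[bad]), collapse = ", "),
         call. = FALSE)
  out <- matrix(unname(map[m]), nrow = nrow(m), dimnames = dimnames(m))
  if (is.null(rownames(out)) || is.null(colnames(out)))
    stop("presence matrix needs subtype rownames and species colnames",
         call. = FALSE)
  if (!is.null(tree)) {
    missing <- setdiff(colnames(out), tree$tip.label)
    if (length(missing))
      stop("species not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  all_absent <- apply(out == "absent", 1, all)
  if (any(all_absent))
    stop("row(s) with no non-absent cell: ",
         paste(rownames(out)[all_absent], collapse = ", "), call. = FALSE)
  structure(out, class = c("presence_matrix", class(matrix())))
}

#' Write a presence matrix using the compact file tokens
#' @param m A `presence_matrix`.
#' @param path Output TSV path.
#' @export
write_presence_matrix <- function(m, path) {
  rev_map <- c(present = "1", pseudogene = "P", absent = "0", unknown = "?")
  out <- matrix(rev_map[m], nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(subtype = rownames(out), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
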