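#' Packaged vertebrate TRPV fixtures
#'
#' The package ships a worked example: the evolution of the vertebrate
#' TRPV ion-channel family across 25 species spanning cyclostomes,
#' chondrichthyans, actinopterygians and sarcopterygians. Three files are
#' provided under `inst/extdata`: a rooted binary species tree with named
#' clades (soft polytomies resolved to a documented default backbone), a
#' subtype-by-species presence/absence matrix, and an event history — the
#' machine-readable evolutionary scenario with the two basal vertebrate
#' WGD rounds (1R/2R) on the vertebrate stem, the teleost round (3R) on
#' the teleost stem and the salmonid round (4R) on the Atlantic salmon
#' branch, plus the lineage-specific local duplications, losses and
#' pseudogenizations needed to reproduce each species' repertoire.
#'
#' The lamprey TRPV1 cell is `unknown` in the matrix (its absence may be
#' an assembly gap) while the history encodes an explicit cyclostome loss;
#' [diff_vs_observed()] treats unknown-vs-anything as a match, so the two
#' encodings are consistent by construction.
#'
#' @return `trpv_species_tree()` a `phylo`; `trpv_presence_matrix()` a
#'   `presence_matrix`; `trpv_event_history()` an `event_history`.
#' @name trpv_fixtures
NULL

.trpv_file <- function(name) {
  path <- system.file("extdata", name, package = "ohnologr")
  if (!nzchar(path)) stop("fixture not found: ", name, call. = FALSE)
  path
}

#' @rdname trpv_fixtures
#' @export
trpv_species_tree <- function() {
  parse_newick(paste(readLines(.trpv_file("trpv_species_tree.nwk")),
                     collapse = ""))
}

#' @rdname trpv_fixtures
#' @export
trpv_presence_matrix <- function() {
  read_presence_matrix(.trpv_file("trpv_presence_matrix.tsv"),
                       tree = trpv_species_tree())
}

#' @rdname trpv_fixtures
#' @export
trpv_event_history <- function() {
  read_event_history(.trpv_file("trpv_event_history.json"),
                     tree = trpv_species_tree())
}
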