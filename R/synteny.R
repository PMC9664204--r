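#' Synteny/paralogon analysis parameters
#'
#' Defaults follow the standard desk procedure for WGD-era paralogon
#' screens: a 10 Mb neighbor window on either side of the focal gene,
#' a two-member floor for candidate neighbor families, an extended search
#' flag for families of genome-wide size 3-4 (the sizes compatible with a
#' 2R quartet), a two-shared-family floor for joining regions, and a
#' four-region cap (the 2R expectation; raise to 8 or 16 for post-3R or
#' post-4R genomes).
#'
#' @param window_radius Window half-width in bp.
#' @param min_family_members Minimum genome-wide family size to select.
#' @param include_family_sizes Genome-wide sizes flagged "extended-search"
#'   (also the effective cap on selected family size).
#' @param min_shared_families_per_region_pair Minimum families a candidate
#'   region must share with an already accepted region.
#' @param max_regions Maximum regions per paralogon.
#' @return A `synteny_config` list.
#' @export
synteny_config <- function(window_radius = 10e6,
                           min_family_members = 2L,
                           include_family_sizes = 3:4,
                           min_shared_families_per_region_pair = 2L,
                           max_regions = 4L) {
  stopifnot(window_radius > 0, min_family_members >= 1,
            min_shared_families_per_region_pair >= 1, max_regions >= 1)
  structure(list(window_radius = window_radius,
                 min_family_members = as.integer(min_family_members),
                 include_family_sizes = as.integer(include_family_sizes),
                 min_shared_families_per_region_pair =
                   as.integer(min_shared_families_per_region_pair),
                 max_regions = as.integer(max_regions)),
            class = "synteny_config")
}

#' Extract the neighbor window around a focal gene
#'
#' The window spans `[focal_start - R, focal_end + R)` on the focal gene's
#' chromosome, clipped at zero; members are all genes overlapping the
#' window (half-open interval overlap), in position order.
#'
#' @param table A [gene_table()].
#' @param focal_gene_id Gene identifier of the focal gene.
#' @param config A [synteny_config()].
#' @return A `neighbor_window` list: `focal` (the gene row), `chromosome`,
#'   `start`, `end`, `members` (data.frame).
#' @export
extract_window <- function(table, focal_gene_id, config = synteny_config()) {
  i <- which(table$gene_id == focal_gene_id)
  if (!length(i))
    stop("focal gene not in table: ", focal_gene_id, call. = FALSE)
  focal <- table[i, ]
  w_start <- max(0, focal$start - config$window_radius)
  w_end <- focal$end + config$window_radius
  on_chr <- table[table$chromosome == focal$chromosome, , drop = FALSE]
  members <- on_chr[on_chr$start < w_end & on_chr$end > w_start, ,
                    drop = FALSE]
  members <- members[order(members$start), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(focal = focal, chromosome = focal$chromosome,
                 start = w_start, end = w_end, members = members),
            class = "neighbor_window")
}

#' Select candidate neighbor families from extracted windows
#'
#' A family qualifies when it has at least one member inside some window
#' and a genome-wide copy number of at least `min_family_members` and at
#' most the top of `include_family_sizes` (larger families are incompatible
#' with the quartet expectation and are dropped). Families whose
#' genome-wide size falls inside `include_family_sizes` are flagged as
#' found by the extended (genome-wide) search.
#'
#' @param windows List of `neighbor_window` objects from one genome.
#' @param genome The full [gene_table()] of that genome.
#' @param config A [synteny_config()].
#' @return data.frame `family_id`, `n_genome`, `extended`, `selected`.
#' @export
select_candidate_families <- function(windows, genome,
                                      config = synteny_config()) {
  in_window <- unique(unlist(lapply(windows, function(w) w$members$family_id)))
  sizes <- table(genome$family_id)
  fam <- names(sizes)
  n <- as.integer(sizes)
  cap <- max(config$include_family_sizes)
  out <- data.frame(family_id = fam, n_genome = n,
                    extended = n %in% config$include_family_sizes,
                    selected = fam %in% in_window &
                      n >= config$min_family_members & n <= cap)
  out[out$family_id %in% in_window, , drop = FALSE]
}

#' Detect a paralogon by greedy region assembly
#'
#' A region is a whole chromosome restricted to the convex hull of its
#' member genes; gene order within a region is deliberately ignored
#' (paralogon evidence is family co-occurrence, not collinearity).
#' Starting from the seed regions, the chromosome sharing the most
#' candidate families with the current region set is added repeatedly,
#' subject to sharing at least `min_shared_families_per_region_pair`
#' families with some accepted region, until `max_regions` regions are
#' assembled or no admissible chromosome remains. Ties break toward
#' higher shared count, then larger member count, then lexicographically
#' smaller chromosome name.
#'
#' @param genome A [gene_table()].
#' @param seed_regions Character vector of seed chromosome names.
#' @param families Character vector of candidate family ids (e.g. the
#'   selected families of [select_candidate_families()]).
#' @param config A [synteny_config()].
#' @return A `paralogon_report`: `regions` (data.frame chromosome/start/end),
#'   `family_membership` (family x region count matrix),
#'   `multiplicity_histogram` (families spanning 4, 3, 2, 1 regions),
#'   `genes_retained`.
#' @export
detect_paralogon <- function(genome, seed_regions, families,
                             config = synteny_config()) {
  if (!length(seed_regions))
    stop("no seed regions supplied", call. = FALSE)
  g <- genome[genome$family_id %in% families, , drop = FALSE]
  missing_seed <- setdiff(seed_regions, unique(genome$chromosome))
  if (length(missing_seed))
    stop("seed region(s) not in genome: ",
         paste(missing_seed, collapse = ", "), call. = FALSE)
  fam_by_chr <- split(g$family_id, g$chromosome)
  current <- unique(seed_regions)
  candidates <- setdiff(names(fam_by_chr), current)
  while (length(current) < config$max_regions && length(candidates)) {
    cur_fams <- lapply(current, function(ch)
      unique(fam_by_chr[[ch]] %||% character(0)))
    score <- vapply(candidates, function(ch) {
      fams <- unique(fam_by_chr[[ch]])
      length(intersect(fams, unique(unlist(cur_fams))))
    }, integer(1))
    pair_ok <- vapply(candidates, function(ch) {
      fams <- unique(fam_by_chr[[ch]])
      any(vapply(cur_fams, function(cf)
        length(intersect(fams, cf)) >=
          config$min_shared_families_per_region_pair, logical(1)))
    }, logical(1))
    admissible <- candidates[pair_ok & score > 0]
    if (!length(admissible)) break
    sc <- score[admissible]
    size <- vapply(admissible, function(ch)
      length(fam_by_chr[[ch]]), integer(1))
    ord <- order(-sc, -size, admissible)
    pick <- admissible[ord[1]]
    current <- c(current, pick)
    candidates <- setdiff(candidates, pick)
  }
  .paralogon_report(g, current)
}

.paralogon_report <- function(g, regions) {
  regions <- unique(regions)
  fams <- sort(unique(g$family_id[g$chromosome %in% regions]))
  membership <- matrix(0L, nrow = length(fams), ncol = length(regions),
                       dimnames = list(fams, regions))
  for (ch in regions) {
    tab <- table(g$family_id[g$chromosome == ch])
    membership[names(tab), ch] <- as.integer(tab)
  }
  reg_df <- do.call(rbind, lapply(regions, function(ch) {
    rows <- g[g$chromosome == ch, , drop = FALSE]
    if (!nrow(rows))
      data.frame(chromosome = ch, start = NA_real_, end = NA_real_)
    else
      data.frame(chromosome = ch, start = min(rows$start),
                 end = max(rows$end))
  }))
  spans <- rowSums(membership > 0)
  hist <- vapply(c("4" = 4, "3" = 3, "2" = 2, "1" = 1),
                 function(k) sum(spans == k), integer(1))
  structure(list(regions = reg_df, family_membership = membership,
                 multiplicity_histogram = hist,
                 genes_retained = sum(membership)),
            class = "paralogon_report")
}

#' Total genes retained in a paralogon report
#'
#' @param report A `paralogon_report`.
#' @return Integer: total member genes across regions and families.
#' @export
genes_retained <- function(report) {
  sum(report$family_membership)
}

#' Cross-species conserved-synteny comparison of a focal family
#'
#' For each species the focal family's status is derived from its gene
#' table (`missing`, `pseudogene`, `present` for one coding copy,
#' `duplicated` for several) and each neighbor family's genome-wide copy
#' number is reduced to `missing`/`present`/`duplicated`. When the focal
#' gene is missing and the two expected flanking families are supplied,
#' the flank-contiguity flag reports whether members of the two flanks sit
#' in adjacent positions on some chromosome — the signature of a clean
#' gene loss rather than an assembly gap. Species with no chromosome
#' carrying any neighbor family member are reported `unplaceable`.
#'
#' @param tables Named list of [gene_table()] objects (name = species).
#' @param focal_family Family id of the focal gene family.
#' @param neighbor_families Character vector of neighbor family ids.
#' @param flank_families Optional length-2 character vector of the families
#'   expected to flank the focal gene.
#' @return data.frame with one row per species: `species`, `focal_status`,
#'   one `nb_<family>` column per neighbor family, `flank_contiguous`,
#'   `unplaceable`.
#' @export
compare_synteny <- function(tables, focal_family, neighbor_families,
                            flank_families = NULL) {
  status_of <- function(n_coding, n_pseudo) {
    if (n_coding >= 2) "duplicated"
    else if (n_coding == 1) "present"
    else if (n_pseudo >= 1) "pseudogene"
    else "missing"
  }
  rows <- lapply(names(tables), function(sp) {
    tb <- tables[[sp]]
    focal_rows <- tb[tb$family_id == focal_family, , drop = FALSE]
    focal_status <- status_of(sum(focal_rows$status == "coding"),
                              sum(focal_rows$status == "pseudogene"))
    nb_status <- vapply(neighbor_families, function(f) {
      n <- sum(tb$family_id == f)
      if (n >= 2) "duplicated" else if (n == 1) "present" else "missing"
    }, character(1))
    unplaceable <- !any(tb$family_id %in% neighbor_families)
    flank <- NA
    if (!is.null(flank_families) && focal_status == "missing" &&
        !unplaceable) {
      flank <- FALSE
      for (ch in unique(tb$chromosome)) {
        rows_ch <- tb[tb$chromosome == ch, , drop = FALSE]
        fams <- rows_ch$family_id[order(rows_ch$start)]
        if (length(fams) < 2) next
        adjacent <- (fams[-length(fams)] == flank_families[1] &
                       fams[-1] == flank_families[2]) |
                    (fams[-length(fams)] == flank_families[2] &
                       fams[-1] == flank_families[1])
        if (any(adjacent)) { flank <- TRUE; break }
      }
    }
    df <- data.frame(species = sp, focal_status = focal_status,
                     t(nb_status), flank_contiguous = flank,
                     unplaceable = unplaceable, check.names = FALSE)
    names(df)[3:(2 + length(neighbor_families))] <-
      paste0("nb_", neighbor_families)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.paralogon_report <- function(x, ...) {
  cat("Paralogon:", nrow(x$regions), "region(s),",
      nrow(x$family_membership), "families,",
      x$genes_retained, "genes retained\n")
  cat("  multiplicity histogram (families in k regions):\n")
  print(x$multiplicity_histogram)
  invisible(x)
}
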