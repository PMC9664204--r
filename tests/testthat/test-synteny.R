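mk_table <- function(df, species = "sp") gene_table(df, species)

linear_genome <- function(families, chrom = "chr1", gap = 1e6,
                          span = 1e4, status = "coding") {
  n <- length(families)
  start <- (seq_len(n) - 1) * gap
  data.frame(gene_id = paste0(chrom, "_g", seq_len(n)),
             family_id = families, chromosome = chrom,
             start = start, end = start + span, strand = "+",
             status = status)
}

test_that("window extraction does the stated interval arithmetic", {
  tb <- mk_table(data.frame(
    gene_id = c("far", "focal", "near"), family_id = c("F1", "F2", "F3"),
    chromosome = "chr1", start = c(5e6, 20e6, 29e6),
    end = c(5.01e6, 20.01e6, 29.01e6), strand = "+", status = "coding"))
  w <- extract_window(tb, "focal")
  expect_equal(w$start, 10e6)
  expect_equal(w$end, 30.01e6)
  expect_setequal(w$members$gene_id, c("focal", "near"))

  tb2 <- mk_table(data.frame(
    gene_id = "edge", family_id = "F1", chromosome = "chr1",
    start = 2e6, end = 2.005e6, strand = "+", status = "coding"))
  w2 <- extract_window(tb2, "edge")
  expect_equal(w2$start, 0)
  expect_equal(w2$end, 12.005e6)

  expect_error(extract_window(tb, "nope"), "focal gene")
})

test_that("window membership equals a brute-force overlap scan", {
  set.seed(9)
  for (i in 1:20) {
    n <- 60
    df <- data.frame(
      gene_id = paste0("g", 1:n), family_id = paste0("F", sample(10, n, TRUE)),
      chromosome = sample(c("chr1", "chr2"), n, TRUE),
      start = sample.int(5e7, n), strand = "+", status = "coding")
    df$end <- df$start + sample.int(5e4, n)
    tb <- mk_table(df)
    focal <- sample(tb$gene_id, 1)
    cfg <- synteny_config(window_radius = 5e6)
    w <- extract_window(tb, focal, cfg)
    frow <- tb[tb$gene_id == focal, ]
    ws <- max(0, frow$start - 5e6); we <- frow$end + 5e6
    oracle <- tb$gene_id[tb$chromosome == frow$chromosome &
                           tb$start < we & tb$end > ws]
    expect_setequal(w$members$gene_id, oracle)
  }
})

test_that("candidate family selection applies floor, cap and extended flag", {
  sizes <- c(F1 = 1, F2 = 2, F3 = 3, F4 = 4, F5 = 5)
  # first member of each family sits in the window chromosome, the rest
  # elsewhere, so genome-wide sizes are exactly 1..5
  probe <- linear_genome(names(sizes), chrom = "chrW")
  probe$gene_id <- paste0("w", seq_len(nrow(probe)))
  rest <- do.call(rbind, lapply(names(sizes), function(f) {
    k <- sizes[[f]] - 1L
    if (k == 0L) return(NULL)
    linear_genome(rep(f, k), chrom = paste0("chr_", f))
  }))
  genome <- mk_table(rbind(rest, probe))
  w <- extract_window(genome, "w1")
  sel <- select_candidate_families(list(w), genome)
  kept <- sel$family_id[sel$selected]
  expect_setequal(kept, c("F2", "F3", "F4"))
  expect_setequal(sel$family_id[sel$extended & sel$selected], c("F3", "F4"))
  # empty window -> empty selection
  empty <- list(list(members = data.frame(family_id = character())))
  sel0 <- select_candidate_families(empty, genome)
  expect_equal(nrow(sel0), 0L)
})

test_that("lossless 2R simulation yields a perfect quartet paralogon", {
  tr <- parse_newick("(A,B)R;")
  cfg <- sim_config(tr, wgd_branches = c("R", "R"),
                    ancestral_chromosomes = 1, genes_per_chromosome = 8,
                    seed = 42)
  sim <- simulate_genomes(cfg)
  tb <- sim$tables[["A"]]
  report <- detect_paralogon(tb, "chr1", unique(tb$family_id))
  expect_equal(nrow(report$regions), 4L)
  expect_equal(unname(report$multiplicity_histogram["4"]), 8L)
  expect_equal(genes_retained(report), 32L)
  truth <- truth_paralogon(sim, "A")[["chr1"]]
  expect_equal(report$multiplicity_histogram, truth$multiplicity_histogram)
})

test_that("a genome with no duplicated family keeps only the seed regions", {
  genome <- mk_table(rbind(linear_genome(paste0("F", 1:5), "chr1"),
                           linear_genome(paste0("G", 1:5), "chr2")))
  report <- detect_paralogon(genome, "chr1", paste0("F", 1:5))
  expect_equal(report$regions$chromosome, "chr1")
  expect_equal(sum(report$multiplicity_histogram[c("4", "3", "2")]), 0L)
  expect_error(detect_paralogon(genome, character(), "F1"), "seed")
})

test_that("constructed quartet/triplet toy reproduces the printed histogram", {
  # 11 neighbor families: 3 span all four regions, 8 span three
  fams <- paste0("F", 1:11)
  spans <- c(rep(4, 3), rep(3, 8))
  regions <- paste0("chr", 1:4)
  rows <- do.call(rbind, lapply(seq_along(fams), function(i) {
    on <- regions[seq_len(spans[i])]
    do.call(rbind, lapply(on, function(ch)
      data.frame(family_id = fams[i], chromosome = ch)))
  }))
  rows$gene_id <- paste0("g", seq_len(nrow(rows)))
  rows$start <- ave(seq_len(nrow(rows)), rows$chromosome,
                    FUN = seq_along) * 1e6
  rows$end <- rows$start + 1e4
  rows$strand <- "+"; rows$status <- "coding"
  genome <- mk_table(rows)
  report <- detect_paralogon(genome, "chr1", fams)
  expect_equal(nrow(report$regions), 4L)
  expect_equal(unname(report$multiplicity_histogram[c("4", "3", "2")]),
               c(3L, 8L, 0L))
  # histogram sums to the number of families in the report
  expect_equal(sum(report$multiplicity_histogram),
               nrow(report$family_membership))
  expect_equal(genes_retained(report), 3L * 4L + 8L * 3L)
})

test_that("a 3-quartet/7-triplet/1-doublet toy retains 35 genes", {
  fams <- paste0("F", 1:11)
  spans <- c(rep(4, 3), rep(3, 7), 2)
  regions <- paste0("chr", 1:4)
  rows <- do.call(rbind, lapply(seq_along(fams), function(i) {
    on <- regions[seq_len(spans[i])]
    do.call(rbind, lapply(on, function(ch)
      data.frame(family_id = fams[i], chromosome = ch)))
  }))
  rows$gene_id <- paste0("g", seq_len(nrow(rows)))
  rows$start <- ave(seq_len(nrow(rows)), rows$chromosome,
                    FUN = seq_along) * 1e6
  rows$end <- rows$start + 1e4
  rows$strand <- "+"; rows$status <- "coding"
  report <- detect_paralogon(mk_table(rows), "chr1", fams)
  expect_equal(genes_retained(report), 35L)
})

test_that("genes_retained equals a brute-force incidence sum", {
  set.seed(5)
  for (i in 1:10) {
    n <- 50
    df <- data.frame(
      gene_id = paste0("g", 1:n),
      family_id = paste0("F", sample(8, n, TRUE)),
      chromosome = paste0("chr", sample(4, n, TRUE)),
      start = sample.int(1e7, n), strand = "+", status = "coding")
    df$end <- df$start + 100
    genome <- mk_table(df)
    fams <- paste0("F", 1:8)
    report <- detect_paralogon(genome, "chr1", fams,
                               synteny_config(min_shared_families_per_region_pair = 1))
    oracle <- sum(df$family_id %in% rownames(report$family_membership) &
                    df$chromosome %in% report$regions$chromosome)
    expect_equal(genes_retained(report), oracle)
  }
})

test_that("reports are equivariant under chromosome renaming", {
  tr <- parse_newick("(A,B)R;")
  cfg <- sim_config(tr, wgd_branches = c("R", "R"),
                    ancestral_chromosomes = 1, genes_per_chromosome = 6,
                    wgd_retention_prob = 0.8, seed = 17)
  sim <- simulate_genomes(cfg)
  tb <- sim$tables[["A"]]
  fams <- unique(tb$family_id)
  r1 <- detect_paralogon(tb, "chr1", fams)
  perm <- stats::setNames(paste0("scaffold_", seq_along(unique(tb$chromosome))),
                          sort(unique(tb$chromosome)))
  tb2 <- as.data.frame(tb)
  tb2$chromosome <- unname(perm[tb2$chromosome])
  tb2 <- mk_table(tb2)
  r2 <- detect_paralogon(tb2, unname(perm["chr1"]), fams)
  expect_equal(unname(r1$multiplicity_histogram),
               unname(r2$multiplicity_histogram))
  expect_equal(genes_retained(r1), genes_retained(r2))
})

test_that("cross-species synteny comparison captures the published patterns", {
  # focal gene lost but expected flanks adjacent -> clean loss signature
  sp_with <- mk_table(linear_genome(c("SERPINI", "TRPV7", "UNCH", "TRPV8",
                                      "GOLIM4")), "keeper")
  sp_without <- mk_table(linear_genome(c("SERPINI", "UNCH", "GOLIM4")),
                         "loser")
  comp <- compare_synteny(list(keeper = sp_with, loser = sp_without),
                          focal_family = "TRPV7",
                          neighbor_families = c("SERPINI", "UNCH", "GOLIM4"),
                          flank_families = c("SERPINI", "UNCH"))
  expect_equal(comp$focal_status[comp$species == "keeper"], "present")
  expect_equal(comp$focal_status[comp$species == "loser"], "missing")
  expect_true(comp$flank_contiguous[comp$species == "loser"])

  # duplicated neighbors in a post-WGD genome vs single copies in a
  # non-duplicated one
  teleost <- mk_table(rbind(
    linear_genome(c("TRPV1", "MYOC", "FAM222B", "FLOT2", "SHPK"), "chrA"),
    linear_genome(c("MYOC", "FAM222B", "FLOT2"), "chrB")), "teleost")
  gar <- mk_table(linear_genome(c("TRPV1", "MYOC", "FAM222B", "FLOT2",
                                  "SHPK")), "gar")
  comp2 <- compare_synteny(list(teleost = teleost, gar = gar),
                           focal_family = "TRPV1",
                           neighbor_families = c("MYOC", "FAM222B", "FLOT2"))
  expect_true(all(comp2[comp2$species == "teleost",
                        c("nb_MYOC", "nb_FAM222B", "nb_FLOT2")] ==
                    "duplicated"))
  expect_true(all(comp2[comp2$species == "gar",
                        c("nb_MYOC", "nb_FAM222B", "nb_FLOT2")] == "present"))

  # identical tables -> everything present; species with no neighbor
  # families is unplaceable, not an error
  empty <- mk_table(linear_genome("OTHER"), "empty")
  comp3 <- compare_synteny(list(a = gar, b = gar, empty = empty),
                           focal_family = "TRPV1",
                           neighbor_families = c("MYOC", "FLOT2"))
  expect_true(all(comp3$focal_status[comp3$species %in% c("a", "b")] ==
                    "present"))
  expect_true(comp3$unplaceable[comp3$species == "empty"])

  # pseudogenized focal copy is reported as such
  ps <- linear_genome(c("TRPV1", "MYOC"))
  ps$status[1] <- "pseudogene"
  comp4 <- compare_synteny(list(x = mk_table(ps, "x")), "TRPV1", "MYOC")
  expect_equal(comp4$focal_status, "pseudogene")
})
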