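test_that("textbook LCA reconciliation cases", {
  sp <- parse_newick("(A,B)R;")
  gt <- parse_newick("((A|g1,B|g2),(A|g3,B|g4));")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$n_duplications, 1L)
  expect_equal(rec$n_losses, 0L)
  expect_equal(unname(rec$duplication_assignments), "R")

  sp2 <- parse_newick("((A,B)AB,C)R;")
  gt2 <- parse_newick("((A|g1,B|g2),C|g3);")
  rec2 <- lca_reconcile(gt2, sp2)
  expect_equal(rec2$n_duplications, 0L)
  expect_equal(rec2$n_losses, 0L)

  # incongruent one-gene-per-species tree implies duplication + losses
  gt3 <- parse_newick("((A|g1,C|g3),B|g2);")
  rec3 <- lca_reconcile(gt3, sp2)
  expect_gt(rec3$n_duplications + rec3$n_losses, 0L)
})

test_that("duplication/loss counts are invariant under child reordering", {
  sp <- parse_newick("((A,B)AB,(C,D)CD)R;")
  gt <- parse_newick("(((A|g1,B|g2),(A|g3,C|g4)),D|g5);")
  gt_swapped <- parse_newick("(D|g5,((A|g3,C|g4),(B|g2,A|g1)));")
  r1 <- lca_reconcile(gt, sp)
  r2 <- lca_reconcile(gt_swapped, sp)
  expect_equal(r1$n_duplications, r2$n_duplications)
  expect_equal(r1$n_losses, r2$n_losses)
  expect_equal(sort(unname(r1$duplication_assignments)),
               sort(unname(r2$duplication_assignments)))
})

test_that("unrooted or unknown-species gene trees are rejected", {
  sp <- parse_newick("((A,B)AB,C)R;")
  unrooted <- ape::unroot(parse_newick("((A|g1,B|g2),(C|g3,C|g4));"))
  expect_error(lca_reconcile(unrooted, sp), "rooted|binary")
  gt <- parse_newick("((A|g1,B|g2),Z|g3);")
  expect_error(lca_reconcile(gt, sp), "absent from species tree")
})

test_that("losses are counted along skipped species-tree edges", {
  sp <- parse_newick("((A,B)AB,C)R;")
  # one gene in A and C only: the AB speciation is skipped -> 1 loss in B
  gt <- parse_newick("(A|g1,C|g2);")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$n_duplications, 0L)
  expect_equal(rec$n_losses, 1L)
})

test_that("no-loss simulations are recovered exactly from true gene trees", {
  tr <- rand_labelled_tree(8, seed = 5)
  cfg <- sim_config(tr, wgd_branches = c(all_labels(tr)[9], "s3"),
                    wgd_tags = c("2R", "T3"),
                    ancestral_chromosomes = 2, genes_per_chromosome = 5,
                    wgd_retention_prob = 1, local_dup_rate = 1, seed = 99)
  sim <- simulate_genomes(cfg)
  for (fam in names(sim$gene_trees)) {
    gt <- sim$gene_trees[[fam]]
    if (is.null(gt)) next
    rec <- lca_reconcile(gt, tr)
    ev <- sim$truth$events
    true_dups <- ev[ev$family_id == fam &
                      ev$kind %in% c("wgd", "local_duplication"), ]
    expect_equal(rec$n_duplications, nrow(true_dups))
    expect_equal(sort(unname(rec$duplication_assignments)),
                 sort(true_dups$branch))
    expect_equal(rec$n_losses, 0L)
  }
})

test_that("mixed-regime recovery matches the pedigree-walk oracle", {
  tr <- rand_labelled_tree(8, seed = 21)
  root_lab <- all_labels(tr)[9]
  cfg <- sim_config(tr, wgd_branches = root_lab, wgd_tags = "2R",
                    ancestral_chromosomes = 2, genes_per_chromosome = 5,
                    wgd_retention_prob = 0.7, local_dup_rate = 1,
                    loss_rate = 1.5, pseudogenization_prob = 0.2,
                    rearrangement_rate = 0.5, seed = 123)
  sim <- simulate_genomes(cfg)
  checked <- 0L
  for (fam in names(sim$gene_trees)) {
    gt <- sim$gene_trees[[fam]]
    if (is.null(gt)) next
    rec <- lca_reconcile(gt, tr)
    oracle <- oracle_observable_dups(sim, fam, tr)
    expect_equal(rec$n_duplications, length(oracle$placements))
    expect_equal(sort(unname(rec$duplication_assignments)),
                 sort(oracle$placements))
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("duplications are classified into the right WGD windows", {
  tree <- trpv_species_tree()
  tags <- trpv_event_history()$wgd_tags
  # teleost 3R ohnolog pair: the two copies' split spans all teleosts
  gt <- parse_newick(paste0("((european_eel|a,medaka|a),",
                            "(european_eel|b,medaka|b));"))
  rec <- lca_reconcile(gt, tree)
  expect_equal(unname(classify_duplications(rec, tags)), "WGD:3R")
  # salmonid 4R pair on a terminal branch
  gt4 <- parse_newick("(atlantic_salmon|x,atlantic_salmon|y);")
  rec4 <- lca_reconcile(gt4, tree)
  expect_equal(unname(classify_duplications(rec4, tags)), "WGD:4R")
  # basal rounds share one stem branch -> joint 1R/2R window label
  gt12 <- parse_newick("((sea_lamprey|c,human|c),(sea_lamprey|d,human|d));")
  rec12 <- lca_reconcile(gt12, tree)
  expect_equal(unname(classify_duplications(rec12, tags)), "WGD:1R/2R")
  # untagged terminal branch -> lineage specific
  gth <- parse_newick("(human|e,human|f);")
  rech <- lca_reconcile(gth, tree)
  expect_equal(unname(classify_duplications(rech, tags)),
               "lineage_specific")
  # untagged internal branch -> local duplication outside any window
  gtg <- parse_newick(paste0("((spotted_catshark|v1,human|v1),",
                             "(spotted_catshark|v3,human|v3));"))
  recg <- lca_reconcile(gtg, tree)
  expect_equal(unname(classify_duplications(recg, tags)),
               "local_prewindow")
})

test_that("gain constraints are inferred from two-subtype gene trees", {
  tree <- trpv_species_tree()
  gt <- parse_newick(paste0(
    "((spotted_catshark|v9,thorny_skate|v9),",
    "(spotted_catshark|v3,(coelacanth|v3,human|v3)));"))
  rec <- lca_reconcile(gt, tree)
  subtypes <- c("spotted_catshark|v9" = "TRPV9", "thorny_skate|v9" = "TRPV9",
                "spotted_catshark|v3" = "TRPV3", "coelacanth|v3" = "TRPV3",
                "human|v3" = "TRPV3")
  expect_equal(infer_gain_constraint(rec, subtypes), "Gnathostomata")

  # subtypes confined to sister species -> their MRCA
  sp <- parse_newick("((A,B)AB,C)R;")
  gt2 <- parse_newick("(A|x,B|y);")
  rec2 <- lca_reconcile(gt2, sp)
  expect_equal(infer_gain_constraint(rec2, c("A|x" = "S1", "B|y" = "S2")),
               "AB")
  expect_error(infer_gain_constraint(rec2, c("A|x" = "S1", "B|y" = "S1")),
               "single subtype")
})

test_that("simulated duplication node recovers the truth for constraints", {
  tr <- rand_labelled_tree(6, seed = 77)
  dup_branch <- all_labels(tr)[8]    # an internal node below the root
  cfg <- sim_config(tr, wgd_branches = dup_branch, wgd_tags = "W",
                    ancestral_chromosomes = 1, genes_per_chromosome = 2,
                    seed = 4)
  sim <- simulate_genomes(cfg)
  gt <- sim$gene_trees[["F1"]]
  # restrict to the species that witnessed the WGD: their ohnolog pair's
  # split node is then the gene-tree root, as in a two-subtype family tree
  dup_node <- match(dup_branch, all_labels(tr))
  sp_under <- tr$tip.label[unlist(phangorn::Descendants(tr, dup_node,
                                                        "tips"))]
  keep <- gt$tip.label[sub("\\|.*$", "", gt$tip.label) %in% sp_under]
  gt_sub <- ape::keep.tip(gt, keep)
  rec <- lca_reconcile(gt_sub, tr)
  lin <- sub("^.*\\|F1_", "", gt_sub$tip.label)
  subtypes <- stats::setNames(ifelse(lin == lin[1], "s1", "s2"),
                              gt_sub$tip.label)
  # the two sides are the two ohnolog lineages created at the WGD
  expect_length(unique(lin), 2L)
  expect_equal(infer_gain_constraint(rec, subtypes), dup_branch)
})
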