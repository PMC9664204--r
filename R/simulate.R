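#' Configuration for the genome-evolution simulator
#'
#' The simulator evolves a genome of gene families along a rooted binary
#' species tree. Whole-genome duplications are placed on specific branches
#' (a branch is the label of its child node; the root label addresses the
#' root branch, so basal WGD rounds can predate the first split). Tandem
#' duplications, losses and rearrangements occur at per-branch Poisson
#' rates — fixture trees carry no calibrated branch lengths, so rates are
#' per branch, not per unit length — with uniformly chosen targets.
#'
#' Every ancestral gene founds its own family, so `n_families` must equal
#' `ancestral_chromosomes * genes_per_chromosome`.
#'
#' @param species_tree Rooted binary `phylo` (as from [parse_newick()]).
#' @param wgd_branches Character vector of branch labels carrying a WGD;
#'   repeat a label for multiple rounds on one branch.
#' @param wgd_tags Optional names for `wgd_branches` entries (e.g. `"2R"`);
#'   defaults to `WGD1`, `WGD2`, ...
#' @param ancestral_chromosomes Number of chromosomes in the root genome.
#' @param genes_per_chromosome Genes per ancestral chromosome.
#' @param n_families Total families; defaults to the product above.
#' @param gene_span Gene length in bp.
#' @param intergenic_gap Gap between consecutive genes in bp.
#' @param wgd_retention_prob Probability each WGD-created copy is retained.
#' @param local_dup_rate Expected tandem duplications per branch.
#' @param loss_rate Expected losses per branch.
#' @param pseudogenization_prob Probability a loss is instead a
#'   pseudogenization (the record is kept with status `pseudogene`).
#' @param rearrangement_rate Expected rearrangements (block cut-and-paste
#'   or in-place inversion) per branch.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_tree, wgd_branches = character(),
                       wgd_tags = NULL,
                       ancestral_chromosomes = 1L,
                       genes_per_chromosome = 5L,
                       n_families = ancestral_chromosomes * genes_per_chromosome,
                       gene_span = 10e3, intergenic_gap = 90e3,
                       wgd_retention_prob = 1, local_dup_rate = 0,
                       loss_rate = 0, pseudogenization_prob = 0,
                       rearrangement_rate = 0, seed = 1L) {
  if (!is_binary_rooted(species_tree))
    stop("simulator requires a rooted binary species tree", call. = FALSE)
  if (n_families != ancestral_chromosomes * genes_per_chromosome)
    stop("n_families must equal ancestral_chromosomes * genes_per_chromosome",
         call. = FALSE)
  probs <- c(wgd_retention_prob, pseudogenization_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(local_dup_rate, loss_rate, rearrangement_rate) < 0))
    stop("rates must be non-negative", call. = FALSE)
  bad <- wgd_branches[!vapply(wgd_branches, has_label, logical(1),
                              tree = species_tree)]
  if (length(bad))
    stop("wgd branch label(s) not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(wgd_tags)) wgd_tags <- paste0("WGD", seq_along(wgd_branches))
  structure(list(species_tree = species_tree, wgd_branches = wgd_branches,
                 wgd_tags = wgd_tags,
                 ancestral_chromosomes = as.integer(ancestral_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 n_families = as.integer(n_families),
                 gene_span = gene_span, intergenic_gap = intergenic_gap,
                 wgd_retention_prob = wgd_retention_prob,
                 local_dup_rate = local_dup_rate, loss_rate = loss_rate,
                 pseudogenization_prob = pseudogenization_prob,
                 rearrangement_rate = rearrangement_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genome evolution along a species tree
#'
#' Runs the process described in [sim_config()] and returns, per leaf
#' species, a sorted [gene_table()]; per family, the true gene tree
#' implied by the realized duplication/loss history (`NULL` for families
#' with fewer than two surviving gene copies); a presence matrix
#' summarizing extant status per family and species (extinct families are
#' dropped); and a truth log holding the realized per-branch events and
#' the gene pedigree (a forest: every extant gene traces to exactly one
#' ancestral gene).
#'
#' @param config A [sim_config()].
#' @return A `genome_sim` list: `tables`, `gene_trees`, `presence_matrix`,
#'   `truth` (list `events`, `pedigree`, `config`).
#' @export
simulate_genomes <- function(config) {
  set.seed(config$seed)
  tree <- config$species_tree

  state <- new.env(parent = emptyenv())
  state$next_lineage <- 1L
  state$events <- list()
  state$pedigree <- list()
  state$tables <- list()

  new_lineage <- function(parent, family, branch, anc_chrom) {
    id <- state$next_lineage
    state$next_lineage <- id + 1L
    state$pedigree[[length(state$pedigree) + 1L]] <- data.frame(
      lineage = id, parent = parent, family_id = family,
      origin_branch = branch, anc_chrom = anc_chrom)
    id
  }
  log_event <- function(branch, order, kind, family = NA_character_,
                        parent = NA_integer_, child = NA_integer_,
                        lineage = NA_integer_, tag = NA_character_) {
    state$events[[length(state$events) + 1L]] <- data.frame(
      branch = branch, order = order, kind = kind, family_id = family,
      parent = parent, child = child, lineage = lineage, tag = tag)
  }

  # ancestral genome: named list chromosome -> ordered gene data.frame
  genome <- list()
  for (ci in seq_len(config$ancestral_chromosomes)) {
    ch <- paste0("chr", ci)
    fams <- paste0("F", (ci - 1L) * config$genes_per_chromosome +
                     seq_len(config$genes_per_chromosome))
    lins <- vapply(fams, function(f)
      new_lineage(NA_integer_, f, "<root>", ch), integer(1))
    genome[[ch]] <- data.frame(
      lineage = unname(lins), family_id = fams,
      gid = paste0(fams, "_", unname(lins)),
      strand = "+", status = "coding", anc_chrom = ch)
  }

  wgd_rounds <- function(branch) which(config$wgd_branches == branch)

  apply_branch <- function(genome, branch) {
    order <- 0L
    nxt <- function() { order <<- order + 1L; order }
    all_genes <- function() do.call(rbind, lapply(names(genome), function(ch)
      cbind(genome[[ch]], chromosome = ch, row = seq_len(nrow(genome[[ch]])))))

    for (round_i in wgd_rounds(branch)) {
      tag <- config$wgd_tags[round_i]
      new_chrs <- list()
      for (ch in names(genome)) {
        df <- genome[[ch]]
        keep <- logical(nrow(df))
        new_rows <- df[0, ]
        for (r in seq_len(nrow(df))) {
          retained <- stats::runif(1) < config$wgd_retention_prob
          if (!retained) next
          keep[r] <- TRUE
          lin <- new_lineage(df$lineage[r], df$family_id[r], branch,
                             df$anc_chrom[r])
          log_event(branch, nxt(), "wgd", df$family_id[r],
                    parent = df$lineage[r], child = lin, tag = tag)
          new_rows <- rbind(new_rows, data.frame(
            lineage = lin, family_id = df$family_id[r],
            gid = paste0(df$family_id[r], "_", lin),
            strand = df$strand[r], status = df$status[r],
            anc_chrom = df$anc_chrom[r]))
        }
        if (nrow(new_rows))
          new_chrs[[paste0(ch, "_w", round_i)]] <- new_rows
      }
      genome <- c(genome, new_chrs)
    }

    n_dup <- stats::rpois(1, config$local_dup_rate)
    for (i in seq_len(n_dup)) {
      ag <- all_genes()
      ag <- ag[ag$status == "coding", , drop = FALSE]
      if (!nrow(ag)) break
      pick <- ag[sample(nrow(ag), 1L), ]
      lin <- new_lineage(pick$lineage, pick$family_id, branch,
                         pick$anc_chrom)
      log_event(branch, nxt(), "local_duplication", pick$family_id,
                parent = pick$lineage, child = lin)
      df <- genome[[pick$chromosome]]
      k <- sum(startsWith(df$gid, paste0(pick$gid, "_d"))) + 1L
      new_row <- data.frame(lineage = lin, family_id = pick$family_id,
                            gid = paste0(pick$gid, "_d", k),
                            strand = pick$strand, status = "coding",
                            anc_chrom = pick$anc_chrom)
      r <- pick$row
      genome[[pick$chromosome]] <-
        rbind(df[seq_len(r), , drop = FALSE], new_row,
              if (r < nrow(df)) df[(r + 1L):nrow(df), , drop = FALSE])
    }

    n_loss <- stats::rpois(1, config$loss_rate)
    for (i in seq_len(n_loss)) {
      ag <- all_genes()
      ag <- ag[ag$status == "coding", , drop = FALSE]
      if (!nrow(ag)) break
      pick <- ag[sample(nrow(ag), 1L), ]
      if (stats::runif(1) < config$pseudogenization_prob) {
        genome[[pick$chromosome]]$status[pick$row] <- "pseudogene"
        log_event(branch, nxt(), "pseudogenization", pick$family_id,
                  lineage = pick$lineage)
      } else {
        genome[[pick$chromosome]] <-
          genome[[pick$chromosome]][-pick$row, , drop = FALSE]
        log_event(branch, nxt(), "loss", pick$family_id,
                  lineage = pick$lineage)
        if (!nrow(genome[[pick$chromosome]]))
          genome[[pick$chromosome]] <- NULL
      }
    }

    n_rearr <- stats::rpois(1, config$rearrangement_rate)
    for (i in seq_len(n_rearr)) {
      chrs <- names(genome)
      if (!length(chrs)) break
      ch <- chrs[sample(length(chrs), 1L)]
      df <- genome[[ch]]
      n <- nrow(df)
      a <- sample(n, 1L)
      b <- if (a < n) sample(a:n, 1L) else n
      if (stats::runif(1) < 0.5) {      # in-place inversion
        block <- df[a:b, , drop = FALSE][rev(seq_len(b - a + 1L)), ,
                                         drop = FALSE]
        block$strand <- ifelse(block$strand == "+", "-", "+")
        df[a:b, ] <- block
        genome[[ch]] <- df
      } else {                          # cut-and-paste translocation
        block <- df[a:b, , drop = FALSE]
        rest <- df[-(a:b), , drop = FALSE]
        genome[[ch]] <- rest
        if (!nrow(rest)) genome[[ch]] <- NULL
        targets <- names(genome)
        if (!length(targets)) { genome[[ch]] <- block; next }
        tgt <- targets[sample(length(targets), 1L)]
        tdf <- genome[[tgt]]
        pos <- sample(nrow(tdf) + 1L, 1L) - 1L
        genome[[tgt]] <- rbind(
          if (pos > 0) tdf[seq_len(pos), , drop = FALSE], block,
          if (pos < nrow(tdf)) tdf[(pos + 1L):nrow(tdf), , drop = FALSE])
      }
      log_event(branch, nxt(), "rearrangement")
    }
    genome
  }

  to_table <- function(genome, species) {
    rows <- lapply(names(genome), function(ch) {
      df <- genome[[ch]]
      n <- nrow(df)
      start <- (seq_len(n) - 1L) * (config$gene_span + config$intergenic_gap)
      data.frame(gene_id = df$gid, family_id = df$family_id,
                 chromosome = ch, start = start,
                 end = start + config$gene_span, strand = df$strand,
                 status = df$status, lineage = df$lineage,
                 anc_chrom = df$anc_chrom)
    })
    df <- do.call(rbind, rows)
    tb <- gene_table(df[, c("gene_id", "family_id", "chromosome", "start",
                            "end", "strand", "status")], species)
    attr(tb, "lineage") <- stats::setNames(df$lineage, df$gene_id)
    attr(tb, "anc_chrom") <- stats::setNames(df$anc_chrom, df$gene_id)
    tb
  }

  walk <- function(node, genome) {
    lab <- node_label(tree, node)
    genome <- apply_branch(genome, lab)
    kids <- tree_children(tree, node)
    if (!length(kids)) {
      state$tables[[lab]] <- to_table(genome, lab)
    } else {
      for (k in kids) walk(k, genome)
    }
  }
  walk(tree_root(tree), genome)

  events <- if (length(state$events)) do.call(rbind, state$events) else
    data.frame(branch = character(), order = integer(), kind = character(),
               family_id = character(), parent = integer(), child = integer(),
               lineage = integer(), tag = character())
  pedigree <- do.call(rbind, state$pedigree)
  truth <- list(events = events, pedigree = pedigree, config = config)

  families <- paste0("F", seq_len(config$n_families))
  pm <- .sim_presence_matrix(state$tables, families, tree)
  trees <- .sim_gene_trees(tree, state$tables, events, pedigree, families)
  structure(list(tables = state$tables, gene_trees = trees,
                 presence_matrix = pm, truth = truth),
            class = "genome_sim")
}

.sim_presence_matrix <- function(tables, families, tree) {
  species <- names(tables)
  m <- matrix("absent", nrow = length(families), ncol = length(species),
              dimnames = list(families, species))
  for (sp in species) {
    tb <- tables[[sp]]
    for (f in families) {
      rows <- tb[tb$family_id == f, , drop = FALSE]
      if (any(rows$status == "coding")) m[f, sp] <- "present"
      else if (nrow(rows)) m[f, sp] <- "pseudogene"
    }
  }
  m <- m[apply(m != "absent", 1, any), , drop = FALSE]
  if (!nrow(m)) return(NULL)
  presence_matrix(m, tree = tree)
}

# True gene trees from the realized event history. A lineage's "thread" on
# a branch is transformed by the branch's ordered events (duplications
# split it, a loss ends it), then continues into both child branches at
# the speciation; surviving structure is emitted as Newick.
.sim_gene_trees <- function(tree, tables, events, pedigree, families) {
  ev_key <- paste(events$branch, events$family_id)
  ev_by <- split(seq_len(nrow(events)), ev_key)
  gid_of <- lapply(tables, function(tb) {
    lin <- attr(tb, "lineage")
    stats::setNames(names(lin), lin)
  })
  ntip <- length(tree$tip.label)

  build <- function(family) {
    enter <- function(lin, node) {
      lab <- node_label(tree, node)
      idx <- ev_by[[paste(lab, family)]]
      struct <- list(tip = TRUE, lin = lin)
      if (!is.null(idx)) {
        for (j in idx[order(events$order[idx])]) {
          kind <- events$kind[j]
          if (kind %in% c("wgd", "local_duplication")) {
            struct <- .dup_in(struct, events$parent[j], events$child[j])
          } else if (kind == "loss") {
            struct <- .del_in(struct, events$lineage[j])
            if (is.null(struct)) return(NULL)
          }
        }
      }
      resolve(struct, node)
    }
    resolve <- function(s, node) {
      if (is.null(s)) return(NULL)
      if (isTRUE(s$tip)) {
        if (node <= ntip) {
          sp <- tree$tip.label[node]
          gid <- gid_of[[sp]][as.character(s$lin)]
          if (is.na(gid)) return(NULL)
          return(paste0(sp, "|", gid))
        }
        kids <- tree_children(tree, node)
        parts <- Filter(Negate(is.null),
                        lapply(kids, function(k) enter(s$lin, k)))
        if (!length(parts)) return(NULL)
        if (length(parts) == 1L) return(parts[[1]])
        return(paste0("(", paste(parts, collapse = ","), ")"))
      }
      l <- resolve(s$left, node)
      r <- resolve(s$right, node)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      paste0("(", l, ",", r, ")")
    }
    root_lin <- pedigree$lineage[pedigree$family_id == family &
                                   is.na(pedigree$parent)]
    frag <- enter(root_lin, tree_root(tree))
    if (is.null(frag) || !grepl(",", frag, fixed = TRUE)) return(NULL)
    parse_newick(paste0(frag, ";"))
  }
  stats::setNames(lapply(families, build), families)
}

.dup_in <- function(s, parent, child) {
  if (is.null(s)) return(NULL)
  if (isTRUE(s$tip)) {
    if (s$lin == parent)
      return(list(tip = FALSE, left = list(tip = TRUE, lin = parent),
                  right = list(tip = TRUE, lin = child)))
    return(s)
  }
  s$left <- .dup_in(s$left, parent, child)
  s$right <- .dup_in(s$right, parent, child)
  s
}

.del_in <- function(s, lin) {
  if (is.null(s)) return(NULL)
  if (isTRUE(s$tip)) {
    if (s$lin == lin) return(NULL)
    return(s)
  }
  l <- .del_in(s$left, lin)
  r <- .del_in(s$right, lin)
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  s$left <- l
  s$right <- r
  s
}

#' Ground-truth paralogon from a simulation's pedigree
#'
#' Groups a leaf species' extant genes by the ancestral chromosome their
#' pedigree traces to and reports, per ancestral chromosome, the extant
#' chromosome regions (convex hulls) holding its descendants together with
#' true family-multiplicity counts — the recovery target for
#' [detect_paralogon()].
#'
#' @param sim A `genome_sim` from [simulate_genomes()].
#' @param species Leaf species name.
#' @return Named list (ancestral chromosome -> `paralogon_report`).
#' @export
truth_paralogon <- function(sim, species) {
  if (!species %in% names(sim$tables))
    stop("species was not simulated: ", species, call. = FALSE)
  tb <- sim$tables[[species]]
  anc <- attr(tb, "anc_chrom")[tb$gene_id]
  out <- list()
  for (ac in sort(unique(anc))) {
    rows <- tb[anc == ac, , drop = FALSE]
    out[[ac]] <- .paralogon_report(rows, sort(unique(rows$chromosome)))
  }
  out
}

#' @export
print.genome_sim <- function(x, ...) {
  counts <- vapply(x$tables, nrow, integer(1))
  cat("Genome simulation:", length(x$tables), "species,",
      x$truth$config$n_families, "families\n")
  cat("  genes per species:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
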