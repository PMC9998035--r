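#' Forward (unconditioned) birth-death simulation
#'
#' Gillespie simulation of a binary-fission birth-death process from a
#' single founding lineage over a fixed time horizon. Used directly in
#' calibration tests (the extant lineage count has expectation
#' `exp((birth - death) * t_max)`) and as the engine behind
#' [simulate_species_tree()].
#'
#' @param birth_rate,death_rate Per-lineage rates (1/time).
#' @param t_max Simulated time horizon.
#' @param seed Optional RNG seed.
#' @param max_lineages Safety cap on total lineages ever created.
#' @return List with `n_extant` (count at `t_max`) and `tree` (ultrametric
#'   `phylo` over extant leaves, or `NULL` if fewer than 2 survive).
#' @export
simulate_birth_death <- function(birth_rate, death_rate = 0, t_max,
                                 seed = NULL, max_lineages = 100000L) {
  if (!is.null(seed)) set.seed(seed)
  if (birth_rate < 0 || death_rate < 0) stop("rates must be non-negative")
  sim <- .bd_forward(birth_rate, death_rate, t_max = t_max,
                     n_target = NA_integer_, max_lineages = max_lineages)
  list(n_extant = sim$n_extant, tree = .bd_to_phylo(sim))
}

#' Simulate a rooted ultrametric species tree with a fixed leaf count
#'
#' Runs the forward birth-death process until the n-th extant lineage is
#' born and stops there, so the returned tree is ultrametric with exactly
#' `n_species` leaves (retrying on extinction before reaching `n_species`).
#'
#' @param n_species Number of extant leaves (>= 3).
#' @param birth_rate,death_rate Per-lineage rates; `death_rate` must be
#'   strictly below `birth_rate` (otherwise the conditioned process need
#'   not terminate).
#' @param seed Optional RNG seed; identical seeds give identical newick.
#' @return Rooted ultrametric `phylo` with leaves `s1..sN` (ranked by
#'   first appearance).
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1,
                                  death_rate = 0, seed = NULL) {
  if (n_species < 3) stop("n_species must be >= 3")
  if (death_rate >= birth_rate) {
    stop("death_rate >= birth_rate: conditioned process may not terminate")
  }
  if (!is.null(seed)) set.seed(seed)
  repeat {
    sim <- .bd_forward(birth_rate, death_rate, t_max = Inf,
                       n_target = as.integer(n_species),
                       max_lineages = 100000L)
    if (sim$n_extant == n_species) break
  }
  tree <- .bd_to_phylo(sim)
  tree$tip.label <- paste0("s", seq_len(n_species))
  tree
}

# Core Gillespie engine. Stops at t_max, or at the moment the extant count
# first reaches n_target (whichever applies). Records, per lineage: parent,
# start time, end time, fate (1 split, 0 dead, 2 extant at stop).
.bd_forward <- function(birth_rate, death_rate, t_max, n_target,
                        max_lineages) {
  parent <- integer(0); t0 <- numeric(0); t1 <- numeric(0); fate <- integer(0)
  new_lineage <- function(p, t) {
    parent[length(parent) + 1L] <<- p
    t0[length(t0) + 1L] <<- t
    t1[length(t1) + 1L] <<- NA_real_
    fate[length(fate) + 1L] <<- NA_integer_
    length(parent)
  }
  new_lineage(0L, 0)
  extant <- 1L
  t <- 0
  while (length(extant) > 0L) {
    if (!is.na(n_target) && length(extant) >= n_target) break
    k <- length(extant)
    rate <- k * (birth_rate + death_rate)
    if (rate == 0) { t <- t_max; break }
    dt <- stats::rexp(1L, rate)
    if (t + dt > t_max) { t <- t_max; break }
    t <- t + dt
    i <- extant[sample.int(k, 1L)]
    if (stats::runif(1L) < birth_rate / (birth_rate + death_rate)) {
      t1[i] <- t; fate[i] <- 1L
      c1 <- new_lineage(i, t); c2 <- new_lineage(i, t)
      extant <- c(setdiff(extant, i), c1, c2)
      if (length(parent) > max_lineages) stop("birth-death simulation exceeded max_lineages")
    } else {
      t1[i] <- t; fate[i] <- 0L
      extant <- setdiff(extant, i)
    }
  }
  if (!is.na(n_target) && length(extant) >= n_target &&
      birth_rate + death_rate > 0) {
    # extend to just before the next event so terminal branches are not zero
    t <- t + stats::rexp(1L, length(extant) * (birth_rate + death_rate))
  }
  t1[extant] <- t; fate[extant] <- 2L
  list(parent = parent, t0 = t0, t1 = t1, fate = fate,
       n_extant = length(extant), t_stop = t)
}

# Convert a forward-simulation record to a phylo over the extant leaves.
.bd_to_phylo <- function(sim) {
  if (sim$n_extant < 2L) return(NULL)
  # keep lineages with at least one extant descendant
  n <- length(sim$parent)
  alive <- sim$fate == 2L
  keep <- alive
  # propagate upwards
  ord <- order(sim$t0, decreasing = TRUE)
  for (i in ord) if (keep[i] && sim$parent[i] > 0L) keep[sim$parent[i]] <- TRUE
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sim$parent[i]
    if (keep[i] && p > 0L) children[[p]] <- c(children[[p]], i)
  }
  # recursively emit newick; suppress unary chains by extending lengths
  leaf_counter <- 0L
  emit <- function(i, extra_len) {
    len <- sim$t1[i] - sim$t0[i] + extra_len
    ch <- children[[i]]
    if (sim$fate[i] == 2L) {
      leaf_counter <<- leaf_counter + 1L
      return(sprintf("L%d:%.12g", i, len))
    }
    kept <- ch[keep[ch]]
    if (length(kept) == 1L) return(emit(kept, len))
    paste0("(", paste(vapply(kept, emit, "", extra_len = 0), collapse = ","),
           "):", sprintf("%.12g", len))
  }
  root <- which(sim$parent == 0L)
  txt <- paste0(emit(root, 0), ";")
  tree <- ape::read.tree(text = txt)
  # leaves labelled by birth order of their lineage record
  ord_ids <- as.integer(sub("^L", "", tree$tip.label))
  tree$tip.label <- paste0("t", rank(ord_ids, ties.method = "first"))
  tree
}

#' Parameters for the coupled two-complex Dollo loss simulator
#'
#' `coupling` links the two loss processes: once one complex is lost on a
#' lineage, the other's loss rate is multiplied by `1 + coupling` (clipped
#' at zero). Negative coupling therefore suppresses the second loss and
#' produces the anti-correlated, mutually exclusive presence pattern seen
#' for analogous complexes that back each other up functionally.
#'
#' @param loss_rate_A,loss_rate_B Expected losses per unit branch length.
#' @param coupling In `[-1, 1]`.
#' @param dropout_rate Per present subunit cell, probability that the
#'   observation fails (recorded as absent; emulates incomplete
#'   transcriptomes). In `[0, 1)`.
#' @param seed Optional RNG seed.
#' @return `dollo_sim_params` object.
#' @export
dollo_sim_params <- function(loss_rate_A = 1, loss_rate_B = 1,
                             coupling = -0.9, dropout_rate = 0,
                             seed = NULL) {
  stopifnot(loss_rate_A >= 0, loss_rate_B >= 0,
            coupling >= -1, coupling <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(loss_rate_A = loss_rate_A, loss_rate_B = loss_rate_B,
                 coupling = coupling, dropout_rate = dropout_rate,
                 seed = seed),
            class = "dollo_sim_params")
}

#' Simulate coupled Dollo losses of two complexes on a species tree
#'
#' Both complexes are present at the root (the ancestral-origin
#' assumption). Loss of a complex is the first arrival of a Poisson
#' process along each root-to-leaf path (at most one loss per path); the
#' two processes are coupled through the rate multiplier described in
#' [dollo_sim_params()]. Dropout noise is applied to the observed matrix
#' only; the returned truth is un-dropped.
#'
#' @param tree Rooted `phylo` species tree with branch lengths.
#' @param params A [dollo_sim_params()] object.
#' @param complexes Named list of two subunit vectors (complex A first).
#' @param conditioning Name of the always-present conditioning gene.
#' @return List with `matrix` (observed [presence_matrix()]), and `truth`:
#'   `presence_A`/`presence_B` (named logical per leaf), `loss_edges_A`/
#'   `loss_edges_B` (data.frames: edge index, child node, clade label).
#' @export
simulate_coupled_dollo <- function(tree, params = dollo_sim_params(),
                                   complexes = default_complexes(),
                                   conditioning = "Ndc80") {
  stopifnot(inherits(tree, "phylo"), length(complexes) == 2L)
  if (!is.null(params$seed)) set.seed(params$seed)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  edges <- tree$edge
  elen <- tree$edge.length
  rates <- c(params$loss_rate_A, params$loss_rate_B)
  # preorder traversal carrying (lostA, lostB)
  state <- matrix(FALSE, nrow = nt + tree$Nnode, ncol = 2L)
  loss_edge <- list(integer(0), integer(0))
  tree_pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree_pre$edge))) {
    par <- tree_pre$edge[e, 1L]; child <- tree_pre$edge[e, 2L]
    lost <- state[par, ]
    t <- 0; L <- tree_pre$edge.length[e]
    repeat {
      r <- ifelse(lost, 0, rates * pmax(0, 1 + params$coupling * rev(lost)))
      total <- sum(r)
      if (total == 0) break
      dt <- stats::rexp(1L, total)
      if (t + dt > L) break
      t <- t + dt
      which_c <- if (stats::runif(1L) < r[1L] / total) 1L else 2L
      lost[which_c] <- TRUE
      loss_edge[[which_c]] <- c(loss_edge[[which_c]], e)
    }
    state[child, ] <- lost
  }
  leaves <- tree$tip.label
  presence_A <- !state[seq_len(nt), 1L]; names(presence_A) <- leaves
  presence_B <- !state[seq_len(nt), 2L]; names(presence_B) <- leaves
  subunits <- c(unlist(complexes, use.names = FALSE), conditioning)
  states <- matrix("absent", nrow = nt, ncol = length(subunits),
                   dimnames = list(leaves, subunits))
  states[, conditioning] <- "present"
  states[presence_A, complexes[[1L]]] <- "present"
  states[presence_B, complexes[[2L]]] <- "present"
  if (params$dropout_rate > 0) {
    su <- unlist(complexes, use.names = FALSE)
    pres <- states[, su, drop = FALSE] == "present"
    drop <- pres & matrix(stats::runif(length(pres)) < params$dropout_rate,
                          nrow = nrow(pres))
    block <- states[, su, drop = FALSE]
    block[drop] <- "absent"
    states[, su] <- block
  }
  edge_df <- function(idx) {
    idx <- sort(unique(idx))
    data.frame(edge = idx,
               child = tree_pre$edge[idx, 2L],
               clade = vapply(tree_pre$edge[idx, 2L], function(nd) {
                 tips <- .node_tips(tree_pre, nd)
                 paste(sort(tree_pre$tip.label[tips]), collapse = "+")
               }, ""))
  }
  list(matrix = presence_matrix(states,
                                complexes = complexes,
                                conditioning = conditioning),
       truth = list(presence_A = presence_A, presence_B = presence_B,
                    loss_edges_A = edge_df(loss_edge[[1L]]),
                    loss_edges_B = edge_df(loss_edge[[2L]]),
                    tree = tree_pre))
}

# tip indices below a node (the node itself if a tip)
.node_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= nt) out <- c(out, nd) else stack <- c(stack, kids[[as.character(nd)]])
  }
  out
}

#' Describe a two-wave duplication history for complex subunits
#'
#' Models the origin scenario of a symmetric two-arm complex: a single
#' proto-subunit duplicates into two arm ancestors (first wave, along the
#' symmetry axis), each of which then diversifies by stepwise duplication
#' into the arm's subunits (second wave), all before the species-tree
#' root. Leaves of the duplication tree are the subunit names of the
#' paralog map; arms have equal subunit counts.
#'
#' @param paralog_map A [paralog_map()]; its pairs define the subunits.
#' @param arm_split_depth Branch length from the proto-subunit to each arm
#'   ancestor (divergence between arms; the signal that roots the tree).
#' @param pair_split_depth Branch length of each within-arm duplication
#'   step.
#' @param root_stem Branch length between the last duplication and the
#'   species-tree root.
#' @return `duplication_history` object containing a `phylo` duplication
#'   tree whose leaves are subunit names.
#' @export
duplication_history <- function(paralog_map = default_paralog_map(),
                                arm_split_depth = 1,
                                pair_split_depth = 0.3,
                                root_stem = 0.1) {
  pm <- paralog_map
  arm1 <- pm$pairs$subunit[pm$pairs$arm == "arm1"]
  arm2 <- pm$pairs$subunit[pm$pairs$arm == "arm2"]
  stopifnot(length(arm1) == length(arm2), length(arm1) >= 1)
  cascade <- function(members, step, tip_len, top_len) {
    # stepwise duplication: (((a,b),c),d) with step-length internal edges;
    # the returned subtree carries branch length top_len at its top.
    txt <- sprintf("%s:%.9g", members[1L], tip_len)
    if (length(members) > 1L) {
      for (i in 2L:length(members)) {
        txt <- sprintf("(%s,%s:%.9g):%.9g", txt, members[i], tip_len, step)
      }
    }
    sub(":[0-9.eE+-]+$", sprintf(":%.9g", top_len), txt)
  }
  t1 <- cascade(arm1, pair_split_depth, root_stem, arm_split_depth)
  t2 <- cascade(arm2, pair_split_depth, root_stem, arm_split_depth)
  dup_tree <- ape::read.tree(text = sprintf("(%s,%s);", t1, t2))
  structure(list(tree = dup_tree, paralog_map = pm,
                 arm_split_depth = arm_split_depth,
                 pair_split_depth = pair_split_depth,
                 root_stem = root_stem),
            class = "duplication_history")
}

#' @export
print.duplication_history <- function(x, ...) {
  cat("duplication_history over", length(x$tree$tip.label), "subunits\n")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Simulate subunit sequences under a planted duplication history
#'
#' Builds the gene tree by grafting one copy of the species tree onto each
#' leaf of the duplication tree (duplications predate the species root),
#' prunes lineages listed in `loss_edges`, and evolves amino-acid
#' sequences along it by a continuous-time Markov substitution process
#' (exact per-branch transition matrices via eigendecomposition).
#'
#' @param tree Rooted species tree (`phylo`).
#' @param history A [duplication_history()].
#' @param model A [phylo_model()] (rate variation ignored for simulation;
#'   the uniform-rate process is used).
#' @param seq_length Number of sites (>= 50).
#' @param loss_edges Optional named list subunit -> integer vector of
#'   species-tree edge indices below which that subunit is absent.
#' @param seed Optional RNG seed.
#' @return List: `alignments` (named list subunit -> named character
#'   vector species -> sequence; all equal length, gap-free), `gene_tree`
#'   (`phylo`, tips `species__subunit`), `species_tree`.
#' @export
simulate_complex_sequences <- function(tree, history,
                                       model = phylo_model("POISSON"),
                                       seq_length = 200L,
                                       loss_edges = NULL, seed = NULL) {
  stopifnot(seq_length >= 50L)
  if (!is.null(seed)) set.seed(seed)
  subunits <- history$tree$tip.label
  # per-subunit surviving species
  survives <- lapply(subunits, function(su) {
    lost <- rep(FALSE, length(tree$tip.label))
    if (!is.null(loss_edges) && !is.null(loss_edges[[su]])) {
      for (e in loss_edges[[su]]) {
        lost[.node_tips(tree, tree$edge[e, 2L])] <- TRUE
      }
    }
    tree$tip.label[!lost]
  })
  names(survives) <- subunits
  # graft: replace each duplication-tree leaf by the species tree with
  # renamed tips
  strip <- function(s) sub(";$", "", s)
  sp_txt <- strip(ape::write.tree(tree))
  dup <- history$tree
  dup_txt <- ape::write.tree(dup)
  for (su in subunits) {
    sub_txt <- gsub("([(,])([A-Za-z0-9_.-]+):", paste0("\\1\\2__", su, ":"),
                    paste0("(", sp_txt, ");"))
    sub_txt <- substr(sub_txt, 2L, nchar(sub_txt) - 2L)  # drop wrapping (...) ;
    dup_txt <- sub(paste0("([(,])", su, ":"),
                   paste0("\\1", sub_txt, ":"), dup_txt)
  }
  gene_tree <- ape::read.tree(text = dup_txt)
  # evolve sequences along gene_tree
  sim <- .simulate_ctmc(gene_tree, model, seq_length)
  aln <- lapply(subunits, function(su) {
    keep <- paste0(survives[[su]], "__", su)
    seqs <- sim[keep]
    names(seqs) <- survives[[su]]
    seqs
  })
  names(aln) <- subunits
  # prune lost tips from the gene tree
  lost_tips <- setdiff(gene_tree$tip.label,
                       unlist(lapply(subunits, function(su)
                         paste0(survives[[su]], "__", su))))
  if (length(lost_tips)) {
    gene_tree <- ape::drop.tip(gene_tree, lost_tips)
  }
  list(alignments = aln, gene_tree = gene_tree, species_tree = tree)
}

# simulate one sequence per tip by CTMC descent from equilibrium
.simulate_ctmc <- function(tree, model, n_sites) {
  aa <- model$alphabet
  nstate <- length(aa)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample.int(nstate, n_sites, replace = TRUE, prob = model$pi)
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    P <- transition_matrix(model, tree$edge.length[e])
    parent_states <- seqs[[par]]
    child_states <- integer(n_sites)
    for (s in seq_len(nstate)) {
      idx <- which(parent_states == s)
      if (length(idx)) {
        child_states[idx] <- sample.int(nstate, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
    seqs[[child]] <- child_states
  }
  out <- vapply(seq_len(nt), function(i) paste(aa[seqs[[i]]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

#' Simulate per-species gene locus tables
#'
#' `clustered = TRUE` places all subunit genes on a single scaffold with
#' independent exponential intergenic gaps (mean `mean_spacing_bp`);
#' `clustered = FALSE` assigns each gene a scaffold uniformly at random,
#' emulating a dispersed genomic layout.
#'
#' @param species Character vector of species ids.
#' @param subunits Character vector of subunit (gene) names.
#' @param n_scaffolds Number of scaffolds per species (>= 1).
#' @param clustered Logical; see above.
#' @param mean_spacing_bp Mean intergenic gap in the clustered layout (bp).
#' @param gene_length_bp Fixed gene length (bp).
#' @param seed Optional RNG seed.
#' @return Locus `data.frame` (species, subunit, scaffold, start, end,
#'   strand; 0-based half-open).
#' @export
simulate_loci <- function(species, subunits, n_scaffolds = 100L,
                          clustered = FALSE, mean_spacing_bp = 10000,
                          gene_length_bp = 1000L, seed = NULL) {
  stopifnot(n_scaffolds >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sp in species) {
    n <- length(subunits)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (clustered) {
      gaps <- stats::rexp(n, rate = 1 / mean_spacing_bp)
      # start_1 = gap_1; start_{i+1} = end_i + gap_{i+1}
      starts <- round(cumsum(gaps + c(0, rep(gene_length_bp, n - 1L))))
      rows[[sp]] <- data.frame(species = sp, subunit = subunits,
                               scaffold = "scaffold_1",
                               start = starts,
                               end = starts + gene_length_bp,
                               strand = strand)
    } else {
      scf <- paste0("scaffold_", sample.int(n_scaffolds, n, replace = TRUE))
      starts <- round(stats::runif(n, 0, 5e6))
      rows[[sp]] <- data.frame(species = sp, subunit = subunits,
                               scaffold = scf, start = starts,
                               end = starts + gene_length_bp,
                               strand = strand)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
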