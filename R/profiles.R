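#' Call per-species presence of a complex
#'
#' A species is flagged present when at least `min_subunits` of the
#' complex's subunit cells are `present`. `unknown` cells never count
#' toward the threshold (absence of evidence) but their per-species count
#' is attached so callers can flag ambiguous species. With
#' `min_subunits = 1` this reproduces a profile-display presence call; the
#' stricter `>= 4` rule is the dataset-inclusion filter for
#' transcriptome-derived proteomes.
#'
#' @param pm A [presence_matrix()].
#' @param complex_name Name of a complex defined in `pm`.
#' @param min_subunits Minimum present subunits (>= 1).
#' @return Named logical vector (species); attribute `n_unknown` carries
#'   per-species unknown-cell counts.
#' @export
call_complex_presence <- function(pm, complex_name, min_subunits = 1L) {
  stopifnot(inherits(pm, "presence_matrix"), min_subunits >= 1L)
  if (!complex_name %in% names(pm$complexes)) {
    stop("unknown complex: ", complex_name)
  }
  block <- pm$states[, pm$complexes[[complex_name]], drop = FALSE]
  n_present <- rowSums(block == "present")
  out <- n_present >= min_subunits
  attr(out, "n_present") <- n_present
  attr(out, "n_unknown") <- rowSums(block == "unknown")
  out
}

#' Co-occurrence summary of two complexes
#'
#' Counts are restricted to species that carry the conditioning gene (so
#' that uninformative genomes do not inflate the "neither" class). The
#' identity `n_A + n_B - n_both + n_neither = n_conditioning` always
#' holds. Because published "either" percentages are ambiguous between
#' inclusive and exclusive readings, both fractions are reported.
#'
#' @inheritParams call_complex_presence
#' @param complex_A,complex_B Complex names defined in `pm`.
#' @return `cooccurrence_summary` object: counts `n_conditioning`, `n_A`,
#'   `n_B`, `n_both`, `n_neither` and fractions (3 dp in the printout;
#'   full precision in the object).
#' @export
cooccurrence_summary <- function(pm, complex_A, complex_B,
                                 min_subunits = 1L) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.na(pm$conditioning)) stop("matrix has no conditioning gene")
  cond <- pm$states[, pm$conditioning] == "present"
  if (!any(cond)) stop("no species carries the conditioning gene")
  a <- call_complex_presence(pm, complex_A, min_subunits)[cond]
  b <- call_complex_presence(pm, complex_B, min_subunits)[cond]
  n <- sum(cond)
  out <- list(complex_A = complex_A, complex_B = complex_B,
              min_subunits = min_subunits,
              n_conditioning = n,
              n_A = sum(a), n_B = sum(b),
              n_both = sum(a & b), n_neither = sum(!a & !b),
              frac_A = sum(a) / n, frac_B = sum(b) / n,
              frac_both = sum(a & b) / n,
              frac_either_inclusive = sum(a | b) / n,
              frac_either_exclusive = sum(xor(a, b)) / n)
  structure(out, class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat(sprintf("co-occurrence of %s and %s (min_subunits = %d)\n",
              x$complex_A, x$complex_B, x$min_subunits))
  cat(sprintf("  conditioning species: %d\n", x$n_conditioning))
  cat(sprintf("  %s: %d/%d (%.3f)\n", x$complex_A, x$n_A,
              x$n_conditioning, x$frac_A))
  cat(sprintf("  %s: %d/%d (%.3f)\n", x$complex_B, x$n_B,
              x$n_conditioning, x$frac_B))
  cat(sprintf("  both: %d/%d (%.3f)   neither: %d/%d (%.3f)\n",
              x$n_both, x$n_conditioning, x$frac_both,
              x$n_neither, x$n_conditioning,
              x$n_neither / x$n_conditioning))
  cat(sprintf("  either (inclusive): %.3f   either (exclusive-or): %.3f\n",
              x$frac_either_inclusive, x$frac_either_exclusive))
  invisible(x)
}

#' Permutation test for mutual exclusivity of two complexes
#'
#' One-sided toward exclusivity: the null keeps complex B's presence
#' labels fixed and permutes complex A's labels among the
#' conditioning-gene-positive species; `p = (1 + #\{n_both* <= n_both\}) /
#' (1 + n_permutations)`. Species sharing a phylogeny are not independent
#' observations, so when a rooted `tree` is supplied the null instead
#' resimulates single-gain loss histories for both complexes conditioned
#' on the observed minimal loss counts (losses placed on branch-length-
#' weighted edges, nested placements excluded) and recomputes the overlap.
#'
#' @inheritParams cooccurrence_summary
#' @param n_permutations At least 100 (default 999).
#' @param seed Optional RNG seed.
#' @param tree Optional rooted `phylo` covering the conditioning species.
#' @return List: `n_both` (observed), `p_value`, `method`, `degenerate`
#'   flag (complex A present in none or all species; then `p = 1` with a
#'   warning).
#' @export
mutual_exclusivity_test <- function(pm, complex_A, complex_B,
                                    min_subunits = 1L,
                                    n_permutations = 999L, seed = NULL,
                                    tree = NULL) {
  stopifnot(n_permutations >= 100L)
  if (!is.null(seed)) set.seed(seed)
  cond <- pm$states[, pm$conditioning] == "present"
  a <- call_complex_presence(pm, complex_A, min_subunits)[cond]
  b <- call_complex_presence(pm, complex_B, min_subunits)[cond]
  # canonical species order: the p-value is then exactly invariant to
  # row reordering of the input matrix
  o <- order(names(a))
  a <- a[o]; b <- b[o]
  obs <- sum(a & b)
  if (sum(a) == 0L || all(a)) {
    warning("degenerate test: complex A present in none or all species")
    return(list(n_both = obs, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (is.null(tree)) {
    perm <- replicate(n_permutations, sum(sample(a) & b))
    method <- "label_permutation"
  } else {
    perm <- .dollo_null_overlaps(pm, complex_A, complex_B, min_subunits,
                                 tree, cond, n_permutations)
    method <- "dollo_resimulation"
  }
  p <- (1 + sum(perm <= obs)) / (1 + n_permutations)
  list(n_both = obs, p_value = p, method = method, degenerate = FALSE)
}

# tree-aware null: replant the observed numbers of losses at random
.dollo_null_overlaps <- function(pm, complex_A, complex_B, min_subunits,
                                 tree, cond, n_permutations) {
  sp <- rownames(pm$states)[cond]
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, sp))
  recA <- dollo_reconstruct(tree, .presence_states(pm, complex_A,
                                                   min_subunits, tree))
  recB <- dollo_reconstruct(tree, .presence_states(pm, complex_B,
                                                   min_subunits, tree))
  kA <- recA$n_losses; kB <- recB$n_losses
  nt <- length(tree$tip.label)
  replicate(n_permutations, {
    presA <- .replant_losses(tree, kA)
    presB <- .replant_losses(tree, kB)
    sum(presA & presB)
  })
}

# place k losses on branch-length-weighted edges, never nested
.replant_losses <- function(tree, k) {
  present <- rep(TRUE, length(tree$tip.label))
  names(present) <- tree$tip.label
  if (k == 0L) return(present)
  avail <- rep(TRUE, nrow(tree$edge))
  lost_tip <- rep(FALSE, length(tree$tip.label))
  for (i in seq_len(k)) {
    w <- tree$edge.length * avail
    if (sum(w) == 0) break
    e <- sample.int(nrow(tree$edge), 1L, prob = w)
    tips <- .node_tips(tree, tree$edge[e, 2L])
    lost_tip[tips] <- TRUE
    # exclude this edge and all edges fully inside/above-overlapping it
    for (j in seq_len(nrow(tree$edge))) {
      if (avail[j]) {
        tj <- .node_tips(tree, tree$edge[j, 2L])
        if (any(lost_tip[tj])) avail[j] <- FALSE
      }
    }
  }
  present[lost_tip] <- FALSE
  present
}

# presence vector in {present,absent} for a complex, ordered by tree tips
.presence_states <- function(pm, complex_name, min_subunits, tree) {
  v <- call_complex_presence(pm, complex_name, min_subunits)
  out <- ifelse(v[tree$tip.label], "present", "absent")
  names(out) <- tree$tip.label
  out
}

#' Per-taxon completeness of each gene
#'
#' Fraction of species per group carrying each gene, the quantity behind
#' per-taxon pie-chart displays. `unknown` cells are excluded from the
#' denominator of their gene (transcriptome absence is ambiguous).
#'
#' @param pm A [presence_matrix()].
#' @param species_table `data.frame` with columns `species` and the
#'   grouping column.
#' @param group_by Name of the grouping column (default `"group"`).
#' @return `data.frame`: group, gene, n_species (informative), n_present,
#'   fraction. Groups with zero species are omitted.
#' @export
taxon_completeness <- function(pm, species_table, group_by = "group") {
  stopifnot(group_by %in% names(species_table),
            "species" %in% names(species_table))
  sp <- rownames(pm$states)
  grp <- species_table[[group_by]][match(sp, species_table$species)]
  if (anyNA(grp)) {
    stop("species without a group label: ",
         paste(sp[is.na(grp)][1:min(3, sum(is.na(grp)))], collapse = ", "))
  }
  rows <- list()
  for (g in unique(grp)) {
    idx <- grp == g
    for (gene in colnames(pm$states)) {
      cells <- pm$states[idx, gene]
      informative <- cells != "unknown"
      n <- sum(informative)
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, gene = gene, n_species = n,
        n_present = sum(cells == "present"),
        fraction = sum(cells == "present") / n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of major groups in which a complex is found
#'
#' @inheritParams taxon_completeness
#' @param complex_name Complex defined in `pm`.
#' @param min_subunits Presence-call threshold.
#' @return List: `n_groups_with_complex`, `n_groups`, `groups` (names).
#' @export
groups_with_complex <- function(pm, species_table, complex_name,
                                min_subunits = 1L, group_by = "group") {
  pres <- call_complex_presence(pm, complex_name, min_subunits)
  grp <- species_table[[group_by]][match(names(pres), species_table$species)]
  hit <- sort(unique(grp[pres]))
  list(n_groups_with_complex = length(hit),
       n_groups = length(unique(grp)), groups = hit)
}
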