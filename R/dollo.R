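#' Minimal-loss (Dollo) reconstruction on a rooted species tree
#'
#' Under a single-gain model the character is gained exactly once (at the
#' root by default, or at the MRCA of the present leaves) and can only be
#' lost thereafter. The minimal loss set places one loss on the edge
#' above each maximal subtree, below the gain node, that contains no
#' present leaf (and, in `unknown = "free"` mode, at least one
#' known-absent leaf). This greedy rootmost placement is optimal: each
#' such subtree requires at least one loss, and one suffices.
#'
#' @param tree Rooted `phylo`.
#' @param presence Named vector over all leaves; values in
#'   `present`/`absent`/`unknown` (or logical with `NA` = unknown).
#' @param gain_policy `"fixed_root"` (ancestral-origin hypothesis) or
#'   `"mrca_of_present"`.
#' @param unknown `"absent"` (default: unknowns count as absent, flagged)
#'   or `"free"` (unknowns take whichever state minimizes losses).
#' @return `dollo_reconstruction`: `gain_node`, `loss_edges` (data.frame
#'   edge/child/clade), `n_losses`, `node_states` (logical presence per
#'   node, internal nodes included), `unknown_leaves`.
#' @export
dollo_reconstruct <- function(tree, presence,
                              gain_policy = c("fixed_root",
                                              "mrca_of_present"),
                              unknown = c("absent", "free")) {
  gain_policy <- match.arg(gain_policy)
  unknown <- match.arg(unknown)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("dollo_reconstruct needs a rooted tree")
  tips <- tree$tip.label
  pres <- .normalize_presence(presence, tips)
  nt <- length(tips)
  root <- nt + 1L
  known_present <- which(pres == "present")
  is_absent_for_cover <- if (unknown == "absent") {
    pres %in% c("absent", "unknown")
  } else {
    pres == "absent"
  }
  if (gain_policy == "mrca_of_present") {
    if (length(known_present) == 0L) {
      stop("gain_policy 'mrca_of_present' needs at least one present leaf")
    }
    gain <- if (length(known_present) == 1L) known_present else
      ape::getMRCA(tree, tips[known_present])
  } else {
    gain <- root
  }
  # postorder flags over the gain subtree
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  has_present <- rep(FALSE, nt + tree$Nnode)
  has_cover_absent <- rep(FALSE, nt + tree$Nnode)
  post <- function(nd) {
    if (nd <= nt) {
      has_present[nd] <<- pres[nd] == "present"
      has_cover_absent[nd] <<- is_absent_for_cover[nd]
    } else {
      for (ch in kids[[as.character(nd)]]) {
        post(ch)
        has_present[nd] <<- has_present[nd] || has_present[ch]
        has_cover_absent[nd] <<- has_cover_absent[nd] || has_cover_absent[ch]
      }
    }
  }
  post(gain)
  # loss nodes: maximal no-present subtrees below gain needing cover
  loss_nodes <- integer(0)
  walk <- function(nd) {
    if (nd != gain && !has_present[nd]) {
      if (has_cover_absent[nd]) loss_nodes <<- c(loss_nodes, nd)
      return(invisible())
    }
    if (nd > nt) for (ch in kids[[as.character(nd)]]) walk(ch)
  }
  walk(gain)
  edge_idx <- match(loss_nodes, tree$edge[, 2L])
  # ancestral states: present below gain unless under a loss node
  in_gain <- rep(FALSE, nt + tree$Nnode)
  mark <- function(nd) {
    in_gain[nd] <<- TRUE
    if (nd > nt) for (ch in kids[[as.character(nd)]]) mark(ch)
  }
  mark(gain)
  node_states <- in_gain
  for (ln in loss_nodes) {
    off <- ln
    sub <- function(nd) {
      node_states[nd] <<- FALSE
      if (nd > nt) for (ch in kids[[as.character(nd)]]) sub(ch)
    }
    sub(off)
  }
  loss_edges <- data.frame(
    edge = edge_idx, child = loss_nodes,
    clade = vapply(loss_nodes, function(nd) {
      paste(sort(tips[.node_tips(tree, nd)]), collapse = "+")
    }, character(1)))
  structure(list(gain_node = gain, loss_edges = loss_edges,
                 n_losses = nrow(loss_edges), node_states = node_states,
                 unknown_leaves = tips[pres == "unknown"],
                 gain_policy = gain_policy, unknown = unknown,
                 tree = tree),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("dollo_reconstruction: gain at node", x$gain_node,
      if (x$gain_policy == "fixed_root") "(root)" else "(MRCA of present)",
      "\n")
  cat("  independent losses:", x$n_losses, "\n")
  if (x$n_losses > 0) {
    show <- utils::head(x$loss_edges$clade, 10L)
    cat("  lost clades:", paste(show, collapse = "; "),
        if (x$n_losses > 10L) "..." else "", "\n")
  }
  if (length(x$unknown_leaves)) {
    cat("  unknown leaves (treated as ", x$unknown, "): ",
        length(x$unknown_leaves), "\n", sep = "")
  }
  invisible(x)
}

.normalize_presence <- function(presence, tips) {
  if (is.logical(presence)) {
    out <- ifelse(is.na(presence), "unknown",
                  ifelse(presence, "present", "absent"))
    names(out) <- names(presence)
  } else {
    out <- presence
    bad <- setdiff(unique(out), c("present", "absent", "unknown"))
    if (length(bad)) stop("invalid presence value(s): ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(names(out))) stop("presence vector must be named by leaf")
  miss <- setdiff(tips, names(out))
  if (length(miss)) stop("presence vector missing leaves: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  out[tips]
}

#' Count independent losses of a complex on a species tree
#'
#' Applies [call_complex_presence()] then [dollo_reconstruct()] with the
#' gain fixed at the root, so the returned count is the minimal number of
#' independent loss events compatible with a single ancestral origin.
#'
#' @inheritParams call_complex_presence
#' @param tree Rooted `phylo`; leaves must be a subset of the matrix
#'   species (matrix species absent from the tree are ignored; tree
#'   leaves missing from the matrix are pruned with a warning).
#' @param unknown Passed to [dollo_reconstruct()].
#' @return Integer loss count, with the full reconstruction as attribute
#'   `"reconstruction"`.
#' @export
count_independent_losses <- function(tree, pm, complex_name,
                                     min_subunits = 1L,
                                     unknown = c("absent", "free")) {
  unknown <- match.arg(unknown)
  missing_sp <- setdiff(tree$tip.label, rownames(pm$states))
  if (length(missing_sp)) {
    warning("pruning ", length(missing_sp),
            " tree leaf/leaves not in the matrix: ",
            paste(utils::head(missing_sp, 5), collapse = ", "))
    tree <- ape::keep.tip(tree, setdiff(tree$tip.label, missing_sp))
  }
  pres <- call_complex_presence(pm, complex_name, min_subunits)
  states <- ifelse(pres[tree$tip.label], "present", "absent")
  unk <- attr(pres, "n_present")[tree$tip.label] == 0 &
    attr(pres, "n_unknown")[tree$tip.label] > 0
  states[unk] <- "unknown"
  names(states) <- tree$tip.label
  rec <- dollo_reconstruct(tree, states, gain_policy = "fixed_root",
                           unknown = unknown)
  structure(rec$n_losses, reconstruction = rec)
}

#' Label reconstructed losses with taxon names
#'
#' @param reconstruction A [dollo_reconstruct()] result.
#' @param species_table `data.frame` with `species` and `group` columns.
#' @return Character vector, one label per loss edge: the shared group
#'   name when the subtended clade is group-homogeneous, the species name
#'   for single-species losses, otherwise `mixed(<groups>)`.
#' @export
map_losses_to_taxa <- function(reconstruction, species_table) {
  stopifnot(inherits(reconstruction, "dollo_reconstruction"))
  tree <- reconstruction$tree
  vapply(reconstruction$loss_edges$child, function(nd) {
    sp <- tree$tip.label[.node_tips(tree, nd)]
    if (length(sp) == 1L) return(sp)
    grp <- unique(species_table$group[match(sp, species_table$species)])
    if (length(grp) == 1L && !is.na(grp)) grp else
      paste0("mixed(", paste(sort(grp), collapse = ","), ")")
  }, character(1))
}
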