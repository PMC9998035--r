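#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with per-branch transition matrices from the
#' model's rate matrix; under a gamma mixture the per-site likelihood is
#' the weighted average over rate classes. Gaps and ambiguous residues
#' (B, Z, X, '?', '*') are missing data: their partial likelihood is 1
#' for every state. Numerically stabilized by per-node rescaling, so long
#' concatenations do not underflow. For a reversible model the total is
#' invariant to the root placement of the same unrooted tree.
#'
#' @param tree `phylo` with branch lengths; leaves must equal the
#'   alignment's row names.
#' @param alignment Named character vector of aligned sequences.
#' @param model A [phylo_model()].
#' @return List: `site_loglik` (numeric, nats, one per site), `total`.
#' @export
site_loglik <- function(tree, alignment, model) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  only_tree <- setdiff(tree$tip.label, names(alignment))
  only_aln <- setdiff(names(alignment), tree$tip.label)
  if (length(only_tree) || length(only_aln)) {
    stop("leaf/row mismatch; only in tree: {",
         paste(only_tree, collapse = ", "), "}, only in alignment: {",
         paste(only_aln, collapse = ", "), "}")
  }
  states <- .encode_alignment(alignment, model$alphabet)
  nt <- length(tree$tip.label)
  n_sites <- ncol(states)
  states <- states[tree$tip.label, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- length(model$class_rates)
  class_ll <- matrix(NA_real_, k, n_sites)
  for (ci in seq_len(k)) {
    partial <- vector("list", nt + tr$Nnode)
    logscale <- rep(0, n_sites)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      P <- transition_matrix(model, tr$edge.length[e],
                             model$class_rates[ci])
      contrib <- if (child <= nt) {
        idx <- states[child, ]
        C <- matrix(1, nrow(P), n_sites)
        ok <- !is.na(idx)
        C[, ok] <- P[, idx[ok]]
        C
      } else {
        P %*% partial[[child]]
      }
      if (is.null(partial[[par]])) {
        partial[[par]] <- contrib
      } else {
        partial[[par]] <- partial[[par]] * contrib
      }
      # rescale after each multiplication to avoid underflow
      mx <- apply(partial[[par]], 2L, max)
      mx[mx == 0] <- 1
      partial[[par]] <- sweep(partial[[par]], 2L, mx, "/")
      logscale <- logscale + log(mx)
      # note: logscale accumulates once per edge; correct because each
      # edge rescales exactly one node's partials
    }
    root <- tr$edge[nrow(tr$edge), 1L]
    lik <- colSums(model$pi * partial[[root]])
    class_ll[ci, ] <- log(lik) + logscale
  }
  # mix rate classes in log space
  w <- log(model$class_weights)
  site_ll <- apply(class_ll + w, 2L, function(v) {
    m <- max(v); m + log(sum(exp(v - m)))
  })
  list(site_loglik = site_ll, total = sum(site_ll))
}

#' Maximum-likelihood branch lengths by coordinate ascent
#'
#' One-dimensional golden-section/parabolic optimization of each branch
#' in turn, repeated until the total log-likelihood improves by less than
#' `tol` in a full round. The trace is monotone non-decreasing.
#'
#' @inheritParams site_loglik
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_rounds Maximum full passes over the branches.
#' @param range Branch-length search interval.
#' @param warn Warn when `max_rounds` is exhausted before convergence
#'   (silenced by the tree search, which deliberately runs few rounds).
#' @return List: `tree` (with fitted lengths), `loglik`, `converged`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, tol = 1e-6,
                                    max_rounds = 20L,
                                    range = c(1e-8, 20), warn = TRUE) {
  cur <- site_loglik(tree, alignment, model)$total
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr2 <- tree
        tr2$edge.length[e] <- x
        site_loglik(tr2, alignment, model)$total
      }
      opt <- stats::optimize(f, interval = range, maximum = TRUE,
                             tol = 1e-8)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged && warn) {
    warning("branch-length optimization did not converge in ",
            max_rounds, " rounds; returning best-so-far")
  }
  list(tree = tree, loglik = cur, converged = converged)
}

#' Model-corrected pairwise distances
#'
#' For the Poisson model the closed form
#' `d = -(19/20) log(1 - (20/19) p)` of the observed difference
#' proportion `p`; for other models the two-sequence maximum-likelihood
#' distance by numeric optimization. Saturated pairs are capped.
#'
#' @inheritParams site_loglik
#' @param max_dist Cap for saturated pairs.
#' @return A `dist` object over the alignment rows.
#' @export
dist_ml <- function(alignment, model, max_dist = 10) {
  states <- .encode_alignment(alignment, model$alphabet)
  n <- nrow(states)
  labs <- rownames(states)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- states[i, ]; b <- states[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) { D[i, j] <- D[j, i] <- max_dist; next }
      p <- mean(a[ok] != b[ok])
      d <- if (model$exchangeability == "POISSON") {
        if (p >= 19 / 20) max_dist else -(19 / 20) * log(1 - (20 / 19) * p)
      } else {
        .two_seq_ml_dist(a[ok], b[ok], model, max_dist)
      }
      D[i, j] <- D[j, i] <- min(d, max_dist)
    }
  }
  stats::as.dist(D)
}

.two_seq_ml_dist <- function(a, b, model, max_dist) {
  tab <- table(a, b)
  ia <- as.integer(rownames(tab)); ib <- as.integer(colnames(tab))
  f <- function(t) {
    P <- transition_matrix(model, t)
    sum(tab * log(model$pi[ia] * P[ia, ib, drop = FALSE] + 1e-300))
  }
  opt <- stats::optimize(f, interval = c(1e-8, max_dist), maximum = TRUE)
  opt$maximum
}

#' Neighbor-joining starting tree from model-corrected distances
#'
#' @inheritParams dist_ml
#' @return Unrooted `phylo` (negative NJ branch lengths clamped to 0).
#' @export
nj_tree <- function(alignment, model = phylo_model("POISSON")) {
  tr <- ape::nj(dist_ml(alignment, model))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
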