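# Nontrivial bipartitions of an (unrooted) tree, restricted to `taxa`,
# as canonical keys: each split is represented by the side NOT containing
# the reference taxon (the alphabetically first of `taxa`).
.tree_splits <- function(tree, taxa = tree$tip.label) {
  taxa <- sort(taxa)
  tr <- ape::keep.tip(tree, intersect(tree$tip.label, taxa))
  if (length(tr$tip.label) < 4L) return(character(0))
  tr <- ape::unroot(tr)
  ref <- taxa[1L]
  nt <- length(tr$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    if (child <= nt) next
    side <- tr$tip.label[.node_tips(tr, child)]
    if (ref %in% side) side <- setdiff(tr$tip.label, side)
    if (length(side) >= 2L && length(side) <= nt - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# TRUE when `tree`, restricted to the constraint's taxa, displays every
# nontrivial bipartition of the constraint tree
.compatible_with_constraint <- function(tree, constraint) {
  taxa <- constraint$tip.label
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) {
    stop("constraint taxa missing from tree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  need <- .tree_splits(constraint, taxa)
  have <- .tree_splits(tree, taxa)
  all(need %in% have)
}

#' Hill-climbing NNI search for the maximum-likelihood topology
#'
#' Starting from `start` (typically [nj_tree()]), branch lengths are
#' fitted, then all nearest-neighbor-interchange rearrangements are
#' scored and the best strict improvement accepted, iterating to a local
#' optimum. With a `constraint` tree, any rearrangement whose induced
#' subtree on the constraint's taxa breaks one of its bipartitions is
#' rejected. Deterministic given inputs.
#'
#' @inheritParams site_loglik
#' @param start Starting `phylo` (>= 4 taxa).
#' @param constraint Optional `phylo` over a subset of taxa.
#' @param tol Minimum log-likelihood gain to accept a move.
#' @param max_iter Maximum accepted moves.
#' @param opt_rounds Branch-length optimization passes per scored tree.
#' @return List: `tree` (with ML branch lengths), `loglik`, `n_moves`.
#' @export
nni_search <- function(start, alignment, model, constraint = NULL,
                       tol = 1e-4, max_iter = 50L, opt_rounds = 3L) {
  if (length(start$tip.label) < 4L) stop("tree search needs >= 4 taxa")
  if (!is.null(constraint) &&
      !all(constraint$tip.label %in% start$tip.label)) {
    stop("constraint incompatible with taxon set: ",
         paste(setdiff(constraint$tip.label, start$tip.label),
               collapse = ", "))
  }
  cur <- ape::unroot(start)
  if (is.null(cur$edge.length)) cur$edge.length <- rep(0.1, nrow(cur$edge))
  fit <- optimize_branch_lengths(cur, alignment, model, tol = tol,
                                 max_rounds = opt_rounds, warn = FALSE)
  cur <- fit$tree; cur_ll <- fit$loglik
  n_moves <- 0L
  repeat {
    if (n_moves >= max_iter) break
    nn <- phangorn::nni(cur)
    # index through [[ so multiPhylo re-attaches compressed tip labels
    neighbors <- lapply(seq_along(nn), function(i) nn[[i]])
    best_ll <- cur_ll; best_tree <- NULL
    for (nb in neighbors) {
      if (!is.null(constraint) &&
          !.compatible_with_constraint(nb, constraint)) next
      if (is.null(nb$edge.length)) {
        nb$edge.length <- rep(mean(cur$edge.length), nrow(nb$edge))
      }
      nfit <- optimize_branch_lengths(nb, alignment, model, tol = tol,
                                      max_rounds = opt_rounds,
                                      warn = FALSE)
      if (nfit$loglik > best_ll + tol) {
        best_ll <- nfit$loglik; best_tree <- nfit$tree
      }
    }
    if (is.null(best_tree)) break
    cur <- best_tree; cur_ll <- best_ll; n_moves <- n_moves + 1L
  }
  list(tree = cur, loglik = cur_ll, n_moves = n_moves)
}

#' Site log-likelihood table over candidate topologies
#'
#' @param trees Named list of `phylo` objects (same leaf set).
#' @inheritParams site_loglik
#' @param optimize Fit branch lengths per topology before scoring.
#' @param opt_rounds Optimization passes per topology when `optimize`.
#' @return Matrix sites x topologies of per-site log-likelihoods.
#' @export
site_loglik_table <- function(trees, alignment, model, optimize = TRUE,
                              opt_rounds = 5L) {
  if (is.null(names(trees))) names(trees) <- paste0("topology", seq_along(trees))
  cols <- lapply(trees, function(tr) {
    if (optimize) {
      tr <- optimize_branch_lengths(tr, alignment, model, tol = 1e-4,
                                    max_rounds = opt_rounds,
                                    warn = FALSE)$tree
    }
    site_loglik(tr, alignment, model)$site_loglik
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(trees)
  out
}

#' RELL bootstrap replicate totals
#'
#' Resamples site indices with replacement (equivalently multinomial
#' site weights) and sums the stored per-site log-likelihoods — no
#' re-optimization. At scale `r`, `ceiling(r * n_sites)` sites are drawn
#' per replicate.
#'
#' @param site_table Matrix sites x topologies (e.g. from
#'   [site_loglik_table()]).
#' @param n_reps Number of replicates.
#' @param seed Optional RNG seed.
#' @param scale Resampling scale `r` (default 1).
#' @return Matrix replicates x topologies of resampled totals.
#' @export
rell_bootstrap <- function(site_table, n_reps = 1000L, seed = NULL,
                           scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(site_table)
  m <- ceiling(scale * n)
  idx <- sample.int(n, m * n_reps, replace = TRUE)
  out <- vapply(seq_len(ncol(site_table)),
                function(t) colSums(matrix(site_table[idx, t], m, n_reps)),
                numeric(n_reps))
  out <- matrix(out, n_reps, ncol(site_table))
  colnames(out) <- colnames(site_table)
  out
}

#' Kishino-Hasegawa test via RELL
#'
#' For each topology, the observed log-likelihood deficit versus the best
#' topology is compared with the centered RELL replicate distribution of
#' that difference; `p` is the fraction of centered replicates at least
#' as unfavorable.
#'
#' @inheritParams rell_bootstrap
#' @return Named numeric vector of p-values (best topology ~ 0.5).
#' @export
kh_test <- function(site_table, n_reps = 1000L, seed = NULL) {
  stopifnot(ncol(site_table) >= 2L)
  totals <- colSums(site_table)
  best <- which.max(totals)
  reps <- rell_bootstrap(site_table, n_reps = n_reps, seed = seed)
  p <- vapply(seq_len(ncol(site_table)), function(t) {
    if (t == best) {
      d_obs <- 0
      d_rep <- reps[, t] - apply(reps[, -t, drop = FALSE], 1L, max)
    } else {
      d_obs <- totals[t] - totals[best]
      d_rep <- reps[, t] - reps[, best]
    }
    centered <- d_rep - mean(d_rep)
    min(1, max(0, mean(centered <= d_obs)))
  }, numeric(1))
  names(p) <- colnames(site_table)
  p
}

#' Approximately unbiased (AU) test via multiscale RELL
#'
#' Bootstrap proportions `BP_r` (fraction of replicates in which the
#' topology attains the maximum total) are computed at each scale `r`,
#' probit-transformed, and fitted by weighted least squares to
#' `z(r) = d * sqrt(r) + c / sqrt(r)`; the p-value is
#' `1 - pnorm(d - c)`. Proportions are clamped to `[1/(2B), 1 - 1/(2B)]`
#' for a finite probit; a topology that never wins at any scale is
#' reported with `p = 0` and a degeneracy flag.
#'
#' @inheritParams rell_bootstrap
#' @param scales Resampling scales (must contain 1).
#' @return List: `p_au` (named vector), `bp` (scales x topologies
#'   matrix), `degenerate` (logical vector).
#' @export
au_test <- function(site_table, scales = seq(0.5, 1.4, by = 0.1),
                    n_reps = 1000L, seed = NULL) {
  stopifnot(ncol(site_table) >= 2L)
  if (!any(abs(scales - 1) < 1e-9)) stop("scales must contain 1.0")
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(site_table)
  bp <- matrix(0, length(scales), k,
               dimnames = list(NULL, colnames(site_table)))
  for (si in seq_along(scales)) {
    reps <- rell_bootstrap(site_table, n_reps = n_reps, seed = NULL,
                           scale = scales[si])
    # random tie-breaking keeps exactly tied topologies exchangeable
    winner <- max.col(reps, ties.method = "random")
    bp[si, ] <- tabulate(winner, nbins = k) / n_reps
  }
  eps <- 1 / (2 * n_reps)
  p_au <- numeric(k); degenerate <- logical(k)
  for (t in seq_len(k)) {
    if (all(bp[, t] == 0)) {
      p_au[t] <- 0; degenerate[t] <- TRUE
      next
    }
    if (all(bp[, t] == 1)) {
      # wins every replicate at every scale: no resolvable signal curve
      p_au[t] <- 1; degenerate[t] <- TRUE
      next
    }
    bpt <- pmin(pmax(bp[, t], eps), 1 - eps)
    z <- stats::qnorm(1 - bpt)
    w <- n_reps * stats::dnorm(stats::qnorm(bpt))^2 / (bpt * (1 - bpt))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[1L]; cc <- fit$coefficients[2L]
    p_au[t] <- min(1, max(0, 1 - stats::pnorm(d - cc)))
  }
  names(p_au) <- colnames(site_table)
  names(degenerate) <- colnames(site_table)
  list(p_au = p_au, bp = bp, degenerate = degenerate)
}

#' Combined topology test report
#'
#' @inheritParams au_test
#' @return `topology_test` data.frame: topology, logL, deltaL, p_KH,
#'   p_AU (+ attribute `params`). The best topology has `deltaL = 0`.
#' @export
topology_test <- function(site_table, scales = seq(0.5, 1.4, by = 0.1),
                          n_reps = 1000L, seed = NULL) {
  totals <- colSums(site_table)
  if (!is.null(seed)) set.seed(seed)
  p_kh <- kh_test(site_table, n_reps = n_reps, seed = NULL)
  au <- au_test(site_table, scales = scales, n_reps = n_reps, seed = NULL)
  out <- data.frame(topology = colnames(site_table),
                    logL = unname(totals),
                    deltaL = unname(max(totals) - totals),
                    p_KH = unname(p_kh),
                    p_AU = unname(au$p_au))
  attr(out, "params") <- list(n_reps = n_reps, scales = scales,
                              seed = seed,
                              degenerate = au$degenerate)
  class(out) <- c("topology_test", "data.frame")
  out
}

#' @export
print.topology_test <- function(x, ...) {
  cat("topology test (RELL; AU by multiscale bootstrap):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat("a topology is rejected when p_AU < 0.05\n")
  invisible(x)
}

#' Check and exploit the arm bipartition of a pseudo-taxon tree
#'
#' Leaves named `<species>__arm1` / `<species>__arm2` come from an
#' arm supermatrix; if the unrooted tree contains the bipartition that
#' separates all arm-1 from all arm-2 pseudo-taxa, the duplication that
#' created the arms predates the species root and the tree is rooted on
#' that branch. Support, when an alignment is given, is the RELL
#' proportion of replicates in which the arm topology beats its NNI
#' rearrangements across the arm branch.
#'
#' @param tree `phylo` over pseudo-taxa.
#' @param alignment,model Optional; enable RELL support computation.
#' @param n_reps RELL replicates for support.
#' @param seed Optional RNG seed.
#' @param groups Optional named vector species -> group for per-arm
#'   monophyly reporting.
#' @return `root_split_report`: `split_present`, `rooted_tree` (or
#'   `NULL`), `support` (`NA` without an alignment), `group_monophyly`
#'   (data.frame or `NULL`).
#' @export
root_split_report <- function(tree, alignment = NULL, model = NULL,
                              n_reps = 1000L, seed = NULL,
                              groups = NULL) {
  labs <- tree$tip.label
  arm <- sub("^.*__", "", labs)
  if (!all(arm %in% c("arm1", "arm2"))) {
    stop("leaves must be named <species>__arm1 or <species>__arm2")
  }
  arm1 <- labs[arm == "arm1"]; arm2 <- labs[arm == "arm2"]
  splits <- .tree_splits(tree)
  key1 <- paste(sort(arm1), collapse = "|")
  key2 <- paste(sort(arm2), collapse = "|")
  present <- (key1 %in% splits) || (key2 %in% splits)
  rooted <- NULL; support <- NA_real_
  if (present) {
    rooted <- ape::root(tree, outgroup = arm1, resolve.root = TRUE)
    if (!is.null(alignment) && !is.null(model)) {
      nn <- phangorn::nni(ape::unroot(tree))
      alts <- Filter(function(nb) {
        s <- .tree_splits(nb)
        !((key1 %in% s) || (key2 %in% s))
      }, lapply(seq_along(nn), function(i) nn[[i]]))
      if (length(alts)) {
        trees <- c(list(arm_split = ape::unroot(tree)), alts)
        names(trees) <- c("arm_split", paste0("alt", seq_along(alts)))
        # one optimization pass per topology: support scoring needs
        # comparable, not fully converged, branch lengths
        st <- site_loglik_table(trees, alignment, model, optimize = TRUE,
                                opt_rounds = 1L)
        reps <- rell_bootstrap(st, n_reps = n_reps, seed = seed)
        support <- mean(max.col(reps, ties.method = "first") == 1L)
      } else {
        support <- 1
      }
    }
  }
  mono <- NULL
  if (!is.null(groups)) {
    sp <- sub("__arm[12]$", "", labs)
    rows <- list()
    for (a in c("arm1", "arm2")) {
      for (g in unique(groups)) {
        tips <- labs[arm == a & groups[sp] == g]
        if (length(tips) < 1L) next
        rows[[paste(a, g)]] <- data.frame(
          arm = a, group = g, n = length(tips),
          monophyletic = length(tips) == 1L ||
            ape::is.monophyletic(tree, tips))
      }
    }
    mono <- do.call(rbind, rows); rownames(mono) <- NULL
  }
  structure(list(split_present = present, rooted_tree = rooted,
                 support = support, group_monophyly = mono,
                 n_arm1 = length(arm1), n_arm2 = length(arm2)),
            class = "root_split_report")
}

#' @export
print.root_split_report <- function(x, ...) {
  cat("arm bipartition present:", x$split_present, "\n")
  if (x$split_present) {
    cat("tree rooted between arms (", x$n_arm1, " arm1 vs ", x$n_arm2,
        " arm2 pseudo-taxa)", sep = "")
    if (!is.na(x$support)) cat("; RELL support ", format(x$support), sep = "")
    cat("\n")
  } else {
    cat("tree left unrooted\n")
  }
  invisible(x)
}
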