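# Independent brute-force oracles and fixture generators used across the
# suite. These deliberately re-derive results by enumeration / naive
# computation, not by calling the package's own algorithms.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

random_alignment <- function(n_rows, width, gap_prob = 0.15,
                             prefix = "r") {
  repeat {
    mat <- matrix(sample(AA20, n_rows * width, TRUE), n_rows, width)
    gaps <- matrix(runif(n_rows * width) < gap_prob, n_rows, width)
    mat[gaps] <- "-"
    # forbid all-gap columns (degenerate in any real alignment)
    if (all(colSums(mat != "-") > 0)) break
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- paste0(prefix, seq_len(n_rows))
  out
}

# ---- Dollo: exhaustive minimal-loss oracle ------------------------------
# Valid single-gain loss set (gain at the root): a subset of edges such
# that every absent leaf has exactly one loss edge on its root path and
# every present leaf has none. Returns the minimum cardinality by
# enumerating all subsets of candidate edges of size < greedy_count to
# prove no smaller valid set exists, and checking one valid set of the
# claimed size exists.
dollo_min_losses_oracle <- function(tree, presence) {
  nt <- length(tree$tip.label)
  pres <- presence[tree$tip.label] == "present"
  # path edges for each leaf
  paths <- lapply(seq_len(nt), function(tip) {
    edges <- integer(0)
    nd <- tip
    repeat {
      e <- which(tree$edge[, 2L] == nd)
      if (length(e) == 0L) break
      edges <- c(edges, e)
      nd <- tree$edge[e, 1L]
    }
    edges
  })
  # candidate edges: subtree contains no present leaf
  cand <- which(vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- which(vapply(paths, function(p) e %in% p, logical(1)))
    !any(pres[below])
  }, logical(1)))
  absent <- which(!pres)
  if (length(absent) == 0L) return(0L)
  valid <- function(set) {
    all(vapply(absent, function(tip)
      sum(paths[[tip]] %in% set) == 1L, logical(1))) &&
      all(vapply(which(pres), function(tip)
        sum(paths[[tip]] %in% set) == 0L, logical(1)))
  }
  # increasing-size exhaustive search over candidate edges
  for (size in 1:length(cand)) {
    combos <- utils::combn(cand, size, simplify = FALSE)
    for (set in combos) if (valid(set)) return(size)
  }
  stop("oracle found no valid loss set")
}

# ---- RBH: naive re-implementation ---------------------------------------
rbh_oracle <- function(evalues, threshold) {
  q <- rownames(evalues); t <- colnames(evalues)
  pairs <- character(0)
  for (a in q) for (b in q) {
    if (a >= b) next
    if (!(b %in% t) || !(a %in% t)) next
    ea <- evalues[a, b]; eb <- evalues[b, a]
    if (is.na(ea) || is.na(eb) || ea > threshold || eb > threshold) next
    others_a <- setdiff(t, a)
    best_a <- others_a[which(evalues[a, others_a] ==
                               min(evalues[a, others_a], na.rm = TRUE))]
    best_a <- sort(best_a)[1L]
    others_b <- setdiff(t, b)
    best_b <- others_b[which(evalues[b, others_b] ==
                               min(evalues[b, others_b], na.rm = TRUE))]
    best_b <- sort(best_b)[1L]
    if (identical(best_a, b) && identical(best_b, a)) {
      pairs <- c(pairs, paste(a, b, sep = "~"))
    }
  }
  sort(pairs)
}

# ---- Superposition: Horn quaternion oracle ------------------------------
quaternion_rmsd_oracle <- function(A, B) {
  n <- nrow(A)
  A0 <- sweep(A, 2L, colMeans(A)); B0 <- sweep(B, 2L, colMeans(B))
  S <- crossprod(B0, A0)  # S[j,k] = sum_i B0[i,j] A0[i,k]
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4L, 4L, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# ---- Likelihood: exhaustive state-sum oracle (unrooted 4-taxon) ---------
# Tree shape ((t1:l1,t2:l2):l5,t3:l3,t4:l4); with internal nodes u (root,
# adjacent to t3,t4) and v (adjacent to t1,t2). Sums over all 20^2
# internal state assignments explicitly.
quartet_loglik_oracle <- function(lens, states, model) {
  P <- lapply(lens, function(t) armroot::transition_matrix(model, t))
  n_sites <- ncol(states)
  pcol <- function(P, s) {
    out <- matrix(1, 20L, n_sites)
    ok <- !is.na(s)
    out[, ok] <- P[, s[ok]]
    out
  }
  C1 <- pcol(P[[1L]], states[1L, ]); C2 <- pcol(P[[2L]], states[2L, ])
  C3 <- pcol(P[[3L]], states[3L, ]); C4 <- pcol(P[[4L]], states[4L, ])
  lik <- rep(0, n_sites)
  for (x in 1:20) for (y in 1:20) {
    lik <- lik + model$pi[x] * C3[x, ] * C4[x, ] * P[[5L]][x, y] *
      C1[y, ] * C2[y, ]
  }
  log(lik)
}

random_quartet <- function(n_sites = 10L, gap_prob = 0,
                           len_range = c(0.05, 1.5)) {
  lens <- runif(5L, len_range[1L], len_range[2L])
  txt <- sprintf("((t1:%.17g,t2:%.17g):%.17g,t3:%.17g,t4:%.17g);",
                 lens[1L], lens[2L], lens[5L], lens[3L], lens[4L])
  tree <- ape::read.tree(text = txt)
  states <- matrix(sample.int(20L, 4L * n_sites, TRUE), 4L, n_sites)
  if (gap_prob > 0) states[runif(length(states)) < gap_prob] <- NA
  chars <- matrix(AA20[states], 4L, n_sites)
  chars[is.na(chars)] <- "-"
  aln <- apply(chars, 1L, paste, collapse = "")
  names(aln) <- paste0("t", 1:4)
  list(tree = tree, lens = lens, states = states, alignment = aln)
}

# ---- Profile alignment: exhaustive affine-gap enumeration oracle --------
# Enumerates every monotone column pairing of the two alignments by DFS
# and returns the optimal score under affine gap costs. `sc` is the
# column-pair score matrix; computed naively by the caller.
enum_align_oracle <- function(sc, gap_open, gap_extend) {
  m <- nrow(sc); n <- ncol(sc)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == m && j == n) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, 1L, acc + sc[i + 1L, j + 1L])
    if (i < m) rec(i + 1L, j, 2L,
                   acc - if (last == 2L) gap_extend else gap_open)
    if (j < n) rec(i, j + 1L, 3L,
                   acc - if (last == 3L) gap_extend else gap_open)
  }
  rec(0L, 0L, 1L, 0)
  best
}

# naive expected BLOSUM62 column-pair scores between two alignments
naive_pair_scores <- function(msa_a, msa_b) {
  B62 <- {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  }
  ma <- do.call(rbind, strsplit(msa_a, ""))
  mb <- do.call(rbind, strsplit(msa_b, ""))
  sc <- matrix(0, ncol(ma), ncol(mb))
  for (i in seq_len(ncol(ma))) for (j in seq_len(ncol(mb))) {
    ra <- ma[, i]; ra <- ra[ra %in% AA20]
    rb <- mb[, j]; rb <- rb[rb %in% AA20]
    if (length(ra) && length(rb)) {
      tot <- 0
      for (x in ra) for (y in rb) tot <- tot + B62[x, y]
      sc[i, j] <- tot / (length(ra) * length(rb))
    }
  }
  sc
}

# score of a given column pairing (from profile_merge_align's column_map)
# under the same affine costs
pairing_score <- function(column_map, sc, gap_open, gap_extend) {
  total <- 0; last <- 1L
  for (r in seq_len(nrow(column_map))) {
    a <- column_map$a_col[r]; b <- column_map$b_col[r]
    if (!is.na(a) && !is.na(b)) {
      total <- total + sc[a, b]; last <- 1L
    } else if (!is.na(a)) {
      total <- total - if (last == 2L) gap_extend else gap_open; last <- 2L
    } else {
      total <- total - if (last == 3L) gap_extend else gap_open; last <- 3L
    }
  }
  total
}

# delete one side's rows from a merged alignment and drop the columns
# that become all-gap: must recover the other input exactly
recover_submsa <- function(merged, side_names) {
  sub <- merged[side_names]
  mat <- do.call(rbind, strsplit(unname(sub), ""))
  keep <- colSums(mat != "-") > 0
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- side_names
  out
}

# ---- misc ---------------------------------------------------------------
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

random_rooted_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  tr$tip.label <- paste0("s", seq_len(n_leaves))
  tr
}

# exchangeable-null site log-likelihood table for two topologies: each
# site's pair of values is randomly swapped, making the columns jointly
# exchangeable by construction
null_site_table <- function(n_sites) {
  base <- rnorm(n_sites, mean = -3)
  delta <- rnorm(n_sites, sd = 0.5)
  swap <- runif(n_sites) < 0.5
  a <- base + ifelse(swap, delta, 0)
  b <- base + ifelse(swap, 0, delta)
  cbind(T1 = a, T2 = b)
}
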