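#' Paralogous subunit pairing with arm labels
#'
#' Describes the internal symmetry of a two-arm complex: each subunit is
#' paired with its structural paralog in the other arm. Subunits without
#' an accepted paralog (no unequivocal structural/profile homology) are
#' listed as excluded and never enter the rooted concatenation.
#'
#' @param pairs `data.frame` with columns `subunit`, `partner`, `arm`
#'   (`arm1`/`arm2`), `pair` (pair label); one row per subunit.
#' @param excluded Character vector of excluded subunits.
#' @return `paralog_map` object.
#' @export
paralog_map <- function(pairs, excluded = character(0)) {
  stopifnot(all(c("subunit", "partner", "arm", "pair") %in% names(pairs)))
  if (anyDuplicated(pairs$subunit)) stop("subunit appears more than once")
  if (!all(pairs$arm %in% c("arm1", "arm2"))) {
    stop("arm labels must be arm1 or arm2")
  }
  for (p in unique(pairs$pair)) {
    arms <- sort(pairs$arm[pairs$pair == p])
    if (!identical(arms, c("arm1", "arm2"))) {
      stop("pair ", p, " must have exactly one subunit per arm")
    }
  }
  if (length(intersect(excluded, pairs$subunit))) {
    stop("excluded subunits cannot appear in a pair")
  }
  structure(list(pairs = pairs, excluded = excluded),
            class = "paralog_map")
}

#' @export
print.paralog_map <- function(x, ...) {
  cat("paralog_map:", length(unique(x$pairs$pair)), "pairs\n")
  for (p in unique(x$pairs$pair)) {
    mem <- x$pairs[x$pairs$pair == p, ]
    cat("  ", p, ": ", paste(mem$subunit, " (", mem$arm, ")",
                             sep = "", collapse = " - "), "\n", sep = "")
  }
  if (length(x$excluded)) cat("  excluded:",
                              paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Default Dam1-C style paralog map
#'
#' The four structurally validated paralogous pairs (Ask1-Dad3,
#' Dad2-Duo1, Dad4-Dad1, Hsk3-Dam1), with Spc19 and Spc34 excluded: their
#' mutual homology is not supported by structure or profile searches and
#' Spc19 is lineage-specific.
#'
#' @return A [paralog_map()].
#' @export
default_paralog_map <- function() {
  paralog_map(
    data.frame(
      subunit = c("Ask1", "Dad2", "Dad4", "Hsk3",
                  "Dad3", "Duo1", "Dad1", "Dam1"),
      partner = c("Dad3", "Duo1", "Dad1", "Dam1",
                  "Ask1", "Dad2", "Dad4", "Hsk3"),
      arm = rep(c("arm1", "arm2"), each = 4L),
      pair = rep(c("Ask1-Dad3", "Dad2-Duo1", "Dad4-Dad1", "Hsk3-Dam1"),
                 2L)),
    excluded = c("Spc19", "Spc34"))
}

# alignment (named character vector) -> character matrix
.aln_mat <- function(msa) {
  if (length(msa) == 0L) return(matrix(character(0), nrow = 0L))
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}

.mat_aln <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# 20-state residue frequency profile per column (gaps excluded); also
# returns per-column non-gap weight
.column_profile <- function(mat, alphabet) {
  n_col <- ncol(mat)
  prof <- matrix(0, nrow = n_col, ncol = length(alphabet),
                 dimnames = list(NULL, alphabet))
  for (j in seq_len(n_col)) {
    res <- mat[, j]
    res <- res[res %in% alphabet]
    if (length(res)) {
      tab <- table(factor(res, levels = alphabet))
      prof[j, ] <- tab / length(res)
    }
  }
  prof
}

#' Merge two sub-alignments by profile-profile global alignment
#'
#' Global (Needleman-Wunsch) alignment of the two alignments' column
#' profiles with affine gaps and BLOSUM62 expected scores. Each input is
#' treated as frozen: its columns are never split, reordered or edited,
#' only interleaved with all-gap columns — so deleting the partner's rows
#' from the output and dropping all-gap columns recovers the input
#' exactly (the sub-MSA preservation contract of profile merging).
#'
#' @param msa_a,msa_b Named character vectors (aligned, equal widths
#'   within each input). `msa_b` may have zero rows, in which case
#'   `msa_a` is returned unchanged.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @return Named character vector over `c(names(msa_a), names(msa_b))`
#'   with attribute `column_map`: data.frame (`a_col`, `b_col`, `NA`
#'   where a side is gapped) and attribute `score` (DP optimum).
#' @export
profile_merge_align <- function(msa_a, msa_b, gap_open = 10,
                                gap_extend = 0.5) {
  if (length(msa_a) == 0L && length(msa_b) == 0L) {
    stop("cannot merge two empty alignments")
  }
  if (length(msa_b) == 0L) {
    attr(msa_a, "column_map") <- data.frame(a_col = seq_len(nchar(msa_a[1L])),
                                            b_col = NA_integer_)
    return(msa_a)
  }
  if (length(msa_a) == 0L) {
    out <- profile_merge_align(msa_b, msa_a, gap_open, gap_extend)
    cm <- attr(out, "column_map")
    attr(out, "column_map") <- data.frame(a_col = cm$b_col, b_col = cm$a_col)
    return(out)
  }
  A <- .aln_mat(msa_a); B <- .aln_mat(msa_b)
  aa <- .aa_alphabet()
  S <- .blosum62()[aa, aa]
  PA <- .column_profile(A, aa); PB <- .column_profile(B, aa)
  sc <- PA %*% S %*% t(PB)  # m x n expected column-pair scores
  m <- nrow(sc); n <- ncol(sc)
  NEG <- -1e18
  M <- matrix(NEG, m + 1L, n + 1L)  # best ending in a paired column
  X <- matrix(NEG, m + 1L, n + 1L)  # best ending in (A column, gap)
  Y <- matrix(NEG, m + 1L, n + 1L)  # best ending in (gap, B column)
  M[1L, 1L] <- 0
  for (i in seq_len(m)) {
    X[i + 1L, 1L] <- -gap_open - gap_extend * (i - 1L)
  }
  for (j in seq_len(n)) {
    Y[1L, j + 1L] <- -gap_open - gap_extend * (j - 1L)
  }
  PM <- matrix(0L, m + 1L, n + 1L)  # predecessor state pointers
  PX <- matrix(0L, m + 1L, n + 1L)
  PY <- matrix(0L, m + 1L, n + 1L)
  PX[seq_len(m) + 1L, 1L] <- 2L; PX[2L, 1L] <- 1L
  PY[1L, seq_len(n) + 1L] <- 3L; PY[1L, 2L] <- 1L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      prev <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(prev)
      M[i + 1L, j + 1L] <- sc[i, j] + prev[k]
      PM[i + 1L, j + 1L] <- k
      candx <- c(M[i, j + 1L] - gap_open, X[i, j + 1L] - gap_extend,
                 Y[i, j + 1L] - gap_open)
      kx <- which.max(candx)
      X[i + 1L, j + 1L] <- candx[kx]
      PX[i + 1L, j + 1L] <- kx
      candy <- c(M[i + 1L, j] - gap_open, X[i + 1L, j] - gap_open,
                 Y[i + 1L, j] - gap_extend)
      ky <- which.max(candy)
      Y[i + 1L, j + 1L] <- candy[ky]
      PY[i + 1L, j + 1L] <- ky
    }
  }
  # traceback from the best terminal state via stored pointers
  i <- m; j <- n
  state <- which.max(c(M[m + 1L, n + 1L], X[m + 1L, n + 1L],
                       Y[m + 1L, n + 1L]))
  best <- max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
  a_cols <- integer(0); b_cols <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      a_cols <- c(i, a_cols); b_cols <- c(j, b_cols)
      state <- PM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      a_cols <- c(i, a_cols); b_cols <- c(NA_integer_, b_cols)
      state <- PX[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      a_cols <- c(NA_integer_, a_cols); b_cols <- c(j, b_cols)
      state <- PY[i + 1L, j + 1L]
      j <- j - 1L
    }
  }
  n_out <- length(a_cols)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = n_out,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ka <- !is.na(a_cols); kb <- !is.na(b_cols)
  out[seq_len(nrow(A)), ka] <- A[, a_cols[ka], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), kb] <- B[, b_cols[kb], drop = FALSE]
  res <- .mat_aln(out)
  attr(res, "column_map") <- data.frame(a_col = a_cols, b_col = b_cols)
  attr(res, "score") <- best
  res
}

.aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.blosum_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$B62 <- e$BLOSUM62
  }
  .blosum_cache$B62
}

#' Gap-threshold column trimming
#'
#' Keeps a column iff its residue (non-gap) fraction is at least
#' `keep_fraction`, the semantics of gap-threshold (`gt`) alignment
#' trimming; column order is preserved and the mapping back to original
#' indices is returned.
#'
#' @param msa Named character vector (alignment).
#' @param keep_fraction In `(0, 1]`; the screening default is 0.05.
#' @return List: `msa` (trimmed), `kept` (original column indices).
#' @export
trim_columns <- function(msa, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  mat <- .aln_mat(msa)
  frac <- colMeans(mat != "-")
  kept <- which(frac >= keep_fraction - 1e-12)
  if (length(kept) == 0L) {
    stop("all ", ncol(mat), " columns removed at keep_fraction = ",
         keep_fraction, " (max residue fraction was ",
         format(max(frac), digits = 3), ")")
  }
  list(msa = .mat_aln(mat[, kept, drop = FALSE]), kept = kept)
}

#' Select species with enough subunits in both arms
#'
#' The rooted concatenation only admits species whose presence row covers
#' at least `min_per_arm` (default 2) non-excluded subunits in arm 1 AND
#' in arm 2, avoiding rows that are mostly gap noise.
#'
#' @param pm A [presence_matrix()].
#' @param paralog_map A [paralog_map()].
#' @param min_per_arm Minimum present subunits per arm (>= 1).
#' @return Character vector of included species.
#' @export
select_species_by_arm_coverage <- function(pm, paralog_map,
                                           min_per_arm = 2L) {
  stopifnot(min_per_arm >= 1L)
  counts <- function(arm) {
    su <- intersect(paralog_map$pairs$subunit[paralog_map$pairs$arm == arm],
                    colnames(pm$states))
    rowSums(pm$states[, su, drop = FALSE] == "present")
  }
  ok <- counts("arm1") >= min_per_arm & counts("arm2") >= min_per_arm
  rownames(pm$states)[ok]
}

#' Build the duplication-rooted arm supermatrix
#'
#' For each paralogous pair, the two subunit sub-alignments are merged by
#' [profile_merge_align()] (sub-MSAs preserved) and trimmed; the merged
#' block then contributes one column interval to the supermatrix. Each
#' included species appears twice, as pseudo-taxa `<species>__arm1`
#' (carrying its arm-1 member sequence in every block) and
#' `<species>__arm2` (the paralog partner), with missing subunits
#' gap-padded. A tree over these rows can be rooted on the arm1/arm2
#' bipartition: the duplication that separated the arms predates the
#' species root.
#'
#' @param alignments Named list subunit -> named character vector
#'   (per-subunit ortholog alignment, names = species).
#' @param paralog_map A [paralog_map()].
#' @param species Included species (e.g. from
#'   [select_species_by_arm_coverage()]).
#' @param trim_keep_fraction Column trim threshold; `NULL` disables
#'   trimming.
#' @param premerged Set `TRUE` when each pair's two sub-alignments were
#'   already aligned to each other externally (equal widths); the merge
#'   step is then skipped and columns are paired one-to-one.
#' @return `arm_supermatrix`: `alignment` (named character vector, rows
#'   `<species>__arm<k>`), `partition` (data.frame block/start/end,
#'   1-based inclusive), `coverage` (per row, non-gap column count).
#' @export
build_arm_supermatrix <- function(alignments, paralog_map, species,
                                  trim_keep_fraction = 0.05,
                                  premerged = FALSE) {
  pm <- paralog_map
  if (any(grepl("__", species, fixed = TRUE))) {
    stop("species ids must not contain the reserved '__' separator")
  }
  pairs <- unique(pm$pairs$pair)
  rows1 <- stats::setNames(rep("", length(species)), species)
  rows2 <- rows1
  part <- list(); pos <- 0L
  for (p in pairs) {
    mem <- pm$pairs[pm$pairs$pair == p, ]
    su1 <- mem$subunit[mem$arm == "arm1"]
    su2 <- mem$subunit[mem$arm == "arm2"]
    a1 <- alignments[[su1]]; a2 <- alignments[[su2]]
    a1 <- a1[intersect(names(a1), species)]
    a2 <- a2[intersect(names(a2), species)]
    if (length(a1) == 0L && length(a2) == 0L) next
    # rows must be distinguishable in the merged alignment
    names(a1) <- if (length(a1)) paste0(names(a1), "__arm1") else character(0)
    names(a2) <- if (length(a2)) paste0(names(a2), "__arm2") else character(0)
    merged <- if (premerged && length(a1) && length(a2)) {
      if (nchar(a1[1L]) != nchar(a2[1L])) {
        stop("premerged pair ", p, " has unequal widths")
      }
      c(a1, a2)
    } else {
      profile_merge_align(a1, a2)
    }
    if (!is.null(trim_keep_fraction)) {
      merged <- trim_columns(merged, trim_keep_fraction)$msa
    }
    w <- nchar(merged[[1L]])
    gaps <- strrep("-", w)
    r1 <- merged[paste0(species, "__arm1")]
    r2 <- merged[paste0(species, "__arm2")]
    r1[is.na(r1)] <- gaps; r2[is.na(r2)] <- gaps
    rows1 <- paste0(rows1, r1); names(rows1) <- species
    rows2 <- paste0(rows2, r2); names(rows2) <- species
    part[[p]] <- data.frame(block = p, start = pos + 1L, end = pos + w)
    pos <- pos + w
  }
  if (pos == 0L) stop("no alignment data for any pair")
  aln <- c(stats::setNames(rows1, paste0(species, "__arm1")),
           stats::setNames(rows2, paste0(species, "__arm2")))
  allgap <- vapply(species, function(s) {
    !grepl("[^-]", rows1[[s]]) || !grepl("[^-]", rows2[[s]])
  }, logical(1))
  if (any(allgap)) {
    stop("included species with an all-gap arm row: ",
         paste(species[allgap], collapse = ", "),
         " (arm-coverage filter violated upstream)")
  }
  partition <- do.call(rbind, part); rownames(partition) <- NULL
  structure(list(alignment = aln, partition = partition,
                 coverage = vapply(aln, function(s)
                   nchar(gsub("-", "", s)), integer(1))),
            class = "arm_supermatrix")
}

#' @export
print.arm_supermatrix <- function(x, ...) {
  cat("arm_supermatrix:", length(x$alignment), "rows x",
      nchar(x$alignment[[1L]]), "columns,",
      nrow(x$partition), "blocks\n")
  invisible(x)
}

#' Plain one-row-per-species concatenation
#'
#' @param alignments Named list subunit -> named character vector.
#' @param species Species to include (rows); missing subunits are
#'   gap-padded.
#' @param subunits Which subunits to concatenate, in block order
#'   (default: all, list order).
#' @return List: `alignment` (named character vector), `partition`
#'   (block/start/end, 1-based inclusive).
#' @export
build_full_concatenation <- function(alignments, species,
                                     subunits = names(alignments)) {
  rows <- stats::setNames(rep("", length(species)), species)
  part <- list(); pos <- 0L
  for (su in subunits) {
    a <- alignments[[su]]
    if (is.null(a) || length(a) == 0L) next
    w <- nchar(a[[1L]])
    r <- a[species]
    r[is.na(r)] <- strrep("-", w)
    rows <- paste0(rows, r); names(rows) <- species
    part[[su]] <- data.frame(block = su, start = pos + 1L, end = pos + w)
    pos <- pos + w
  }
  if (pos == 0L) stop("no alignment data for any subunit")
  partition <- do.call(rbind, part); rownames(partition) <- NULL
  list(alignment = rows, partition = partition)
}

#' Write a partition map as a text table
#'
#' @param partition `data.frame` with block/start/end (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
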