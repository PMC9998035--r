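#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' of `R b + t` onto `a` over the given one-to-one correspondence, via
#' SVD of the cross-covariance matrix with the standard sign correction
#' on the smallest singular component so that reflections (which would
#' invert protein chirality) are excluded.
#'
#' @param coords_a,coords_b n x 3 matrices or [coord_set()] objects with
#'   equal point counts (n >= 3), correspondence by row.
#' @return `superposition`: `rotation` (3 x 3, det +1), `translation`
#'   (length 3), `rmsd` (Angstrom), `n_pairs`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- .as_xyz(coords_a); B <- .as_xyz(coords_b)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in length")
  n <- nrow(A)
  if (n < 3L) stop("superposition needs at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(B0, A0)  # 3x3, maps B-frame to A-frame
  sv <- svd(H)
  if (sv$d[2L] <= 1e-10 * max(sv$d[1L], 1)) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(ca - R %*% cb)
  diffs <- A - (B %*% t(R) + matrix(t_vec, n, 3L, byrow = TRUE))
  rmsd <- sqrt(sum(diffs^2) / n)
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd = %.4f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

.as_xyz <- function(x) {
  if (inherits(x, "coord_set")) x <- x$xyz
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L, all(is.finite(x)))
  unname(x)
}

#' Build residue correspondence between two chains
#'
#' `sequence_align` mode globally aligns the two sequences (BLOSUM62,
#' affine gaps) and keeps gap-free columns only; `one_to_one` requires
#' equal lengths and pairs residues by rank.
#'
#' @param coords_a,coords_b [coord_set()]s (or n x 3 matrices).
#' @param seq_a,seq_b One-letter sequences matching the coordinate
#'   lengths (required for `sequence_align`).
#' @param mode `"sequence_align"` or `"one_to_one"`.
#' @return Two-column integer matrix of paired indices into a and b.
#' @export
pair_correspondence <- function(coords_a, coords_b, seq_a = NULL,
                                seq_b = NULL,
                                mode = c("sequence_align", "one_to_one")) {
  mode <- match.arg(mode)
  na <- nrow(.as_xyz(coords_a)); nb <- nrow(.as_xyz(coords_b))
  if (mode == "one_to_one") {
    if (na != nb) stop("one_to_one correspondence requires equal lengths")
    return(cbind(a = seq_len(na), b = seq_len(nb)))
  }
  if (is.null(seq_a) || is.null(seq_b)) {
    stop("sequence_align mode needs seq_a and seq_b")
  }
  if (nchar(seq_a) != na || nchar(seq_b) != nb) {
    stop("sequence length does not match coordinate count")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  if (!any(keep)) stop("empty correspondence between the two sequences")
  cbind(a = ia[keep], b = ib[keep])
}

#' Superposition RMSD for every paralog pair of a structure
#'
#' @param chains Named list of [coord_set()]s, one per subunit.
#' @param paralog_map A [paralog_map()].
#' @param sequences Optional named character vector of subunit sequences;
#'   when given, correspondence uses `sequence_align`, otherwise
#'   `one_to_one` (requiring equal chain lengths).
#' @return `data.frame` with one row per pair: `pair`, `subunit_a`,
#'   `subunit_b`, `rmsd`, `n_pairs`, `status` (`ok` or the failure
#'   reason; failed pairs are reported, never dropped).
#' @export
paralog_rmsd_table <- function(chains, paralog_map, sequences = NULL) {
  pairs <- unique(paralog_map$pairs$pair)
  rows <- lapply(pairs, function(p) {
    mem <- paralog_map$pairs$subunit[paralog_map$pairs$pair == p]
    a <- mem[1L]; b <- mem[2L]
    row <- data.frame(pair = p, subunit_a = a, subunit_b = b,
                      rmsd = NA_real_, n_pairs = NA_integer_,
                      status = "ok")
    miss <- setdiff(c(a, b), names(chains))
    if (length(miss)) {
      stop("chain missing from structure for subunit: ",
           paste(miss, collapse = ", "))
    }
    res <- tryCatch({
      corr <- if (is.null(sequences)) {
        pair_correspondence(chains[[a]], chains[[b]], mode = "one_to_one")
      } else {
        pair_correspondence(chains[[a]], chains[[b]],
                            sequences[[a]], sequences[[b]],
                            mode = "sequence_align")
      }
      sup <- kabsch_superpose(.as_xyz(chains[[a]])[corr[, 1L], , drop = FALSE],
                              .as_xyz(chains[[b]])[corr[, 2L], , drop = FALSE])
      row$rmsd <- sup$rmsd; row$n_pairs <- sup$n_pairs
      row
    }, error = function(e) {
      row$status <- conditionMessage(e)
      row
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
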