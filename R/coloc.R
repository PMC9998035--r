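#' Per-species scaffold-sharing classification of complex genes
#'
#' Classifies each species with at least two located subunit genes by how
#' its loci distribute over scaffolds: `all_distinct` (one scaffold per
#' gene), `single_scaffold` (all genes on one scaffold), or
#' `partial_shared`. Species with fewer than two loci are reported as
#' `insufficient`, never silently dropped.
#'
#' @param loci Locus `data.frame` as from [read_loci_tsv()] or
#'   [simulate_loci()].
#' @param subunits Optional subset of subunits to consider.
#' @return List: `per_species` data.frame (species, n_loci, n_scaffolds,
#'   class) and `counts` (named integer vector of class totals over
#'   species with sufficient loci).
#' @export
scaffold_sharing_summary <- function(loci, subunits = NULL) {
  if (!is.null(subunits)) loci <- loci[loci$subunit %in% subunits, ]
  sp <- unique(loci$species)
  per <- do.call(rbind, lapply(sp, function(s) {
    sub <- loci[loci$species == s, ]
    n <- nrow(sub); k <- length(unique(sub$scaffold))
    cls <- if (n < 2L) "insufficient"
    else if (k == n) "all_distinct"
    else if (k == 1L) "single_scaffold"
    else "partial_shared"
    data.frame(species = s, n_loci = n, n_scaffolds = k, class = cls)
  }))
  rownames(per) <- NULL
  lev <- c("all_distinct", "partial_shared", "single_scaffold")
  counts <- table(factor(per$class[per$class != "insufficient"],
                         levels = lev))
  list(per_species = per, counts = c(counts),
       n_sufficient = sum(per$class != "insufficient"),
       n_insufficient = sum(per$class == "insufficient"))
}

#' Pairwise intergenic distances for genes sharing a scaffold
#'
#' The distance between two loci on the same scaffold is the intergenic
#' gap `max(0, later.start - earlier.end)`; overlapping or adjacent genes
#' get distance 0 with an overlap flag. Midpoint distance is also
#' emitted since "distance apart" is ambiguous in the literature.
#'
#' @inheritParams scaffold_sharing_summary
#' @return List: `pairs` data.frame (species, scaffold, subunit_a,
#'   subunit_b, gap_bp, midpoint_bp, overlap) and `mean_gap_bp` over all
#'   same-scaffold pairs across species (`NaN` if none).
#' @export
same_scaffold_distances <- function(loci, subunits = NULL) {
  if (!is.null(subunits)) loci <- loci[loci$subunit %in% subunits, ]
  rows <- list()
  for (s in unique(loci$species)) {
    sub <- loci[loci$species == s, ]
    for (scf in unique(sub$scaffold)) {
      g <- sub[sub$scaffold == scf, ]
      if (nrow(g) < 2L) next
      g <- g[order(g$start), ]
      for (i in seq_len(nrow(g) - 1L)) {
        for (j in (i + 1L):nrow(g)) {
          gap <- max(0, g$start[j] - g$end[i])
          mid <- abs((g$start[j] + g$end[j]) / 2 -
                       (g$start[i] + g$end[i]) / 2)
          rows[[length(rows) + 1L]] <- data.frame(
            species = s, scaffold = scf,
            subunit_a = g$subunit[i], subunit_b = g$subunit[j],
            gap_bp = gap, midpoint_bp = mid,
            overlap = g$start[j] < g$end[i])
        }
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), scaffold = character(0),
               subunit_a = character(0), subunit_b = character(0),
               gap_bp = numeric(0), midpoint_bp = numeric(0),
               overlap = logical(0))
  list(pairs = pairs, mean_gap_bp = mean(pairs$gap_bp),
       mean_midpoint_bp = mean(pairs$midpoint_bp))
}

#' Co-localization verdict for a complex's genes
#'
#' Declares the complex "clustered" (a layout compatible with wholesale
#' horizontal transfer) only when a majority of classifiable species have
#' all genes on a single scaffold AND the mean same-scaffold intergenic
#' gap is below `max_mean_gap_bp`; otherwise "dispersed". Thresholds are
#' echoed in the output.
#'
#' @param sharing A [scaffold_sharing_summary()] result.
#' @param distances A [same_scaffold_distances()] result.
#' @param majority Required single-scaffold species fraction (default 0.5).
#' @param max_mean_gap_bp Maximum mean gap for clustering (default 1e5).
#' @return List: `verdict` ("clustered"/"dispersed"), `frac_single_scaffold`,
#'   `mean_gap_bp`, `thresholds`, `text` (one-line report).
#' @export
colocalization_verdict <- function(sharing, distances, majority = 0.5,
                                   max_mean_gap_bp = 1e5) {
  frac_single <- if (sharing$n_sufficient > 0)
    unname(sharing$counts["single_scaffold"]) / sharing$n_sufficient else 0
  gap <- distances$mean_gap_bp
  clustered <- isTRUE(frac_single > majority) &&
    isTRUE(!is.nan(gap) && gap < max_mean_gap_bp)
  verdict <- if (clustered) "clustered" else "dispersed"
  list(verdict = verdict,
       frac_single_scaffold = frac_single,
       mean_gap_bp = gap,
       thresholds = c(majority = majority,
                      max_mean_gap_bp = max_mean_gap_bp),
       text = sprintf(
         paste0("%d/%d species single-scaffold (%.2f); mean same-scaffold ",
                "gap %.0f bp; verdict (majority > %.2f, gap < %.0f bp): %s"),
         unname(sharing$counts["single_scaffold"]), sharing$n_sufficient,
         frac_single, if (is.nan(gap)) NA else gap, majority,
         max_mean_gap_bp, verdict))
}
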