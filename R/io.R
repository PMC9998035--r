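#' Read protein sequences or alignments from FASTA
#'
#' Sequences are upper-cased and '.' gap characters are normalized to '-'
#' so that externally produced alignments (which often mix the two) can be
#' consumed directly.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (possibly rooted) tree from a newick file
#'
#' Internal node labels are kept and, where numeric, are interpreted as
#' support values (stored in `tree$node.label` as `ape` does).
#'
#' @param path Path to a newick file.
#' @param rooted If `TRUE`, a basal bifurcation is accepted and preserved.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, rooted = FALSE) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unmatched parentheses in ", path, " (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("newick parse failure in ", path)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf label(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (rooted && !ape::is.rooted(tree)) {
    stop("tree in ", path, " is unrooted but rooted input was required")
  }
  tree
}

#' Write a tree as newick text
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the newick string is
#'   returned instead of written.
#' @param digits Significant digits for branch lengths (>= 10 preserves the
#'   round-trip contract).
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Default complex definitions for a Dam1-C/Ska-C style screen
#'
#' Ten Dam1-C subunits, three Ska-C subunits, and `Ndc80` as the
#' conditioning gene (a kinetochore protein expected in every informative
#' species, used to restrict co-occurrence denominators).
#'
#' @return Named list of subunit character vectors.
#' @export
default_complexes <- function() {
  list(
    Dam1C = c("Dad1", "Dad2", "Dad3", "Dad4", "Dam1", "Duo1", "Ask1",
              "Hsk3", "Spc19", "Spc34"),
    SkaC = c("Ska1", "Ska2", "Ska3")
  )
}

#' Construct a presence/absence matrix object
#'
#' @param states Character matrix (species x subunit) with cells in
#'   `present`, `absent`, `unknown`.
#' @param complexes Named list mapping complex name to subunit columns.
#' @param conditioning Name of the conditioning gene column (default
#'   `"Ndc80"`); may be `NA` when no conditioning column exists.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(states, complexes = default_complexes(),
                            conditioning = "Ndc80") {
  stopifnot(is.matrix(states), !is.null(rownames(states)),
            !is.null(colnames(states)))
  if (anyDuplicated(rownames(states))) stop("duplicate species in matrix")
  bad <- setdiff(unique(as.vector(states)), c("present", "absent", "unknown"))
  if (length(bad)) stop("invalid presence state(s): ", paste(bad, collapse = ", "))
  for (cx in names(complexes)) {
    miss <- setdiff(complexes[[cx]], colnames(states))
    if (length(miss)) {
      stop("complex ", cx, " subunit(s) missing from matrix: ",
           paste(miss, collapse = ", "))
    }
  }
  if (!is.na(conditioning) && !conditioning %in% colnames(states)) {
    stop("conditioning gene column not in matrix: ", conditioning)
  }
  structure(list(states = states, complexes = complexes,
                 conditioning = conditioning),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$states), "species x", ncol(x$states),
      "genes\n")
  cat("complexes:",
      paste(sprintf("%s (%d subunits)", names(x$complexes),
                    lengths(x$complexes)), collapse = ", "), "\n")
  cat("conditioning gene:", x$conditioning, "\n")
  tab <- table(factor(x$states, levels = c("present", "absent", "unknown")))
  cat("cells:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a presence/absence TSV into a `presence_matrix`
#'
#' First column is the species id; remaining columns are genes. Cells may
#' be `1/0`, `yes/no` (case-insensitive) or `NA`; `NA` maps to `unknown`
#' (absence of evidence, e.g. from an incomplete transcriptome, is not
#' evidence of absence and is excluded from denominators downstream).
#'
#' @inheritParams presence_matrix
#' @param path Path to the TSV.
#' @return A `presence_matrix`.
#' @export
read_presence_tsv <- function(path, complexes = default_complexes(),
                              conditioning = "Ndc80") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L) stop("presence TSV needs a species column plus genes: ", path)
  species <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  map_cell <- function(v) {
    v <- tolower(trimws(v))
    out <- rep(NA_character_, length(v))
    out[v %in% c("1", "yes", "present", "true")] <- "present"
    out[v %in% c("0", "no", "absent", "false")] <- "absent"
    out[v %in% c("na", "", "?", "unknown")] <- "unknown"
    out
  }
  states <- apply(cells, 2L, map_cell)
  if (anyNA(states)) {
    bad <- which(is.na(states), arr.ind = TRUE)[1L, ]
    stop("unparseable presence cell in ", path, " at data row ", bad[1L],
         ", column '", colnames(cells)[bad[2L]], "'")
  }
  dimnames(states) <- list(species, colnames(cells))
  presence_matrix(states, complexes = complexes, conditioning = conditioning)
}

#' Read a profile-vs-profile E-value matrix from TSV
#'
#' Row names are query profiles, column headers target profiles. Scientific
#' notation is accepted; empty cells are `NA` (no reported hit).
#'
#' @param path Path to the TSV (first column = query labels).
#' @return Numeric matrix of E-values.
#' @export
read_evalue_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  q <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !(trimws(cells) %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric E-value in ", path, " at data row ", bad[1L, 1L],
         ", column '", colnames(cells)[bad[1L, 2L]], "': '",
         cells[bad[1L, , drop = FALSE]], "'")
  }
  if (any(num < 0, na.rm = TRUE)) stop("negative E-value in ", path)
  dimnames(num) <- list(q, colnames(cells))
  num
}

#' Read a BED-like gene locus table
#'
#' Columns: `species`, `subunit`, `scaffold`, `start`, `end`, `strand`
#' (header required). Coordinates are 0-based, half-open.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with typed columns.
#' @export
read_loci_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("species", "subunit", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("loci TSV missing column(s): ", paste(miss, collapse = ", "))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- which(!(df$end > df$start))
  if (length(bad)) {
    stop("locus with end <= start in ", path, " at data row ", bad[1L])
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("invalid strand value in ", path, " (must be +, - or .)")
  }
  if (anyDuplicated(df[, c("species", "subunit")])) {
    stop("duplicate (species, subunit) locus in ", path)
  }
  df[, need]
}

#' Read C-alpha coordinates from a PDB file
#'
#' Keeps the first altLoc of each residue and orders by residue number;
#' 1-based residue numbering from the PDB records is preserved.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; `NULL` takes the whole file.
#' @return A `coord_set`: list with `xyz` (n x 3 matrix, Angstrom),
#'   `resno`, `resid` (3-letter codes), `chain`.
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  keep <- atoms$elety == "CA" & atoms$type == "ATOM"
  if (!is.null(chain)) {
    if (!chain %in% atoms$chain) stop("chain not found in ", path, ": ", chain)
    keep <- keep & atoms$chain == chain
  }
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no CA atoms", if (!is.null(chain)) paste0(" for chain ", chain), " in ", path)
  atoms <- atoms[!duplicated(atoms$resno), , drop = FALSE]  # first altLoc wins
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  coord_set(as.matrix(atoms[, c("x", "y", "z")]), resno = atoms$resno,
            resid = atoms$resid, chain = if (is.null(chain)) atoms$chain[1L] else chain)
}

#' Construct a C-alpha coordinate set
#'
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param resno Residue numbers (default `1:n`).
#' @param resid Residue 3-letter codes (optional).
#' @param chain Chain id.
#' @return `coord_set` object.
#' @export
coord_set <- function(xyz, resno = seq_len(nrow(xyz)), resid = NULL,
                      chain = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  structure(list(xyz = unname(xyz), resno = resno, resid = resid,
                 chain = chain),
            class = "coord_set")
}

#' @export
print.coord_set <- function(x, ...) {
  cat("coord_set: ", nrow(x$xyz), " CA atoms, chain ", x$chain, "\n", sep = "")
  invisible(x)
}

#' Analysis configuration with the pipeline's tunable thresholds
#'
#' Defaults encode the screening rules used throughout: ortholog-inclusion
#' E-value 1e-3 with >= 4 subunits for dataset inclusion, permissive
#' network E-value 10 for deep-homology edges, >= 2 subunits per arm for
#' the rooted concatenation, and gap-threshold trimming keeping columns
#' with >= 5% residues.
#'
#' @param evalue_inclusion_threshold E-value cutoff for calling an ortholog
#'   detection trustworthy (default `1e-3`).
#' @param evalue_network_threshold Permissive E-value cutoff for
#'   profile-vs-profile homology edges (default `10`).
#' @param min_subunits_for_species_inclusion Minimum detected subunits for
#'   a species to enter the dataset (default `4`).
#' @param min_subunits_per_arm Minimum subunits per arm for the rooted
#'   supermatrix (default `2`).
#' @param trim_keep_fraction Keep an alignment column iff its residue
#'   (non-gap) fraction is at least this value (default `0.05`).
#' @param rng_seed Integer seed recorded with every stochastic stage.
#' @param substitution_model `"POISSON"` or `"LG"`.
#' @param frequencies `"model"` or `"empirical"` (+F).
#' @param rates `"uniform"` or `"gamma"`.
#' @param gamma_classes Number of discrete gamma classes (default 4).
#' @param rell_replicates RELL bootstrap replicates (default 1000).
#' @param au_scales Multiscale bootstrap scales; strictly increasing and
#'   containing 1 (default `seq(0.5, 1.4, by = 0.1)`).
#' @return `analysis_config` object (validated list).
#' @export
analysis_config <- function(evalue_inclusion_threshold = 1e-3,
                            evalue_network_threshold = 10,
                            min_subunits_for_species_inclusion = 4L,
                            min_subunits_per_arm = 2L,
                            trim_keep_fraction = 0.05,
                            rng_seed = 1L,
                            substitution_model = c("POISSON", "LG"),
                            frequencies = c("model", "empirical"),
                            rates = c("uniform", "gamma"),
                            gamma_classes = 4L,
                            rell_replicates = 1000L,
                            au_scales = seq(0.5, 1.4, by = 0.1)) {
  substitution_model <- match.arg(substitution_model)
  frequencies <- match.arg(frequencies)
  rates <- match.arg(rates)
  stopifnot(evalue_inclusion_threshold > 0, evalue_network_threshold > 0,
            min_subunits_for_species_inclusion >= 1,
            min_subunits_per_arm >= 1,
            trim_keep_fraction > 0, trim_keep_fraction <= 1,
            rell_replicates >= 1)
  if (any(diff(au_scales) <= 0)) stop("au_scales must be strictly increasing")
  if (!any(abs(au_scales - 1) < 1e-12)) stop("au_scales must contain 1.0")
  structure(as.list(environment()), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) cat("  ", k, " = ", paste(format(x[[k]]), collapse = " "),
                          "\n", sep = "")
  invisible(x)
}
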