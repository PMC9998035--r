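#' Amino-acid substitution model specification
#'
#' A reversible 20-state continuous-time Markov model built from an
#' exchangeability matrix (`POISSON`: all exchanges equal; `LG`: the
#' Le-Gascuel empirical matrix, constants taken from phangorn) and
#' equilibrium frequencies (`model`: the matrix's own, uniform for
#' POISSON; `empirical`: +F, estimated from data via
#' [empirical_frequencies()]). Among-site rate variation is either
#' uniform or a discrete gamma mixture with `gamma_classes` equal-weight
#' classes and shape `alpha`. The rate matrix is normalized to one
#' expected substitution per unit branch length.
#'
#' @param exchangeability `"POISSON"` or `"LG"`.
#' @param frequencies `"model"` or `"empirical"`.
#' @param rates `"uniform"` or `"gamma"`.
#' @param gamma_classes Number of discrete gamma classes (default 4).
#' @param alpha Gamma shape (default 1).
#' @param empirical_freqs Length-20 frequency vector (required when
#'   `frequencies = "empirical"`); see [empirical_frequencies()].
#' @return `phylo_model` object with the eigendecomposition cached for
#'   fast transition matrices.
#' @export
phylo_model <- function(exchangeability = c("POISSON", "LG"),
                        frequencies = c("model", "empirical"),
                        rates = c("uniform", "gamma"),
                        gamma_classes = 4L, alpha = 1,
                        empirical_freqs = NULL) {
  exchangeability <- match.arg(exchangeability)
  frequencies <- match.arg(frequencies)
  rates <- match.arg(rates)
  aa <- .aa_alphabet()
  n <- length(aa)
  if (exchangeability == "POISSON") {
    S <- matrix(1, n, n); diag(S) <- 0
    pi_model <- rep(1 / n, n)
  } else {
    lg <- utils::getFromNamespace(".LG", "phangorn")
    S <- matrix(0, n, n)
    S[lower.tri(S)] <- lg$Q
    S <- S + t(S)
    pi_model <- unname(lg$bf)
  }
  pi <- if (frequencies == "empirical") {
    if (is.null(empirical_freqs)) {
      stop("frequencies = 'empirical' needs empirical_freqs (+F)")
    }
    stopifnot(length(empirical_freqs) == n)
    empirical_freqs / sum(empirical_freqs)
  } else {
    pi_model
  }
  if (abs(sum(pi) - 1) > 1e-12) pi <- pi / sum(pi)
  Q <- S * rep(pi, each = n)   # Q[i, j] = S[i, j] * pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetrize for a stable eigendecomposition (reversibility)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- eig$vectors / sq         # rows scaled by 1/sqrt(pi)
  Vi <- t(eig$vectors) * rep(sq, each = n)
  class_rates <- if (rates == "gamma") {
    phangorn::discrete.gamma(alpha, gamma_classes)
  } else 1
  class_weights <- rep(1 / length(class_rates), length(class_rates))
  structure(list(exchangeability = exchangeability,
                 frequencies = frequencies, rates = rates,
                 alpha = alpha, alphabet = aa, pi = pi,
                 Q = Q, eigen_values = eig$values, V = V, Vi = Vi,
                 class_rates = class_rates,
                 class_weights = class_weights),
            class = "phylo_model")
}

#' @export
print.phylo_model <- function(x, ...) {
  rate_txt <- if (x$rates == "gamma") {
    sprintf("gamma(%d classes, alpha = %g)", length(x$class_rates), x$alpha)
  } else "uniform"
  cat(sprintf("phylo_model: %s + %s frequencies, %s rates\n",
              x$exchangeability,
              if (x$frequencies == "empirical") "empirical (+F)" else "model",
              rate_txt))
  invisible(x)
}

#' Transition probability matrix P(t) for a model
#'
#' @param model A [phylo_model()].
#' @param t Branch length (expected substitutions per site).
#' @param rate Rate multiplier (gamma class rate).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  e <- exp(model$eigen_values * t * rate)
  P <- model$V %*% (e * model$Vi)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Empirical amino-acid frequencies of an alignment (+F)
#'
#' @param alignment Named character vector of (aligned) sequences.
#' @param pseudocount Added per residue class to avoid zeros (default 1).
#' @return Length-20 frequency vector in the model's alphabet order.
#' @export
empirical_frequencies <- function(alignment, pseudocount = 1) {
  aa <- .aa_alphabet()
  chars <- unlist(strsplit(toupper(alignment), ""))
  counts <- table(factor(chars[chars %in% aa], levels = aa))
  f <- as.numeric(counts) + pseudocount
  f / sum(f)
}

# alignment -> integer state matrix (taxa x sites); NA = gap/ambiguous
.encode_alignment <- function(alignment, alphabet) {
  mat <- .aln_mat(toupper(alignment))
  idx <- match(mat, alphabet)
  dim(idx) <- dim(mat)
  rownames(idx) <- rownames(mat)
  idx
}
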