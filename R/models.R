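#' Substitution models
#'
#' Builds a reversible continuous-time Markov substitution model. Two kinds
#' are supported: `poisson_equal` (all exchangeabilities and frequencies
#' equal -- the amino-acid analogue of Jukes-Cantor) and `empirical`
#' (exchangeabilities and frequencies from a PAML-format data file, e.g. the
#' bundled JTT matrix). The rate matrix is `Q = S diag(pi)` rescaled so the
#' expected rate at equilibrium is 1 substitution per site per unit branch
#' length. Optional discrete-gamma rate variation uses `n_rate_categories`
#' equal-probability categories with category means (Yang's discrete
#' approximation).
#'
#' @param kind `"poisson_equal"`, `"empirical"`, or `"nucleotide"` (a
#'   4-state equal-rate model used for nucleotide-level ancestral states).
#' @param paml_file Path to a PAML-format rate file (required for
#'   `kind = "empirical"`); defaults to the bundled JTT file.
#' @param gamma_shape Positive shape of gamma rate variation, or `NULL`.
#' @param n_rate_categories Number of discrete gamma categories (>= 1).
#' @return A `subst_model`: list with `kind`, `states`, `exchangeability`,
#'   `frequencies`, `Q`, eigendecomposition fields, `gamma_shape`,
#'   `n_rate_categories`, `rates`, `rate_weights`.
#' @export
#' @examples
#' m <- subst_model("poisson_equal")
#' rowSums(transition_matrix(m, 0.1))  # all 1
subst_model <- function(kind = c("poisson_equal", "empirical", "nucleotide"),
                        paml_file = NULL, gamma_shape = NULL,
                        n_rate_categories = if (is.null(gamma_shape)) 1L else 4L) {
  kind <- match.arg(kind)
  if (kind == "empirical") {
    if (is.null(paml_file))
      paml_file <- system.file("extdata", "jtt.dat", package = "bitterevo")
    dat <- read_paml_dat(paml_file)
    S <- dat$exchangeability
    pi <- dat$frequencies
    states <- AA_STATES
  } else if (kind == "poisson_equal") {
    states <- AA_STATES
    n <- length(states)
    S <- matrix(1, n, n); diag(S) <- 0
    pi <- rep(1 / n, n)
  } else {
    states <- NT_STATES
    S <- matrix(1, 4, 4); diag(S) <- 0
    pi <- rep(0.25, 4)
  }
  dimnames(S) <- list(states, states)
  names(pi) <- states
  if (abs(sum(pi) - 1) > 1e-8) stop("frequencies do not sum to 1")
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetric decomposition of the reversible generator
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / sp) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(sp)
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0, n_rate_categories >= 1)
    rates <- discrete_gamma_rates(gamma_shape, n_rate_categories)
  } else {
    n_rate_categories <- as.integer(n_rate_categories)
    rates <- rep(1, n_rate_categories)
  }
  structure(list(kind = kind, states = states, exchangeability = S,
                 frequencies = pi, Q = Q, U = U, Uinv = Uinv,
                 lambda = eig$values, gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 rates = rates,
                 rate_weights = rep(1 / length(rates), length(rates))),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %s, %d states%s\n", x$kind, length(x$states),
              if (!is.null(x$gamma_shape))
                sprintf(", +G(shape=%.3g, %d categories)", x$gamma_shape,
                        x$n_rate_categories) else ""))
  invisible(x)
}

#' Read a PAML-format amino-acid rate file
#'
#' The PAML `dat` layout: 19 lines holding the lower triangle of the 20x20
#' symmetric exchangeability matrix (row 2 has 1 entry ... row 20 has 19),
#' followed by the 20 equilibrium frequencies. Comments/extra text after the
#' numbers are ignored.
#'
#' @param path File path.
#' @return List with `exchangeability` (20x20 symmetric) and `frequencies`
#'   (named numeric, normalized to sum to 1).
#' @export
read_paml_dat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  nums <- suppressWarnings(as.numeric(unlist(strsplit(
    paste(txt, collapse = " "), "\\s+"))))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 190 + 20)
    stop("PAML file holds ", length(nums),
         " numbers; need 190 rates + 20 frequencies")
  rates <- nums[1:190]
  freqs <- nums[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- rates[k]
    k <- k + 1L
  }
  freqs <- freqs / sum(freqs)
  list(exchangeability = S, frequencies = setNames(freqs, AA_STATES))
}

# Discrete gamma category means (k equal-probability bins, mean-normalized).
discrete_gamma_rates <- function(shape, k) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  brk <- qgamma(seq_len(k - 1) / k, shape = shape, rate = shape)
  brk <- c(0, brk, Inf)
  # mean of X in (b0,b1] for X~Gamma(a,a): k*(F_{a+1}(b1)-F_{a+1}(b0))
  means <- k * (pgamma(brk[-1], shape + 1, shape) -
                pgamma(brk[-(k + 1)], shape + 1, shape))
  means / mean(means) * 1  # exact mean 1 up to rounding
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the eigendecomposition of the reversible generator; rows
#' sum to one and `P(0)` is the identity. Satisfies the Chapman-Kolmogorov
#' semigroup property.
#'
#' @param model A [subst_model()].
#' @param t Branch length (substitutions/site), `t >= 0`.
#' @param rate Optional rate multiplier (gamma category or lineage rate).
#' @return `n x n` matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (t < 0) stop("branch length must be >= 0, got ", t)
  P <- model$U %*% (exp(model$lambda * t * rate) * model$Uinv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}
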