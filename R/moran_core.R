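#' Population configuration for the Moran process
#'
#' @param N population size, an integer >= 2 (number of individuals).
#' @param beta intensity of selection, a nonnegative real. \code{beta = 0} is
#'   neutral drift; \code{beta = Inf} is routed to the exact strong-selection
#'   limit rather than evaluated at a large finite value.
#' @return an object of class \code{moran_population}.
#' @export
moran_population <- function(N, beta) {
  if (length(N) != 1 || is.na(N) || N < 2 || N != round(N)) {
    stop("N must be a single integer >= 2")
  }
  if (length(beta) != 1 || is.na(beta) || beta < 0) {
    stop("beta must be a single nonnegative number")
  }
  structure(list(N = as.integer(N), beta = as.numeric(beta)),
            class = "moran_population")
}

#' @export
print.moran_population <- function(x, ...) {
  cat("Moran population: N =", x$N, ", beta =", x$beta, "\n")
  invisible(x)
}

#' Expected payoffs in a two-strategy population state
#'
#' In a population of \code{N} individuals holding \code{i} copies of strategy
#' \code{a} and \code{N - i} of strategy \code{b}, each individual plays every
#' other individual but not itself, so payoffs are averaged over the
#' \code{N - 1} co-players:
#' \deqn{\pi_a(i) = \frac{a_{aa}(i-1) + a_{ab}(N-i)}{N-1}, \qquad
#'       \pi_b(i) = \frac{a_{ba} i + a_{bb}(N-i-1)}{N-1}.}
#'
#' @param game a [payoff_matrix()].
#' @param a,b strategy labels or indices (the pair under consideration).
#' @param i number of \code{a}-individuals, \code{0 <= i <= N}; may be a
#'   vector.
#' @param N population size.
#' @return a two-column matrix with columns \code{pi_a}, \code{pi_b}, one row
#'   per value of \code{i} (dropped to a length-2 vector for scalar \code{i}).
#' @export
expected_payoffs <- function(game, a, b, i, N) {
  if (N < 2) stop("N must be at least 2")
  if (any(i < 0 | i > N)) stop("i must lie in [0, N]")
  ia <- strategy_index(game, a)
  ib <- strategy_index(game, b)
  pa <- (game[ia, ia] * (i - 1) + game[ia, ib] * (N - i)) / (N - 1)
  pb <- (game[ib, ia] * i + game[ib, ib] * (N - i - 1)) / (N - 1)
  out <- cbind(pi_a = pa, pi_b = pb)
  if (length(i) == 1) out[1, ] else out
}

# Payoff-difference profile for one invader pair: delta[i] = pi_inv(i) -
# pi_res(i) for i = 1..N-1 invaders. Fixation probabilities under the
# exponential fitness mapping depend on the pair only through this profile.
pair_delta <- function(game, invader, resident, N) {
  i <- seq_len(N - 1)
  p <- expected_payoffs(game, invader, resident, i, N)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p[, 1] - p[, 2]
}

# log(1 + exp(x)) without overflow.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fixation probability from a payoff-difference profile
#'
#' Core birth--death computation: for a single invader among \code{N - 1}
#' residents, with the exponential payoff-to-fitness mapping
#' \eqn{f = e^{\beta \pi}}, the backward/forward transition ratio at \code{i}
#' invaders is \eqn{e^{-\beta \Delta\pi(i)}}, giving
#' \deqn{\rho = \frac{1}{1 + \sum_{k=1}^{N-1} e^{-\beta S_k}}, \qquad
#'       S_k = \sum_{i=1}^{k} \Delta\pi(i).}
#' Evaluated entirely in log space (cumulative sums plus a max-shifted
#' log-sum-exp), so no overflow occurs even for \eqn{\beta |\pi| N} of order
#' \eqn{10^4}.
#'
#' @param delta numeric vector of payoff differences
#'   \eqn{\Delta\pi(i) = \pi_{inv}(i) - \pi_{res}(i)} for \code{i = 1..N-1}.
#' @param beta intensity of selection (\code{Inf} routes to
#'   [strong_fixation_from_delta()]).
#' @return the fixation probability, in \code{[0, 1]}.
#' @export
fixation_from_delta <- function(delta, beta) {
  if (is.infinite(beta)) return(strong_fixation_from_delta(delta))
  exp(log_fixation_from_delta(delta, beta))
}

# log of the fixation probability; stays finite (never -Inf from underflow)
# even when rho itself underflows, which the abundance margins rely on.
log_fixation_from_delta <- function(delta, beta) {
  if (!all(is.finite(delta))) stop("payoff differences must be finite")
  S <- cumsum(delta)
  -log1pexp(logsumexp(-beta * S))
}

#' Strong-selection limit of the fixation probability
#'
#' Exact combinatorial limit of [fixation_from_delta()] as
#' \eqn{\beta \to \infty}: with cumulative sums \eqn{S_k}, the probability is
#' 0 if any \eqn{S_k < 0}, and otherwise \eqn{1 / (1 + \#\{k : S_k = 0\})}.
#' Equality is decided with tolerance \code{1e-12 * max(1, scale)} because
#' neutral payoff paths (e.g. punisher vs cooperator with no defectors
#' present) arise from exactly equal payoffs, not near-equality.
#'
#' @param delta payoff-difference profile as in [fixation_from_delta()].
#' @param scale magnitude of the payoffs involved, used to set the equality
#'   tolerance.
#' @return the limiting fixation probability.
#' @export
strong_fixation_from_delta <- function(delta, scale = max(1, abs(delta))) {
  S <- cumsum(delta)
  tol <- 1e-12 * max(1, scale)
  if (any(S < -tol)) return(0)
  1 / (1 + sum(abs(S) <= tol))
}

#' Fixation probability of a single mutant under the Moran process
#'
#' Probability that one \code{invader} individual takes over a population of
#' \code{N - 1} \code{resident}s, with fitness \eqn{f = e^{\beta\pi}} and
#' self-interaction excluded from payoffs. \code{beta = 0} returns exactly
#' \code{1/N} (neutral drift); \code{beta = Inf} is evaluated by the exact
#' strong-selection limit.
#'
#' @inheritParams expected_payoffs
#' @param invader,resident distinct strategy labels or indices.
#' @param pop a [moran_population()].
#' @return the fixation probability \eqn{\rho \in [0, 1]}.
#' @examples
#' g <- payoff_matrix(rbind(c(3, 0), c(5, 1)), labels = c("C", "D"))
#' fixation_probability(g, "D", "C", moran_population(50, 1))
#' @export
fixation_probability <- function(game, invader, resident, pop) {
  stopifnot(inherits(pop, "moran_population"))
  if (strategy_index(game, invader) == strategy_index(game, resident)) {
    stop("invader and resident must be distinct strategies")
  }
  delta <- pair_delta(game, invader, resident, pop$N)
  if (is.infinite(pop$beta)) {
    return(strong_fixation_from_delta(delta, scale = max(abs(game))))
  }
  fixation_from_delta(delta, pop$beta)
}

#' Strong-selection fixation probability for a matrix game
#'
#' @inheritParams fixation_probability
#' @param N population size.
#' @return the \eqn{\beta \to \infty} fixation probability.
#' @export
strong_selection_fixation <- function(game, invader, resident, N) {
  delta <- pair_delta(game, invader, resident, N)
  strong_fixation_from_delta(delta, scale = max(abs(game)))
}

#' Pairwise fixation-probability matrix for a matrix game
#'
#' @inheritParams fixation_probability
#' @return an n x n matrix \code{rho} with \code{rho[a, b]} the probability
#'   that a single \code{b} mutant fixates in a population of \code{a}s;
#'   diagonal is \code{NA}.
#' @export
fixation_matrix <- function(game, pop) {
  n <- n_strategies(game)
  labs <- strategy_labels(game)
  rho <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) rho[a, b] <- fixation_probability(game, b, a, pop)
    }
  }
  rho
}
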