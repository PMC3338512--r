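#' Embedded Markov chain over monomorphic states
#'
#' In the rare-mutation limit the population is almost always monomorphic;
#' a mutant appears, fixates or goes extinct, and the next mutant only arises
#' afterwards. The dynamics then reduce to a Markov chain over the
#' monomorphic states with off-diagonal transition probabilities proportional
#' to (mutation probability a to b) times (fixation probability of one b
#' mutant among N - 1 a-residents):
#' \deqn{T_{ab} = s \, M_{ab} \, \rho_{ab}, \qquad T_{aa} = 1 - \sum_{b \ne a} T_{ab}.}
#' The positive constant \code{s} merely keeps rows valid probability vectors;
#' the stationary distribution is invariant to it.
#'
#' \code{embedded_chain_from_rho()} is the general builder taking a
#' precomputed fixation matrix (used by the public-goods systems, whose
#' payoffs are not bilinear); \code{embedded_chain()} is the convenience route
#' for matrix games.
#'
#' @param game a [payoff_matrix()].
#' @param kernel a [mutation_kernel()] of matching dimension.
#' @param pop a [moran_population()].
#' @param scale the row scale \code{s}; the default 1 is always valid since
#'   \code{rho <= 1} and kernel off-diagonal mass is at most 1.
#' @return an object of class \code{embedded_chain}: a list with the
#'   transition matrix \code{T}, the fixation matrix \code{rho}, the kernel,
#'   the scale and the state labels.
#' @export
embedded_chain <- function(game, kernel, pop, scale = 1) {
  if (n_strategies(game) != nrow(kernel)) {
    stop("kernel dimension must equal the number of strategies")
  }
  rho <- fixation_matrix(game, pop)
  embedded_chain_from_rho(rho, kernel, scale = scale)
}

#' @rdname embedded_chain
#' @param rho matrix of pairwise fixation probabilities, \code{rho[a, b]} the
#'   probability that one \code{b} mutant fixates among \code{a}s.
#' @export
embedded_chain_from_rho <- function(rho, kernel, scale = 1) {
  m <- nrow(kernel)
  if (!all(dim(rho) == m)) stop("rho and kernel dimensions disagree")
  if (!(scale > 0)) stop("scale must be positive")
  offdiag <- !diag(m)
  if (any(rho[offdiag] < 0 | rho[offdiag] > 1, na.rm = FALSE) ||
      any(!is.finite(rho[offdiag]))) {
    stop("off-diagonal fixation probabilities must lie in [0, 1]")
  }
  Tm <- scale * unclass(kernel) * rho
  diag(Tm) <- 0
  rs <- rowSums(Tm)
  if (any(rs > 1 + 1e-12)) {
    stop("internal error: scaled off-diagonal mass exceeds 1; choose a smaller scale")
  }
  diag(Tm) <- 1 - rs
  labs <- rownames(kernel)
  dimnames(Tm) <- list(labs, labs)
  off <- Tm
  diag(off) <- 0
  unreachable <- unreachable_states(off > 0)
  if (length(unreachable)) {
    stop("embedded chain is reducible; states not mutually reachable: ",
         paste(labs[unreachable], collapse = ", "))
  }
  structure(list(T = Tm, rho = rho, kernel = kernel, scale = scale,
                 labels = labs),
            class = "embedded_chain")
}

#' @export
print.embedded_chain <- function(x, ...) {
  cat("Embedded monomorphic-state chain over", length(x$labels),
      "strategies (row scale", format(x$scale), ")\n")
  print(x$T, ...)
  invisible(x)
}

#' Stationary distribution of an embedded chain
#'
#' Unique left fixed vector \eqn{\pi = \pi T}, normalised to sum one. Solved
#' deterministically as a null-space problem: the singular system
#' \eqn{(T' - I)\pi = 0} with one equation replaced by the normalisation
#' constraint. No random initialisation is involved; a numerically singular
#' solve (degenerate ties) fails loudly rather than returning an arbitrary
#' vector.
#'
#' @param chain an [embedded_chain()], or a row-stochastic matrix.
#' @return an object of class \code{stationary_distribution}: a named
#'   nonnegative vector summing to one.
#' @export
stationary_distribution <- function(chain) {
  Tm <- if (inherits(chain, "embedded_chain")) chain$T else as.matrix(chain)
  m <- nrow(Tm)
  if (m != ncol(Tm)) stop("transition matrix must be square")
  if (any(Tm < -1e-12) || any(abs(rowSums(Tm) - 1) > 1e-9)) {
    stop("input is not a row-stochastic matrix")
  }
  off <- Tm
  diag(off) <- 0
  unreachable <- unreachable_states(off > 0)
  if (length(unreachable)) {
    labs <- rownames(Tm)
    if (is.null(labs)) labs <- as.character(seq_len(m))
    stop("chain is reducible; states not mutually reachable: ",
         paste(labs[unreachable], collapse = ", "))
  }
  # Solve pi Q = 0 with the generator rebuilt from the off-diagonal mass:
  # recovering Q's diagonal as -(off-diagonal row sum) avoids the
  # cancellation in T_ii - 1 for near-identity chains, and rescaling by the
  # largest exit mass keeps the system well scaled against the
  # normalisation row. pi is shared by every chain I + s(T - I).
  off <- Tm
  diag(off) <- 0
  qd <- rowSums(off)
  s <- 0.5 / max(qd)
  A <- s * (t(off) - diag(qd))
  A[m, ] <- 1
  b <- c(rep(0, m - 1), 1)
  pi <- tryCatch({
    x <- solve(A, b)
    x + solve(A, b - A %*% x)  # one step of iterative refinement
  }, error = function(e) {
    stop("stationary solve failed (numerically ambiguous rank): ",
         conditionMessage(e))
  })
  pi <- drop(pi)
  if (any(pi < -1e-10)) stop("stationary solve produced negative probabilities")
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  resid <- max(abs(drop(pi %*% Tm) - pi))
  if (resid > 1e-10) {
    stop("stationary vector fails pi = pi T (residual ", format(resid), ")")
  }
  names(pi) <- rownames(Tm)
  structure(pi, class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, digits = 6, ...) {
  cat("Stationary distribution over", length(x), "monomorphic states\n")
  v <- as.numeric(x)
  names(v) <- names(x)
  print(round(v, digits), ...)
  invisible(x)
}

#' @export
summary.stationary_distribution <- function(object, ...) {
  ord <- order(as.numeric(object), decreasing = TRUE)
  data.frame(strategy = names(object)[ord],
             abundance = as.numeric(object)[ord],
             row.names = NULL)
}

#' Two-state closed form of the stationary distribution
#'
#' For two strategies the chain is reversible and the stationary distribution
#' has the closed form
#' \deqn{\pi_A = \frac{\mu_{BA}\rho_A}{\mu_{BA}\rho_A + \mu_{AB}\rho_B}}
#' where \eqn{\rho_A} is the fixation probability of a single A in a B
#' population. Used as an independent cross-check of the generic solver.
#'
#' @param mu_ab,mu_ba mutation probabilities A to B and B to A.
#' @param rho_a,rho_b fixation probabilities of a single A among Bs and a
#'   single B among As.
#' @return named vector \code{c(A = pi_A, B = pi_B)}.
#' @export
stationary_two_state <- function(mu_ab, mu_ba, rho_a, rho_b) {
  wa <- mu_ba * rho_a
  wb <- mu_ab * rho_b
  c(A = wa / (wa + wb), B = wb / (wa + wb))
}
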