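#' Construct a mutation kernel
#'
#' A mutation kernel is a row-stochastic matrix \code{M} of per-reproduction
#' mutation probabilities: \code{M[i, j]} is the probability that an offspring
#' copied from a strategy-\code{i} parent is of strategy \code{j}. The diagonal
#' carries the no-mutation mass, so rows sum to one exactly. Ergodicity of the
#' evolutionary process requires that every strategy be reachable from every
#' other through chains of mutations, i.e. the off-diagonal support graph must
#' be strongly connected; a kernel violating this is rejected at construction.
#'
#' @param M numeric n x n matrix with entries in \code{[0, 1]} and unit row
#'   sums (tolerance \code{1e-9}; rows are renormalised exactly afterwards).
#' @param rate overall mutation scale mu in \code{(0, 1)} used by the
#'   simulator; inferred as the largest off-diagonal row mass when omitted.
#' @param labels optional strategy names.
#' @return an object of class \code{mutation_kernel}.
#' @seealso [uniform_kernel()], [bitwise_kernel()], [loner_kernel()],
#'   [bitwise_kernel_24()]
#' @export
mutation_kernel <- function(M, rate = NULL, labels = NULL) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n != ncol(M) || n < 2) stop("mutation kernel must be square, n >= 2")
  if (!is.numeric(M) || !all(is.finite(M))) stop("kernel entries must be finite numbers")
  if (any(M < 0) || any(M > 1)) stop("kernel entries must lie in [0, 1]")
  if (is.null(labels)) {
    labels <- rownames(M)
    if (is.null(labels)) labels <- paste0("S", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) stop("need ", n, " unique labels")
  rs <- rowSums(M)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad)) {
    stop("kernel rows must sum to 1: row ", paste(labels[bad], collapse = ", "),
         " sums to ", paste(signif(rs[bad], 8), collapse = ", "))
  }
  M <- M / rs  # exact renormalisation of rounding slack
  off <- M
  diag(off) <- 0
  unreachable <- unreachable_states(off > 0)
  if (length(unreachable)) {
    stop("mutation kernel is not ergodic; states not mutually reachable: ",
         paste(labels[unreachable], collapse = ", "))
  }
  if (is.null(rate)) rate <- max(rowSums(off))
  if (!(rate > 0 && rate < 1)) stop("mutation rate must lie in (0, 1)")
  dimnames(M) <- list(labels, labels)
  structure(M, rate = rate, class = c("mutation_kernel", "matrix", "array"))
}

#' @export
print.mutation_kernel <- function(x, ...) {
  cat("Mutation kernel (", nrow(x), " strategies, rate mu = ",
      format(attr(x, "rate")), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

# States failing strong connectivity of a directed support graph, as indices.
# A directed graph is strongly connected iff some vertex reaches all others
# and is reached by all others.
unreachable_states <- function(adj) {
  n <- nrow(adj)
  fwd <- reach_from(adj, 1L)
  bwd <- reach_from(t(adj), 1L)
  which(!(fwd & bwd))
}

reach_from <- function(adj, v) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[v] <- TRUE
  frontier <- v
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Uniform mutation kernel
#'
#' Every strategy mutates to each of the other \code{n - 1} strategies with
#' the same probability \code{mu / (n - 1)}; no mutation with probability
#' \code{1 - mu}. This is the standard "model-less" assumption of evolutionary
#' game dynamics.
#'
#' @param n number of strategies (n >= 2).
#' @param mu overall mutation probability per reproduction, in (0, 1).
#' @param labels optional strategy names.
#' @return a [mutation_kernel()].
#' @export
uniform_kernel <- function(n, mu, labels = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  M <- matrix(mu / (n - 1), n, n)
  diag(M) <- 1 - mu
  mutation_kernel(M, rate = mu, labels = labels)
}
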