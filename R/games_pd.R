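#' The eight deterministic memory-one strategies of the repeated PD
#'
#' Each strategy is a 3-bit code \code{(first move, reply to C, reply to D)}
#' with 0 = cooperate, 1 = defect. The eight codes exhaust the deterministic
#' strategies conditioning on the opponent's last move. \code{TFTbar} and
#' \code{STFTbar} reverse the opponent's last move (the overbarred variants of
#' TFT and suspicious TFT).
#'
#' @return a data frame with columns \code{name}, \code{code} (binary string),
#'   \code{first}, \code{onC}, \code{onD} (bits), in standard 000..111 order.
#' @export
pd_strategies <- function() {
  bits <- expand.grid(onD = 0:1, onC = 0:1, first = 0:1)[, 3:1]
  names <- c("ALLC", "TFT", "TFTbar", "NALLD",
             "SALLC", "STFT", "STFTbar", "ALLD")
  data.frame(name = names,
             code = paste0(bits$first, bits$onC, bits$onD),
             first = bits$first, onC = bits$onC, onD = bits$onD,
             stringsAsFactors = FALSE)
}

# Accept a strategy as a name ("TFT"), a binary code ("001"), an index 1..8,
# or a 3-bit vector; return the corresponding row of pd_strategies().
pd_strategy <- function(s) {
  tab <- pd_strategies()
  if (is.numeric(s) && length(s) == 3) {
    s <- paste0(as.integer(s), collapse = "")
  }
  if (is.character(s)) {
    i <- match(s, tab$name)
    if (is.na(i)) i <- match(s, tab$code)
    if (is.na(i)) stop("unknown memory-one strategy: ", s)
  } else {
    i <- as.integer(s)
    if (is.na(i) || i < 1 || i > 8) stop("strategy index out of range")
  }
  tab[i, ]
}

#' Repeated prisoner's dilemma specification
#'
#' One-shot payoffs \code{R} (mutual cooperation), \code{S} (sucker),
#' \code{T} (temptation), \code{P} (mutual defection) with the dilemma
#' ordering \code{T > R > P > S} and \code{2R > T + S}, plus the continuation
#' probability \code{w}: after each round the game continues with probability
#' \code{w}, and repeated-game payoffs are the \code{(1 - w)}-normalised
#' discounted sums. Defaults are the classic Axelrod values.
#'
#' @param R,S,T,P one-shot payoffs.
#' @param w continuation probability in \code{[0, 1)}.
#' @return an object of class \code{rpd_spec}.
#' @export
rpd_spec <- function(R = 3, S = 0, T = 5, P = 1, w = 0.9) {
  if (!(w >= 0 && w < 1)) stop("continuation probability w must lie in [0, 1)")
  if (!(T > R && R > P && P > S)) {
    stop("payoffs must satisfy the prisoner's dilemma ordering T > R > P > S")
  }
  if (!(2 * R > T + S)) {
    stop("payoffs must satisfy 2R > T + S (mutual cooperation efficient)")
  }
  structure(list(R = R, S = S, T = T, P = P, w = w,
                 one_shot = matrix(c(R, T, S, P), 2, 2,
                                   dimnames = list(c("C", "D"), c("C", "D")))),
            class = "rpd_spec")
}

#' @export
print.rpd_spec <- function(x, ...) {
  cat("Repeated PD: (R, S, T, P) = (", x$R, ", ", x$S, ", ", x$T, ", ", x$P,
      "), w = ", x$w, "\n", sep = "")
  invisible(x)
}

#' Play two memory-one strategies against each other
#'
#' Iterates the two automata from their opening moves. Joint play is
#' deterministic on the joint last-action state, hence eventually periodic
#' with preperiod plus minimal cycle of at most five rounds; the trace is
#' found by detecting the first repeated joint state.
#'
#' @param s1,s2 strategies accepted by any of: canonical name (e.g. "TFT"), binary code,
#'   index 1..8, or 3-bit vector.
#' @return an object of class \code{play_trace}: a list with integer matrices
#'   \code{preperiod} and \code{cycle} (columns = the two players' actions,
#'   0 = C, 1 = D; \code{cycle} is the minimal period and is non-empty).
#' @examples
#' play("TFT", "ALLD")  # (C,D) once, then (D,D) forever
#' @export
play <- function(s1, s2) {
  p1 <- pd_strategy(s1)
  p2 <- pd_strategy(s2)
  reply <- function(p, opp_last) if (opp_last == 0) p$onC else p$onD
  a <- p1$first
  b <- p2$first
  states <- matrix(NA_integer_, 6, 2)
  seen <- integer(0)
  for (t in 1:6) {
    states[t, ] <- c(a, b)
    key <- a * 2L + b
    prev <- match(key, seen)
    if (!is.na(prev)) {
      pre <- states[seq_len(prev - 1), , drop = FALSE]
      cyc <- states[prev:(t - 1), , drop = FALSE]
      colnames(pre) <- colnames(cyc) <- c("p1", "p2")
      return(structure(list(preperiod = pre, cycle = cyc),
                       class = "play_trace"))
    }
    seen <- c(seen, key)
    a_new <- reply(p1, b)
    b <- reply(p2, a)
    a <- a_new
  }
  stop("internal error: no cycle within the joint state space")  # unreachable
}

#' @export
print.play_trace <- function(x, ...) {
  fmt <- function(m) {
    if (nrow(m) == 0) return("-")
    paste(apply(m, 1, function(r) paste0(c("C", "D")[r + 1], collapse = "")),
          collapse = " ")
  }
  cat("Play trace: preperiod [", fmt(x$preperiod), "] cycle [",
      fmt(x$cycle), "]\n")
  invisible(x)
}

#' Exact discounted payoff of a play trace
#'
#' Computes \eqn{(1-w)\sum_t w^t \pi_t} in closed form: the finite preperiod
#' sum plus the cycle sum times \eqn{w^{k}/(1 - w^{c})} for preperiod length
#' k and cycle length c, all scaled by \eqn{1 - w}. No truncation error.
#'
#' @param trace a [play()] trace.
#' @param spec an [rpd_spec()].
#' @param perspective \code{"first"} or \code{"second"} player.
#' @return the normalised discounted payoff.
#' @export
discounted_payoff <- function(trace, spec, perspective = c("first", "second")) {
  perspective <- match.arg(perspective)
  w <- spec$w
  if (!(w < 1)) stop("continuation probability must be < 1")
  one_shot <- spec$one_shot
  pay <- function(m) {
    if (nrow(m) == 0) return(numeric(0))
    if (perspective == "first") {
      one_shot[cbind(m[, 1] + 1, m[, 2] + 1)]
    } else {
      one_shot[cbind(m[, 2] + 1, m[, 1] + 1)]
    }
  }
  ppre <- pay(trace$preperiod)
  pcyc <- pay(trace$cycle)
  k <- length(ppre)
  cl <- length(pcyc)
  pre_sum <- if (k) sum(w^(seq_len(k) - 1) * ppre) else 0
  cyc_sum <- sum(w^(seq_len(cl) - 1) * pcyc) * w^k / (1 - w^cl)
  (1 - w) * (pre_sum + cyc_sum)
}

#' Exact payoff matrix of the repeated PD over the eight memory-one strategies
#'
#' Entry (i, j) is the row player's normalised discounted payoff when
#' strategy i meets strategy j, computed from the closed-form trace payoffs.
#'
#' @param spec an [rpd_spec()].
#' @param strategies subset of strategies (names, codes or indices); defaults
#'   to all eight in code order.
#' @return a [payoff_matrix()] labelled with the strategy names.
#' @export
pd_payoff_matrix <- function(spec, strategies = pd_strategies()$name) {
  n <- length(strategies)
  labs <- vapply(strategies, function(s) pd_strategy(s)$name, character(1))
  A <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- discounted_payoff(play(strategies[i], strategies[j]), spec,
                                   perspective = "first")
    }
  }
  payoff_matrix(A, labels = unname(labs))
}

#' Bitwise mutation kernel on the 3-cube of memory-one strategies
#'
#' Mutations flip exactly one bit of the 3-bit strategy code, so each
#' strategy has exactly three neighbours, each reached with probability
#' \code{mu/3}; no mutation with probability \code{1 - mu}. The kernel is
#' symmetric and connected (the 3-dimensional hypercube), and its
#' neighbourhood structure is invariant under permutations of bit positions
#' and global bit flips.
#'
#' @param mu overall mutation probability per reproduction, in (0, 1).
#' @return an 8x8 [mutation_kernel()] in strategy-code order.
#' @export
bitwise_kernel <- function(mu) {
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  tab <- pd_strategies()
  bits <- as.matrix(tab[, c("first", "onC", "onD")])
  hamming <- outer(seq_len(8), seq_len(8),
                   Vectorize(function(i, j) sum(bits[i, ] != bits[j, ])))
  M <- ifelse(hamming == 1, mu / 3, 0)
  diag(M) <- 1 - mu
  mutation_kernel(M, rate = mu, labels = tab$name)
}

#' Classify strategies as fully cooperative in self-play
#'
#' A strategy is fully cooperative when its self-play trace is eventually all
#' mutual cooperation (the cycle consists solely of (C, C) rounds). The
#' classification is computed from traces, not hard-coded.
#'
#' @param strategies strategies in any accepted form; defaults to all eight.
#' @return a named logical vector.
#' @export
is_fully_cooperative <- function(strategies = pd_strategies()$name) {
  out <- vapply(strategies, function(s) {
    tr <- play(s, s)
    all(tr$cycle == 0)
  }, logical(1))
  names(out) <- vapply(strategies, function(s) pd_strategy(s)$name, character(1))
  out
}

#' Stationary mass on fully cooperative states
#'
#' @param pi a [stationary_distribution()] over the eight memory-one
#'   strategies (canonical names).
#' @return the summed abundance of strategies whose self-play is eventually
#'   all mutual cooperation.
#' @export
cooperative_mass <- function(pi) {
  coop <- is_fully_cooperative(names(pi))
  sum(as.numeric(pi)[coop])
}

#' Heuristic validity check for the rare-mutation approximation
#'
#' The monomorphic-chain analytics require mutations to be much slower than
#' fixation sweeps. As a rough guide, a neutral sweep takes of order N
#' generations (N^2 birth--death events), so the product of the per-event
#' mutation probability and N^2 should be small. A warning is emitted when
#' \code{mu * N^2 > 0.1}.
#'
#' @param N population size.
#' @param mu per-reproduction mutation probability.
#' @return invisibly, the heuristic product \code{mu * N^2}.
#' @export
check_rare_mutation_regime <- function(N, mu) {
  q <- mu * N^2
  if (q > 0.1) {
    warning("mu * N^2 = ", signif(q, 3),
            " > 0.1: mutations may not be rare enough for the ",
            "monomorphic-chain approximation", call. = FALSE)
  }
  invisible(q)
}
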