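#' Parameters of the optional public goods game with punishment
#'
#' A well-mixed population of size \code{N}; at each interaction, groups of
#' \code{n_group} are sampled without replacement. Participants (bases C and
#' D) may play the public goods game: contributors invest \code{c_invest},
#' the pot is multiplied by \code{r_mult} and split equally among all
#' participants. Loners (base L) abstain and receive the fixed payoff
#' \code{sigma}; a group with fewer than two participants yields \code{sigma}
#' for the would-be participant as well (no game takes place). Punishment:
#' each punisher imposes a fine of \code{fine} on every group member of a
#' targeted base type, paying \code{fine_cost} per fine. \code{alpha} deflates
#' the exit mutation rates of loners in the loner-biased kernel. The
#' punishment-game literature often denotes the fine by beta; it is renamed
#' here because beta is the intensity of selection throughout this package.
#'
#' The standard loner condition \code{0 < sigma < c_invest * (r_mult - 1)}
#' (abstaining beats universal defection but not universal cooperation) is
#' checked with a warning, not an error.
#'
#' @param N population size.
#' @param n_group interaction group size, \code{2 <= n_group <= N}.
#' @param c_invest contribution cost (payoff units).
#' @param r_mult multiplication factor of the pot (> 1).
#' @param sigma loner payoff.
#' @param fine fine per punisher--target pair.
#' @param fine_cost cost paid by the punisher per fine imposed.
#' @param alpha loner-exit mutation deflation factor in (0, 1].
#' @return an object of class \code{pgg_params}.
#' @export
pgg_params <- function(N = 100, n_group = 5, c_invest = 1, r_mult = 3,
                       sigma = 1, fine = 1, fine_cost = 0.3, alpha = 1) {
  if (!(n_group >= 2 && n_group <= N)) stop("need 2 <= n_group <= N")
  if (!(r_mult > 1)) stop("r_mult must exceed 1")
  if (!(c_invest > 0)) stop("c_invest must be positive")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (!(sigma > 0 && sigma < c_invest * (r_mult - 1))) {
    warning("sigma outside (0, c_invest * (r_mult - 1)): loners are not ",
            "intermediate between universal defection and cooperation",
            call. = FALSE)
  }
  structure(list(N = as.integer(N), n_group = as.integer(n_group),
                 c_invest = c_invest, r_mult = r_mult, sigma = sigma,
                 fine = fine, fine_cost = fine_cost, alpha = alpha),
            class = "pgg_params")
}

#' @export
print.pgg_params <- function(x, ...) {
  cat("Optional PGG with punishment: N =", x$N, ", n =", x$n_group,
      ", c =", x$c_invest, ", r =", x$r_mult, ", sigma =", x$sigma,
      ", fine =", x$fine, ", fine cost =", x$fine_cost,
      ", alpha =", x$alpha, "\n")
  invisible(x)
}

#' Strategy tables for the punishment games
#'
#' Strategies are four-tuples: a base action (C contribute, D free-ride,
#' L abstain) plus three punishment flags targeting cooperators, defectors
#' and loners respectively (labels like \code{"C-NPN"}: a cooperator that
#' punishes defectors, i.e. the classic altruistic punisher).
#'
#' \code{pgg4_strategies()} gives the four-type system C, D, P, L (P is the
#' punishing cooperator C-NPN); \code{rand_nowak_strategies()} gives the full
#' 24-strategy space (3 bases x 2^3 flag combinations) in lexicographic
#' (base, flags) order.
#'
#' @return a data frame with columns \code{label}, \code{base},
#'   \code{punishC}, \code{punishD}, \code{punishL} (logical flags).
#' @export
rand_nowak_strategies <- function() {
  grid <- expand.grid(punishL = c("N", "P"), punishD = c("N", "P"),
                      punishC = c("N", "P"), base = c("C", "D", "L"),
                      stringsAsFactors = FALSE)[, 4:1]
  data.frame(label = paste0(grid$base, "-", grid$punishC, grid$punishD,
                            grid$punishL),
             base = grid$base,
             punishC = grid$punishC == "P",
             punishD = grid$punishD == "P",
             punishL = grid$punishL == "P",
             stringsAsFactors = FALSE)
}

#' @rdname rand_nowak_strategies
#' @export
pgg4_strategies <- function() {
  data.frame(label = c("C", "D", "P", "L"),
             base = c("C", "D", "C", "L"),
             punishC = FALSE,
             punishD = c(FALSE, FALSE, TRUE, FALSE),
             punishL = FALSE,
             stringsAsFactors = FALSE)
}

# Resolve strategies given as labels (of either table) or table rows to a
# data frame of tuples.
pgg_strategy_rows <- function(s) {
  if (is.data.frame(s)) return(s)
  tab24 <- rand_nowak_strategies()
  tab4 <- pgg4_strategies()
  rows <- lapply(s, function(lab) {
    i <- match(lab, tab4$label)
    if (!is.na(i)) return(tab4[i, ])
    i <- match(lab, tab24$label)
    if (!is.na(i)) return(tab24[i, ])
    stop("unknown punishment-game strategy: ", lab)
  })
  do.call(rbind, rows)
}

punishes <- function(strategy_row, target_base) {
  switch(target_base,
         C = strategy_row$punishC,
         D = strategy_row$punishD,
         L = strategy_row$punishL)
}

# Payoff of a focal individual in one group: focal strategy plus k_inv
# co-members of strategy `inv` and (n_group - 1 - k_inv) of strategy `res`.
pgg_group_payoff <- function(params, focal, inv, res, k_inv) {
  n_oth <- params$n_group - 1
  k_res <- n_oth - k_inv
  n_C <- (focal$base == "C") + k_inv * (inv$base == "C") + k_res * (res$base == "C")
  n_part <- n_C + (focal$base == "D") + k_inv * (inv$base == "D") +
    k_res * (res$base == "D")
  if (focal$base == "L" || n_part < 2) {
    game <- params$sigma
  } else {
    game <- params$r_mult * params$c_invest * n_C / n_part -
      (focal$base == "C") * params$c_invest
  }
  received <- params$fine *
    (k_inv * punishes(inv, focal$base) + k_res * punishes(res, focal$base))
  paid <- params$fine_cost *
    (k_inv * punishes(focal, inv$base) + k_res * punishes(focal, res$base))
  game - received - paid
}

#' Exact expected payoffs in a two-strategy punishment-game population
#'
#' Population of \code{i} invaders and \code{N - i} residents; groups of
#' \code{n_group} are sampled without replacement, so a focal individual's
#' co-members follow a hypergeometric composition. The expectation is the
#' exact hypergeometric-weighted sum over group compositions (no Monte
#' Carlo), covering both the 4-strategy C/D/P/L system and the 24-strategy
#' space (labels of either are accepted).
#'
#' @param params a [pgg_params()].
#' @param invader,resident strategy labels (e.g. \code{"P"},
#'   \code{"C-NPN"}) or rows of the strategy tables.
#' @param i number of invaders, \code{0 < i < N}; may be a vector.
#' @param N population size (defaults to \code{params$N}).
#' @return a two-column matrix \code{(pi_inv, pi_res)}, one row per \code{i}
#'   (dropped to a vector for scalar \code{i}).
#' @export
pgg_pair_payoffs <- function(params, invader, resident, i, N = params$N) {
  if (any(i <= 0 | i >= N)) stop("need 0 < i < N (both types present)")
  inv <- pgg_strategy_rows(invader)
  res <- pgg_strategy_rows(resident)
  if (nrow(inv) != 1 || nrow(res) != 1) stop("invader and resident must be single strategies")
  n_oth <- params$n_group - 1
  k <- 0:n_oth
  g_inv <- vapply(k, function(kk) pgg_group_payoff(params, inv, inv, res, kk),
                  numeric(1))
  g_res <- vapply(k, function(kk) pgg_group_payoff(params, res, inv, res, kk),
                  numeric(1))
  # weights over k = number of invaders among the n_group - 1 co-members
  W_inv <- outer(i, k, function(ii, kk) stats::dhyper(kk, ii - 1, N - ii, n_oth))
  W_res <- outer(i, k, function(ii, kk) stats::dhyper(kk, ii, N - 1 - ii, n_oth))
  out <- cbind(pi_inv = drop(W_inv %*% g_inv), pi_res = drop(W_res %*% g_res))
  if (length(i) == 1) out[1, ] else out
}

#' @rdname pgg_pair_payoffs
#' @export
pgg4_payoffs <- function(params, invader, resident, i, N = params$N) {
  if (!all(c(invader, resident) %in% pgg4_strategies()$label)) {
    stop("4-strategy labels are C, D, P, L")
  }
  pgg_pair_payoffs(params, invader, resident, i, N)
}

#' @rdname pgg_pair_payoffs
#' @export
rand_nowak_payoffs <- function(params, invader, resident, i, N = params$N) {
  if (!all(c(invader, resident) %in% rand_nowak_strategies()$label)) {
    stop("24-strategy labels have the form X-abc, e.g. C-NPN")
  }
  pgg_pair_payoffs(params, invader, resident, i, N)
}

# Payoff-difference profile (i = 1..N-1 invaders) for a punishment-game pair.
pgg_pair_delta <- function(params, invader, resident, N = params$N) {
  p <- pgg_pair_payoffs(params, invader, resident, seq_len(N - 1), N)
  p[, 1] - p[, 2]
}

# Payoff magnitude bound used for strong-selection equality tolerances.
pgg_payoff_scale <- function(params) {
  max(abs(params$sigma), params$r_mult * params$c_invest,
      params$n_group * (params$fine + params$fine_cost))
}

#' Pairwise fixation probabilities for a punishment-game strategy set
#'
#' @param params a [pgg_params()].
#' @param strategies a strategy table ([pgg4_strategies()] or
#'   [rand_nowak_strategies()]) or a vector of labels.
#' @param beta intensity of selection; \code{Inf} gives the exact
#'   strong-selection limit.
#' @param N population size (defaults to \code{params$N}).
#' @return an m x m matrix, \code{[a, b]} the fixation probability of one
#'   \code{b} mutant among \code{a}s; diagonal \code{NA}.
#' @export
pgg_fixation_matrix <- function(params, strategies = pgg4_strategies(),
                                beta, N = params$N) {
  strat <- pgg_strategy_rows(strategies)
  m <- nrow(strat)
  rho <- matrix(NA_real_, m, m, dimnames = list(strat$label, strat$label))
  scale <- pgg_payoff_scale(params)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      delta <- pgg_pair_delta(params, strat[b, ], strat[a, ], N)
      rho[a, b] <- if (is.infinite(beta)) {
        strong_fixation_from_delta(delta, scale = scale)
      } else {
        fixation_from_delta(delta, beta)
      }
    }
  }
  rho
}

#' Loner-biased mutation kernel for the C, D, P, L system
#'
#' Rows C, D, P mutate uniformly (probability \code{mu/3} to each other
#' type); the loner row's off-diagonal entries are deflated by \code{alpha}
#' (mutations out of the asocial state are rarer), the diagonal absorbing the
#' difference. \code{alpha = 1} recovers the uniform kernel exactly.
#'
#' @param alpha deflation factor in (0, 1].
#' @param mu overall mutation probability in (0, 1).
#' @return a 4x4 [mutation_kernel()] in order C, D, P, L.
#' @export
loner_kernel <- function(alpha, mu) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  M <- matrix(mu / 3, 4, 4)
  diag(M) <- 1 - mu
  M[4, 1:3] <- alpha * mu / 3
  M[4, 4] <- 1 - alpha * mu
  mutation_kernel(M, rate = mu, labels = pgg4_strategies()$label)
}

#' Bitwise-like mutation kernel on the 24-strategy space
#'
#' Two strategies are neighbours iff they differ in exactly one of the four
#' positions (base or one punishment flag). The base position contributes two
#' neighbours and each flag one, so every strategy has exactly five
#' neighbours, each reached with probability \code{mu/5}; no mutation with
#' probability \code{1 - mu}.
#'
#' @param mu overall mutation probability in (0, 1).
#' @return a 24x24 [mutation_kernel()] in lexicographic (base, flags) order.
#' @export
bitwise_kernel_24 <- function(mu) {
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  tab <- rand_nowak_strategies()
  pos <- cbind(tab$base, tab$punishC, tab$punishD, tab$punishL)
  m <- nrow(tab)
  diffs <- outer(seq_len(m), seq_len(m),
                 Vectorize(function(i, j) sum(pos[i, ] != pos[j, ])))
  M <- ifelse(diffs == 1, mu / 5, 0)
  diag(M) <- 1 - mu
  mutation_kernel(M, rate = mu, labels = tab$label)
}

#' Rare-mutation stationary distribution of a punishment game
#'
#' Builds the embedded monomorphic-state chain from the exact pairwise
#' fixation probabilities and the given kernel, and solves for its
#' stationary distribution.
#'
#' @inheritParams pgg_fixation_matrix
#' @param kernel a [mutation_kernel()] over the same strategies.
#' @return a [stationary_distribution()].
#' @export
pgg_stationary <- function(params, kernel, beta,
                           strategies = NULL, N = params$N) {
  if (is.null(strategies)) {
    strategies <- if (nrow(kernel) == 4) pgg4_strategies() else
      rand_nowak_strategies()
  }
  strat <- pgg_strategy_rows(strategies)
  if (nrow(strat) != nrow(kernel)) stop("kernel and strategy set disagree")
  rho <- pgg_fixation_matrix(params, strat, beta, N)
  stationary_distribution(embedded_chain_from_rho(rho, kernel))
}

#' Strong-selection stationary distribution of the four-type system
#'
#' In the parameter regime of the classic punishment lineage the
#' strong-selection transition structure is: D invades C and L invades D
#' with probability one; C and P drift neutrally into each other (1/N); L
#' drifts into C or P with probability 1/2 each (the first step is neutral
#' because a lone participant receives sigma, all later steps are
#' advantageous); every other invasion is impossible. The stationary
#' distribution then has the closed form
#' \deqn{\pi \propto (2,\; 2,\; N + 2,\; 2/\alpha)} in order (C, D, P, L),
#' with \eqn{\alpha = 1} for the uniform kernel. The regime is detected
#' automatically from the computed pairwise strong-selection fixation
#' values; if it does not hold, the generic embedded-chain route is used and
#' a notice is emitted (never a silent closed form).
#'
#' @param params a [pgg_params()] (supplies \code{alpha} for the loner
#'   kernel).
#' @param kernel_kind \code{"uniform"} or \code{"loner"}.
#' @param N population size (defaults to \code{params$N}).
#' @return a [stationary_distribution()] over C, D, P, L with attribute
#'   \code{"route"} set to \code{"closed_form"} or \code{"generic"}.
#' @export
strong_selection_stationary_4 <- function(params,
                                          kernel_kind = c("uniform", "loner"),
                                          N = params$N) {
  kernel_kind <- match.arg(kernel_kind)
  alpha <- if (kernel_kind == "loner") params$alpha else 1
  rho <- pgg_fixation_matrix(params, pgg4_strategies(), beta = Inf, N = N)
  expected <- matrix(0, 4, 4, dimnames = dimnames(rho))
  expected["C", "D"] <- 1
  expected["D", "L"] <- 1
  expected["C", "P"] <- expected["P", "C"] <- 1 / N
  expected["L", "C"] <- expected["L", "P"] <- 1 / 2
  diag(expected) <- NA
  if (isTRUE(all(abs(rho - expected) <= 1e-12, na.rm = TRUE))) {
    pi <- c(C = 2, D = 2, P = N + 2, L = 2 / alpha)
    pi <- pi / sum(pi)
    return(structure(pi, class = "stationary_distribution",
                     route = "closed_form"))
  }
  message("strong-selection transition structure outside the closed-form ",
          "regime; using the generic embedded-chain route")
  kern <- if (kernel_kind == "loner") loner_kernel(alpha, mu = 0.01) else
    uniform_kernel(4, mu = 0.01, labels = pgg4_strategies()$label)
  pi <- stationary_distribution(embedded_chain_from_rho(rho, kern))
  attr(pi, "route") <- "generic"
  pi
}

#' Is playing the game more abundant than abstaining at strong selection?
#'
#' Under the loner-biased kernel the strong-selection closed form gives
#' combined mass \eqn{N + 6} (in units of the common factor) to the social
#' types C, D, P and \eqn{2/\alpha} to loners, so sociality prevails iff
#' \deqn{\alpha (N + 6) > 2.}
#' For \eqn{\alpha = 1} this holds for every N; as \eqn{\alpha \to 0} at
#' fixed N, abstention wins. The inequality route and the generic
#' stationary-mass route are both computed and must agree.
#'
#' @inheritParams strong_selection_stationary_4
#' @param route \code{"inequality"} (closed form) or \code{"generic"}
#'   (compare stationary masses from the embedded chain).
#' @return logical: \code{TRUE} when the combined C + D + P mass exceeds the
#'   loner mass.
#' @export
sociality_condition <- function(params, N = params$N,
                                route = c("inequality", "generic")) {
  route <- match.arg(route)
  if (route == "inequality") {
    return(params$alpha * (N + 6) > 2)
  }
  pi <- strong_selection_stationary_4(params, "loner", N = N)
  sum(pi[c("C", "D", "P")]) > pi["L"]
}

#' Ranked display of a 24-strategy stationary distribution
#'
#' Optionally drops self-punishing strategies (those whose punishment flag
#' targets their own base: C-P.., D-.P., L-..P) from the display only --
#' never from the computation, so the underlying probabilities still sum to
#' one -- and ranks the rest by abundance.
#'
#' @param pi a [stationary_distribution()] over the 24 labels.
#' @param exclude_self_punishers drop self-punishing strategies from the
#'   display (default TRUE).
#' @return a data frame with columns \code{rank}, \code{strategy},
#'   \code{abundance}, \code{self_punisher}, ordered by abundance.
#' @export
report_distribution_24 <- function(pi, exclude_self_punishers = TRUE) {
  strat <- pgg_strategy_rows(names(pi))
  selfp <- mapply(function(i) punishes(strat[i, ], strat$base[i]),
                  seq_len(nrow(strat)))
  tab <- data.frame(strategy = names(pi), abundance = as.numeric(pi),
                    self_punisher = selfp, stringsAsFactors = FALSE)
  if (exclude_self_punishers) tab <- tab[!tab$self_punisher, ]
  tab <- tab[order(tab$abundance, decreasing = TRUE), ]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
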