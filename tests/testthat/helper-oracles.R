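# Independent oracles used to cross-check the package's closed-form routes.
# These deliberately use brute-force formulations (explicit enumeration,
# linear solves, truncated series, round-by-round simulation) rather than the
# implementation's own code paths.

# Fixation probability of a single invader via the absorbing birth-death
# chain solved as a linear system. Conditioning on a move (the jump chain)
# leaves the absorption probabilities unchanged: the forward jump
# probability is p_i = T+_i / (T+_i + T-_i) = 1 / (1 + e^{-beta * delta_i})
# and x_i = (1 - p_i) x_{i-1} + p_i x_{i+1}, x_0 = 0, x_N = 1. Under strong
# selection the elimination cancels catastrophically in double precision
# (coexistence games put an interior fitness maximum between the absorbing
# boundaries), so the tridiagonal system is solved in 60-digit arithmetic;
# cases are batched through a single external process.
oracle_fixation_linear_batch <- function(cases) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  stopifnot(nzchar(python))
  payload <- jsonlite::toJSON(lapply(cases, function(cs) {
    list(beta = cs$beta, delta = cs$delta)
  }), auto_unbox = TRUE, digits = NA)
  infile <- tempfile(fileext = ".json")
  writeLines(payload, infile)
  out <- system2(python, test_path("oracle_fixation.py"),
                 stdin = infile, stdout = TRUE)
  unlink(infile)
  as.numeric(out)
}

oracle_fixation_linear <- function(game, invader, resident, N, beta) {
  delta <- moranmut:::pair_delta(game, invader, resident, N)
  oracle_fixation_linear_batch(list(list(beta = beta, delta = delta)))
}

# Round-by-round play of two memory-one strategies (no cycle detection).
oracle_play_rounds <- function(s1, s2, rounds) {
  tab <- moranmut::pd_strategies()
  get <- function(s) {
    i <- match(s, tab$name)
    if (is.na(i)) i <- match(s, tab$code)
    tab[i, ]
  }
  p1 <- get(s1); p2 <- get(s2)
  acts <- matrix(NA_integer_, rounds, 2)
  a <- p1$first; b <- p2$first
  for (t in seq_len(rounds)) {
    acts[t, ] <- c(a, b)
    a_new <- if (b == 0) p1$onC else p1$onD
    b <- if (a == 0) p2$onC else p2$onD
    a <- a_new
  }
  acts
}

# Truncated discounted payoff from direct simulation.
oracle_truncated_payoff <- function(s1, s2, spec, rounds,
                                    perspective = "first") {
  acts <- oracle_play_rounds(s1, s2, rounds)
  M <- spec$one_shot
  pays <- if (perspective == "first") {
    M[cbind(acts[, 1] + 1, acts[, 2] + 1)]
  } else {
    M[cbind(acts[, 2] + 1, acts[, 1] + 1)]
  }
  (1 - spec$w) * sum(spec$w^(seq_len(rounds) - 1) * pays)
}

# Expected pair payoffs in the punishment game by exhaustive enumeration of
# every group of co-members (all subsets of size n_group - 1 of the N - 1
# labelled non-focal individuals), uniformly weighted.
oracle_pgg_brute <- function(params, invader, resident, i, N) {
  inv <- moranmut:::pgg_strategy_rows(invader)
  res <- moranmut:::pgg_strategy_rows(resident)
  popn <- c(rep("inv", i), rep("res", N - i))
  focal_payoff <- function(focal_row, others_tags) {
    rows <- list(inv = inv, res = res)
    members <- lapply(others_tags, function(tg) rows[[tg]])
    n_C <- (focal_row$base == "C") +
      sum(vapply(members, function(m) m$base == "C", logical(1)))
    n_part <- n_C + (focal_row$base == "D") +
      sum(vapply(members, function(m) m$base == "D", logical(1)))
    if (focal_row$base == "L" || n_part < 2) {
      game <- params$sigma
    } else {
      game <- params$r_mult * params$c_invest * n_C / n_part -
        (focal_row$base == "C") * params$c_invest
    }
    pun_on_me <- sum(vapply(members, function(m) {
      switch(focal_row$base, C = m$punishC, D = m$punishD, L = m$punishL)
    }, logical(1)))
    pun_by_me <- sum(vapply(members, function(m) {
      switch(m$base, C = focal_row$punishC, D = focal_row$punishD,
             L = focal_row$punishL)
    }, logical(1)))
    game - params$fine * pun_on_me - params$fine_cost * pun_by_me
  }
  avg_for <- function(which_focal) {
    focal_row <- if (which_focal == "inv") inv else res
    others <- popn[-match(which_focal, popn)]
    combos <- utils::combn(length(others), params$n_group - 1)
    mean(apply(combos, 2, function(idx) focal_payoff(focal_row, others[idx])))
  }
  c(pi_inv = avg_for("inv"), pi_res = avg_for("res"))
}

# Seeded random 2x2 games with entries on [0, 10].
random_game_2x2 <- function() {
  payoff_matrix(matrix(runif(4, 0, 10), 2, 2), labels = c("A", "B"))
}
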