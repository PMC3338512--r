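test_that("degenerate and boundary payoffs follow the game rules", {
  p <- pgg_params(N = 20)
  # a lone loner among loners: no game is ever played
  both <- pgg_pair_payoffs(p, "L", "L", i = 1)
  expect_equal(unname(both), c(p$sigma, p$sigma))
  # one defector among cooperators, fines off: free-riding pays when r < n
  p0 <- pgg_params(N = 20, fine = 0, fine_cost = 0)
  pay <- pgg4_payoffs(p0, "D", "C", i = 1)
  expect_gt(pay["pi_inv"], pay["pi_res"])
  expect_error(pgg_pair_payoffs(p, "C", "D", i = 0), "0 < i < N")
  expect_error(pgg_params(n_group = 1), "n_group")
  expect_warning(pgg_params(sigma = 5), "sigma")
})

test_that("pair payoffs equal exhaustive group enumeration", {
  set.seed(101)
  N <- 12
  for (rep in 1:6) {
    # random draws may fall outside the conventional loner-payoff window,
    # which only triggers an advisory warning
    p <- suppressWarnings(
      pgg_params(N = N, n_group = 5, c_invest = runif(1, 0.5, 2),
                 r_mult = runif(1, 1.5, 4), sigma = runif(1, 0.2, 1.5),
                 fine = runif(1, 0, 2), fine_cost = runif(1, 0, 1)))
    labs4 <- pgg4_strategies()$label
    pair <- sample(labs4, 2)
    i <- sample(seq_len(N - 1), 1)
    expect_equal(unname(pgg4_payoffs(p, pair[1], pair[2], i)),
                 unname(oracle_pgg_brute(p, pair[1], pair[2], i, N)),
                 tolerance = 1e-12)
    labs24 <- rand_nowak_strategies()$label
    pair24 <- sample(labs24, 2)
    expect_equal(unname(rand_nowak_payoffs(p, pair24[1], pair24[2], i)),
                 unname(oracle_pgg_brute(p, pair24[1], pair24[2], i, N)),
                 tolerance = 1e-12)
  }
})

test_that("unpunishing 24-space strategies reduce to the 4-type system", {
  p <- pgg_params(N = 40)
  for (i in c(1, 7, 39)) {
    expect_equal(unname(rand_nowak_payoffs(p, "C-NNN", "D-NNN", i)),
                 unname(pgg4_payoffs(p, "C", "D", i)))
    expect_equal(unname(rand_nowak_payoffs(p, "L-NNN", "C-NNN", i)),
                 unname(pgg4_payoffs(p, "L", "C", i)))
    # the altruistic punisher flag pattern is the 4-type punisher
    expect_equal(unname(rand_nowak_payoffs(p, "C-NPN", "D-NNN", i)),
                 unname(pgg4_payoffs(p, "P", "D", i)))
  }
})

test_that("the loner kernel deflates only the exit row", {
  expect_equal(unclass(loner_kernel(1, 0.03)), unclass(uniform_kernel(4, 0.03)),
               ignore_attr = TRUE)
  k <- loner_kernel(0.2, 0.03)
  off <- unclass(k); diag(off) <- 0
  expect_equal(sum(off[4, ]), 0.2 * sum(off[1, ]))
  expect_equal(unname(rowSums(k)), rep(1, 4))
  expect_error(loner_kernel(0, 0.03), "alpha")
})

test_that("loner mass at strong selection grows monotonically as alpha falls", {
  masses <- vapply(c(1, 0.5, 0.2, 0.1, 0.05), function(a) {
    pi <- strong_selection_stationary_4(pgg_params(alpha = a), "loner")
    unname(pi["L"])
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("strong-selection closed form matches the generic chain route", {
  for (N in c(10, 50, 100)) {
    for (a in c(1, 0.3)) {
      p <- pgg_params(N = N, alpha = a)
      kind <- if (a == 1) "uniform" else "loner"
      pi_cf <- strong_selection_stationary_4(p, kind)
      expect_identical(attr(pi_cf, "route"), "closed_form")
      rho <- pgg_fixation_matrix(p, beta = Inf)
      kern <- if (a == 1) uniform_kernel(4, 0.01, labels = pgg4_strategies()$label)
              else loner_kernel(a, 0.01)
      pi_gen <- stationary_distribution(embedded_chain_from_rho(rho, kern))
      expect_equal(as.numeric(pi_cf), as.numeric(pi_gen), tolerance = 1e-10)
    }
  }
})

test_that("regime detection falls back to the generic route when broken", {
  # with punishment disabled, defectors also invade the punisher state,
  # breaking the closed-form transition structure (but not ergodicity)
  p <- pgg_params(fine = 0, fine_cost = 0.1)
  expect_message(pi <- strong_selection_stationary_4(p, "uniform"), "generic")
  expect_identical(attr(pi, "route"), "generic")
})

test_that("sociality condition: inequality and generic routes agree", {
  expect_true(sociality_condition(pgg_params(alpha = 1), N = 10))
  expect_true(sociality_condition(pgg_params(alpha = 1), N = 1000))
  # near-absorbing loner row: abstention wins
  expect_false(sociality_condition(pgg_params(alpha = 0.01), N = 50))
  for (a in c(0.01, 0.05, 0.2, 0.6, 1)) {
    for (N in c(10, 40, 160)) {
      p <- pgg_params(N = N, alpha = a)
      expect_identical(sociality_condition(p, N = N),
                       unname(sociality_condition(p, N = N, route = "generic")))
    }
  }
})

test_that("the loner share crossing in N exists and is unique", {
  p <- pgg_params(alpha = 0.05)
  Ns <- seq(8, 120, by = 4)
  lead <- vapply(Ns, function(N) {
    pi <- strong_selection_stationary_4(p, "loner", N = N)
    unname(pi["L"] - sum(pi[c("C", "D", "P")]))
  }, numeric(1))
  expect_equal(sum(diff(sign(lead)) != 0), 1)
})

test_that("the 24-strategy space and its bitwise-like kernel are correct", {
  tab <- rand_nowak_strategies()
  expect_equal(nrow(tab), 24)
  expect_equal(anyDuplicated(tab$label), 0)
  k <- bitwise_kernel_24(0.05)
  nb <- names(which(unclass(k)["D-NNN", ] > 0))
  nb <- setdiff(nb, "D-NNN")
  expect_setequal(nb, c("D-NNP", "D-NPN", "D-PNN", "C-NNN", "L-NNN"))
  off <- unclass(k); diag(off) <- 0
  expect_true(all(rowSums(off > 0) == 5))
  expect_true(all(off[off > 0] == 0.01))
  expect_equal(unclass(k), t(unclass(k)))
  # breadth-first search: connected with diameter 4
  adj <- off > 0
  dist <- matrix(Inf, 24, 24)
  for (s in 1:24) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 &
                     !is.finite(dist[s, ]))
      dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  expect_equal(max(dist), 4)
})

test_that("the display filter drops exactly the self-punishers", {
  p <- pgg_params()
  ku <- uniform_kernel(24, 0.001, labels = rand_nowak_strategies()$label)
  pi <- pgg_stationary(p, ku, beta = 0.25)
  expect_equal(sum(as.numeric(pi)), 1, tolerance = 1e-12)
  full <- report_distribution_24(pi, exclude_self_punishers = FALSE)
  filt <- report_distribution_24(pi)
  expect_equal(nrow(full), 24)
  expect_equal(nrow(filt), 12)
  expect_equal(sum(full$self_punisher), 12)
  expect_false(any(filt$self_punisher))
  # filtering is display-only: the distribution itself is untouched
  expect_equal(sum(full$abundance), 1, tolerance = 1e-12)
  expect_true(all(diff(filt$abundance) <= 0))
})
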