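test_that("expected payoffs exclude self-interaction", {
  const <- payoff_matrix(matrix(1, 2, 2), labels = c("A", "B"))
  for (i in c(0, 3, 6)) {
    expect_equal(unname(expected_payoffs(const, "A", "B", i, 6)), c(1, 1))
  }
  set.seed(11)
  g <- random_game_2x2()
  # boundary: with i = N every co-player of an A is an A
  expect_equal(unname(expected_payoffs(g, "A", "B", 6, 6)[1]), g[1, 1])
  # enumeration oracle: average payoff over the N - 1 explicit co-players
  N <- 6; i <- 3
  coplayers_of_A <- c(rep(1, i - 1), rep(2, N - i))
  coplayers_of_B <- c(rep(1, i), rep(2, N - i - 1))
  expect_equal(unname(expected_payoffs(g, "A", "B", i, N)),
               c(mean(g[1, coplayers_of_A]), mean(g[2, coplayers_of_B])))
  expect_error(expected_payoffs(g, "A", "B", 7, 6), "i must")
  expect_error(expected_payoffs(g, "A", "B", 1, 1), "N must")
})

test_that("neutral drift fixes with probability 1/N", {
  set.seed(4)
  g <- random_game_2x2()
  for (N in c(2, 17, 400)) {
    expect_equal(fixation_probability(g, "A", "B", moran_population(N, 0)),
                 1 / N, tolerance = 1e-14)
  }
})

test_that("N = 2 fixation reduces to a single logistic term", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_game_2x2()
    beta <- runif(1, 0, 3)
    d <- unname(expected_payoffs(g, "A", "B", 1, 2))
    expect_equal(fixation_probability(g, "A", "B", moran_population(2, beta)),
                 1 / (1 + exp(-beta * (d[1] - d[2]))), tolerance = 1e-14)
  }
})

test_that("fixation probabilities match the absorbing-chain linear solve", {
  set.seed(21)
  cases <- list()
  rhos <- numeric(30)
  for (rep in 1:30) {
    g <- random_game_2x2()
    N <- sample(3:50, 1)
    beta <- sample(c(0.1, 1, 10), 1)
    rhos[rep] <- fixation_probability(g, "A", "B", moran_population(N, beta))
    cases[[rep]] <- list(beta = beta,
                         delta = moranmut:::pair_delta(g, 1, 2, N))
  }
  expect_equal(rhos, oracle_fixation_linear_batch(cases), tolerance = 1e-10)
})

test_that("log-space evaluation survives extreme selection without overflow", {
  g <- payoff_matrix(rbind(c(10, 0), c(10, 10)), labels = c("A", "B"))
  rho <- fixation_probability(g, "A", "B", moran_population(1000, 10))
  expect_true(is.finite(rho) && rho >= 0 && rho <= 1)
  # uniform payoff advantage of 10 at beta = 10: fixation is near certain
  g2 <- payoff_matrix(rbind(c(0, 0), c(10, 10)), labels = c("A", "B"))
  rho2 <- fixation_probability(g2, "B", "A", moran_population(1000, 10))
  expect_true(rho2 > 0.99)
})

test_that("strong-selection limit handles zero, positive and mixed paths", {
  # all cumulative sums zero: neutral pair
  expect_equal(strong_fixation_from_delta(rep(0, 9)), 1 / 10)
  # all positive: certain fixation
  expect_equal(strong_fixation_from_delta(rep(0.5, 9)), 1)
  # any negative partial sum kills fixation
  expect_equal(strong_fixation_from_delta(c(-0.1, rep(1, 8))), 0)
  # beta = Inf in the population config routes to the limit
  g <- payoff_matrix(rbind(c(2, 2), c(1, 1)), labels = c("A", "B"))
  expect_equal(fixation_probability(g, "A", "B", moran_population(20, Inf)), 1)
  expect_equal(fixation_probability(g, "B", "A", moran_population(20, Inf)), 0)
})

test_that("two-strategy embedded chain reproduces the mu * rho structure", {
  set.seed(31)
  g <- random_game_2x2()
  pop <- moran_population(30, 0.7)
  mu_ab <- 0.002; mu_ba <- 0.006
  M <- matrix(c(1 - mu_ab, mu_ab, mu_ba, 1 - mu_ba), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  ch <- embedded_chain(g, mutation_kernel(M, rate = 0.006), pop, scale = 1)
  expect_equal(ch$T["A", "B"],
               mu_ab * fixation_probability(g, "B", "A", pop))
  expect_equal(ch$T["B", "A"],
               mu_ba * fixation_probability(g, "A", "B", pop))
  expect_equal(rowSums(ch$T), c(A = 1, B = 1))
})

test_that("neutral selection with a uniform kernel gives equal transitions", {
  g <- payoff_matrix(matrix(runif(9, 0, 5), 3, 3))
  ch <- embedded_chain(g, uniform_kernel(3, 0.01), moran_population(40, 0))
  off <- ch$T[row(ch$T) != col(ch$T)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-15)
})

test_that("the stationary vector is invariant to the row scale", {
  set.seed(41)
  g <- payoff_matrix(matrix(runif(16, 0, 8), 4, 4))
  k <- random_kernel(4, mu = 0.05)
  pop <- moran_population(25, 0.4)
  p1 <- stationary_distribution(embedded_chain(g, k, pop, scale = 1))
  p2 <- stationary_distribution(embedded_chain(g, k, pop, scale = 0.037))
  expect_equal(max(abs(as.numeric(p1) - as.numeric(p2))), 0,
               tolerance = 1e-10)
  expect_error(embedded_chain(g, k, pop, scale = 1e6), "scale")
})

test_that("generic stationary solver agrees with the two-state closed form", {
  set.seed(51)
  for (rep in 1:50) {
    mu_ab <- runif(1, 1e-4, 0.2); mu_ba <- runif(1, 1e-4, 0.2)
    rho_a <- runif(1); rho_b <- runif(1)
    Tm <- rbind(c(1 - mu_ab * rho_b, mu_ab * rho_b),
                c(mu_ba * rho_a, 1 - mu_ba * rho_a))
    pi <- stationary_distribution(Tm)
    expect_equal(as.numeric(pi),
                 unname(stationary_two_state(mu_ab, mu_ba, rho_a, rho_b)),
                 tolerance = 1e-12)
  }
})

test_that("symmetric chains have uniform stationary distributions", {
  # doubly symmetric transition matrix
  S <- matrix(0.02, 4, 4); S[1, 2] <- S[2, 1] <- 0.07
  diag(S) <- 0; diag(S) <- 1 - rowSums(S)
  expect_equal(as.numeric(stationary_distribution(S)), rep(0.25, 4),
               tolerance = 1e-12)
  # identity-plus-cycle with equal off-diagonals
  C <- diag(5) * 0.9
  for (j in 1:5) C[j, j %% 5 + 1] <- 0.1
  expect_equal(as.numeric(stationary_distribution(C)), rep(0.2, 5),
               tolerance = 1e-12)
})

test_that("reducible or malformed chains are rejected with state names", {
  Tm <- rbind(c(1, 0), c(0.3, 0.7))
  dimnames(Tm) <- list(c("up", "down"), c("up", "down"))
  expect_error(stationary_distribution(Tm), "reducible.*down|down.*reducible")
  expect_error(stationary_distribution(rbind(c(0.5, 0.4), c(0.2, 0.8))),
               "stochastic")
})

test_that("mutation kernels are validated at construction", {
  M <- rbind(c(0.99, 0.01), c(0.03, 0.95))
  expect_error(mutation_kernel(M, labels = c("X", "Y")), "row Y")
  # one-way support graph is not ergodic
  M2 <- rbind(c(0.99, 0.01, 0), c(0, 0.99, 0.01), c(0, 0, 1))
  expect_error(mutation_kernel(M2, labels = c("a", "b", "c")), "ergodic")
  expect_error(uniform_kernel(4, 1.2), "mu")
})
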