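#' Monte Carlo simulation configuration
#'
#' @param runs number of independent repetitions (>= 1).
#' @param generations Moran events per run divided by N (one generation =
#'   N birth--death events).
#' @param mu per-reproduction mutation probability; must match the kernel's
#'   rate.
#' @param window_fraction trailing fraction of each run over which the
#'   population composition is averaged, in (0, 1].
#' @param seed RNG root seed; each run uses an independent stream derived
#'   from (seed, run index), so results are reproducible regardless of
#'   execution order.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(runs, generations, mu, window_fraction = 0.5,
                       seed = 1) {
  if (runs < 1 || generations < 1) stop("runs and generations must be >= 1")
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0, 1)")
  if (!(window_fraction > 0 && window_fraction <= 1)) {
    stop("window_fraction must lie in (0, 1]")
  }
  structure(list(runs = as.integer(runs), generations = as.numeric(generations),
                 mu = as.numeric(mu), window_fraction = window_fraction,
                 seed = as.numeric(seed)),
            class = "sim_config")
}

#' Punishment game bundle for the simulator
#'
#' Pairs a [pgg_params()] object with a strategy table so the simulator can
#' evaluate exact expected payoffs for arbitrary population compositions.
#'
#' @param params a [pgg_params()].
#' @param strategies a strategy table ([pgg4_strategies()] or
#'   [rand_nowak_strategies()]) or labels.
#' @return an object of class \code{pgg_game}.
#' @export
pgg_game <- function(params, strategies = pgg4_strategies()) {
  strat <- pgg_strategy_rows(strategies)
  structure(list(params = params, strategies = strat), class = "pgg_game")
}

#' Simulate the Moran process at finite mutation rates
#'
#' Seeded, reproducible event-level simulation: reproduction proportional to
#' \eqn{x_s e^{\beta \pi_s}} with payoffs recomputed from the current
#' composition at every event, mutation applied to the offspring according
#' to the kernel row of the parent, and a uniformly chosen individual
#' (possibly the parent) removed. Each run starts from a population drawn
#' uniformly at random over integer compositions unless \code{init} is
#' given, and the composition is averaged over the trailing window.
#'
#' @param game a [payoff_matrix()] (matrix game) or a [pgg_game()].
#' @param kernel a [mutation_kernel()] of matching dimension; its rate must
#'   equal \code{sim$mu}.
#' @param pop a [moran_population()] (finite beta).
#' @param sim a [sim_config()].
#' @param init optional integer vector of initial counts summing to N
#'   (e.g. a monomorphic start for empirical fixation checks); default is a
#'   uniformly random composition per run.
#' @return an object of class \code{moran_sim}: list with
#'   \code{mean_abundance} (sums to 1), \code{stderr} (per-strategy standard
#'   error across runs), \code{per_run} (runs x strategies matrix),
#'   \code{labels}, and the configuration used.
#' @export
run_moran <- function(game, kernel, pop, sim, init = NULL) {
  stopifnot(inherits(kernel, "mutation_kernel"),
            inherits(pop, "moran_population"),
            inherits(sim, "sim_config"))
  if (is.infinite(pop$beta)) stop("the simulator requires finite beta")
  if (abs(attr(kernel, "rate") - sim$mu) > 1e-12) {
    stop("kernel rate (", attr(kernel, "rate"),
         ") does not match sim$mu (", sim$mu, ")")
  }
  m <- nrow(kernel)
  if (!is.null(init)) {
    init <- as.integer(init)
    if (length(init) != m || sum(init) != pop$N || any(init < 0)) {
      stop("init must be ", m, " nonnegative counts summing to N")
    }
  } else {
    init <- integer(0)
  }
  check_rare_mutation_regime(pop$N, sim$mu)
  if (inherits(game, "payoff_matrix")) {
    if (n_strategies(game) != m) stop("game and kernel dimensions disagree")
    labels <- strategy_labels(game)
    per_run <- .moran_sim_cpp(0L, unclass(game), integer(m),
                              matrix(0L, m, 3), 2L, 0, 2, 0, 0, 0,
                              unclass(kernel), pop$N, pop$beta,
                              sim$runs, sim$generations, sim$window_fraction,
                              sim$seed, init)
  } else if (inherits(game, "pgg_game")) {
    strat <- game$strategies
    if (nrow(strat) != m) stop("game and kernel dimensions disagree")
    labels <- strat$label
    p <- game$params
    base <- match(strat$base, c("C", "D", "L")) - 1L
    pun <- cbind(as.integer(strat$punishC), as.integer(strat$punishD),
                 as.integer(strat$punishL))
    per_run <- .moran_sim_cpp(1L, matrix(0, m, m), base, pun,
                              p$n_group, p$c_invest, p$r_mult, p$sigma,
                              p$fine, p$fine_cost,
                              unclass(kernel), pop$N, pop$beta,
                              sim$runs, sim$generations, sim$window_fraction,
                              sim$seed, init)
  } else {
    stop("game must be a payoff_matrix or a pgg_game")
  }
  colnames(per_run) <- labels
  mean_ab <- colMeans(per_run)
  se <- apply(per_run, 2, stats::sd) / sqrt(sim$runs)
  structure(list(mean_abundance = mean_ab, stderr = se, per_run = per_run,
                 labels = labels, pop = pop, config = sim),
            class = "moran_sim")
}

#' @export
print.moran_sim <- function(x, digits = 4, ...) {
  cat("Moran simulation:", x$config$runs, "runs of",
      format(x$config$generations), "generations, N =", x$pop$N,
      ", beta =", x$pop$beta, ", mu =", x$config$mu, "\n")
  tab <- rbind(mean = round(x$mean_abundance, digits),
               stderr = signif(x$stderr, 3))
  print(tab, ...)
  invisible(x)
}

#' @export
summary.moran_sim <- function(object, ...) {
  data.frame(strategy = object$labels,
             mean_abundance = as.numeric(object$mean_abundance),
             stderr = as.numeric(object$stderr),
             row.names = NULL)
}
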