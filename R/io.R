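#' Read and write payoff matrices and mutation kernels as TSV
#'
#' The on-disk format is a tab-separated table with a header row of strategy
#' labels and a leading label column; values are decimal floats. Kernels are
#' validated on load (row stochasticity to 1e-9, entries in [0, 1],
#' ergodicity), with errors naming the offending row.
#'
#' @param path file path.
#' @param as \code{"payoff"} or \code{"kernel"}.
#' @param rate optional mutation rate to attach when reading a kernel.
#' @return a [payoff_matrix()] or [mutation_kernel()].
#' @export
load_matrix <- function(path, as = c("payoff", "kernel"), rate = NULL) {
  as <- match.arg(as)
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  M <- as.matrix(tab)
  if (!is.numeric(M)) stop("malformed TSV: non-numeric entries in ", path)
  if (as == "payoff") {
    payoff_matrix(M, labels = rownames(M))
  } else {
    mutation_kernel(M, rate = rate, labels = rownames(M))
  }
}

#' @rdname load_matrix
#' @param x a [payoff_matrix()] or [mutation_kernel()].
#' @export
write_matrix <- function(x, path) {
  vals <- apply(unclass(x), 2, function(col) sprintf("%.17g", col))
  df <- data.frame(strategy = rownames(x), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stationary distribution as a two-column TSV
#'
#' Columns \code{strategy} and \code{abundance}; probabilities are printed
#' with 12 significant digits.
#'
#' @param pi a [stationary_distribution()].
#' @param path file path.
#' @export
write_stationary <- function(pi, path) {
  df <- data.frame(strategy = names(pi),
                   abundance = formatC(as.numeric(pi), format = "g",
                                       digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate random game and kernel fixtures
#'
#' Seeded generation of random payoff matrices (sizes 2..8, entries uniform
#' on [0, 10]) and random connected mutation kernels of matching sizes,
#' written as TSV files. Identical seeds produce identical fixture sets.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
make_fixtures <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  for (n in 2:8) {
    g <- random_game(n)
    k <- random_kernel(n)
    fg <- file.path(dir, sprintf("game_%d.tsv", n))
    fk <- file.path(dir, sprintf("kernel_%d.tsv", n))
    write_matrix(g, fg)
    write_matrix(k, fk)
    files <- c(files, fg, fk)
  }
  invisible(files)
}

#' @rdname make_fixtures
#' @param n number of strategies.
#' @export
random_game <- function(n) {
  payoff_matrix(matrix(stats::runif(n * n, 0, 10), n, n))
}

#' @rdname make_fixtures
#' @param mu mutation rate of the generated kernel.
#' @export
random_kernel <- function(n, mu = 0.01) {
  repeat {
    supp <- matrix(stats::runif(n * n) < 0.6, n, n)
    diag(supp) <- FALSE
    # guarantee a cycle so the kernel is always ergodic
    for (j in seq_len(n)) supp[j, j %% n + 1] <- TRUE
    w <- matrix(stats::runif(n * n), n, n) * supp
    M <- mu * w / rowSums(w)
    diag(M) <- 1 - rowSums(M)
    k <- tryCatch(mutation_kernel(M, rate = mu), error = function(e) NULL)
    if (!is.null(k)) return(k)
  }
}
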