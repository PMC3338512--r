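#' Construct a payoff matrix
#'
#' A payoff matrix holds the payoffs of an n-strategy symmetric game: entry
#' \code{(i, j)} is the payoff of the row strategy \code{i} against the column
#' strategy \code{j}, in dimensionless payoff units.
#'
#' @param entries numeric n x n matrix, all entries finite, n >= 2.
#' @param labels optional character vector of n unique strategy names; taken
#'   from \code{dimnames(entries)} when absent, else \code{"S1"..."Sn"}.
#' @return an object of class \code{payoff_matrix} (a labelled numeric matrix).
#' @examples
#' g <- payoff_matrix(rbind(c(3, 0), c(5, 1)), labels = c("C", "D"))
#' g["D", "C"]
#' @export
payoff_matrix <- function(entries, labels = NULL) {
  entries <- as.matrix(entries)
  if (!is.numeric(entries)) stop("payoff entries must be numeric")
  n <- nrow(entries)
  if (n != ncol(entries)) stop("payoff matrix must be square")
  if (n < 2) stop("a game needs at least 2 strategies")
  if (!all(is.finite(entries))) stop("payoff entries must all be finite")
  if (is.null(labels)) {
    labels <- rownames(entries)
    if (is.null(labels)) labels <- paste0("S", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need exactly ", n, " strategy labels")
  if (anyDuplicated(labels)) stop("strategy labels must be unique")
  dimnames(entries) <- list(labels, labels)
  class(entries) <- c("payoff_matrix", "matrix", "array")
  entries
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Payoff matrix (", nrow(x), " strategies)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

n_strategies <- function(x) nrow(x)

strategy_labels <- function(x) rownames(x)

# Resolve a strategy given as label or index to its integer position.
strategy_index <- function(game, s) {
  labs <- rownames(game)
  if (is.character(s)) {
    idx <- match(s, labs)
    if (anyNA(idx)) stop("unknown strategy label: ", paste(s[is.na(idx)], collapse = ", "))
    return(idx)
  }
  s <- as.integer(s)
  if (any(s < 1L | s > nrow(game))) stop("strategy index out of range")
  s
}
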