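#' Kleinberg HITS hub and authority scores of a bipartite web
#'
#' Power iteration on the (optionally log-transformed) rectangular weight
#' matrix `W` (insects x hosts): `authority <- t(W) %*% hub`,
#' `hub <- W %*% authority`, renormalized each step from a uniform positive
#' start, so the result is deterministic. Converged vectors are rescaled so
#' the maximum on each side is exactly 1. Insects act as hubs, hosts as
#' authorities. Scores are invariant to a global rescaling of `W`.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param transform `"log10"` (default; `log10(x) + 1` on positive cells,
#'   zero cells stay zero) or `"none"`.
#' @param tol convergence tolerance on the max absolute change of either
#'   normalized vector.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   last residual.
#' @return object of class `centrality_result`: list with `hub` (named, per
#'   insect), `authority` (named, per host), `iterations`, `residual`.
#' @examples
#' hits_scores(matrix(1, 2, 2))$hub # both exactly 1
#' @export
hits_scores <- function(web, transform = c("log10", "none"),
                        tol = 1e-12, max_iter = 1e4) {
  transform <- match.arg(transform)
  if (tol <= 0) stop("tol must be positive")
  a <- as_interaction_web(web)$counts
  W <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(a))
  pos <- a > 0
  W[pos] <- if (transform == "log10") log10(a[pos]) + 1 else a[pos]
  hub <- rep(1, nrow(W)) / sqrt(nrow(W))
  auth <- rep(1, ncol(W)) / sqrt(ncol(W))
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    auth_new <- as.numeric(crossprod(W, hub))
    auth_new <- auth_new / sqrt(sum(auth_new^2))
    hub_new <- as.numeric(W %*% auth_new)
    hub_new <- hub_new / sqrt(sum(hub_new^2))
    res <- max(max(abs(auth_new - auth)), max(abs(hub_new - hub)))
    auth <- auth_new
    hub <- hub_new
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("HITS did not converge in %d iterations (residual %.3e)",
                 max_iter, res))
  structure(list(hub = stats::setNames(hub / max(hub), rownames(W)),
                 authority = stats::setNames(auth / max(auth), colnames(W)),
                 iterations = it, residual = res),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("HITS centrality (", x$iterations, " iterations, residual ",
      format(x$residual, digits = 3), ")\n", sep = "")
  cat("Top hubs (insects):\n")
  print(round(utils::head(sort(x$hub, decreasing = TRUE), 5), 3))
  cat("Authorities (hosts):\n")
  print(round(sort(x$authority, decreasing = TRUE), 3))
  invisible(x)
}
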