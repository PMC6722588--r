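#' Reconstruct an integer count web from column percentages
#'
#' Publications often print a quantitative web as column-wise percentage
#' abundance plus exact per-species totals. This inverts that presentation:
#' it solves for non-negative host (column) totals `c_j` minimizing
#' `sum_i (sum_j pct_ij c_j / 100 - T_i)^2` subject to `sum_j c_j = m`
#' (non-negative least squares with the equality handled by a penalty row
#' and a final rescaling), then converts `pct_ij c_j / 100` to integers by
#' largest-remainder rounding within each row so every row sums exactly to
#' its printed total `T_i`. Row totals are the only exact integers in the
#' printed table, so rows — not columns — get the exact constraint.
#'
#' @param p a [percentage_table()].
#' @param tol_resid maximum tolerated absolute residual (individuals) of any
#'   row total before rounding; larger residuals abort with a report.
#' @return an `interaction_web` with `m = p$grand_total`. The solved column
#'   totals and the pre-rounding residuals are attached as attributes
#'   `"col_totals"` and `"residuals"`.
#' @examples
#' p <- percentage_table(matrix(c(75, 25), 2, 1), row_totals = c(3, 1))
#' reconstruct_counts(p)$counts
#' @export
reconstruct_counts <- function(p, tol_resid = 2) {
  stopifnot(inherits(p, "percentage_table"))
  P <- p$pct / 100
  Tn <- as.numeric(p$row_totals)
  m <- p$grand_total
  if (ncol(P) == 1L) {
    cj <- m
  } else {
    lam <- 1e4
    A <- rbind(P, rep(lam, ncol(P)))
    b <- c(Tn, lam * m)
    cj <- pracma::lsqnonneg(A, b)$x
    if (sum(cj) <= 0) stop("reconstruction infeasible: all column totals zero")
    cj <- cj * (m / sum(cj))
  }
  names(cj) <- colnames(P)
  resid <- stats::setNames(as.numeric(P %*% cj - Tn), rownames(P))
  if (max(abs(resid)) > tol_resid) {
    worst <- which.max(abs(resid))
    stop(sprintf(paste0("reconstruction residual too large: species %s off by ",
                        "%.3f individuals (tolerance %.3f)"),
                 rownames(P)[worst], resid[worst], tol_resid))
  }
  raw <- sweep(P, 2, cj, `*`)
  counts <- matrix(0L, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (i in seq_len(nrow(raw)))
    counts[i, ] <- largest_remainder(raw[i, ], Tn[i])
  web <- interaction_web(counts, trim = FALSE)
  attr(web, "col_totals") <- cj
  attr(web, "residuals") <- resid
  web
}

#' Largest-remainder integer apportionment
#'
#' Rounds a non-negative real vector to integers summing exactly to
#' `target`: floor everything, then hand the remaining units to the cells
#' with the largest fractional parts (ties broken by position). If the
#' floors already exceed the target, units are removed from the smallest
#' fractional parts among positive cells. Cells that are exactly zero stay
#' zero whenever feasible.
#'
#' @param x non-negative numeric vector.
#' @param target non-negative integer, the required sum.
#' @return integer vector of `length(x)` summing to `target`.
#' @export
largest_remainder <- function(x, target = round(sum(x))) {
  if (any(x < 0)) stop("negative values")
  target <- as.integer(round(target))
  fl <- as.integer(floor(x))
  frac <- x - fl
  need <- target - sum(fl)
  if (need > 0) {
    ord <- order(-frac, seq_along(x))
    take <- ord[seq_len(need)]
    fl[take] <- fl[take] + 1L
  } else if (need < 0) {
    ord <- order(frac, seq_along(x))
    k <- -need
    for (j in ord) {
      if (k == 0L) break
      if (fl[j] > 0L) { fl[j] <- fl[j] - 1L; k <- k - 1L }
    }
    if (k > 0L) stop("cannot apportion: target below attainable sum")
  }
  fl
}
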