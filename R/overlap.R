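#' Morisita-Horn similarity of two abundance vectors
#'
#' `C = 2 sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)` with
#' `X = sum(x)`, `Y = sum(y)`. Equals 1 for proportionally identical
#' vectors, 0 for disjoint support; invariant to rescaling either vector.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' morisita_horn(c(2, 2), c(1, 1)) # 1
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  X <- sum(x)
  Y <- sum(y)
  if (X == 0 || Y == 0) stop("zero-sum abundance vector")
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Mean niche overlap at one trophic level
#'
#' Unweighted mean of the Morisita-Horn similarity over all unordered pairs
#' of species at the chosen level — resource-use overlap among the insects
#' (rows) or among the hosts (columns).
#'
#' @param web an `interaction_web` (or count matrix).
#' @param level `"insects"` (default) or `"hosts"`.
#' @return mean pairwise similarity in \[0, 1\].
#' @export
mean_niche_overlap <- function(web, level = c("insects", "hosts")) {
  level <- match.arg(level)
  a <- as_interaction_web(web)$counts
  if (level == "hosts") a <- t(a)
  n <- nrow(a)
  if (n < 2) stop("need at least two species to compute overlap")
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(k) morisita_horn(a[k[1], ], a[k[2], ])))
}
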