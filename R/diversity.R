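## Sample-based richness estimation over infructescence units and
## Baselga's balanced/gradient partition of Bray-Curtis dissimilarity.

# unit x species abundance matrix from a record table; units are
# (host, unit_id) pairs
unit_matrix <- function(records) {
  unit <- paste(records$host, records$unit_id, sep = "//")
  tab <- tapply(records$count, list(unit, records$species), sum, default = 0L)
  tab[, colSums(tab) > 0, drop = FALSE]
}

#' Sample-based species accumulation curve
#'
#' Mean (and sd) cumulative species richness as sampling units
#' (infructescences) are accumulated in random order, via
#' [vegan::specaccum()] with `method = "random"`. The curve is monotone
#' non-decreasing and its final point equals the pooled observed richness.
#'
#' @param records a [record_table()].
#' @param n_perm number of random unit orderings.
#' @param seed RNG seed (caller's RNG state is restored).
#' @return data frame with columns `k` (units), `mean`, `sd`.
#' @export
accumulation_curve <- function(records, n_perm = 100, seed = 1) {
  comm <- unit_matrix(records)
  if (nrow(comm) == 0L) stop("no sampling units in record table")
  if (nrow(comm) == 1L)
    return(data.frame(k = 1L, mean = sum(colSums(comm) > 0), sd = 0))
  sac <- with_seed(seed,
    vegan::specaccum(comm, method = "random", permutations = n_perm))
  data.frame(k = sac$sites, mean = sac$richness,
             sd = ifelse(is.na(sac$sd), 0, sac$sd))
}

#' First-order jackknife richness estimate
#'
#' `S_jack1 = S_obs + Q1 (m - 1) / m` over `m` sampling units, where `Q1`
#' counts the species found in exactly one unit (`variant = "incidence"`,
#' the classical estimator) or, alternatively, the species represented by
#' exactly one individual (`variant = "abundance"`). Sampling completeness
#' is `100 S_obs / S_jack1`.
#'
#' @param records a [record_table()].
#' @param variant `"incidence"` (default) or `"abundance"` definition of
#'   `Q1`.
#' @return object of class `richness_estimate`: `S_obs`, `Q1`, `m_units`,
#'   `S_jack1`, `completeness`, `variant`.
#' @export
jackknife1 <- function(records, variant = c("incidence", "abundance")) {
  variant <- match.arg(variant)
  comm <- unit_matrix(records)
  m <- nrow(comm)
  if (m < 2) stop("jackknife needs at least two sampling units")
  S_obs <- sum(colSums(comm) > 0)
  Q1 <- if (variant == "incidence") sum(colSums(comm > 0) == 1)
        else sum(colSums(comm) == 1)
  S_jack1 <- S_obs + Q1 * (m - 1) / m
  structure(list(S_obs = S_obs, Q1 = Q1, m_units = m, S_jack1 = S_jack1,
                 completeness = sampling_completeness(S_obs, S_jack1),
                 variant = variant),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(paste0("Jackknife-1 (%s): S_obs = %d, Q1 = %d over %d units; ",
                     "S_jack1 = %.1f (completeness %.1f%%)\n"),
              x$variant, x$S_obs, x$Q1, x$m_units, x$S_jack1, x$completeness))
  invisible(x)
}

#' Sampling completeness
#'
#' @param s_obs observed richness.
#' @param s_jack1 estimated richness.
#' @return percentage `100 * s_obs / s_jack1`.
#' @examples
#' sampling_completeness(34, 43.3) # 78.5
#' @export
sampling_completeness <- function(s_obs, s_jack1) {
  if (s_jack1 <= 0) stop("estimated richness must be positive")
  100 * s_obs / s_jack1
}

#' Balanced/gradient partition of Bray-Curtis dissimilarity
#'
#' Baselga's abundance-based decomposition for one site pair: with
#' `A = sum(pmin(x, y))`, `B = sum(x) - A`, `C = sum(y) - A`, the total
#' dissimilarity `d_BC = (B + C) / (2A + B + C)` splits into a
#' balanced-variation component `min(B, C) / (A + min(B, C))` (abundances
#' of some species decline from one site to the other while others
#' increase by the same magnitude) and an abundance-gradient remainder
#' (all species declining or increasing together).
#'
#' @param x,y non-negative abundance vectors on a shared species list.
#' @return object of class `beta_decomposition`: `total`, `balanced`,
#'   `gradient` (components sum to `total`), `n_sites = 2`.
#' @examples
#' bray_curtis_partition(c(2, 2), c(1, 1)) # pure gradient, d = 1/3
#' @export
bray_curtis_partition <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) + sum(y) == 0) stop("both sites empty")
  A <- sum(pmin(x, y))
  B <- sum(x) - A
  C <- sum(y) - A
  total <- (B + C) / (2 * A + B + C)
  balanced <- if (A + min(B, C) == 0) 0 else min(B, C) / (A + min(B, C))
  structure(list(total = total, balanced = balanced,
                 gradient = total - balanced, n_sites = 2L),
            class = "beta_decomposition")
}

#' Multi-site balanced/gradient Bray-Curtis partition
#'
#' Components built from sums over all site pairs:
#' `balanced = sum min(B,C) / (sum A + sum min(B,C))` and
#' `total = (sum B + sum C) / (2 sum A + sum B + sum C)`, with
#' `gradient = total - balanced`. With two sites this reduces exactly to
#' [bray_curtis_partition()].
#'
#' @param mat abundance matrix, sites x species; every site needs a
#'   positive total.
#' @return object of class `beta_decomposition`.
#' @export
multi_site_bray <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least two sites")
  if (any(mat < 0)) stop("negative abundances")
  if (any(rowSums(mat) == 0)) stop("site with zero total abundance")
  sumA <- 0
  sumB <- 0
  sumC <- 0
  summin <- 0
  for (i in seq_len(nrow(mat) - 1)) for (j in (i + 1):nrow(mat)) {
    A <- sum(pmin(mat[i, ], mat[j, ]))
    B <- sum(mat[i, ]) - A
    C <- sum(mat[j, ]) - A
    sumA <- sumA + A
    sumB <- sumB + B
    sumC <- sumC + C
    summin <- summin + min(B, C)
  }
  total <- (sumB + sumC) / (2 * sumA + sumB + sumC)
  balanced <- if (sumA + summin == 0) 0 else summin / (sumA + summin)
  structure(list(total = total, balanced = balanced,
                 gradient = total - balanced, n_sites = nrow(mat)),
            class = "beta_decomposition")
}

#' @export
print.beta_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Bray-Curtis dissimilarity (%d sites): total = %.3f = ",
                     "balanced %.3f + gradient %.3f\n"),
              x$n_sites, x$total, x$balanced, x$gradient))
  invisible(x)
}
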