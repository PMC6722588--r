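## Network-level (H2') and species-level (d') specialization after
## Bluthgen's standardized Shannon/Kullback-Leibler indices. All entropies
## are in nats.

xlogx <- function(v) {
  out <- numeric(length(v))
  pos <- v > 0
  out[pos] <- v[pos] * log(v[pos])
  out
}

#' Two-dimensional Shannon entropy of an interaction web
#'
#' `H2 = -sum_ij p_ij ln p_ij` with `p_ij = a_ij / m`, the entropy of the
#' joint interaction frequency distribution.
#'
#' @param web an `interaction_web` (or count matrix).
#' @return entropy in nats, between 0 and `ln(#cells)`.
#' @examples
#' shannon_H2(matrix(c(1, 0, 0, 1), 2, 2)) # ln 2
#' @export
shannon_H2 <- function(web) {
  a <- as_interaction_web(web)$counts
  p <- a / sum(a)
  -sum(xlogx(p))
}

# proportional integer fill: floor of the marginal-product expectation,
# remainders handed one unit at a time to the feasible cell with the
# largest fractional part (ties by index)
fill_proportional <- function(r, c) {
  m <- sum(r)
  e <- outer(r, c) / m
  a <- floor(e)
  frac <- e - a
  dr <- r - rowSums(a)
  dc <- c - colSums(a)
  while (sum(dr) > 0) {
    ok <- outer(dr > 0, dc > 0, `&`)
    cand <- which(ok)
    pick <- cand[which.max(frac[cand])]
    i <- (pick - 1) %% length(r) + 1
    j <- (pick - 1) %/% length(r) + 1
    a[i, j] <- a[i, j] + 1
    dr[i] <- dr[i] - 1
    dc[j] <- dc[j] - 1
  }
  a
}

# greedy concentration fill: repeatedly place min(remaining row, remaining
# column) in the cell pairing the two largest remaining marginals; an
# optional forced first pairing seeds alternative concentration patterns
fill_concentrated <- function(r, c, first = NULL) {
  a <- matrix(0, length(r), length(c))
  r2 <- r
  c2 <- c
  place <- function(i, j) {
    x <- min(r2[i], c2[j])
    a[i, j] <<- a[i, j] + x
    r2[i] <<- r2[i] - x
    c2[j] <<- c2[j] - x
  }
  if (!is.null(first)) place(first[1], first[2])
  while (sum(r2) > 0) place(which.max(r2), which.max(c2))
  a
}

# which initial pairing the greedy starts from matters: a largest-largest
# start can be a local minimum no marginal-preserving 2x2 move escapes, so
# every (row, column) seed is tried and the most concentrated fill kept
fill_concentrated_best <- function(r, c) {
  best <- fill_concentrated(r, c)
  bg <- sum(xlogx(best))
  for (i in seq_along(r)) for (j in seq_along(c)) {
    a <- fill_concentrated(r, c, first = c(i, j))
    g <- sum(xlogx(a))
    if (g > bg + 1e-12) {
      best <- a
      bg <- g
    }
  }
  best
}

# deterministic first-improvement hill climb over the 2x2 unit moves that
# preserve both marginals; minimizes (or maximizes) sum v*log(v), i.e.
# maximizes (minimizes) the table entropy
entropy_refine <- function(a, maximize = TRUE, max_pass = 200) {
  nr <- nrow(a)
  nc <- ncol(a)
  if (nr < 2 || nc < 2) return(a)
  f <- function(v) if (v > 0) v * log(v) else 0
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(nr - 1)) for (ii in (i + 1):nr)
      for (j in seq_len(nc - 1)) for (jj in (j + 1):nc)
        for (s in c(1, -1)) {
          # move: a[i,j]+s, a[ii,jj]+s, a[i,jj]-s, a[ii,j]-s
          if (s == 1 && (a[i, jj] < 1 || a[ii, j] < 1)) next
          if (s == -1 && (a[i, j] < 1 || a[ii, jj] < 1)) next
          dg <- f(a[i, j] + s) - f(a[i, j]) + f(a[ii, jj] + s) - f(a[ii, jj]) +
                f(a[i, jj] - s) - f(a[i, jj]) + f(a[ii, j] - s) - f(a[ii, j])
          good <- if (maximize) dg < -1e-12 else dg > 1e-12
          if (good) {
            a[i, j] <- a[i, j] + s
            a[ii, jj] <- a[ii, jj] + s
            a[i, jj] <- a[i, jj] - s
            a[ii, j] <- a[ii, j] - s
            improved <- TRUE
          }
        }
    if (!improved) break
  }
  a
}

#' Entropy extrema of integer tables with fixed marginals
#'
#' Bounds for standardizing H2: `H2max` from the most even integer filling
#' consistent with both marginals (proportional fill with remainder
#' distribution), `H2min` from the greedy concentration fill; both are then
#' refined by a deterministic hill climb over marginal-preserving 2x2 unit
#' moves. On small tables the refined bounds coincide with exhaustive
#' enumeration over all integer tables with those marginals.
#'
#' @param row_totals,col_totals integer marginals with equal sums.
#' @return list with `H2min`, `H2max` (nats) and the two filled tables
#'   (`table_min`, `table_max`).
#' @examples
#' h2_extrema(c(6, 3), c(6, 3)) # H2min 0.6365, H2max 1.2730
#' @export
h2_extrema <- function(row_totals, col_totals) {
  r <- as.numeric(row_totals)
  c <- as.numeric(col_totals)
  if (any(r < 0) || any(c < 0)) stop("negative marginals")
  if (abs(sum(r) - sum(c)) > 1e-8) stop("row and column totals must have equal sums")
  if (sum(r) <= 0) stop("empty marginals")
  amax <- entropy_refine(fill_proportional(r, c), maximize = TRUE)
  amin <- entropy_refine(fill_concentrated_best(r, c), maximize = FALSE)
  list(H2min = shannon_H2(interaction_web(amin, trim = TRUE)),
       H2max = shannon_H2(interaction_web(amax, trim = TRUE)),
       table_min = amin, table_max = amax)
}

#' Network-level standardized specialization H2'
#'
#' `H2' = (H2max - H2) / (H2max - H2min)`: 1 means interactions are as
#' concentrated as the species marginals allow (maximal specialization),
#' 0 means they follow the marginal-product expectation (opportunistic
#' use). Returns 0 when the marginals admit only one table
#' (`H2max = H2min`).
#'
#' @param web an `interaction_web` (or count matrix).
#' @return list of class `specialization_result` with `H2`, `H2min`,
#'   `H2max` and `H2prime`.
#' @examples
#' h2prime(matrix(c(6, 0, 0, 3), 2, 2))$H2prime # 1
#' @export
h2prime <- function(web) {
  web <- as_interaction_web(web)
  H2 <- shannon_H2(web)
  ex <- h2_extrema(rowSums(web$counts), colSums(web$counts))
  denom <- ex$H2max - ex$H2min
  H2p <- if (denom <= 1e-12) 0 else (ex$H2max - H2) / denom
  structure(list(H2 = H2, H2min = ex$H2min, H2max = ex$H2max,
                 H2prime = min(max(H2p, 0), 1)),
            class = "specialization_result")
}

#' @export
print.specialization_result <- function(x, ...) {
  cat(sprintf("H2 = %.4f nats (bounds %.4f - %.4f), H2' = %.3f\n",
              x$H2, x$H2min, x$H2max, x$H2prime))
  invisible(x)
}

# shift single units between columns of one species' host-use vector to
# decrease (or increase) its KL divergence from q, keeping column caps
kl_refine <- function(v, q, caps, maximize = FALSE, max_pass = 200) {
  A <- sum(v)
  kl_term <- function(x, qq) if (x > 0) (x / A) * log((x / A) / qq) else 0
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_along(v)) for (jj in seq_along(v)) {
      if (j == jj || v[j] < 1 || v[jj] + 1 > caps[jj]) next
      dd <- kl_term(v[j] - 1, q[j]) - kl_term(v[j], q[j]) +
            kl_term(v[jj] + 1, q[jj]) - kl_term(v[jj], q[jj])
      good <- if (maximize) dd > 1e-12 else dd < -1e-12
      if (good) {
        v[j] <- v[j] - 1
        v[jj] <- v[jj] + 1
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  v
}

#' Species-level standardized selectivity d'
#'
#' For each species `i` at the chosen level, the Kullback-Leibler
#' divergence `d_i = sum_j p'_ij ln(p'_ij / q_j)` of its host-use
#' distribution `p'_ij = a_ij / A_i` from the overall resource availability
#' `q_j = A_j / m`, standardized to `d'_i = (d_i - d_min) / (d_max -
#' d_min)`. `d_max` comes from the marginal-feasible integer filling of
#' `A_i` into the scarcest resources (greedy into the columns with smallest
#' `q_j`, capped by the column marginals); `d_min` from the
#' closest-to-proportional integer filling; both are refined by
#' single-unit shift moves. `d' = 0` is assigned when `d_max = d_min`.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param axis `"insects"` (rows, default) or `"hosts"` (columns).
#' @return data frame with one row per species: `species`, `d`, `dmin`,
#'   `dmax`, `dprime`.
#' @export
dprime <- function(web, axis = c("insects", "hosts")) {
  axis <- match.arg(axis)
  web <- as_interaction_web(web)
  a <- web$counts
  if (axis == "hosts") a <- t(a)
  m <- sum(a)
  q <- colSums(a) / m
  caps <- colSums(a)
  kl <- function(v) {
    A <- sum(v)
    pos <- v > 0
    sum((v[pos] / A) * log((v[pos] / A) / q[pos]))
  }
  res <- lapply(seq_len(nrow(a)), function(i) {
    Ai <- sum(a[i, ])
    d <- kl(a[i, ])
    # most selective feasible fill: pack into the scarcest columns first
    ordq <- order(q, seq_along(q))
    vmax <- numeric(length(q))
    left <- Ai
    for (j in ordq) {
      take <- min(left, caps[j])
      vmax[j] <- take
      left <- left - take
      if (left == 0) break
    }
    vmax <- kl_refine(vmax, q, caps, maximize = TRUE)
    # closest-to-proportional integer fill
    vmin <- largest_remainder(Ai * q, Ai)
    vmin <- kl_refine(vmin, q, caps, maximize = FALSE)
    dmax <- kl(vmax)
    dmin <- kl(vmin)
    dp <- if (dmax - dmin <= 1e-12) 0 else (d - dmin) / (dmax - dmin)
    data.frame(species = rownames(a)[i], d = d, dmin = dmin, dmax = dmax,
               dprime = min(max(dp, 0), 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
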