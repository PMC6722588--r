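#' Patefield fixed-marginal random table
#'
#' Draws a random contingency table with exactly the given row and column
#' totals from the multivariate hypergeometric law of Patefield (1981) —
#' cells filled sequentially, each conditioned on the remaining marginals —
#' as implemented by [stats::r2dtable()].
#'
#' @param row_totals,col_totals non-negative integer marginals with equal
#'   sums.
#' @param n number of tables to draw.
#' @param seed optional seed (the caller's RNG state is restored).
#' @return a single integer matrix when `n = 1`, otherwise a list of them.
#' @export
patefield_sample <- function(row_totals, col_totals, n = 1, seed = NULL) {
  r <- as.integer(round(row_totals))
  c <- as.integer(round(col_totals))
  if (any(r < 0) || any(c < 0)) stop("negative marginals")
  if (sum(r) != sum(c)) stop("row and column totals must have equal sums")
  if (sum(r) == 0L) stop("empty marginals")
  draws <- with_seed(seed, stats::r2dtable(n, r, c))
  if (n == 1) draws[[1]] else draws
}

# named statistics usable by null_ensemble and the pipeline
resolve_statistic <- function(statistic) {
  if (is.function(statistic)) return(list(fn = statistic, name = "custom"))
  name <- match.arg(statistic, c("H2prime", "Q", "NO", "H2"))
  fn <- switch(name,
    H2prime = function(w) h2prime(w)$H2prime,
    Q = function(w) dirt_lpawb_plus(w, n_restarts = 5, seed = 1)$Q,
    NO = function(w) mean_niche_overlap(w, "insects"),
    H2 = shannon_H2)
  list(fn = fn, name = name)
}

#' Null-model ensemble of a network statistic
#'
#' Evaluates a statistic on `n` Patefield draws from the web's marginals
#' and compares it with the observed value via the Z-score
#' `(obs - mean(null)) / sd(null)` and the empirical tail probabilities
#' `p = (1 + b) / (n + 1)`. The conventional significance rule is
#' `|Z| >= 2`. A degenerate ensemble (`sd = 0`, e.g. a marginal-conserved
#' statistic) flags `degenerate = TRUE` and reports `Z = NA` rather than
#' erroring.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param statistic a function of a web returning one number, or one of
#'   `"H2prime"`, `"Q"`, `"NO"`, `"H2"`.
#' @param n number of randomizations (default 100).
#' @param seed RNG seed; ensembles are bit-reproducible given
#'   `(seed, n, statistic)`.
#' @return object of class `null_ensemble`: `observed`, `null` (length-n
#'   vector), `Z`, `p` (two-sided), `p_upper`, `p_lower`, `significant`
#'   (`|Z| >= 2`), `degenerate`, `n`, `seed`, `statistic`.
#' @export
null_ensemble <- function(web, statistic = "H2prime", n = 100, seed = 1) {
  web <- as_interaction_web(web)
  st <- resolve_statistic(statistic)
  r <- rowSums(web$counts)
  c <- colSums(web$counts)
  if (identical(st$name, "H2prime")) {
    # Patefield draws conserve the marginals, so the entropy bounds are
    # shared by the whole ensemble; compute them once
    ex <- h2_extrema(r, c)
    denom <- ex$H2max - ex$H2min
    st$fn <- function(w) {
      if (denom <= 1e-12) return(0)
      min(max((ex$H2max - shannon_H2(w)) / denom, 0), 1)
    }
  }
  obs <- st$fn(web)
  dn <- dimnames(web$counts)
  nulls <- with_seed(seed, {
    draws <- stats::r2dtable(n, r, c)
    vapply(draws, function(tab) {
      dimnames(tab) <- dn
      st$fn(interaction_web(tab, trim = FALSE))
    }, numeric(1))
  })
  s <- stats::sd(nulls)
  degenerate <- !is.finite(s) || s < 1e-15
  Z <- if (degenerate) NA_real_ else (obs - mean(nulls)) / s
  p_upper <- (1 + sum(nulls >= obs)) / (n + 1)
  p_lower <- (1 + sum(nulls <= obs)) / (n + 1)
  structure(list(observed = obs, null = nulls, Z = Z,
                 p = min(1, 2 * min(p_upper, p_lower)),
                 p_upper = p_upper, p_lower = p_lower,
                 significant = isTRUE(!degenerate && abs(Z) >= 2),
                 degenerate = degenerate, n = n, seed = seed,
                 statistic = st$name),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble (%s, n = %d): obs = %.4f, null %.4f +/- %.4f\n",
              x$statistic, x$n, x$observed, mean(x$null), stats::sd(x$null)))
  if (x$degenerate) cat("Z undefined (degenerate null: sd = 0)\n")
  else cat(sprintf("Z = %.2f (%ssignificant at |Z| >= 2), two-sided p = %.3f\n",
                   x$Z, if (x$significant) "" else "not ", x$p))
  invisible(x)
}
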