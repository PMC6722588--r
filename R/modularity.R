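## Barber's weighted bipartite modularity and its maximization by
## label propagation with module merging (LPAwb+), wrapped in a
## repeated-restart driver (DIRTLPAwb+-style).

#' Barber modularity of a bipartite partition
#'
#' `Q = (1/m) sum_ij (a_ij - k_i d_j / m) delta(g_i, h_j)` where `k_i` and
#' `d_j` are the row and column marginals and the delta compares the module
#' labels of insect `i` and host `j`. `Q = 0` when all nodes share one
#' module; `Q` always lies in \[-1, 1\].
#'
#' @param web an `interaction_web` (or count matrix).
#' @param row_labels,col_labels module id per row / column node.
#' @return Barber modularity.
#' @examples
#' barber_modularity(matrix(c(5, 0, 0, 5), 2, 2), c(1, 2), c(1, 2)) # 0.5
#' @export
barber_modularity <- function(web, row_labels, col_labels) {
  a <- as_interaction_web(web)$counts
  if (length(row_labels) != nrow(a) || length(col_labels) != ncol(a))
    stop("label vector length does not match web dimensions")
  m <- sum(a)
  B <- a - outer(rowSums(a), colSums(a)) / m
  sum(B[outer(row_labels, col_labels, `==`)]) / m
}

# core label-propagation + merge engine; B = a - k d'/m precomputed
lpawb_engine <- function(a, init_row_labels) {
  m <- sum(a)
  k <- rowSums(a)
  d <- colSums(a)
  B <- a - outer(k, d) / m
  gl <- as.integer(init_row_labels)
  hl <- rep(NA_integer_, ncol(a))
  propagate <- function(gl, hl, best) {
    repeat {
      labs <- sort(unique(gl))
      # each column adopts the row label with the largest modularity gain
      sc <- rowsum(B, gl)[as.character(labs), , drop = FALSE]
      hl <- labs[apply(sc, 2, which.max)]
      labs2 <- sort(unique(hl))
      sr <- t(rowsum(t(B), hl))[, as.character(labs2), drop = FALSE]
      gl <- labs2[apply(sr, 1, which.max)]
      Qn <- sum(B[outer(gl, hl, `==`)]) / m
      if (Qn <= best$Q + 1e-12) return(best)
      best <- list(gl = gl, hl = hl, Q = Qn)
    }
  }
  st <- propagate(gl, hl, list(gl = gl, hl = rep(gl[1], ncol(a)), Q = -Inf))
  # agglomeration: merge the module pair with the best positive gain, then
  # re-propagate; repeat until no merge improves Q
  repeat {
    labs <- sort(unique(c(st$gl, st$hl)))
    if (length(labs) < 2) break
    best <- 1e-12
    bp <- NULL
    for (x in seq_along(labs)[-1]) for (y in seq_len(x - 1)) {
      ri <- st$gl == labs[x] | st$gl == labs[y]
      cj <- st$hl == labs[x] | st$hl == labs[y]
      # gain = newly-joined cross terms between the two modules
      gain <- sum(B[st$gl == labs[x], st$hl == labs[y], drop = FALSE]) +
              sum(B[st$gl == labs[y], st$hl == labs[x], drop = FALSE])
      gain <- gain / m
      if (gain > best) {
        best <- gain
        bp <- c(labs[x], labs[y])
      }
    }
    if (is.null(bp)) break
    st$gl[st$gl == bp[1]] <- bp[2]
    st$hl[st$hl == bp[1]] <- bp[2]
    st$Q <- sum(B[outer(st$gl, st$hl, `==`)]) / m
    st <- propagate(st$gl, st$hl, st)
  }
  st
}

finish_partition <- function(a, st, seed) {
  labs <- sort(unique(c(st$gl, st$hl)))
  gl <- match(st$gl, labs)
  hl <- match(st$hl, labs)
  structure(list(row_labels = stats::setNames(gl, rownames(a)),
                 col_labels = stats::setNames(hl, colnames(a)),
                 Q = barber_modularity(a, gl, hl),
                 n_modules = length(unique(c(gl, hl))),
                 seed = seed),
            class = "module_partition")
}

#' Single-run weighted bipartite label propagation (LPAwb+)
#'
#' Rows start with unique labels (or a supplied initialization); columns
#' and rows then alternately adopt the label with the largest Barber
#' modularity gain (ties broken by the lowest module id, sweeps in
#' ascending index order, so the run is deterministic), and once
#' propagation stalls, module merges that increase Q are applied and
#' propagation resumes. Returns a locally optimal partition.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param seed recorded in the result for provenance; the single run is
#'   deterministic given its initialization.
#' @param init_row_labels optional integer initialization for row nodes.
#' @return object of class `module_partition`: `row_labels`, `col_labels`
#'   (module ids renumbered 1..n_modules), `Q`, `n_modules`, `seed`.
#' @export
lpawb_plus <- function(web, seed = NULL, init_row_labels = NULL) {
  a <- as_interaction_web(web)$counts
  if (is.null(init_row_labels)) init_row_labels <- seq_len(nrow(a))
  if (length(init_row_labels) != nrow(a)) stop("bad initialization length")
  finish_partition(a, lpawb_engine(a, init_row_labels), seed)
}

#' Repeated-restart modularity maximization (DIRTLPAwb+ style)
#'
#' Runs [lpawb_plus()] from `n_restarts` initializations — the canonical
#' unique-labels start, aggregated starts with `c = 2 ... min(dim)`
#' modules, and seeded uniform-random labelings — and keeps the partition
#' with the largest Q. Reproducible given `seed`.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param n_restarts number of restarts (>= 1), default 20.
#' @param seed integer seed driving the random initializations.
#' @return the best `module_partition` found.
#' @examples
#' w <- matrix(c(5, 0, 0, 5), 2, 2)
#' dirt_lpawb_plus(w, n_restarts = 4, seed = 1)$Q # 0.5
#' @export
dirt_lpawb_plus <- function(web, n_restarts = 20, seed = 1) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  a <- as_interaction_web(web)$counts
  cmax <- max(2L, min(dim(a)))
  with_seed(seed, {
    best <- lpawb_plus(a, seed = seed)
    r <- 1L
    cseq <- if (cmax >= 2) 2L:cmax else integer(0)
    ci <- 1L
    while (r < n_restarts) {
      r <- r + 1L
      init <- if (ci <= length(cseq)) {
        k <- cseq[ci]
        ci <- ci + 1L
        sample.int(k, nrow(a), replace = TRUE)
      } else {
        sample.int(sample.int(cmax, 1L), nrow(a), replace = TRUE)
      }
      cand <- lpawb_plus(a, seed = seed, init_row_labels = init)
      if (cand$Q > best$Q) best <- cand
    }
    best
  })
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Bipartite module partition: %d modules, Barber Q = %.4f\n",
              x$n_modules, x$Q))
  invisible(x)
}
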