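# Independent brute-force oracles and small data builders used across the
# suite. Everything here is deliberately naive so that it cannot share a
# defect with the implementation under test.

# all integer tables with the given margins, by row-wise recursion
enum_tables <- function(row_totals, col_totals) {
  out <- list()
  nr <- length(row_totals)
  nc <- length(col_totals)
  fill_row <- function(remaining, caps) {
    # all compositions of `remaining` into nc cells bounded by caps
    if (length(caps) == 1) {
      if (remaining <= caps) return(list(remaining)) else return(list())
    }
    res <- list()
    for (v in 0:min(remaining, caps[1]))
      for (rest in fill_row(remaining - v, caps[-1]))
        res[[length(res) + 1]] <- c(v, rest)
    res
  }
  rec <- function(rows_done, caps) {
    i <- length(rows_done) + 1
    if (i > nr) {
      if (all(caps == 0)) out[[length(out) + 1]] <<- do.call(rbind, rows_done)
      return()
    }
    for (row in fill_row(row_totals[i], caps))
      rec(c(rows_done, list(row)), caps - row)
  }
  rec(list(), col_totals)
  out
}

entropy_of <- function(a) {
  p <- a[a > 0] / sum(a)
  -sum(p * log(p))
}

# exact entropy range over all integer tables with the margins
enum_entropy_range <- function(row_totals, col_totals) {
  hs <- vapply(enum_tables(row_totals, col_totals), entropy_of, numeric(1))
  c(min = min(hs), max = max(hs))
}

# exhaustive Barber-Q maximum: every set partition of the rows (restricted
# growth strings) with the provably optimal per-column module choice
# (a column-only module contributes zero, so columns pick the best row
# module or stay neutral)
best_Q_exhaustive <- function(a) {
  m <- sum(a)
  B <- a - outer(rowSums(a), colSums(a)) / m
  n <- nrow(a)
  best <- -Inf
  rec <- function(labels, mx) {
    if (length(labels) == n) {
      q <- 0
      for (j in seq_len(ncol(a))) {
        s <- tapply(B[, j], labels, sum)
        q <- q + max(0, max(s))
      }
      best <<- max(best, q / m)
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(labels, v), max(mx, v))
  }
  rec(integer(0), 0L)
  best
}

# small random count web with no empty margins
random_web <- function(nr, nc, lambda = 2, seed = 1) {
  set.seed(seed)
  repeat {
    a <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) return(a)
  }
}

# record table from a named list unit -> named species counts, one host
records_from_units <- function(units, host = "HA", elevation = "low") {
  rows <- list()
  for (u in names(units)) {
    cts <- units[[u]]
    for (s in names(cts)) {
      rows[[length(rows) + 1]] <- data.frame(
        host = host, elevation = elevation, unit_id = u, species = s,
        count = cts[[s]], stringsAsFactors = FALSE)
    }
  }
  record_table(do.call(rbind, rows))
}
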