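#' Frequency/abundance index (IFA)
#'
#' `IFA = rf * ra * 100`, combining occupancy with numerical dominance:
#' `rf` is the proportion of a host's sampled infructescences occupied by
#' the species and `ra` the proportion of the individuals reared from that
#' host belonging to the species. Ranges from 0 (absent) to 100
#' (monodominant and present in every unit).
#'
#' @param rf relative frequency in \[0, 1\].
#' @param ra relative abundance in \[0, 1\].
#' @return IFA in \[0, 100\].
#' @examples
#' ifa_index(1, 0.4621) # 46.21
#' @export
ifa_index <- function(rf, ra) {
  if (any(rf < 0 | rf > 1) || any(ra < 0 | ra > 1))
    stop("rf and ra must lie in [0, 1]")
  rf * ra * 100
}

#' Per-host IFA table from rearing records
#'
#' For each insect species in the chosen host: `rf` = occupied units /
#' sampled units of that host, `ra` = species individuals / all
#' individuals reared from that host, `IFA = rf * ra * 100`; rows sorted by
#' IFA descending.
#'
#' @param records a [record_table()].
#' @param host host code; `NULL` (default) returns all hosts stacked.
#' @return data frame with columns `host`, `species`, `rf`, `ra`, `ifa`.
#' @export
ifa_table <- function(records, host = NULL) {
  hosts <- unique(as.character(records$host))
  if (!is.null(host)) {
    if (!host %in% hosts) stop("unknown host: ", host)
    hosts <- host
  }
  out <- lapply(hosts, function(h) {
    sub <- records[as.character(records$host) == h, , drop = FALSE]
    units <- unique(sub$unit_id)
    tot <- sum(sub$count)
    if (length(units) == 0L || tot == 0L)
      stop("host ", h, " has no sampled units with individuals")
    sp <- sort(unique(as.character(sub$species)))
    rows <- lapply(sp, function(s) {
      ss <- sub[as.character(sub$species) == s & sub$count > 0, , drop = FALSE]
      rf <- length(unique(ss$unit_id)) / length(units)
      ra <- sum(ss$count) / tot
      data.frame(host = h, species = s, rf = rf, ra = ra,
                 ifa = ifa_index(rf, ra), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[df$ra > 0, , drop = FALSE]
    df[order(-df$ifa, df$species), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate an interaction web into a guild-by-host count table
#'
#' Cell `(g, h)` sums the counts of all insect species of trophic guild `g`
#' in host `h`; marginals conserve the web totals.
#'
#' @param web an `interaction_web` (or count matrix).
#' @param guilds named character vector mapping every insect species of the
#'   web to its guild.
#' @return integer matrix, guilds x hosts.
#' @export
guild_abundance_table <- function(web, guilds) {
  a <- as_interaction_web(web)$counts
  miss <- setdiff(rownames(a), names(guilds))
  if (length(miss)) stop("species without guild: ", paste(miss, collapse = ", "))
  g <- as.character(guilds[rownames(a)])
  tab <- rowsum(a, g)
  tab[order(rownames(tab)), , drop = FALSE]
}

#' G-test of independence with the Williams correction
#'
#' Log-likelihood-ratio test for an r x c count table:
#' `G = 2 sum O ln(O / E)` with `E = row * col / N` (zero cells contribute
#' 0), Williams factor
#' `q = 1 + (N sum(1/R_i) - 1)(N sum(1/C_j) - 1) / (6 N (r-1)(c-1))`,
#' corrected statistic `G_adj = G / q`, and the p-value from the chi-square
#' upper tail of `G_adj` at `df = (r-1)(c-1)`.
#'
#' @param table matrix of non-negative counts with strictly positive row
#'   and column marginals (collapse empty levels first).
#' @return object of class `g_test`: `G`, `q`, `G_adj`, `df`, `p`.
#' @examples
#' williams_g_test(matrix(c(20, 10, 10, 20), 2, 2))
#' @export
williams_g_test <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("negative counts")
  R <- rowSums(O)
  C <- colSums(O)
  if (any(R == 0) || any(C == 0))
    stop("zero row or column marginal; collapse empty levels first")
  N <- sum(O)
  E <- outer(R, C) / N
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  q <- 1 + (N * sum(1 / R) - 1) * (N * sum(1 / C) - 1) / (6 * N * df)
  G_adj <- G / q
  structure(list(G = G, q = q, G_adj = G_adj, df = df,
                 p = stats::pchisq(G_adj, df, lower.tail = FALSE)),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf(paste0("Williams-corrected G-test: G = %.2f, q = %.4f, ",
                     "G_adj = %.2f, df = %d, p = %.3g\n"),
              x$G, x$q, x$G_adj, x$df, x$p))
  invisible(x)
}
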