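#' Curated survey tables
#'
#' The package ships, as plain-CSV fixtures, the printed data tables of the
#' Los Tuxtlas aroid-infructescence insect survey that all worked examples
#' and reproduction checks run on:
#'
#' * `"table1"` — infructescences sampled per host at each of the three
#'   elevation strata (BSLT low, La Perla mid, Caleria high); 250 units in
#'   total.
#' * `"table2"` — the 34 insect species x 8 hosts table of column-wise
#'   percentage abundance, per-species total specimens (16,120 individuals
#'   overall) and trophic-guild labels (P, S, M, P-S).
#' * `"table5"` — per-host relative frequency (proportion of that host's
#'   sampled infructescences occupied), relative abundance and the
#'   frequency/abundance index IFA for the dominant species of each host.
#'
#' Each table is transcribed verbatim; where the printed tables disagree on
#' per-host infructescence counts (e.g. 77 vs 73 for *D. oerstedii*) each
#' fixture keeps its own printed values, and IFA reproduction uses table 5's
#' denominators.
#'
#' @param name one of `"table1"`, `"table2"`, `"table5"`.
#' @return `"table1"`: data frame of unit counts per host x elevation with a
#'   `total` column. `"table2"`: an object of class `percentage_table`, a
#'   list with `pct` (34 x 8 matrix of percentages), `row_totals` (named
#'   per-species specimen totals), `grand_total`, `guilds` (named guild
#'   vector) and `species` (full names). `"table5"`: data frame with
#'   `host_code`, `n_units`, `species_code`, `rf`, `ra`, `ifa`.
#' @examples
#' t1 <- load_fixture("table1")
#' sum(t1$total) # 250 sampled infructescences
#' @export
load_fixture <- function(name = c("table1", "table2", "table5")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "aroidnet", mustWork = TRUE)
  switch(name,
    table1 = utils::read.csv(path("infructescence_counts.csv"),
                             stringsAsFactors = FALSE),
    table2 = {
      df <- utils::read.csv(path("abundance_percentages.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
      pct <- as.matrix(df[, c("Dioe", "Phin", "Phra", "Phsa",
                              "Phse", "Phtr", "Rhwe", "Xaro")])
      rownames(pct) <- df$code
      percentage_table(pct, row_totals = stats::setNames(df$total, df$code),
                       guilds = stats::setNames(df$guild, df$code),
                       species = stats::setNames(df$species, df$code))
    },
    table5 = utils::read.csv(path("ifa_reference.csv"), stringsAsFactors = FALSE)
  )
}

#' Column-percentage presentation of a count web
#'
#' A `percentage_table` is the published form of a quantitative web: each
#' column gives the percentage of that host's individuals belonging to each
#' insect species (non-zero columns sum to 100 up to printed rounding), and
#' the exact integers are the per-species row totals and the grand total.
#' [reconstruct_counts()] inverts this presentation.
#'
#' @param pct matrix of percentages in \[0, 100\], insects x hosts.
#' @param row_totals named integer vector of per-species specimen totals.
#' @param grand_total total individuals; defaults to `sum(row_totals)`.
#' @param guilds optional named guild vector carried along.
#' @param species optional named full-name vector carried along.
#' @param tol allowed deviation of non-zero column sums from 100.
#' @return an object of class `percentage_table`.
#' @export
percentage_table <- function(pct, row_totals, grand_total = sum(row_totals),
                             guilds = NULL, species = NULL, tol = 0.5) {
  pct <- as.matrix(pct)
  if (any(pct < 0) || any(pct > 100)) stop("percentages must lie in [0, 100]")
  cs <- colSums(pct)
  bad <- cs > 0 & abs(cs - 100) > tol
  if (any(bad)) stop("column(s) ", paste(colnames(pct)[bad], collapse = ", "),
                     " do not sum to 100 within tolerance")
  if (length(row_totals) != nrow(pct)) stop("row_totals length mismatch")
  if (abs(sum(row_totals) - grand_total) > 1e-8)
    stop("row totals do not add up to the grand total")
  structure(list(pct = pct, row_totals = row_totals, grand_total = grand_total,
                 guilds = guilds, species = species),
            class = "percentage_table")
}

#' @export
print.percentage_table <- function(x, ...) {
  cat("Percentage abundance table:", nrow(x$pct), "species x", ncol(x$pct),
      "hosts;", x$grand_total, "individuals\n")
  invisible(x)
}

#' The reconstructed survey interaction web
#'
#' Convenience wrapper: loads the percentage-abundance fixture and inverts
#' it to the 34 x 8 integer count web via [reconstruct_counts()]. Row sums
#' equal the printed per-species totals exactly and the grand total is
#' 16,120 individuals; host (column) totals are inferred by the constrained
#' least-squares solver.
#'
#' @return an `interaction_web`.
#' @examples
#' w <- aroid_web()
#' dim(w$counts)
#' @export
aroid_web <- function() {
  reconstruct_counts(load_fixture("table2"))
}

#' Trophic-guild labels of the survey species
#'
#' @return named character vector mapping species code to guild
#'   (`P`, `S`, `M`, `P-S`).
#' @export
aroid_guilds <- function() {
  load_fixture("table2")$guilds
}
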