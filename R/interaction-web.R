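#' Quantitative bipartite interaction web
#'
#' An `interaction_web` holds the integer count matrix of a quantitative
#' bipartite network: insect (consumer) species in rows, host plants in
#' columns, cell `a_ij` = number of individuals of insect `i` reared from
#' host `j`. The grand total `m` is the number of individuals in the web;
#' row sums `A_i` and column sums `A_j` are the species marginals every
#' specialization and null-model computation conditions on.
#'
#' @param counts numeric matrix of non-negative counts, insects x hosts.
#' @param row_labels,col_labels character labels; default taken from
#'   `dimnames(counts)`, or generated (`I1..`, `H1..`) when absent.
#' @param trim drop all-zero rows/columns (default `TRUE`). A web with an
#'   all-zero margin after trimming is an error.
#' @param round if `TRUE`, round cells within `sqrt(.Machine$double.eps)` of
#'   an integer; otherwise non-integer cells are rejected.
#' @return An object of class `interaction_web`: a list with elements
#'   `counts` (integer matrix with dimnames) and `m` (grand total).
#' @examples
#' w <- interaction_web(matrix(c(4, 2, 2, 1), 2, 2))
#' w$m
#' @export
interaction_web <- function(counts, row_labels = NULL, col_labels = NULL,
                            trim = TRUE, round = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be numeric")
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("negative interaction counts are not allowed")
  eps <- sqrt(.Machine$double.eps)
  off <- abs(counts - round(counts))
  if (any(off > eps)) {
    if (round) counts <- round(counts)
    else stop("non-integer counts; set `round = TRUE` to round them")
  }
  storage.mode(counts) <- "integer"
  if (is.null(row_labels)) row_labels <- rownames(counts)
  if (is.null(col_labels)) col_labels <- colnames(counts)
  if (is.null(row_labels)) row_labels <- paste0("I", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("H", seq_len(ncol(counts)))
  if (anyDuplicated(row_labels)) stop("duplicate row labels")
  if (anyDuplicated(col_labels)) stop("duplicate column labels")
  if (length(row_labels) != nrow(counts) || length(col_labels) != ncol(counts))
    stop("label length does not match matrix dimension")
  dimnames(counts) <- list(row_labels, col_labels)
  if (trim) counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) == 0L || ncol(counts) == 0L || sum(counts) == 0L)
    stop("web is empty after trimming")
  if (any(rowSums(counts) == 0L) || any(colSums(counts) == 0L))
    stop("web has an all-zero row or column (use trim = TRUE)")
  structure(list(counts = counts, m = sum(counts)), class = "interaction_web")
}

#' Coerce to an interaction web
#'
#' @param x an `interaction_web`, matrix or data frame of counts.
#' @param ... passed on to [interaction_web()].
#' @return an `interaction_web`.
#' @export
as_interaction_web <- function(x, ...) {
  if (inherits(x, "interaction_web")) return(x)
  interaction_web(x, ...)
}

#' @export
print.interaction_web <- function(x, ...) {
  cat("Quantitative interaction web:", nrow(x$counts), "insect species x",
      ncol(x$counts), "hosts,", x$m, "individuals\n")
  if (nrow(x$counts) <= 12L) print(x$counts) else {
    print(utils::head(x$counts, 10L))
    cat("... (", nrow(x$counts) - 10L, " more rows)\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.interaction_web <- function(x, ...) {
  z <- log10(t(x$counts) + 1)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  xlab = "host", ylab = "insect species", axes = FALSE,
                  main = "Interaction web (log10 counts)", ...)
  graphics::axis(1, seq_len(nrow(z)), rownames(z), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(z)), colnames(z), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Read / write a delimited interaction web
#'
#' `read_web` reads a CSV/TSV file whose first column holds row labels and
#' whose header holds column labels; `write_web` is its inverse
#' (UTF-8, LF line endings). The two round-trip cell-identically.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param orientation `"insects-rows"` (default) or `"insects-cols"`; the
#'   latter transposes on read so insects always end up in rows.
#' @param sep field separator override.
#' @param round passed to [interaction_web()].
#' @param trim passed to [interaction_web()].
#' @return `read_web`: an `interaction_web`. `write_web`: `path`, invisibly.
#' @export
read_web <- function(path, orientation = c("insects-rows", "insects-cols"),
                     sep = NULL, round = FALSE, trim = TRUE) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, quote = "\"",
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("malformed web file: non-numeric cells or header")
  if (orientation == "insects-cols") mat <- t(mat)
  interaction_web(mat, round = round, trim = trim)
}

#' @rdname read_web
#' @param web an `interaction_web`.
#' @export
write_web <- function(web, path, sep = ",") {
  web <- as_interaction_web(web)
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("", colnames(web$counts)), collapse = sep)
  body <- vapply(seq_len(nrow(web$counts)), function(i)
    paste(c(rownames(web$counts)[i], web$counts[i, ]), collapse = sep), "")
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Per-infructescence rearing records
#'
#' A `record_table` is the long-format sampling-unit view of the data: one
#' row per (host, elevation, infructescence, insect species) combination
#' with the number of individuals reared. `(host, unit_id)` pairs identify
#' sampling units (individual infructescences); aggregating over units
#' reproduces an [interaction_web()].
#'
#' @param df data frame with columns `host`, `elevation`, `unit_id`,
#'   `species`, `count` (non-negative integers).
#' @return the validated data frame with class `record_table` prepended.
#' @export
record_table <- function(df) {
  need <- c("host", "elevation", "unit_id", "species", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("record table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty record table")
  if (anyNA(df[need])) stop("record table contains missing values")
  if (any(df$count < 0)) stop("negative counts in record table")
  if (any(df$count != round(df$count))) stop("non-integer counts in record table")
  df$count <- as.integer(df$count)
  class(df) <- c("record_table", setdiff(class(df), "record_table"))
  df
}

#' Read a long-format record table from CSV
#'
#' @param path CSV path with columns `host,elevation,unit_id,species,count`.
#' @return a [record_table()].
#' @export
read_records <- function(path) {
  record_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Aggregate rearing records into an interaction web
#'
#' @param records a [record_table()].
#' @param trim drop all-zero rows/columns.
#' @return an `interaction_web` with insects in rows, hosts in columns.
#' @export
records_to_web <- function(records, trim = TRUE) {
  tab <- tapply(records$count, list(records$species, records$host), sum,
                default = 0L)
  interaction_web(tab, trim = trim)
}

#' Split records into per-stratum interaction webs
#'
#' One web per elevation stratum (or per host), trimmed of all-zero margins;
#' pooling the returned webs cell-wise reproduces the full web.
#'
#' @param records a [record_table()].
#' @param by stratification field, `"elevation"` or `"host"`.
#' @return named list of `interaction_web` objects, strata with no
#'   individuals omitted.
#' @export
stratify <- function(records, by = c("elevation", "host")) {
  by <- match.arg(by)
  keys <- unique(as.character(records[[by]]))
  out <- list()
  for (k in keys) {
    sub <- records[as.character(records[[by]]) == k, , drop = FALSE]
    if (sum(sub$count) == 0L) next
    out[[k]] <- records_to_web(record_table(sub))
  }
  out
}

# restore the RNG state after a seeded computation so package functions do
# not silently advance the caller's random stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
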