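## Synthetic per-infructescence community generator. Emulates the
## statistical structure the analyses assume — hosts sampled with unequal
## effort at three elevation strata, a dominance-skewed species-abundance
## distribution, planted modular host use, and species turnover along the
## gradient — so every pipeline stage can be validated against known
## ground truth.

#' Configuration for the synthetic community generator
#'
#' @param n_hosts,n_insects community dimensions.
#' @param units integer matrix `n_hosts x n_elevations` of sampling units
#'   (infructescences) per host and stratum; default 10 each.
#' @param n_elevations number of elevation strata (default 3); ignored when
#'   `units` is supplied.
#' @param insect_blocks,host_blocks planted module id per insect / host;
#'   default round-robin into `n_blocks` blocks.
#' @param n_blocks number of planted modules (default 3).
#' @param kappa within-block interaction concentration in \[0, 1\]: the
#'   probability an individual lands in a host of its species' own block
#'   (1 = perfectly modular, 0 = all individuals outside the block).
#' @param meanlog,sdlog lognormal species-abundance parameters; `sdlog`
#'   controls dominance (few hyperabundant species).
#' @param tau elevational turnover rate in \[0, 1\]: the fraction of the
#'   species pool replaced per stratum step (0 = identical pools,
#'   1 = complete replacement between adjacent strata).
#' @param seed RNG seed; generation is fully reproducible given the config.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_hosts = 8, n_insects = 20,
                             units = NULL, n_elevations = 3,
                             insect_blocks = NULL, host_blocks = NULL,
                             n_blocks = 3, kappa = 0.85,
                             meanlog = 3, sdlog = 1.5, tau = 0.3, seed = 1) {
  if (n_hosts < 1 || n_insects < 1) stop("dimensions must be >= 1")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (is.null(units))
    units <- matrix(10L, n_hosts, n_elevations)
  units <- as.matrix(units)
  if (nrow(units) != n_hosts) stop("units must have one row per host")
  if (any(units < 0) || sum(units) == 0) stop("no sampling units configured")
  n_elevations <- ncol(units)
  if (is.null(insect_blocks))
    insect_blocks <- rep(seq_len(n_blocks), length.out = n_insects)
  if (is.null(host_blocks))
    host_blocks <- rep(seq_len(n_blocks), length.out = n_hosts)
  if (length(insect_blocks) != n_insects || length(host_blocks) != n_hosts)
    stop("block map length mismatch")
  structure(list(n_hosts = n_hosts, n_insects = n_insects, units = units,
                 n_elevations = n_elevations,
                 insect_blocks = insect_blocks, host_blocks = host_blocks,
                 kappa = kappa, meanlog = meanlog, sdlog = sdlog,
                 tau = tau, seed = seed),
            class = "synthetic_config")
}

#' Configuration matching the survey design of the curated fixtures
#'
#' 8 hosts, 34 insect species, 3 elevation strata and the fixture's actual
#' 250-infructescence sampling layout (123 / 94 / 33 units at the low, mid
#' and high strata), with lognormal dominance set so the four most
#' abundant species hold roughly three quarters of all individuals.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
survey_config <- function(...) {
  t1 <- load_fixture("table1")
  units <- as.matrix(t1[, c("BSLT", "LaPerla", "Caleria")])
  rownames(units) <- t1$host_code
  defaults <- list(n_hosts = nrow(units), n_insects = 34, units = units,
                   n_blocks = 4, kappa = 0.85, meanlog = 3.5, sdlog = 3,
                   tau = 0.3, seed = 1)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

#' Generate a synthetic per-infructescence community
#'
#' Per-species total abundances are drawn from the lognormal dominance
#' distribution; each individual is assigned a host inside its species'
#' planted block with probability `kappa` and uniformly among the
#' remaining hosts otherwise; species pools turn over along the elevation
#' gradient via a sliding rank window (fraction `tau` replaced per stratum
#' step); individuals are spread over the elevations available to their
#' species in proportion to sampling effort and over the host's units by a
#' symmetric multinomial.
#'
#' @param config a [synthetic_config()].
#' @return a [record_table()] with attributes `web` (the aggregated
#'   `interaction_web`), `insect_blocks`, `host_blocks`, `pools` (species
#'   pool per elevation) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  hosts <- if (!is.null(rownames(cf$units))) rownames(cf$units)
           else sprintf("H%02d", seq_len(cf$n_hosts))
  elevs <- if (!is.null(colnames(cf$units))) colnames(cf$units)
           else c("low", "mid", "high", paste0("E", seq_len(max(0, cf$n_elevations - 3)) + 3))[seq_len(cf$n_elevations)]
  species <- sprintf("S%02d", seq_len(cf$n_insects))
  with_seed(cf$seed, {
    abund <- pmax(1L, as.integer(round(stats::rlnorm(cf$n_insects,
                                                     cf$meanlog, cf$sdlog))))
    # sliding rank window over a shuffled species order: adjacent strata
    # share a fraction (1 - tau) of their pools
    perm <- sample.int(cf$n_insects)
    E <- cf$n_elevations
    L <- max(1L, floor(cf$n_insects / (1 + cf$tau * (E - 1))))
    pools <- lapply(seq_len(E), function(e) {
      start <- 1L + round((e - 1) * cf$tau * L)
      sort(perm[seq.int(start, min(start + L - 1L, cf$n_insects))])
    })
    counts <- array(0L, dim = c(cf$n_insects, cf$n_hosts, E))
    for (i in seq_len(cf$n_insects)) {
      in_pool <- vapply(pools, function(p) i %in% p, TRUE)
      # a stratum is available if sampled units exist there
      elig <- which(in_pool & colSums(cf$units) > 0)
      if (!length(elig)) elig <- which(colSums(cf$units) > 0)
      wt_e <- colSums(cf$units)[elig]
      n_e <- as.integer(stats::rmultinom(1, abund[i], wt_e))
      for (kk in seq_along(elig)) {
        e <- elig[kk]
        if (n_e[kk] == 0L) next
        avail <- cf$units[, e] > 0
        inb <- avail & cf$host_blocks == cf$insect_blocks[i]
        outb <- avail & cf$host_blocks != cf$insect_blocks[i]
        w <- numeric(cf$n_hosts)
        if (any(inb)) w[inb] <- cf$kappa / sum(inb)
        if (any(outb)) w[outb] <- (1 - cf$kappa) / sum(outb)
        if (sum(w) == 0) w[avail] <- 1
        n_h <- as.integer(stats::rmultinom(1, n_e[kk], w))
        counts[i, , e] <- counts[i, , e] + n_h
      }
    }
    # spread each host x elevation x species total over that cell's units
    recs <- list()
    for (h in seq_len(cf$n_hosts)) for (e in seq_len(E)) {
      nu <- cf$units[h, e]
      if (nu == 0L) next
      ids <- sprintf("%s-%s-u%03d", hosts[h], elevs[e], seq_len(nu))
      for (i in seq_len(cf$n_insects)) {
        tot <- counts[i, h, e]
        if (tot == 0L) next
        per_unit <- as.integer(stats::rmultinom(1, tot, rep(1, nu)))
        keep <- per_unit > 0
        if (!any(keep)) next
        recs[[length(recs) + 1L]] <- data.frame(
          host = hosts[h], elevation = elevs[e], unit_id = ids[keep],
          species = species[i], count = per_unit[keep],
          stringsAsFactors = FALSE)
      }
    }
    out <- record_table(do.call(rbind, recs))
    web <- interaction_web(apply(counts, c(1, 2), sum),
                           row_labels = species, col_labels = hosts,
                           trim = TRUE)
    attr(out, "web") <- web
    attr(out, "insect_blocks") <- stats::setNames(cf$insect_blocks, species)
    attr(out, "host_blocks") <- stats::setNames(cf$host_blocks, hosts)
    attr(out, "pools") <- lapply(pools, function(p) species[p])
    attr(out, "config") <- cf
    out
  })
}
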