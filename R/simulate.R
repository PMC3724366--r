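#' Configuration for the synthetic interval generator
#'
#' Defaults emulate an exon-annotation workload on a compact test genome:
#' 10 chromosomes of 10 Mb, exon-scale interval lengths (lognormal around
#' 150 bp), nesting up to depth 4 driven by a per-interval child probability,
#' and a fraction of siblings shifted to overlap a neighbour partially.
#'
#' @param n_base_intervals Number of root-level (base) intervals.
#' @param genome_length Total genome length in bp, split evenly across
#'   chromosomes.
#' @param n_chrom Number of chromosomes (named `chr1..chrN`).
#' @param mean_length Mean base-interval length in bp.
#' @param child_prob Probability parameter for children: each interval above
#'   the deepest level spawns `Binomial(2, child_prob)` children strictly
#'   inside itself.
#' @param max_depth Maximum nesting depth (base intervals are depth 1).
#' @param child_frac Length of a child as a fraction of its parent, drawn
#'   uniformly from this 2-vector; both entries must lie in (0, 1) so a child
#'   is never as long as its parent.
#' @param partial_overlap Fraction of intervals (those with a preceding
#'   sibling) shifted so that they partially overlap that sibling.
#' @param seed Optional integer seed; identical config + seed gives identical
#'   output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_base_intervals = 1000, genome_length = 1e8,
                         n_chrom = 10, mean_length = 150, child_prob = 0.3,
                         max_depth = 4, child_frac = c(0.2, 0.6),
                         partial_overlap = 0.15, seed = NULL) {
  cfg <- list(n_base_intervals = as.numeric(n_base_intervals),
              genome_length = as.numeric(genome_length),
              n_chrom = as.integer(n_chrom),
              mean_length = as.numeric(mean_length),
              child_prob = as.numeric(child_prob),
              max_depth = as.integer(max_depth),
              child_frac = as.numeric(child_frac),
              partial_overlap = as.numeric(partial_overlap),
              seed = seed)
  if (cfg$n_base_intervals < 1 || cfg$genome_length < 1 || cfg$n_chrom < 1 ||
      cfg$mean_length < 1 || cfg$max_depth < 1) {
    stop("synth_config: counts and lengths must be positive", call. = FALSE)
  }
  if (cfg$child_prob < 0 || cfg$child_prob > 1 ||
      cfg$partial_overlap < 0 || cfg$partial_overlap > 1) {
    stop("synth_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$child_frac) != 2 || any(cfg$child_frac <= 0) ||
      any(cfg$child_frac >= 1) || cfg$child_frac[1] > cfg$child_frac[2]) {
    stop("synth_config: child_frac must be an increasing pair inside (0, 1); ",
         "a child as long as its parent is infeasible", call. = FALSE)
  }
  if (cfg$mean_length >= cfg$genome_length / cfg$n_chrom) {
    stop("synth_config: mean interval length exceeds chromosome length",
         call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic interval database
#'
#' Base intervals are placed uniformly across the genome with lognormal
#' lengths. Each interval at depth `d < max_depth` spawns
#' `Binomial(2, child_prob)` children strictly inside itself (children are
#' shorter than their parent by construction). Finally a `partial_overlap`
#' fraction of intervals that have a preceding sibling are shifted so they
#' straddle that sibling's end, producing partial overlaps; a shift is
#' skipped when it cannot produce a valid partial overlap within the
#' enclosing bounds. Labels are unique synthetic tokens carrying the nesting
#' depth. Output is deterministic for a given config and seed.
#'
#' @param config A [synth_config()].
#' @return An interval data frame with an extra `depth` column (dropped by
#'   [write_bed()]).
#' @export
generate_intervals <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    chrom_len <- floor(config$genome_length / config$n_chrom)
    nb <- config$n_base_intervals
    sdlog <- 0.8
    len <- pmax(2, round(stats::rlnorm(nb, meanlog = log(config$mean_length) -
                                         sdlog^2 / 2, sdlog = sdlog)))
    len <- pmin(len, chrom_len - 1)
    chrom_i <- sample.int(config$n_chrom, nb, replace = TRUE)
    start <- floor(stats::runif(nb, 0, chrom_len - len))
    lv <- list(data.frame(chrom_i = chrom_i, start = start, stop = start + len,
                          depth = 1, stringsAsFactors = FALSE))
    d <- 1L
    while (d < config$max_depth) {
      par <- lv[[d]]
      par <- par[par$stop - par$start >= 3, , drop = FALSE]
      if (nrow(par) == 0L) break
      nch <- stats::rbinom(nrow(par), 2L, config$child_prob)
      if (sum(nch) == 0L) break
      pi <- rep(seq_len(nrow(par)), nch)
      plen <- par$stop[pi] - par$start[pi]
      clen <- pmax(1, pmin(plen - 1,
                           round(plen * stats::runif(length(pi),
                                                     config$child_frac[1],
                                                     config$child_frac[2]))))
      off <- floor(stats::runif(length(pi), 0, plen - clen + 1))
      # a child spanning its parent exactly would be a sibling, not a child
      full <- clen >= plen
      cs <- par$start[pi] + off
      lv[[d + 1L]] <- data.frame(chrom_i = par$chrom_i[pi][!full],
                                 start = cs[!full], stop = (cs + clen)[!full],
                                 depth = d + 1, stringsAsFactors = FALSE)
      d <- d + 1L
    }
    iv <- do.call(rbind, lv)

    # partial-overlap shifts: within each (chromosome, depth) group ordered by
    # start, a selected interval is moved so it starts inside its predecessor
    # and ends beyond it
    if (config$partial_overlap > 0 && nrow(iv) > 1L) {
      o <- order(iv$chrom_i, iv$depth, iv$start, iv$stop, method = "radix")
      iv <- iv[o, , drop = FALSE]
      grp_new <- c(TRUE, diff(iv$chrom_i) != 0 | diff(iv$depth) != 0)
      pick <- stats::runif(nrow(iv)) < config$partial_overlap & !grp_new
      for (i in which(pick)) {
        w <- iv$stop[i] - iv$start[i]
        ps <- iv$start[i - 1L]; pe <- iv$stop[i - 1L]
        ns <- ps + max(1, floor((pe - ps) / 2))
        if (ns + w > pe && ns + w <= chrom_len && ns < pe) {
          iv$start[i] <- ns
          iv$stop[i] <- ns + w
        }
      }
    }
    genomic_intervals(paste0("chr", iv$chrom_i), iv$start, iv$stop,
                      sprintf("iv%06d_d%d", seq_len(nrow(iv)), iv$depth)) ->
      out
    out$depth <- iv$depth
    out
  })
}

#' Generate uniform random genomic positions
#'
#' Positions are drawn uniformly over `[0, genome_length)` and mapped onto
#' `n_chrom` equal-length chromosomes, emulating variant positions drawn
#' uniformly across a genome.
#'
#' @param n Number of positions.
#' @param genome_length Total genome length in bp.
#' @param n_chrom Number of chromosomes.
#' @param seed Optional integer seed.
#' @return A position data frame (`chrom`, `pos`).
#' @export
generate_positions <- function(n, genome_length = 1e8, n_chrom = 10,
                               seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  with_seed(seed, {
    chrom_len <- floor(genome_length / n_chrom)
    g <- floor(stats::runif(n, 0, chrom_len * n_chrom))
    genomic_positions(paste0("chr", g %/% chrom_len + 1), g %% chrom_len)
  })
}
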