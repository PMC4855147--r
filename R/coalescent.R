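# Heterochronous coalescent simulation of allele retention through a
# bottleneck, and the drift-null grid scan over (N_EB, N_EW).

#' Three-epoch demographic model on a years-BP time axis
#'
#' Piecewise-constant diploid effective sizes: an island population of
#' size `N_EW` from the present back to the end of the bottleneck, a
#' bottleneck of `N_EB` lasting `bottleneck_generations` generations and
#' ending at `bottleneck_start` years BP, and an ancestral population of
#' size `N_anc` before that.
#'
#' @param N_EW island (post-bottleneck) diploid effective size.
#' @param N_EB bottleneck diploid effective size.
#' @param N_anc ancestral diploid effective size (default 100,000).
#' @param bottleneck_start years BP at which the bottleneck begins,
#'   looking forward in time (default 12,000).
#' @param bottleneck_generations bottleneck duration (default 5).
#' @param generation_years years per generation (default 31).
#' @return Object of class `demography_model` with epoch starts (in
#'   generations BP) and sizes.
#' @export
demography_model <- function(N_EW, N_EB, N_anc = 1e5,
                             bottleneck_start = 12000,
                             bottleneck_generations = 5,
                             generation_years = 31) {
  stopifnot(N_EW >= 1, N_EB >= 1, N_anc >= 1, bottleneck_start > 0,
            bottleneck_generations >= 0, generation_years > 0)
  g_start <- bottleneck_start / generation_years
  g_end <- g_start - bottleneck_generations
  if (g_end < 0) stop("bottleneck longer than its start time")
  structure(list(N_EW = N_EW, N_EB = N_EB, N_anc = N_anc,
                 bottleneck_start = bottleneck_start,
                 bottleneck_generations = bottleneck_generations,
                 generation_years = generation_years,
                 epoch_starts_gen = c(0, g_end, g_start),
                 epoch_sizes = c(N_EW, N_EB, N_anc)),
            class = "demography_model")
}

#' Constant-size demography (no bottleneck)
#'
#' Degenerate single-epoch model, used for calibration checks against
#' closed-form coalescent results.
#'
#' @param N diploid effective size.
#' @param generation_years years per generation (default 31).
#' @return A `demography_model` with one epoch.
#' @export
constant_demography <- function(N, generation_years = 31) {
  structure(list(N_EW = N, N_EB = N, N_anc = N,
                 bottleneck_start = NA_real_,
                 bottleneck_generations = 0,
                 generation_years = generation_years,
                 epoch_starts_gen = 0, epoch_sizes = N),
            class = "demography_model")
}

#' Serial sampling scheme for the simulator
#'
#' Each sampled diploid contributes two gene copies entering the genealogy
#' at its calibrated age. Samples older than `ancestral_min_age` (default
#' 12,000 years BP, the bottleneck onset) form the ancestral stratum, the
#' rest the island stratum.
#'
#' @param ages_cal_bp numeric vector, one age per sampled diploid.
#' @param loci named integer vector of locus fragment lengths in bp
#'   (default the three DQA fragments: 99, 89, 92).
#' @param ancestral_min_age stratum split in years BP (default 12,000).
#' @return Object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(ages_cal_bp,
                            loci = c(exon2 = 99L, intron2a = 89L,
                                     exon4 = 92L),
                            ancestral_min_age = 12000) {
  stopifnot(all(ages_cal_bp >= 0), length(ages_cal_bp) >= 1,
            !is.null(names(loci)))
  period <- ifelse(ages_cal_bp > ancestral_min_age, "ancestral", "island")
  structure(list(ages_cal_bp = as.numeric(ages_cal_bp),
                 period = period, loci = loci,
                 ancestral_min_age = ancestral_min_age),
            class = "sampling_scheme")
}

#' Sampling scheme of the dated mammoth specimens
#'
#' The packaged calibrated ages ([mammoth_samples()]): 12 ancestral
#' (> 12 ka) and 12 island diploids, at the three DQA fragment lengths.
#'
#' @inheritParams sampling_scheme
#' @return A [sampling_scheme()].
#' @export
mammoth_sampling_scheme <- function(loci = c(exon2 = 99L, intron2a = 89L,
                                             exon4 = 92L),
                                    ancestral_min_age = 12000) {
  sampling_scheme(mammoth_samples()$age_cal_bp, loci = loci,
                  ancestral_min_age = ancestral_min_age)
}

# gene-copy entry times in generations BP (two copies per diploid)
copy_times_gen <- function(scheme, demography) {
  rep(scheme$ages_cal_bp, each = 2) / demography$generation_years
}

copy_periods <- function(scheme) rep(scheme$period, each = 2)

#' Simulate heterochronous genealogies
#'
#' One independent genealogy per locus: gene copies enter at their
#' sampling times and, within an epoch of diploid size N, each pair of
#' lineages coalesces at rate 1/(2N) per generation (continuous-time
#' approximation; a discrete-generation Wright-Fisher mode is available
#' for cross-checking at small N).
#'
#' @param demography a [demography_model()].
#' @param scheme a [sampling_scheme()].
#' @param seed optional integer seed.
#' @param discrete use the generation-by-generation mode.
#' @return named list (per locus) of `genealogy` objects: `parent`
#'   (0-based, -1 at the root), `node_time` (generations BP), `n_tip`,
#'   `tip_period`.
#' @export
simulate_genealogy <- function(demography, scheme, seed = NULL,
                               discrete = FALSE) {
  stopifnot(inherits(demography, "demography_model"),
            inherits(scheme, "sampling_scheme"))
  if (!is.null(seed)) set.seed(seed)
  times <- copy_times_gen(scheme, demography)
  periods <- copy_periods(scheme)
  out <- lapply(names(scheme$loci), function(l) {
    g <- cpp_coalesce(times, demography$epoch_starts_gen,
                      demography$epoch_sizes, discrete)
    structure(list(parent = g$parent, node_time = g$node_time,
                   n_tip = length(times), tip_period = periods,
                   locus_id = l), class = "genealogy")
  })
  names(out) <- names(scheme$loci)
  out
}

#' Drop finite-sites mutations on a genealogy
#'
#' Mutations occur along each branch as a Poisson process at rate
#' `mu_per_site * locus_length` per generation; each hits a uniform site
#' and substitutes a uniform different base (no transition bias). The
#' root sequence is uniform random.
#'
#' @param genealogy a `genealogy` from [simulate_genealogy()].
#' @param locus_length fragment length in bp.
#' @param mu_per_site mutation rate per site per generation.
#' @param seed optional integer seed.
#' @return character vector of tip sequences, in tip order.
#' @export
drop_mutations <- function(genealogy, locus_length, mu_per_site,
                           seed = NULL) {
  stopifnot(inherits(genealogy, "genealogy"), mu_per_site >= 0,
            locus_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  cpp_tip_sequences(genealogy$parent, genealogy$node_time,
                    genealogy$n_tip, as.integer(locus_length),
                    mu_per_site)
}

#' Convert a genealogy to an ape-style "phylo" object
#'
#' @param genealogy a `genealogy` from [simulate_genealogy()].
#' @return A `phylo` list (edge, edge.length, tip.label, Nnode).
#' @export
genealogy_to_phylo <- function(genealogy) {
  n <- genealogy$n_tip
  if (n < 2) stop("phylo conversion needs >= 2 tips")
  n_nodes <- 2 * n - 1
  # ape numbering: tips 1..n, root n+1; our internals were created in
  # increasing time order so the oldest (index 2n-2) is the root
  map <- c(seq_len(n), rev(seq(n + 1, n_nodes)))
  parent <- genealogy$parent
  child <- which(parent >= 0)
  edge <- cbind(map[parent[child] + 1L], map[child])
  len <- genealogy$node_time[parent[child] + 1L] -
    genealogy$node_time[child]
  structure(list(edge = edge, edge.length = len,
                 tip.label = paste0("t", seq_len(n), "_",
                                    genealogy$tip_period),
                 Nnode = n - 1L), class = "phylo")
}

#' Allele retention statistic
#'
#' Counts distinct sequences per locus in the ancestral and island
#' samples; `A_shared` counts ancestral alleles whose exact sequence also
#' occurs in the island sample. Counts are summed over loci and the
#' retained fraction is `A_shared / A_anc` (optionally `A_island /
#' A_anc`).
#'
#' @param tip_sequences named list (per locus) of tip sequence vectors.
#' @param periods character vector per tip, `"ancestral"` or `"island"`
#'   (recycled across loci).
#' @param threshold retained-fraction threshold (default 0.63, i.e.
#'   12 of 19 alleles).
#' @param statistic `"island_count"` (default): the fraction is the ratio
#'   of island to ancestral allele numbers, the quantity a per-population
#'   allele-count summary yields; or `"shared"`: only ancestral alleles
#'   whose exact sequence recurs in the island sample count.
#' @return Object of class `retention_statistic`: list with `A_anc`,
#'   `A_shared`, `A_island`, `fraction`, `retained`, `per_locus`.
#' @export
retention_statistic <- function(tip_sequences, periods, threshold = 0.63,
                                statistic = c("island_count", "shared")) {
  statistic <- match.arg(statistic)
  if (!is.list(tip_sequences)) tip_sequences <- list(tip_sequences)
  anc_i <- periods == "ancestral"
  isl_i <- periods == "island"
  if (!any(anc_i) || !any(isl_i))
    stop("both periods must be sampled")
  per_locus <- do.call(rbind, lapply(seq_along(tip_sequences),
                                     function(k) {
    seqs <- tip_sequences[[k]]
    anc <- unique(seqs[anc_i])
    isl <- unique(seqs[isl_i])
    data.frame(locus = k, A_anc = length(anc),
               A_shared = sum(anc %in% isl), A_island = length(isl))
  }))
  A_anc <- sum(per_locus$A_anc)
  A_shared <- sum(per_locus$A_shared)
  A_island <- sum(per_locus$A_island)
  num <- if (statistic == "shared") A_shared else A_island
  fraction <- num / A_anc
  structure(list(A_anc = A_anc, A_shared = A_shared,
                 A_island = A_island, fraction = fraction,
                 threshold = threshold,
                 retained = fraction >= threshold,
                 per_locus = per_locus), class = "retention_statistic")
}

# one simulation: genealogy + mutations per locus, retention counts
simulate_retention_once <- function(demography, scheme, mu,
                                    discrete = FALSE) {
  times <- copy_times_gen(scheme, demography)
  anc_i <- copy_periods(scheme) == "ancestral"
  A_anc <- A_shared <- A_island <- 0L
  for (L in scheme$loci) {
    g <- cpp_coalesce(times, demography$epoch_starts_gen,
                      demography$epoch_sizes, discrete)
    seqs <- cpp_tip_sequences(g$parent, g$node_time, length(times),
                              as.integer(L), mu)
    anc <- unique(seqs[anc_i])
    isl <- unique(seqs[!anc_i])
    A_anc <- A_anc + length(anc)
    A_shared <- A_shared + sum(anc %in% isl)
    A_island <- A_island + length(isl)
  }
  c(A_anc = A_anc, A_shared = A_shared, A_island = A_island)
}

#' Replicated retention simulations at one parameter combination
#'
#' @param demography a [demography_model()].
#' @param scheme a [sampling_scheme()].
#' @param n_sims number of simulations.
#' @param mu mutation rate per site per generation (default 1e-7).
#' @param seed optional integer seed.
#' @param discrete use the discrete-generation coalescent mode.
#' @param statistic retained-fraction definition, as in
#'   [retention_statistic()].
#' @return data.frame with one row per simulation: `A_anc`, `A_shared`,
#'   `A_island`, `fraction`.
#' @export
simulate_retention <- function(demography, scheme, n_sims, mu = 1e-7,
                               seed = NULL, discrete = FALSE,
                               statistic = c("island_count", "shared")) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n_sims, 3)
  for (s in seq_len(n_sims)) {
    out[s, ] <- simulate_retention_once(demography, scheme, mu,
                                        discrete = discrete)
  }
  df <- as.data.frame(out)
  names(df) <- c("A_anc", "A_shared", "A_island")
  num <- if (statistic == "shared") df$A_shared else df$A_island
  df$fraction <- num / df$A_anc
  df
}

#' Log-spaced grid values
#'
#' @param n number of points (default 20).
#' @param lower,upper range (defaults 2 and 10,000).
#' @return numeric vector, equally spaced on the log scale.
#' @export
log_grid <- function(n = 20, lower = 2, upper = 10000) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Drift-null probability surface over (N_EB, N_EW)
#'
#' For each grid cell, runs `n_sims` retention simulations and records
#' `P = P(retained fraction >= threshold)` with an exact binomial
#' confidence interval. Cells with `P < alpha` reject the null hypothesis
#' that drift alone explains the observed allele loss.
#'
#' @param scheme a [sampling_scheme()].
#' @param N_EB_values,N_EW_values grid values (diploid sizes), e.g. from
#'   [log_grid()].
#' @param n_sims simulations per cell (default 1000).
#' @param mu mutation rate per site per generation (default 1e-7).
#' @param N_anc ancestral diploid size (default 100,000).
#' @param threshold retained-fraction threshold (default 0.63).
#' @param alpha rejection level (default 0.05).
#' @param seed optional integer seed.
#' @param condition_A_anc optional `c(lo, hi)`: restrict to simulations
#'   whose ancestral allele count falls in the range (sensitivity option;
#'   default off).
#' @param statistic retained-fraction definition, as in
#'   [retention_statistic()].
#' @param ... passed to [demography_model()] (bottleneck timing etc.).
#' @return Object of class `probability_surface`: data.frame `grid` with
#'   `N_EB`, `N_EW`, `P`, `ci_low`, `ci_high`, `n_used`, plus `alpha` and
#'   `threshold`.
#' @export
run_grid <- function(scheme, N_EB_values, N_EW_values, n_sims = 1000,
                     mu = 1e-7, N_anc = 1e5, threshold = 0.63,
                     alpha = 0.05, seed = NULL, condition_A_anc = NULL,
                     statistic = c("island_count", "shared"), ...) {
  stopifnot(n_sims >= 1)
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (neb in N_EB_values) {
    for (new in N_EW_values) {
      dem <- demography_model(N_EW = new, N_EB = neb, N_anc = N_anc, ...)
      sims <- simulate_retention(dem, scheme, n_sims, mu = mu,
                                 statistic = statistic)
      if (!is.null(condition_A_anc)) {
        sims <- sims[sims$A_anc >= condition_A_anc[1] &
                       sims$A_anc <= condition_A_anc[2], , drop = FALSE]
      }
      n_used <- nrow(sims)
      k <- sum(sims$fraction >= threshold)
      ci <- if (n_used > 0)
        stats::binom.test(k, n_used)$conf.int else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        N_EB = neb, N_EW = new, P = if (n_used) k / n_used else NA_real_,
        ci_low = ci[1], ci_high = ci[2], n_used = n_used)
    }
  }
  structure(list(grid = do.call(rbind, rows), alpha = alpha,
                 threshold = threshold, n_sims = n_sims),
            class = "probability_surface")
}

#' @export
print.probability_surface <- function(x, ...) {
  cat("drift-null probability surface:",
      length(unique(x$grid$N_EB)), "x", length(unique(x$grid$N_EW)),
      "cells,", x$n_sims, "sims/cell, threshold", x$threshold, "\n")
  cat(sum(x$grid$P < x$alpha, na.rm = TRUE), "cell(s) with P <",
      x$alpha, "\n")
  invisible(x)
}

#' Write a probability surface to CSV
#'
#' @param surface a `probability_surface`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(surface$grid, path, row.names = FALSE)
  invisible(path)
}

#' Largest island size at which the drift null is rejected
#'
#' Scans grid columns (N_EW values) restricted to rows with
#' `N_EB >= min_NEB` and returns the largest N_EW whose cells all have
#' `P < alpha`, together with the bracketing interval up to the next grid
#' value (the grid-resolution uncertainty).
#'
#' @param surface a `probability_surface` from [run_grid()].
#' @param alpha rejection level (default 0.05).
#' @param min_NEB smallest bottleneck size to include (default 10).
#' @return list with `N_EW` (NA when no column is rejected), `bracket`
#'   (c(boundary, next grid value)) and `rejected_columns`.
#' @export
rejection_boundary <- function(surface, alpha = 0.05, min_NEB = 10) {
  g <- surface$grid[surface$grid$N_EB >= min_NEB, , drop = FALSE]
  if (!nrow(g)) stop("no grid rows with N_EB >= ", min_NEB)
  news <- sort(unique(g$N_EW))
  rejected <- vapply(news, function(w) {
    all(g$P[g$N_EW == w] < alpha, na.rm = TRUE)
  }, logical(1))
  if (!any(rejected)) {
    return(list(N_EW = NA_real_, bracket = c(NA_real_, NA_real_),
                rejected_columns = numeric(0)))
  }
  boundary <- max(news[rejected])
  nxt <- news[news > boundary]
  list(N_EW = boundary,
       bracket = c(boundary, if (length(nxt)) min(nxt) else Inf),
       rejected_columns = news[rejected])
}
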