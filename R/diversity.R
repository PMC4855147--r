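# Temporal genetic-diversity statistics: H_O, H_E, allele counts, unique
# alleles, hypergeometric rarefaction of allelic richness, the 2x2
# heterozygote chi-square test and percent-decline summaries.

period_calls <- function(matrix, locus, period) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!"period" %in% names(matrix$samples))
    stop("samples carry no period labels; run assign_periods() first")
  ids <- matrix$samples$sample_id[matrix$samples$period == period]
  matrix$calls[matrix$calls$locus_id == locus &
                 matrix$calls$sample_id %in% ids, , drop = FALSE]
}

#' Observed heterozygosity
#'
#' Fraction of diploid samples whose two alleles differ, for one locus and
#' temporal period.
#'
#' @param matrix a [genotype_matrix()] with period labels (see
#'   [assign_periods()]).
#' @param locus locus id.
#' @param period period label.
#' @return H_O in `[0, 1]`; errors when the locus/period has no genotypes.
#' @export
observed_heterozygosity <- function(matrix, locus, period) {
  g <- period_calls(matrix, locus, period)
  if (!nrow(g)) stop("no genotypes for ", locus, " / ", period)
  mean(g$allele1 != g$allele2)
}

#' Unbiased expected heterozygosity
#'
#' `H_E = n/(n-1) * (1 - sum(p_i^2))` with `n` the number of gene copies
#' (twice the diploid sample count) and `p_i` the sample allele
#' frequencies — the small-sample-corrected (unbiased) estimator.
#'
#' @inheritParams observed_heterozygosity
#' @param unbiased apply the `n/(n-1)` correction (default TRUE).
#' @return H_E in `[0, 1]`.
#' @export
expected_heterozygosity <- function(matrix, locus, period,
                                    unbiased = TRUE) {
  g <- period_calls(matrix, locus, period)
  copies <- c(g$allele1, g$allele2)
  n <- length(copies)
  if (n < 2) stop("need >= 2 gene copies for H_E at ", locus, "/", period)
  p <- as.vector(table(copies)) / n
  h <- 1 - sum(p^2)
  if (unbiased) h * n / (n - 1) else h
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies
#' drawn without replacement from the observed copies — the hypergeometric
#' expectation `sum_j [1 - choose(N - N_j, g) / choose(N, g)]` used to
#' compare allele numbers at a standardized sample size.
#'
#' @param allele_copy_counts integer vector of gene-copy counts per allele.
#' @param g subsample size, `1 <= g <= sum(counts)`.
#' @return Expected distinct alleles (real).
#' @examples
#' rarefied_allele_richness(c(12, 8, 4), 24)  # = 3, the full sample
#' @export
rarefied_allele_richness <- function(allele_copy_counts, g) {
  counts <- allele_copy_counts[allele_copy_counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must be in [1, ", N, "], got ", g)
  # log-scale binomials to stay exact-ish for large N
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefaction curve for one locus and period
#'
#' @param matrix a [genotype_matrix()] with period labels.
#' @param locus locus id.
#' @param period period label.
#' @param g_max standardized maximum subsample size in gene copies
#'   (default 24, i.e. 12 diploids); capped at the available copies.
#' @return data.frame with `g` (1..g_max) and `expected_distinct_alleles`
#'   (non-decreasing in `g`).
#' @export
rarefaction_curve <- function(matrix, locus, period, g_max = 24) {
  g <- period_calls(matrix, locus, period)
  counts <- as.vector(table(c(g$allele1, g$allele2)))
  gmax <- min(g_max, sum(counts))
  data.frame(locus_id = locus, period = period, g = seq_len(gmax),
             expected_distinct_alleles = vapply(
               seq_len(gmax), function(k)
                 rarefied_allele_richness(counts, k), numeric(1)))
}

#' Heterozygote-frequency chi-square test
#'
#' Pearson chi-square on the 2x2 table of heterozygote/homozygote counts
#' in two groups, without continuity correction (the uncorrected statistic
#' is what the printed per-locus values use); p from the chi-square
#' distribution with 1 df. Yates' correction is available as an option.
#'
#' @param het_a,hom_a heterozygote and homozygote counts in group A.
#' @param het_b,hom_b counts in group B.
#' @param correct apply Yates' continuity correction (default FALSE).
#' @return list with `table`, `chi2`, `p`.
#' @examples
#' het_chi_square(12, 0, 4, 8)$chi2  # 12
#' @export
het_chi_square <- function(het_a, hom_a, het_b, hom_b, correct = FALSE) {
  tab <- matrix(c(het_a, hom_a, het_b, hom_b), nrow = 2,
                dimnames = list(c("het", "hom"), c("A", "B")))
  stopifnot(all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: a margin of the 2x2 table is zero")
  res <- suppressWarnings(
    stats::chisq.test(tab, correct = correct))
  list(table = tab, chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Per-locus diversity table for both periods
#'
#' @param matrix a [genotype_matrix()] with period labels.
#' @param periods the two period labels to compare (first is the
#'   reference, typically the older stratum).
#' @param unbiased_he use the unbiased H_E estimator (default TRUE).
#' @return data.frame with one row per locus x period: `n_samples`, `H_O`,
#'   `H_E`, `N_A` and `unique_alleles` (alleles absent from the other
#'   period at the same locus).
#' @export
locus_diversity <- function(matrix, periods = c("mainland", "island"),
                            unbiased_he = TRUE) {
  loci <- unique(matrix$calls$locus_id)
  out <- list()
  for (l in loci) {
    alleles_by_period <- lapply(periods, function(p) {
      g <- period_calls(matrix, l, p)
      unique(c(g$allele1, g$allele2))
    })
    for (i in seq_along(periods)) {
      p <- periods[i]
      g <- period_calls(matrix, l, p)
      if (!nrow(g)) stop("no genotypes for ", l, " in period ", p)
      other <- alleles_by_period[[if (i == 1) 2 else 1]]
      out[[length(out) + 1L]] <- data.frame(
        locus_id = l, period = p, n_samples = nrow(g),
        H_O = observed_heterozygosity(matrix, l, p),
        H_E = expected_heterozygosity(matrix, l, p,
                                      unbiased = unbiased_he),
        N_A = length(alleles_by_period[[i]]),
        unique_alleles = sum(!alleles_by_period[[i]] %in% other),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Temporal diversity summary with percent declines
#'
#' Per-locus statistics for the two periods, their across-locus means and
#' sample SDs, and the percent decline of each mean from the first
#' (reference) period to the second, rounded to the nearest integer:
#' `100 * (mean_ref - mean_other) / mean_ref`.
#'
#' @inheritParams locus_diversity
#' @return list with `per_locus` (from [locus_diversity()]), `means`
#'   (period x statistic means and SDs) and `percent_decline` (named
#'   vector for H_O, H_E, N_A).
#' @export
temporal_summary <- function(matrix, periods = c("mainland", "island"),
                             unbiased_he = TRUE) {
  pl <- locus_diversity(matrix, periods = periods,
                        unbiased_he = unbiased_he)
  stats_cols <- c("H_O", "H_E", "N_A")
  means <- do.call(rbind, lapply(periods, function(p) {
    sub <- pl[pl$period == p, ]
    data.frame(period = p,
               stat = stats_cols,
               mean = vapply(stats_cols, function(s) mean(sub[[s]]),
                             numeric(1)),
               sd = vapply(stats_cols, function(s) stats::sd(sub[[s]]),
                           numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  decline <- vapply(stats_cols, function(s) {
    m1 <- means$mean[means$period == periods[1] & means$stat == s]
    m2 <- means$mean[means$period == periods[2] & means$stat == s]
    round(100 * (m1 - m2) / m1)
  }, numeric(1))
  list(per_locus = pl, means = means, percent_decline = decline)
}

#' Heterozygote chi-square tests for every locus
#'
#' Derives het/hom counts from the calls of each period and applies
#' [het_chi_square()] per locus.
#'
#' @inheritParams locus_diversity
#' @return data.frame with per-locus counts, `chi2` and `p`.
#' @export
het_tests <- function(matrix, periods = c("mainland", "island")) {
  loci <- unique(matrix$calls$locus_id)
  do.call(rbind, lapply(loci, function(l) {
    cnt <- lapply(periods, function(p) {
      g <- period_calls(matrix, l, p)
      c(het = sum(g$allele1 != g$allele2),
        hom = sum(g$allele1 == g$allele2))
    })
    res <- het_chi_square(cnt[[1]]["het"], cnt[[1]]["hom"],
                          cnt[[2]]["het"], cnt[[2]]["hom"])
    data.frame(locus_id = l,
               het_a = cnt[[1]][["het"]], hom_a = cnt[[1]][["hom"]],
               het_b = cnt[[2]][["het"]], hom_b = cnt[[2]][["hom"]],
               chi2 = res$chi2, p = res$p, stringsAsFactors = FALSE)
  }))
}
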