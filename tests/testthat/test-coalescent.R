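# generation_years = 1 makes node times directly comparable to
# coalescent theory in generations
contemp_scheme <- function(n_diploid, L = 50L) {
  sampling_scheme(rep(0, n_diploid), loci = c(l = as.integer(L)),
                  ancestral_min_age = -1)
}

test_that("pairwise TMRCA matches the coalescent expectation", {
  N <- 400
  d <- constant_demography(N, generation_years = 1)
  s <- contemp_scheme(1)  # one diploid = two gene copies
  set.seed(101)
  h <- replicate(1500, max(simulate_genealogy(d, s)$l$node_time))
  # E[T2] = 2N, SD = 2N
  expect_lt(abs(mean(h) - 2 * N), 3 * 2 * N / sqrt(length(h)))
})

test_that("degenerate and serial-sampling genealogies are well formed", {
  d <- constant_demography(100, generation_years = 1)
  s1 <- sampling_scheme(c(5), loci = c(l = 10L), ancestral_min_age = 2)
  # single diploid still coalesces its two copies above the sample time
  g1 <- simulate_genealogy(d, s1, seed = 1)$l
  expect_equal(g1$n_tip, 2)
  expect_true(max(g1$node_time) >= 5)

  # two samples 10 generations apart: tree height always spans the gap
  d2 <- constant_demography(1e8, generation_years = 1)
  s2 <- sampling_scheme(c(0, 10), loci = c(l = 10L),
                        ancestral_min_age = 5)
  set.seed(2)
  for (i in 1:20) {
    g <- simulate_genealogy(d2, s2)$l
    expect_gte(max(g$node_time), 10)
    # parents are strictly older than children
    kids <- which(g$parent >= 0)
    expect_true(all(g$node_time[g$parent[kids] + 1] >=
                      g$node_time[kids]))
  }
})

test_that("continuous and discrete modes agree on pairwise TMRCA at small N", {
  N <- 10
  d <- constant_demography(N, generation_years = 1)
  s <- contemp_scheme(1)
  set.seed(3)
  h_cont <- replicate(2000, max(simulate_genealogy(d, s)$l$node_time))
  h_disc <- replicate(2000, max(simulate_genealogy(d, s,
                                                   discrete = TRUE)$l$node_time))
  # geometric mean 2N vs exponential mean 2N; allow Monte-Carlo error
  expect_lt(abs(mean(h_cont) - mean(h_disc)),
            3 * sqrt(stats::var(h_cont) / 2000 + stats::var(h_disc) / 2000)
            + 1)  # +1 for the discrete-time rounding offset
})

test_that("mutation dropping follows the Poisson finite-sites model", {
  d <- constant_demography(50, generation_years = 1)
  s <- contemp_scheme(6)
  g <- simulate_genealogy(d, s, seed = 4)$l

  # mu = 0: all tips identical
  expect_equal(length(unique(drop_mutations(g, 50, 0))), 1)

  # pairwise differences on a fixed two-tip genealogy: Poisson mutations
  # at rate mu per site per generation over 2 * TMRCA generations give
  # per-site difference probability (3/4)(1 - exp(-(4/3) * 2 * TMRCA * mu))
  # (uniform finite-sites model), i.e. ~ 2 * TMRCA * mu * L pre-saturation
  s2 <- contemp_scheme(1, L = 200L)
  g2 <- simulate_genealogy(d, s2, seed = 5)$l
  tmrca <- max(g2$node_time)
  mu <- 5e-4
  set.seed(6)
  diffs <- replicate(800, {
    tips <- drop_mutations(g2, 200, mu)
    sum(strsplit(tips[1], "")[[1]] != strsplit(tips[2], "")[[1]])
  })
  expected <- 200 * 0.75 * (1 - exp(-(4 / 3) * 2 * tmrca * mu))
  expect_lt(abs(mean(diffs) - expected),
            3 * stats::sd(diffs) / sqrt(length(diffs)))
  # linear approximation holds to ~the second-order term
  expect_lt(abs(expected - 2 * tmrca * mu * 200),
            (2 * tmrca * mu)^2 * 200)
})

test_that("doubling the mutation rate never lowers mean allele counts", {
  d <- constant_demography(100, generation_years = 1)
  s <- contemp_scheme(8)
  mus <- c(2e-4, 4e-4, 8e-4)
  set.seed(7)
  means <- vapply(mus, function(mu) {
    mean(replicate(300, {
      g <- simulate_genealogy(d, s)$l
      length(unique(drop_mutations(g, 50, mu)))
    }))
  }, numeric(1))
  expect_true(all(diff(means) > -0.15))  # monotone up to Monte-Carlo noise
})

test_that("allele counts match the Ewens sampling formula", {
  N <- 1e5
  mu <- 1e-7
  L <- 99
  theta <- 4 * N * mu * L
  n_copies <- 24
  d <- constant_demography(N, generation_years = 1)
  s <- contemp_scheme(12, L = 99L)
  set.seed(8)
  k <- replicate(500, {
    g <- simulate_genealogy(d, s)$l
    length(unique(drop_mutations(g, L, mu)))
  })
  expected <- ewens_expected_k(theta, n_copies)
  expect_lt(abs(mean(k) - expected),
            3 * stats::sd(k) / sqrt(length(k)) + 0.03 * expected)
})

test_that("retention statistic counts shared and total island alleles", {
  periods <- c("ancestral", "ancestral", "island", "island")
  # identical tips everywhere: one allele per locus, fraction 1
  r1 <- retention_statistic(list(rep("AAA", 4), rep("CCC", 4)), periods)
  expect_equal(r1$A_anc, 2)
  expect_equal(r1$fraction, 1)
  expect_true(r1$retained)

  # island holds all ancestral alleles plus a novel one
  r2 <- retention_statistic(list(c("AAA", "TTT", "AAA", "GGG")), periods,
                            statistic = "shared")
  expect_equal(r2$A_anc, 2)
  expect_equal(r2$A_shared, 1)
  expect_equal(r2$A_island, 2)
  expect_equal(r2$fraction, 0.5)
  # the count-based fraction can exceed 1 when the island sample holds
  # novel alleles; it is still "retained" under the threshold rule
  r3 <- retention_statistic(list(c("AAA", "TTT", "AAA", "TTT"),
                                 c("GGG", "GGG", "GGG", "CCC")), periods)
  expect_equal(r3$A_anc, 3)
  expect_equal(r3$A_island, 4)
  expect_equal(r3$fraction, 4 / 3)
  expect_true(r3$retained)

  expect_error(retention_statistic(list(c("A", "A")), c("island", "island")),
               "both periods")

  # permuting tips within a sampling stratum leaves the statistic unchanged
  seqs <- list(c("AAA", "TTT", "AAA", "GGG", "TTT", "AAA"))
  per <- c("ancestral", "ancestral", "ancestral", "island", "island",
           "island")
  base <- retention_statistic(seqs, per)
  for (i in 1:5) {
    perm <- c(sample(1:3), sample(4:6))
    rp <- retention_statistic(list(seqs[[1]][perm]), per)
    expect_equal(rp$fraction, base$fraction)
    expect_equal(rp$A_anc, base$A_anc)
  }
})

test_that("grid scan probabilities behave at the extremes", {
  scheme <- mammoth_sampling_scheme()
  # threshold 0: vacuously retained everywhere
  surf0 <- run_grid(scheme, N_EB_values = 10, N_EW_values = c(5, 500),
                    n_sims = 20, threshold = 0, seed = 9)
  expect_true(all(surf0$grid$P == 1))

  # little drift at large sizes: P near 1
  surf1 <- run_grid(scheme, N_EB_values = 10000, N_EW_values = 10000,
                    n_sims = 60, seed = 10)
  expect_gt(surf1$grid$P, 0.5)

  # severe bottleneck: retention of >= 63% is essentially impossible
  surf2 <- run_grid(scheme, N_EB_values = 2, N_EW_values = c(50, 5000),
                    n_sims = 60, seed = 11)
  expect_true(all(surf2$grid$P < 0.05))
})

test_that("rejection boundary scans columns above the bottleneck floor", {
  grid <- expand.grid(N_EB = c(10, 100), N_EW = c(2, 20, 200, 2000))
  grid$P <- ifelse(grid$N_EW <= 20, 0.01, 0.5)
  grid$ci_low <- NA
  grid$ci_high <- NA
  grid$n_used <- 100
  surf <- structure(list(grid = grid, alpha = 0.05, threshold = 0.63,
                         n_sims = 100), class = "probability_surface")
  b <- rejection_boundary(surf)
  expect_equal(b$N_EW, 20)
  expect_equal(b$bracket, c(20, 200))

  # all-accepting surface: empty boundary
  grid$P <- 1
  surf$grid <- grid
  expect_true(is.na(rejection_boundary(surf)$N_EW))

  # rejection only at the smallest value
  grid$P <- ifelse(grid$N_EW == 2, 0.001, 0.9)
  surf$grid <- grid
  expect_equal(rejection_boundary(surf)$N_EW, 2)
})

test_that("binomial confidence intervals tighten with more simulations", {
  scheme <- mammoth_sampling_scheme()
  s1 <- run_grid(scheme, 100, 1000, n_sims = 50, seed = 12)
  s2 <- run_grid(scheme, 100, 1000, n_sims = 200, seed = 12)
  w1 <- s1$grid$ci_high - s1$grid$ci_low
  w2 <- s2$grid$ci_high - s2$grid$ci_low
  expect_lt(w2, w1)
})

test_that("genealogies convert to valid phylo trees", {
  d <- constant_demography(100, generation_years = 1)
  g <- simulate_genealogy(d, contemp_scheme(5), seed = 13)$l
  ph <- genealogy_to_phylo(g)
  expect_s3_class(ph, "phylo")
  expect_equal(ph$Nnode, 9)
  expect_equal(nrow(ph$edge), 18)
  expect_true(all(ph$edge.length >= 0))
  skip_if_not_installed("ape")
  expect_true(ape::is.rooted(ph))
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
})
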