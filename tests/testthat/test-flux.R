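# enumeration oracle for the fluxes at N = 1 (every neutral mutation fixes):
# sum of neutral event sizes over the full event space
enum_flux <- function(arch, type, lm = 50) {
  rep_ <- enumerate_neutrality(arch, type, lm = lm)
  h <- rep_$size_histogram
  if (is.null(h)) return(0)
  sum(as.numeric(names(h)) * h) / rep_$total_events
}

test_that("fluxes at N = 1 equal the enumerated neutral-size totals", {
  r <- two_type_rates(1e-3)
  for (a in list(toy_arch(), genome_architecture(3, 9, 6),
                 genome_architecture(4, 12, 8))) {
    expect_equal(delta_deletion(a, r, 1), enum_flux(a, "deletion"))
    expect_equal(delta_duplication(a, r, 1), enum_flux(a, "duplication"))
    ri <- mutation_rates(mu = 1e-3, lambda_indel_plus = 1,
                         lambda_indel_minus = 1, lm = 2)
    di <- delta_indels(a, ri, 1)
    expect_equal(di[["plus"]], enum_flux(a, "indel_plus", lm = 2))
    expect_equal(di[["minus"]], enum_flux(a, "indel_minus", lm = 2))
  }
})

test_that("degenerate architectures yield zero fluxes", {
  r <- two_type_rates(1e-3)
  a0 <- genome_architecture(3, 9, 0)       # znc = 0
  expect_equal(delta_deletion(a0, r, 10), 0)
  amin <- genome_architecture(2, 2, 0)     # zc = g: every base a promoter
  expect_equal(delta_duplication(amin, r, 10), 0)
  ri <- mutation_rates(mu = 1e-3, lambda_indel_plus = 1, lambda_indel_minus = 1,
                       lm = 1)
  di0 <- delta_indels(a0, ri, 10)
  expect_equal(di0[["minus"]], 0)
  # lm = 1, N = 1 single-size identities
  a <- toy_arch()
  di <- delta_indels(a, ri, 1)
  expect_equal(di[["plus"]], (a$znc + a$g) / a$L)
  expect_equal(di[["minus"]], a$znc / a$L)
})

test_that("duplication flux shrinks as the population grows (stronger robustness selection)", {
  a <- fig_arch(1e6)
  r <- two_type_rates(1e-10)
  d <- vapply(c(1e6, 1e7, 1e8, 1e9), function(N) delta_duplication(a, r, N), 0)
  expect_true(all(diff(d) < 0))
})

test_that("small insertions outweigh small deletions in the indel-only model", {
  # indels alone create no robustness selection for shorter genomes: their
  # per-genome neutral rate saturates, so the insertion flux always wins
  r <- mutation_rates(mu = 1e-10, lambda_dupl = 0, lambda_del = 0,
                      lambda_indel_plus = 1, lambda_indel_minus = 1, lm = 50)
  for (z in 10^seq(3, 9, 2)) {
    di <- delta_indels(fig_arch(z), r, 1e8)
    expect_gt(di[["plus"]], di[["minus"]])
  }
})

test_that("the structural bias crosses 1 exactly once on the reference sweep", {
  r <- two_type_rates(1e-10)
  zg <- 10^seq(3, 9, 0.5)
  for (N in c(1e6, 1e8)) {
    B <- vapply(zg, function(z) bias(fig_arch(z), r, N), 0)
    expect_lt(B[1], 1)
    expect_gt(B[length(B)], 1)
    expect_equal(sum(diff(sign(B - 1)) != 0), 1)    # single crossing
    expect_true(all(diff(B) > 0))                   # monotone in znc
  }
})

test_that("at N = 1 the bias reduces to the neutral flux ratio and favors growth", {
  r <- two_type_rates(1e-6)
  for (z in c(1e4, 1e6, 1e8)) {
    a <- fig_arch(z)
    fb <- flux_balance(a, r, 1, model = "structural_only")
    expect_lt(fb$bias_B, 1)
    expect_equal(fb$regime, "growing")
  }
})

test_that("bias is invariant under (N, mu) -> (c N, mu / c) in the small-mu regime", {
  a <- fig_arch(1e6)
  for (cc in c(10, 100)) {
    B1 <- bias(a, two_type_rates(1e-10), 1e7)
    B2 <- bias(a, two_type_rates(1e-10 / cc), 1e7 * cc)
    expect_equal(B2 / B1, 1, tolerance = 1e-6)
  }
})

test_that("the bisection solver finds the equilibrium with a tight bias residual", {
  r <- two_type_rates(1e-10)
  eq <- equilibrium_noncoding(1e6, 2000, r, 1e8)
  expect_true(eq$converged)
  expect_equal(eq$bias_at_root, 1, tolerance = 1e-5)
  expect_equal(eq$fraction_star, eq$znc_star / (eq$znc_star + 1e6))
  # the returned root is a true sign change
  expect_lt(bias(fig_arch(eq$znc_star / 1.01), r, 1e8), 1)
  expect_gt(bias(fig_arch(eq$znc_star * 1.01), r, 1e8), 1)
})

test_that("equal N x mu products give identical equilibrium fractions", {
  eq1 <- equilibrium_noncoding(1e6, 2000, two_type_rates(1e-9), 1e6)
  eq2 <- equilibrium_noncoding(1e6, 2000, two_type_rates(1e-10), 1e7)
  expect_equal(eq2$fraction_star / eq1$fraction_star, 1, tolerance = 1e-6)
})

test_that("the indel-only model has no equilibrium: bias < 1 everywhere", {
  ri <- mutation_rates(mu = 1e-10, lambda_dupl = 0, lambda_del = 0,
                       lambda_indel_plus = 1, lambda_indel_minus = 1, lm = 50)
  B <- vapply(10^seq(3, 9), function(z)
    bias(fig_arch(z), ri, 1e8, model = "indel_only"), 0)
  expect_true(all(B < 1))
  eq <- equilibrium_noncoding(1e6, 2000, ri, 1e8, model = "indel_only")
  expect_false(eq$converged)
  expect_match(eq$reason, "growing")
})

test_that("no-sign-change brackets are reported, not silently rooted", {
  r <- two_type_rates(1e-10)
  # bracket entirely below the root: bias < 1 throughout
  eq <- equilibrium_noncoding(1e6, 2000, r, 1e8, bracket = c(1e3, 1e4),
                              check_monotone = FALSE)
  expect_false(eq$converged)
  expect_true(is.na(eq$znc_star))
})

test_that("equilibrium curve is monotone in N x mu with kappa-ordered fractions", {
  tab <- equilibrium_curve(n_mu = c(1e-3, 1e-2, 1e-1), kappa = c(1, 2))
  expect_equal(nrow(tab), 6)
  for (km in unique(tab$kappa)) {
    fr <- tab$fraction_star[tab$kappa == km][order(tab$N_mu[tab$kappa == km])]
    expect_true(all(diff(fr) < 0))
  }
  # stronger deletion bias, smaller equilibrium fraction at every N x mu
  for (nm in unique(tab$N_mu))
    expect_gt(tab$fraction_star[tab$kappa == 1 & tab$N_mu == nm],
              tab$fraction_star[tab$kappa == 2 & tab$N_mu == nm])
})

test_that("equilibrium fraction is insensitive to gene number at fixed gene length", {
  gs <- gene_number_sensitivity(c(500, 2000, 20000), gene_len = 500,
                                rates = two_type_rates(1e-10), pop = 1e8)
  expect_true(all(gs$converged))
  expect_lt(attr(gs, "max_relative_spread"), 0.01)
  one <- gene_number_sensitivity(2000, gene_len = 500,
                                 rates = two_type_rates(1e-10), pop = 1e8)
  expect_equal(attr(one, "max_relative_spread"), 0)
})

test_that("enumerable and analytic parameterizations agree on a small instance", {
  # same physical genome, integer vs real-valued handling of znc
  r <- two_type_rates(1e-4)
  a_int <- genome_architecture(4, 40, 24)
  a_real <- genome_architecture(4, 40, 24, mode = "analytic")
  expect_equal(bias(a_int, r, 20), bias(a_real, r, 20))
  expect_equal(effective_fitness(a_int, r)$log_fe,
               effective_fitness(a_real, r)$log_fe)
})
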