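test_that("architecture constructor derives lengths and enforces invariants", {
  a <- genome_architecture(3, 9, 6)
  expect_equal(a$L, 15)
  expect_equal(a$period, 5)
  expect_equal(a$gene_len, 3)
  expect_equal(a$intergene_len, 2)
  expect_identical(a$L, a$zc + a$znc)

  expect_error(genome_architecture(0, 5, 5), "g must be")
  expect_error(genome_architecture(2, 1, 4), "zc must be >= g")
  expect_error(genome_architecture(2, 6, -1), "znc must be")
  expect_error(genome_architecture(2, 6, 3), "divide")
  expect_error(genome_architecture(2, 7, 4), "divide")
  # analytic mode accepts non-divisible real-valued noncoding sizes
  expect_silent(genome_architecture(2, 6, 3.7, mode = "analytic"))
})

test_that("rate constructors validate and derive kappa", {
  r <- mutation_rates(mu = 1e-9, lambda_dupl = 2, lambda_del = 3)
  expect_equal(r$kappa, 1.5)
  expect_error(mutation_rates(mu = 1.2), "mu must be")
  expect_error(mutation_rates(mu = 1e-9, lambda_del = -1), ">= 0")
  expect_error(mutation_rates(mu = 0.5, lambda_del = 3), "< 1")

  k <- kappa_rates(mu = 1e-9, kappa = 3)
  lam <- k$lambda
  expect_equal(lam[["deletion"]], lam[["indel_minus"]])
  expect_equal(lam[["duplication"]], lam[["indel_plus"]])
  expect_equal(sum(lam[c("deletion", "duplication", "indel_plus", "indel_minus")]), 4)
  expect_equal(lam[["deletion"]] / lam[["duplication"]], 3)
  expect_equal(k$kappa, 3)
})

test_that("structural neutrality closed forms match frozen enumeration values", {
  a <- toy_arch()
  expect_equal(neutral_prob(a, "deletion"), 0.06)        # 6 of 100 events
  expect_equal(neutral_prob(a, "duplication"), 0.12)     # 120 of 1000 events
  expect_equal(neutral_prob(genome_architecture(3, 9, 0), "deletion"), 0)
  expect_equal(neutral_prob(genome_architecture(2, 2, 0), "duplication"), 0)
  big <- fig_arch(1e6)
  expect_equal(neutral_prob(big, "deletion"), 6.2625e-5)
  expect_equal(neutral_prob(big, "duplication"), 1.2512475e-4)
})

test_that("deletion/duplication neutrality ratio equals znc/(znc + zc - g)", {
  for (a in toy_arch_matrix()) {
    if (a$znc == 0 || a$zc <= a$g) next
    ratio <- neutral_prob(a, "deletion") / neutral_prob(a, "duplication")
    expect_equal(ratio, a$znc / (a$znc + a$zc - a$g))
    expect_lte(ratio, 1)
  }
})

test_that("neutrality probabilities are nondecreasing in znc at fixed coding architecture", {
  zncs <- c(0, 4, 40, 400, 4000)
  for (type in c("deletion", "duplication", "inversion", "point",
                 "indel_plus", "indel_minus")) {
    nus <- vapply(zncs, function(z)
      neutral_prob(genome_architecture(2, 6, z), type, lm = 3), 0)
    expect_true(all(diff(nus) >= 0), info = type)
  }
})

test_that("size-conditional neutrality matches counting and has hard cutoffs", {
  a <- toy_arch()
  expect_equal(neutral_prob_given_size(a, "deletion", 1), 0.4)
  expect_equal(neutral_prob_given_size(a, "duplication", 4), 0.12)
  # above the architectural cutoffs no mutation can be neutral
  expect_equal(neutral_prob_given_size(a, "deletion", a$intergene_len + 1), 0)
  expect_equal(neutral_prob_given_size(a, "duplication", a$period), 0)
})

test_that("summing size-conditional neutrality over the size measure recovers nu", {
  for (a in toy_arch_matrix()) {
    k <- seq_len(a$L)
    expect_equal(sum(neutral_prob_given_size(a, "deletion", k)) / a$L,
                 neutral_prob(a, "deletion"))
    expect_equal(sum(neutral_prob_given_size(a, "duplication", k)) / a$L,
                 neutral_prob(a, "duplication"))
    lm <- 3
    expect_equal(sum(neutral_prob_given_size(a, "indel_minus", seq_len(lm))) / lm,
                 neutral_prob(a, "indel_minus", lm = lm))
  }
})

test_that("extended-type neutrality matches frozen values", {
  a <- toy_arch()
  expect_equal(neutral_prob(a, "indel_plus"), 0.6)   # 6 of 10 junctions
  expect_equal(neutral_prob(a, "indel_minus", lm = 2), 0.3)
  expect_equal(neutral_prob(a, "inversion"), 0.36)
  expect_equal(neutral_prob(genome_architecture(3, 9, 0), "point"), 0)
})

test_that("mean neutral sizes favor duplications over deletions", {
  a <- toy_arch()
  expect_equal(mean_neutral_size(a, "deletion"), 4 / 3)
  for (arch in toy_arch_matrix()) {
    if (arch$znc == 0 || arch$zc <= arch$g) next
    expect_gt(mean_neutral_size(arch, "duplication"),
              mean_neutral_size(arch, "deletion"))
  }
  # single-base intergenes admit only 1-bp neutral deletions
  expect_equal(mean_neutral_size(genome_architecture(2, 6, 2), "deletion"), 1)
  expect_error(mean_neutral_size(genome_architecture(3, 9, 0), "deletion"),
               "no neutral")
})

test_that("event classification follows the lethality rules", {
  a <- genome_architecture(3, 9, 6)  # period 5, genes at 0-2, 5-7, 10-12
  # deletion entirely inside one intergenic tract is neutral
  expect_true(classify_event(a, mutation_event("deletion", start = 3, size = 2)))
  # deletion touching a coding base is lethal
  expect_false(classify_event(a, mutation_event("deletion", start = 3, size = 3)))
  # copied segment starting at a gene's first base carries the promoter: lethal
  expect_false(classify_event(a, mutation_event("duplication", start = 5, size = 2,
                                                insertion_point = 4)))
  # promoter-free partial gene copy into an intergenic junction is neutral
  expect_true(classify_event(a, mutation_event("duplication", start = 6, size = 2,
                                               insertion_point = 4)))
  # same copy inserted strictly inside a gene is lethal
  expect_false(classify_event(a, mutation_event("duplication", start = 6, size = 2,
                                                insertion_point = 1)))
  # insertion junction between two intergenic bases is neutral
  expect_true(classify_event(a, mutation_event("indel_plus", insertion_point = 4)))
  expect_false(classify_event(a, mutation_event("indel_plus", insertion_point = 2)))
  # junction at a gene's first base separates two genes' sequence: neutral
  expect_true(classify_event(a, mutation_event("indel_plus", insertion_point = 5)))
  # point mutations: coding lethal, noncoding neutral
  expect_false(classify_event(a, mutation_event("point", start = 0)))
  expect_true(classify_event(a, mutation_event("point", start = 4)))
  # inversions need both breakpoint junctions outside genes
  expect_true(classify_event(a, mutation_event("inversion", start = 3, size = 5)))
  expect_false(classify_event(a, mutation_event("inversion", start = 3, size = 3)))
  expect_error(classify_event(a, mutation_event("point", start = 15)), "range")
})

test_that("with_znc preserves coding architecture and tracks mode", {
  a <- toy_arch()
  b <- with_znc(a, 8)
  expect_equal(b$mode, "enumerable")
  expect_equal(b$znc, 8)
  c <- with_znc(a, 8.5)
  expect_equal(c$mode, "analytic")
  expect_equal(c$zc, a$zc)
})
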