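# shared fixtures and independent oracle helpers

toy_arch <- function() genome_architecture(g = 2, zc = 6, znc = 4)

fig_arch <- function(znc = 1e6)
  genome_architecture(g = 2000, zc = 1e6, znc = znc, mode = "analytic")

two_type_rates <- function(mu) mutation_rates(mu = mu)

six_type_rates <- function(mu, lm = 50)
  mutation_rates(mu = mu, lambda_inv = 1, lambda_pm = 1,
                 lambda_indel_plus = 1, lambda_indel_minus = 1, lm = lm)

# matrix of small enumerable architectures used by the oracle-equivalence tests
toy_arch_matrix <- function() {
  specs <- list(
    c(2, 6, 4), c(2, 2, 0), c(3, 9, 0), c(3, 9, 6), c(1, 5, 7),
    c(4, 12, 8), c(2, 10, 2), c(5, 15, 20), c(1, 2, 9), c(3, 30, 12),
    c(2, 8, 14), c(4, 20, 4)
  )
  lapply(specs, function(s) genome_architecture(s[1], s[2], s[3]))
}

# compensated (Kahan) direct per-position summation of the log fe terms;
# algorithmically independent of the grouped closed-form evaluation
kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

oracle_log_fe <- function(arch, rates) {
  total <- 0
  for (type in names(rates$lambda)[rates$lambda > 0]) {
    nu <- position_neutrality(arch, type, lm = rates$lm)
    lmu <- rates$lambda[[type]] * rates$mu
    total <- total + kahan_sum(log1p(-lmu * (1 - nu)))
  }
  total
}

# fe(znc + k) / fe(znc) from two independent full evaluations
oracle_fe_ratio <- function(arch, rates, k) {
  a2 <- with_znc(arch, arch$znc + k)
  exp(oracle_log_fe(a2, rates) - oracle_log_fe(arch, rates))
}
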