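## ---- internal: grouped log-sum machinery -----------------------------------
##
## log fe is a sum over the L start positions and the active mutation types of
## log[(1 - lambda*mu) + lambda*mu * nu_{t,i}].  Positions group by symmetry
## into at most period-many classes per type, and each per-type sum reduces to
##   n0 * log(ct) + sum_{r=1}^{n} log1p(beta * r)          (ct = 1 - lambda*mu)
## The inner sum is evaluated either exactly (vectorized, small n) or through
## a power-sum series in beta (beta*(n+1) < SERIES_EPS), which is accurate to
## ~ (beta*n)^4 relative — far below double precision in every regime where n
## is too large to sum directly.  Upper limits n may be real (analytic mode);
## the series uses the polynomial continuation of the power sums and the
## direct branch adds a linearly interpolated fractional term.

SERIES_EPS <- 1e-4
DIRECT_MAX_N <- 5e6

pow_sum1 <- function(n) n * (n + 1) / 2
pow_sum2 <- function(n) n * (n + 1) * (2 * n + 1) / 6
pow_sum3 <- function(n) (n * (n + 1) / 2)^2
pow_sum4 <- function(n) n * (n + 1) * (2 * n + 1) * (3 * n^2 + 3 * n - 1) / 30

## sum_{r=1}^{n} log1p(beta * r); n real >= 0, scalar; beta scalar >= 0
sum_log1p_linear <- function(n, beta) {
  if (n <= 0) return(0)
  if (beta == 0) return(0)
  if (beta * (n + 1) < SERIES_EPS) {
    beta * pow_sum1(n) - beta^2 * pow_sum2(n) / 2 +
      beta^3 * pow_sum3(n) / 3 - beta^4 * pow_sum4(n) / 4
  } else {
    if (n > DIRECT_MAX_N)
      stop("mutation rate too large for this genome size: ",
           "per-position log-sum is outside the supported precision regime")
    nf <- floor(n)
    s <- sum(log1p(beta * seq_len(nf)))
    if (n > nf) s <- s + (n - nf) * log1p(beta * (nf + 1))
    s
  }
}

## higher-order remainder of the series branch: sum_log1p_linear minus its
## leading beta * S1(n) term (used by the stable difference path); vectorized.
sum_log1p_linear_ho <- function(n, beta) {
  out <- -beta^2 * pow_sum2(n) / 2 + beta^3 * pow_sum3(n) / 3 -
    beta^4 * pow_sum4(n) / 4
  out[n <= 0 | beta == 0] <- 0
  out
}

series_ok <- function(n, beta) beta * (n + 1) < SERIES_EPS

## indel_minus noncoding-position sum, split into a bounded "small" part and a
## coefficient multiplying log1p(lambda*mu/ct) = -log(ct):
##   sum_{r=1}^{m} log1p(lambda*mu*min(r, lm)/(lm*ct)) = small + coef*(-log ct)
indel_minus_V <- function(m, lm, lmu, ct) {
  if (m <= 0) return(list(small = 0, coef = 0))
  x <- lmu / (lm * ct)
  if (m >= lm) {
    small <- sum(log1p(x * seq_len(lm - 1)))
    list(small = small, coef = m - lm + 1)
  } else {
    nf <- floor(m)
    small <- sum(log1p(x * seq_len(nf)))
    if (m > nf) small <- small + (m - nf) * log1p(x * (nf + 1))
    list(small = small, coef = 0)
  }
}

## active mutation types for a model variant
#' Restrict mutation rates to a model variant
#'
#' Returns a copy of `rates` with the multipliers of all types outside the
#' variant zeroed. `"structural_only"` keeps duplications and deletions,
#' `"indel_only"` keeps the two indel types, `"expanded"` keeps all six.
#'
#' @param rates a [mutation_rates()] object.
#' @param model `"structural_only"`, `"expanded"` or `"indel_only"`.
#' @return A `"mutation_rates"` object.
#' @export
restrict_rates <- function(rates, model = c("structural_only", "expanded", "indel_only")) {
  stopifnot_rates(rates)
  model <- match.arg(model)
  keep <- switch(model,
    structural_only = c("duplication", "deletion"),
    indel_only = c("indel_plus", "indel_minus"),
    expanded = MUTATION_TYPES)
  lam <- rates$lambda
  lam[setdiff(MUTATION_TYPES, keep)] <- 0
  mutation_rates(mu = rates$mu,
                 lambda_dupl = lam[["duplication"]], lambda_del = lam[["deletion"]],
                 lambda_inv = lam[["inversion"]], lambda_pm = lam[["point"]],
                 lambda_indel_plus = lam[["indel_plus"]],
                 lambda_indel_minus = lam[["indel_minus"]],
                 lm = rates$lm)
}

active_types <- function(rates) names(rates$lambda)[rates$lambda > 0]

## per-type contribution to log fe at noncoding size z (scalar), for a fixed
## coding architecture (g, zc). Returns a named numeric over active types.
log_fe_terms_at <- function(z, g, zc, rates) {
  mu <- rates$mu; lm <- rates$lm
  L <- zc + z
  m <- z / g
  p <- L / g
  out <- c()
  for (type in active_types(rates)) {
    lmu <- rates$lambda[[type]] * mu
    ct <- 1 - lmu
    lct <- log1p(-lmu)
    val <- switch(type,
      deletion    = L * lct + g * sum_log1p_linear(m, lmu / (L * ct)),
      duplication = L * lct + g * sum_log1p_linear(p - 1, lmu * (z + g) / (L^2 * ct)),
      inversion   = L * lct + (z + g) * log1p(lmu * (z + g) / (L * ct)),
      point       = zc * lct,
      indel_plus  = (zc - g) * lct,
      indel_minus = {
        V <- indel_minus_V(m, lm, lmu, ct)
        L * lct + g * (V$small - V$coef * lct)
      }
    )
    out[type] <- val
  }
  out
}

#' Effective fitness (robustness) of a genome
#'
#' The effective fitness `fe` is the probability that a reproduction event
#' yields a viable offspring: at each of the `L` positions and for each active
#' mutation type, either no mutation initiates there (probability
#' `1 - lambda_t * mu`) or the initiated mutation is neutral. Mutation types
#' and positions are treated as independent, so
#' `log fe = sum_t sum_i log[(1 - lambda_t mu) + lambda_t mu nu_{t,i}]`,
#' with `nu_{t,i}` the neutrality probability of a type-`t` mutation starting
#' at position `i`. The position sums are grouped by symmetry into at most
#' period-many classes and evaluated in the log domain (see the methods
#' vignette for the numerical contract).
#'
#' `fe` decreases with both the noncoding size and the mutation rate: larger
#' genomes initiate more (potentially lethal) structural mutations per
#' replication, which is the robustness cost that ultimately balances the
#' neutral bias toward growth.
#'
#' @param arch a [genome_architecture()].
#' @param rates a [mutation_rates()] object; every type with a positive
#'   multiplier contributes.
#' @return A list of class `"fitness_result"` with `fe`, `log_fe` (natural
#'   log, `<= 0`) and `per_type_log_terms` (named decomposition summing to
#'   `log_fe`).
#' @examples
#' a <- genome_architecture(2000, 1e6, 1e6, mode = "analytic")
#' effective_fitness(a, mutation_rates(mu = 1e-10))
#' @export
effective_fitness <- function(arch, rates) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  terms <- log_fe_terms_at(arch$znc, arch$g, arch$zc, rates)
  log_fe <- if (length(terms)) sum(terms) else 0
  structure(list(fe = exp(log_fe), log_fe = log_fe,
                 per_type_log_terms = terms),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("Effective fitness: fe = %.12g (log fe = %.12g)\n", x$fe, x$log_fe))
  invisible(x)
}

#' Small-mu exponential approximation of the effective fitness
#'
#' Drops every neutrality correction and keeps only the per-position hazard:
#' `fe ~ exp(-mu * sum_t lambda_t * n_t)` with `n_t` the number of positions
#' at which type `t` can initiate (`L` for deletions, duplications and
#' inversions, `zc` for point mutations and small deletions, `zc - g` for
#' small insertions). In the two-structural-type model this is the classical
#' `(1 - mu)^(2L) ~ exp(-2 L mu)` form, so
#' `fe(znc)/fe(znc + k) ~ exp(2 k mu)` as `mu -> 0`.
#'
#' This is an approximation for exposition and asymptotic analysis only; the
#' exact pipeline never calls it.
#'
#' @inheritParams effective_fitness
#' @return A `"fitness_result"` list (with the per-type decomposition of the
#'   approximate log).
#' @export
effective_fitness_approx <- function(arch, rates) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  mu <- rates$mu
  n_pos <- c(duplication = arch$L, deletion = arch$L, inversion = arch$L,
             point = arch$zc, indel_plus = arch$zc - arch$g,
             indel_minus = arch$zc)
  act <- active_types(rates)
  terms <- -mu * rates$lambda[act] * n_pos[act]
  names(terms) <- act
  log_fe <- if (length(terms)) sum(terms) else 0
  structure(list(fe = exp(log_fe), log_fe = log_fe,
                 per_type_log_terms = terms),
            class = "fitness_result")
}

## ---- stable log fe differences ---------------------------------------------
##
## delta_log_fe(z, k) = log fe(znc = z) - log fe(znc = z + k).  Subtracting two
## log fe values loses up to |log fe| / |delta| digits, so in the analytic
## regime the difference is assembled term by term from exact rational-function
## differences; only the (absolutely tiny) higher-order series remainders are
## differenced naively. Falls back to direct subtraction whenever the series
## branch does not apply (small/toy genomes, where cancellation is mild).

## exact first-order difference helpers; all return f(z) - f(z + k)
## G(z) = z (z + g) / L         (deletion leading term, L = zc + z)
## F(z) = (z + g)(L - g) / L    (duplication leading term)
## H(z) = (z + g)^2 / L         (inversion leading term)
diff_G <- function(z, k, g, zc) {
  L <- zc + z
  -k + zc * (zc - g) * k / (L * (L + k))
}
diff_F <- function(z, k, g, zc) {
  L <- zc + z
  -k + g * (zc - g) * k / (L * (L + k))
}
diff_H <- function(z, k, g, zc) {
  L <- zc + z
  -k + (zc - g)^2 * k / (L * (L + k))
}

## can the stable path be used for every element of z + k?
stable_delta_ok <- function(z, k, g, zc, rates) {
  mu <- rates$mu
  if (mu == 0) return(TRUE)
  zmax <- max(z, z + k); zmin <- min(z, z + k)
  Lmax <- zc + zmax
  ok <- TRUE
  lam <- rates$lambda
  if (lam[["deletion"]] > 0) {
    lmu <- lam[["deletion"]] * mu
    ok <- ok && series_ok(zmax / g, lmu / ((zc + zmin) * (1 - lmu)))
  }
  if (lam[["duplication"]] > 0) {
    lmu <- lam[["duplication"]] * mu
    ok <- ok && series_ok(Lmax / g - 1, lmu * (zmax + g) / ((zc + zmin)^2 * (1 - lmu)))
  }
  ok
}

## vectorized over k (scalar z)
delta_log_fe <- function(z, k, g, zc, rates) {
  if (any(z + k < 0)) stop("znc + k must be >= 0")
  if (rates$mu == 0) return(rep(0, length(k)))
  if (!stable_delta_ok(z, k, g, zc, rates)) {
    lf <- vapply(z + k, function(zz) sum(log_fe_terms_at(zz, g, zc, rates)), 0)
    return(sum(log_fe_terms_at(z, g, zc, rates)) - lf)
  }
  mu <- rates$mu; lm <- rates$lm
  L1 <- zc + z; L2 <- zc + z + k
  m1 <- z / g; m2 <- (z + k) / g
  delta <- numeric(length(k))
  for (type in active_types(rates)) {
    lmu <- rates$lambda[[type]] * mu
    ct <- 1 - lmu
    lct <- log1p(-lmu)
    d <- switch(type,
      deletion = {
        b1 <- lmu / (L1 * ct); b2 <- lmu / (L2 * ct)
        -k * lct + (lmu / (2 * g * ct)) * diff_G(z, k, g, zc) +
          g * (sum_log1p_linear_ho(m1, b1) - sum_log1p_linear_ho(m2, b2))
      },
      duplication = {
        b1 <- lmu * (z + g) / (L1^2 * ct); b2 <- lmu * (z + k + g) / (L2^2 * ct)
        -k * lct + (lmu / (2 * g * ct)) * diff_F(z, k, g, zc) +
          g * (sum_log1p_linear_ho(L1 / g - 1, b1) -
                 sum_log1p_linear_ho(L2 / g - 1, b2))
      },
      inversion = {
        q1 <- lmu * (z + g) / (L1 * ct); q2 <- lmu * (z + k + g) / (L2 * ct)
        ho1 <- (z + g) * (log1p(q1) - q1)
        ho2 <- (z + k + g) * (log1p(q2) - q2)
        -k * lct + (lmu / ct) * diff_H(z, k, g, zc) + (ho1 - ho2)
      },
      point = 0,
      indel_plus = 0,
      indel_minus = {
        if (m1 >= lm && all(m2 >= lm)) 0 else {
          V1 <- indel_minus_V(m1, lm, lmu, ct)
          vapply(seq_along(k), function(i) {
            V2 <- indel_minus_V(m2[i], lm, lmu, ct)
            -k[i] * lct + g * ((V1$small - V2$small) - (V1$coef - V2$coef) * lct)
          }, 0)
        }
      }
    )
    delta <- delta + d
  }
  delta
}

#' Selection coefficient of a neutral size-changing mutation
#'
#' A mutation adding `k` noncoding bases (negative `k` for deletions) does not
#' change viability, but it changes the effective fitness of the lineage. The
#' exact selection coefficient is
#' `s = fe(znc + k)/fe(znc) - 1`, computed here from the log-domain
#' effective-fitness difference. In the two-structural-type model the small-mu
#' limit is `s ~ -2 k mu` (method `"small_mu"`): deletions (`k < 0`) increase
#' robustness and carry a positive selection coefficient.
#'
#' @param arch a [genome_architecture()].
#' @param rates a [mutation_rates()].
#' @param k signed size change in bp (vectorized); `znc + k >= 0` required.
#' @param method `"exact"` (default) or `"small_mu"`.
#' @return Numeric vector of selection coefficients.
#' @export
selection_coefficient <- function(arch, rates, k, method = c("exact", "small_mu")) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  method <- match.arg(method)
  if (any(arch$znc + k < 0))
    stop("znc + k must be >= 0 (deletion larger than the noncoding complement)")
  if (method == "small_mu") return(-2 * k * rates$mu)
  expm1(-delta_log_fe(arch$znc, k, arch$g, arch$zc, rates))
}

## ---- fixation probability ---------------------------------------------------

## Pfix from a = 2 * (log fe(znc) - log fe(znc + k)) under a haploid
## Wright-Fisher population of size N: (1 - e^a)/(1 - e^(N a)), evaluated with
## expm1 and routed through the log scale when N*a would overflow.
pfix_from_a <- function(a, N) {
  out <- numeric(length(a))
  zero <- a == 0
  out[zero] <- 1 / N
  big <- !zero & (N * a > 700)
  if (any(big)) {
    ab <- a[big]
    lnum <- ifelse(ab > 37, ab, log(expm1(ab)))
    out[big] <- exp(lnum - N * ab)
  }
  rest <- !zero & !big
  out[rest] <- expm1(a[rest]) / expm1(N * a[rest])
  out
}

#' Fixation probability of a genome-size-changing mutant
#'
#' Probability that a single mutant whose mutation adds `k` noncoding bases
#' (viability-neutral, but robustness-altering) fixes in a haploid
#' Wright-Fisher population of size `N`:
#' `Pfix = (1 - r^2) / (1 - r^(2N))` with `r = fe(znc)/fe(znc + k)`.
#' The ratio is computed in the log domain through a cancellation-free
#' effective-fitness difference, and the `expm1` forms keep the evaluation
#' stable in overflow-prone regimes. `k = 0` returns the neutral limit `1/N`;
#' `N = 1` returns 1.
#'
#' @param arch a [genome_architecture()].
#' @param rates a [mutation_rates()].
#' @param pop a [population_params()] object or scalar `N`.
#' @param k signed size change in bp (vectorized).
#' @return Vector of fixation probabilities in `(0, 1]`.
#' @export
fixation_probability <- function(arch, rates, pop, k) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  pop <- as_population(pop)
  if (any(arch$znc + k < 0)) stop("znc + k must be >= 0")
  a <- 2 * delta_log_fe(arch$znc, k, arch$g, arch$zc, rates)
  pfix_from_a(a, pop$N)
}

#' Small-mu asymptotic fixation probability
#'
#' The limit of the fixation probability in the two-structural-type model as
#' `mu -> 0`, where `fe(znc)/fe(znc+k) ~ exp(2 k mu)`:
#' `Pfix ~ (1 - exp(4 k mu)) / (1 - exp(4 N k mu))`.
#' Both numerator and denominator are written with a consistent sign (the
#' `1 - exp(...)` form), and `k = 0` is handled as the limit `1/N`. `Pfix`
#' depends on `mu` and on the compound `N * mu` only, which is the origin of
#' the `N x mu` invariance of the equilibrium.
#'
#' @param pop a [population_params()] or scalar `N`.
#' @param mu per-base per-type mutation rate.
#' @param k signed size change in bp (vectorized).
#' @return Vector of fixation probabilities.
#' @export
fixation_probability_asymptotic <- function(pop, mu, k) {
  pop <- as_population(pop)
  pfix_from_a(4 * k * mu, pop$N)
}
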