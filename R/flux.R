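#' Expected fixed-length flux of duplications
#'
#' Average number of base pairs added to the noncoding genome per duplication
#' event, counting only events that are neutral and ultimately fix:
#' `delta_dupl = g (znc + g) / L^3 * sum_{j=1}^{period - 1} (period - j) j Pfix(+j)`.
#' The weight `g (period - j)` counts the copied segments of size `j` that
#' avoid every promoter, `(znc + g)` the neutral insertion junctions, and the
#' sum runs over all architecturally possible neutral sizes. Expressed in bp
#' per generation per mutation event.
#'
#' @param arch a [genome_architecture()].
#' @param rates a [mutation_rates()] (all active types enter the fixation
#'   probability through the effective fitness).
#' @param pop a [population_params()] or scalar `N`.
#' @return Nonnegative scalar flux (bp/generation/event).
#' @export
delta_duplication <- function(arch, rates, pop) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  pop <- as_population(pop)
  p <- arch$period
  jmax <- ceiling(p) - 1
  if (jmax < 1) return(0)
  j <- seq_len(jmax)
  pf <- fixation_probability(arch, rates, pop, j)
  arch$g * (arch$znc + arch$g) / arch$L^3 * sum((p - j) * j * pf)
}

#' Expected fixed-length flux of deletions
#'
#' Average number of base pairs removed from the noncoding genome per deletion
#' event, counting only neutral, ultimately fixed events:
#' `delta_del = g / L^2 * sum_{j=1}^{znc/g} (znc/g - j + 1) j Pfix(-j)`.
#' Zero when `znc = 0` (no neutral deletion exists).
#'
#' @inheritParams delta_duplication
#' @return Nonnegative scalar flux (bp/generation/event).
#' @export
delta_deletion <- function(arch, rates, pop) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  pop <- as_population(pop)
  m <- arch$intergene_len
  if (m <= 0) return(0)
  jmax <- ceiling(m + 1) - 1
  j <- seq_len(jmax)
  w <- pmax(m - j + 1, 0)
  pf <- fixation_probability(arch, rates, pop, -j)
  arch$g / arch$L^2 * sum(w * j * pf)
}

#' Expected fixed-length fluxes of small indels
#'
#' Small insertions land at a uniform junction with a size uniform on
#' `1..lm` and are neutral whenever the junction lies outside genes:
#' `delta_indel_plus = (znc + g)/(L lm) * sum_{j=1}^{lm} j Pfix(+j)`.
#' Small deletions behave like size-capped deletions:
#' `delta_indel_minus = g/(L lm) * sum_{j=1}^{min(lm, znc/g)}
#'   (znc/g - j + 1) j Pfix(-j)`.
#'
#' @inheritParams delta_duplication
#' @return Named numeric vector `c(plus = ..., minus = ...)` in
#'   bp/generation/event.
#' @export
delta_indels <- function(arch, rates, pop) {
  stopifnot_arch(arch); stopifnot_rates(rates)
  pop <- as_population(pop)
  lm <- rates$lm
  j <- seq_len(lm)
  pf_plus <- fixation_probability(arch, rates, pop, j)
  d_plus <- (arch$znc + arch$g) / (arch$L * lm) * sum(j * pf_plus)
  m <- arch$intergene_len
  d_minus <- 0
  if (m > 0) {
    jmax <- min(lm, ceiling(m + 1) - 1)
    jm <- seq_len(jmax)
    w <- pmax(m - jm + 1, 0)
    pf_minus <- fixation_probability(arch, rates, pop, -jm)
    d_minus <- arch$g / (arch$L * lm) * sum(w * jm * pf_minus)
  }
  c(plus = d_plus, minus = d_minus)
}

#' Flux balance between shrinking and growing mutations
#'
#' Computes the per-type fixed-length fluxes and the bias
#' `B = (shrinking flux) / (growing flux)`. Since every flux shares the common
#' origination factor `mu L N`, that factor cancels and `B` depends on `N` and
#' `mu` essentially only through their product. Variants:
#' \describe{
#'   \item{structural_only}{`B = lambda_del delta_del / (lambda_dupl delta_dupl)`
#'     (the printed two-type form when the multipliers are equal).}
#'   \item{expanded}{deletion-side fluxes `lambda_del delta_del +
#'     lambda_indel_minus delta_indel_minus` over insertion-side fluxes
#'     `lambda_dupl delta_dupl + lambda_indel_plus delta_indel_plus`; point
#'     mutations and inversions do not change genome size and enter only
#'     through the effective fitness.}
#'   \item{indel_only}{small-deletion flux over small-insertion flux.}
#' }
#' `B > 1` means deletions dominate and the noncoding genome shrinks;
#' `B < 1` means it grows; `B = 1` is the equilibrium.
#'
#' @param arch a [genome_architecture()].
#' @param rates a [mutation_rates()]; multipliers of types outside the variant
#'   are ignored (zeroed) for both the fluxes and the effective fitness.
#' @param pop a [population_params()] or scalar `N`.
#' @param model `"structural_only"`, `"expanded"` or `"indel_only"`.
#' @param tol half-width of the `B = 1` band used to call the regime.
#' @return A list of class `"flux_result"` with the per-type `delta` values
#'   (weighted by their multipliers in the totals), `bias_B`, and `regime`
#'   (`"growing"`, `"shrinking"` or `"at_equilibrium"`).
#' @export
flux_balance <- function(arch, rates, pop,
                         model = c("structural_only", "expanded", "indel_only"),
                         tol = 1e-9) {
  model <- match.arg(model)
  r <- restrict_rates(rates, model)
  pop <- as_population(pop)
  lam <- r$lambda
  d_dupl <- if (lam[["duplication"]] > 0) delta_duplication(arch, r, pop) else 0
  d_del  <- if (lam[["deletion"]] > 0) delta_deletion(arch, r, pop) else 0
  d_ind  <- if (lam[["indel_plus"]] > 0 || lam[["indel_minus"]] > 0)
    delta_indels(arch, r, pop) else c(plus = 0, minus = 0)
  num <- lam[["deletion"]] * d_del + lam[["indel_minus"]] * d_ind[["minus"]]
  den <- lam[["duplication"]] * d_dupl + lam[["indel_plus"]] * d_ind[["plus"]]
  if (den <= 0)
    stop("growing-side flux is zero: no possible insertions under this model")
  B <- num / den
  structure(list(
    delta_dupl = d_dupl, delta_del = d_del,
    delta_indel_plus = d_ind[["plus"]], delta_indel_minus = d_ind[["minus"]],
    bias_B = B,
    regime = if (abs(B - 1) <= tol) "at_equilibrium"
             else if (B > 1) "shrinking" else "growing",
    model = model
  ), class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("Flux balance (%s model): B = %.9g (%s)\n",
              x$model, x$bias_B, x$regime))
  cat(sprintf("  delta_dupl = %.6g, delta_del = %.6g, delta_indel+ = %.6g, delta_indel- = %.6g\n",
              x$delta_dupl, x$delta_del, x$delta_indel_plus, x$delta_indel_minus))
  invisible(x)
}

#' Bias toward shrinking or growing the noncoding genome
#'
#' Thin wrapper around [flux_balance()] returning only the dimensionless bias
#' `B`.
#'
#' @inheritParams flux_balance
#' @return Scalar `B`.
#' @export
bias <- function(arch, rates, pop,
                 model = c("structural_only", "expanded", "indel_only")) {
  flux_balance(arch, rates, pop, model)$bias_B
}
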