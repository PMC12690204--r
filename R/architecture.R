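#' Idealized circular genome architecture
#'
#' Constructs the coding/noncoding layout used throughout the package: a
#' circular haploid genome of length `L = zc + znc` carrying `g` identical,
#' equally spaced genes. Each gene occupies `zc/g` consecutive bases, starts
#' with a promoter (its first base), and is followed by an intergenic tract of
#' `znc/g` bases. The genome is therefore fully described by `(g, zc, znc)`.
#'
#' Two modes are supported. In `"enumerable"` mode all segment lengths must be
#' integers and `g` must divide both `zc` and `znc` exactly, so that every
#' mutation event can be enumerated (used by the oracles). In `"analytic"`
#' mode `znc` may be any nonnegative real and the polynomial closed forms are
#' used directly; this is the mode the equilibrium solver works in.
#'
#' @param g number of genes (integer, >= 1).
#' @param zc total coding length in bp (>= g, each gene contains at least its
#'   promoter base).
#' @param znc total noncoding length in bp (>= 0; real-valued allowed in
#'   analytic mode).
#' @param mode `"enumerable"` or `"analytic"`.
#' @return An object of class `"genome_arch"`: a list with fields `g`, `zc`,
#'   `znc`, and derived quantities `L` (total length), `period` (`L/g`, the
#'   gene + intergene repeating unit), `gene_len` (`zc/g`) and `intergene_len`
#'   (`znc/g`).
#' @examples
#' genome_architecture(g = 2, zc = 6, znc = 4)
#' genome_architecture(g = 2000, zc = 1e6, znc = 3.7e5, mode = "analytic")
#' @export
genome_architecture <- function(g, zc, znc, mode = c("enumerable", "analytic")) {
  mode <- match.arg(mode)
  if (length(g) != 1L || length(zc) != 1L || length(znc) != 1L)
    stop("g, zc and znc must be scalars")
  if (!is.finite(g) || !is.finite(zc) || !is.finite(znc))
    stop("g, zc and znc must be finite")
  if (g < 1 || g != round(g)) stop("g must be an integer >= 1")
  if (zc < g) stop("zc must be >= g (each gene contains at least its promoter)")
  if (znc < 0) stop("znc must be >= 0")
  if (mode == "enumerable") {
    if (zc != round(zc) || znc != round(znc))
      stop("enumerable mode requires integer zc and znc")
    if (zc %% g != 0 || znc %% g != 0)
      stop("enumerable mode requires g to divide zc and znc exactly")
  } else {
    if (zc != round(zc)) stop("zc must be an integer (gene lengths are fixed)")
  }
  structure(
    list(
      g = as.numeric(g), zc = as.numeric(zc), znc = as.numeric(znc),
      L = as.numeric(zc + znc),
      period = (zc + znc) / g,
      gene_len = zc / g,
      intergene_len = znc / g,
      mode = mode
    ),
    class = "genome_arch"
  )
}

#' @export
print.genome_arch <- function(x, ...) {
  cat(sprintf(
    "Circular genome: g = %g genes, zc = %g bp coding, znc = %g bp noncoding\n",
    x$g, x$zc, x$znc))
  cat(sprintf("  L = %g bp, period = %g bp, gene = %g bp, intergene = %g bp (%s mode)\n",
              x$L, x$period, x$gene_len, x$intergene_len, x$mode))
  invisible(x)
}

is_genome_arch <- function(x) inherits(x, "genome_arch")

stopifnot_arch <- function(arch) {
  if (!is_genome_arch(arch)) stop("expected a 'genome_arch' object")
  invisible(arch)
}

#' Replace the noncoding size of an architecture
#'
#' Returns a copy of `arch` with noncoding size `znc`, switching to analytic
#' mode when the new size is not exactly divisible. Used extensively by the
#' solver, which sweeps `znc` at fixed coding architecture.
#'
#' @param arch a [genome_architecture()] object.
#' @param znc new noncoding size (bp, >= 0).
#' @return A `genome_arch` object.
#' @export
with_znc <- function(arch, znc) {
  stopifnot_arch(arch)
  mode <- if (arch$mode == "enumerable" && znc == round(znc) && znc %% arch$g == 0)
    "enumerable" else "analytic"
  genome_architecture(arch$g, arch$zc, znc, mode = mode)
}

MUTATION_TYPES <- c("duplication", "deletion", "inversion", "point",
                    "indel_plus", "indel_minus")

#' Per-type mutation rates
#'
#' Bundles the basal per-base per-type mutation rate `mu` with the
#' dimensionless per-type rate multipliers `lambda_i` (so type `i` occurs at
#' per-base rate `lambda_i * mu`), the maximum indel size `lm`, and the derived
#' deletion bias `kappa = lambda_del / lambda_dupl`.
#'
#' @param mu basal per-base per-type mutation rate (probability per bp per
#'   generation, `0 <= mu < 1`).
#' @param lambda_dupl,lambda_del,lambda_inv,lambda_pm,lambda_indel_plus,lambda_indel_minus
#'   nonnegative rate multipliers; a multiplier of 0 disables the type.
#' @param lm maximum indel size in bp (>= 1); indel sizes are uniform on
#'   `1..lm`.
#' @return An object of class `"mutation_rates"`.
#' @seealso [kappa_rates()] for the deletion-bias parameterization.
#' @examples
#' mutation_rates(mu = 1e-10)                          # two structural types
#' mutation_rates(mu = 1e-10, lambda_pm = 1, lambda_inv = 1,
#'                lambda_indel_plus = 1, lambda_indel_minus = 1)
#' @export
mutation_rates <- function(mu,
                           lambda_dupl = 1, lambda_del = 1,
                           lambda_inv = 0, lambda_pm = 0,
                           lambda_indel_plus = 0, lambda_indel_minus = 0,
                           lm = 50) {
  lambda <- c(duplication = lambda_dupl, deletion = lambda_del,
              inversion = lambda_inv, point = lambda_pm,
              indel_plus = lambda_indel_plus, indel_minus = lambda_indel_minus)
  if (length(mu) != 1L || !is.finite(mu) || mu < 0 || mu >= 1)
    stop("mu must be a scalar in [0, 1)")
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("all lambda multipliers must be finite and >= 0")
  if (any(lambda * mu >= 1))
    stop("lambda_i * mu must be < 1 for every mutation type")
  if (length(lm) != 1L || !is.finite(lm) || lm < 1 || lm != round(lm))
    stop("lm must be an integer >= 1")
  structure(
    list(mu = mu, lambda = lambda, lm = as.numeric(lm),
         kappa = if (lambda[["duplication"]] > 0)
           lambda[["deletion"]] / lambda[["duplication"]] else NA_real_),
    class = "mutation_rates"
  )
}

#' Deletion-bias (kappa) parameterization of mutation rates
#'
#' Builds a six-type rate set in which the structural and indel deletion
#' multipliers are tied (`lambda_del = lambda_indel_minus`,
#' `lambda_dupl = lambda_indel_plus`), the four size-changing multipliers sum
#' to 4, and `kappa = lambda_del / lambda_dupl` sets the deletion bias:
#' `lambda_del = 2*kappa/(1+kappa)`, `lambda_dupl = 2/(1+kappa)`.
#'
#' @param mu basal per-base per-type mutation rate.
#' @param kappa deletion bias (> 0); `kappa > 1` favors deletions.
#' @param lambda_pm,lambda_inv multipliers for point mutations and inversions.
#' @param lm maximum indel size (bp).
#' @return A `"mutation_rates"` object with the constraint
#'   `lambda_del + lambda_dupl + lambda_indel_minus + lambda_indel_plus = 4`.
#' @examples
#' kappa_rates(mu = 1e-9, kappa = 2)
#' @export
kappa_rates <- function(mu, kappa, lambda_pm = 1, lambda_inv = 1, lm = 50) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a finite scalar > 0")
  l_del <- 2 * kappa / (1 + kappa)
  l_dup <- 2 / (1 + kappa)
  mutation_rates(mu = mu,
                 lambda_dupl = l_dup, lambda_del = l_del,
                 lambda_inv = lambda_inv, lambda_pm = lambda_pm,
                 lambda_indel_plus = l_dup, lambda_indel_minus = l_del,
                 lm = lm)
}

#' @export
print.mutation_rates <- function(x, ...) {
  cat(sprintf("Mutation rates: mu = %g per bp per type per generation\n", x$mu))
  lam <- x$lambda[x$lambda > 0]
  if (length(lam))
    cat("  active types:",
        paste(sprintf("%s (lambda = %g)", names(lam), lam), collapse = ", "), "\n")
  else cat("  no active mutation types\n")
  cat(sprintf("  lm = %g bp, kappa = %s\n", x$lm,
              if (is.na(x$kappa)) "undefined" else format(x$kappa)))
  invisible(x)
}

is_mutation_rates <- function(x) inherits(x, "mutation_rates")

stopifnot_rates <- function(rates) {
  if (!is_mutation_rates(rates)) stop("expected a 'mutation_rates' object")
  invisible(rates)
}

#' Population parameters
#'
#' @param N population size (>= 1; integer in simulation contexts, may be real
#'   in the analytic formulas).
#' @return An object of class `"population_params"`.
#' @export
population_params <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N < 1)
    stop("N must be a finite scalar >= 1")
  structure(list(N = as.numeric(N)), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Population: N = %g haploid individuals\n", x$N))
  invisible(x)
}

as_population <- function(pop) {
  if (inherits(pop, "population_params")) return(pop)
  if (is.numeric(pop) && length(pop) == 1L) return(population_params(pop))
  stop("expected a 'population_params' object or a scalar N")
}

#' A single mutation event
#'
#' Describes one mutation event on the circular genome in 0-based coordinates.
#' Base positions are `0..L-1`; junctions (insertion points, inversion
#' breakpoints) are identified with the `L` inter-base positions, junction `j`
#' sitting immediately before base `j`. A junction is "inside a gene" iff both
#' flanking bases belong to the same gene, so exactly `zc - g` junctions are
#' lethal insertion/inversion sites and `znc + g` are neutral.
#'
#' @param type one of `"duplication"`, `"deletion"`, `"inversion"`, `"point"`,
#'   `"indel_plus"`, `"indel_minus"`.
#' @param start start coordinate: first deleted/copied base (deletions,
#'   duplications, indel_minus), the mutated base (point), or the first
#'   breakpoint junction (inversions).
#' @param size event length in bp (0 for point mutations; for inversions the
#'   distance from `start` to the second breakpoint).
#' @param insertion_point junction coordinate where the copied or inserted
#'   segment lands (duplications and indel_plus only).
#' @return An object of class `"mutation_event"`.
#' @export
mutation_event <- function(type, start = NA_real_, size = 0,
                           insertion_point = NA_real_) {
  type <- match.arg(type, MUTATION_TYPES)
  structure(list(type = type, start = start, size = size,
                 insertion_point = insertion_point),
            class = "mutation_event")
}
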