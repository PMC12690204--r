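## ---- layout helpers for enumeration ----------------------------------------
## All enumeration works on the explicit 0-based layout of an enumerable-mode
## architecture; nothing here uses the polynomial closed forms.

## run length of consecutive noncoding bases starting at each position
## (0 at coding positions). Never wraps the whole genome (g >= 1 gene).
noncoding_run_lengths <- function(arch) {
  L <- arch$L
  coding <- is_coding_pos(arch, 0:(L - 1))
  r <- integer(L)
  # scan twice around the circle so runs crossing the origin are correct
  run <- 0L
  for (i in rev(seq_len(2 * L))) {
    pos <- (i - 1L) %% L
    if (coding[pos + 1L]) run <- 0L else run <- run + 1L
    if (i <= L) r[pos + 1L] <- run
  }
  pmin(r, L)
}

## run length of consecutive non-promoter bases starting at each position
promoter_free_run_lengths <- function(arch) {
  L <- arch$L
  promoter <- is_promoter_pos(arch, 0:(L - 1))
  r <- integer(L)
  run <- 0L
  for (i in rev(seq_len(2 * L))) {
    pos <- (i - 1L) %% L
    if (promoter[pos + 1L]) run <- 0L else run <- run + 1L
    if (i <= L) r[pos + 1L] <- run
  }
  pmin(r, L)
}

neutral_junction_flags <- function(arch) !is_lethal_junction(arch, 0:(arch$L - 1))

check_enumerable <- function(arch, max_L, what) {
  if (arch$mode != "enumerable")
    stop("enumeration requires an enumerable-mode architecture")
  if (arch$L > max_L)
    stop(sprintf(
      "L = %g exceeds the %s enumeration guard (%g); use sample_neutrality() instead",
      arch$L, what, max_L))
}

#' Exhaustive enumeration of mutation neutrality
#'
#' Ground-truth counts obtained by iterating every event of the given type on
#' the explicit base-level layout of a small circular genome: all `L^2`
#' (start, size) deletions, all `L^3` (start, size, insertion) duplications
#' (the independent insertion junction is enumerated separately and multiplied
#' through), all `L^2` junction pairs for inversions, all `L` bases for point
#' mutations and all `L * lm` (start, size) indels. Events are classified with
#' the same base-level rules as [classify_event()]; no closed form enters.
#'
#' @param arch an enumerable-mode [genome_architecture()] with `L <= 10^4`
#'   (`L <= 200` for duplications, whose event space is cubic).
#' @param type mutation type.
#' @param lm maximum indel size (indel types only).
#' @param max_L,max_L_dupl enumeration guards.
#' @return A list of class `"enumeration_report"`: `type`, `total_events`,
#'   `neutral_events`, `neutral_fraction` (the exact ratio of the two integer
#'   counts), and `size_histogram` (neutral event count per size; `NULL` for
#'   point mutations and inversions).
#' @examples
#' a <- genome_architecture(2, 6, 4)
#' enumerate_neutrality(a, "deletion")$neutral_events    # 6 of 100
#' enumerate_neutrality(a, "duplication")$neutral_events # 120 of 1000
#' @export
enumerate_neutrality <- function(arch, type, lm = 50,
                                 max_L = 1e4, max_L_dupl = 200) {
  stopifnot_arch(arch)
  type <- match.arg(type, MUTATION_TYPES)
  check_enumerable(arch, if (type == "duplication") max_L_dupl else max_L, type)
  L <- arch$L
  report <- function(total, neutral, hist = NULL) {
    structure(list(type = type, total_events = total, neutral_events = neutral,
                   neutral_fraction = neutral / total,
                   size_histogram = hist),
              class = "enumeration_report")
  }
  size_counts_from_runs <- function(runs, kmax) {
    # number of starts whose neutral run covers size k, for k = 1..kmax
    if (kmax < 1) return(integer(0))
    vapply(seq_len(kmax), function(k) sum(runs >= k), 0L)
  }
  switch(type,
    deletion = {
      runs <- noncoding_run_lengths(arch)
      cnt <- size_counts_from_runs(runs, max(runs))
      hist <- if (length(cnt)) stats::setNames(cnt, seq_along(cnt)) else NULL
      report(L^2, sum(as.numeric(cnt)), hist)
    },
    indel_minus = {
      runs <- noncoding_run_lengths(arch)
      cnt <- size_counts_from_runs(pmin(runs, lm), min(max(runs), lm))
      hist <- if (length(cnt)) stats::setNames(cnt, seq_along(cnt)) else NULL
      report(L * lm, sum(as.numeric(cnt)), hist)
    },
    duplication = {
      seg <- promoter_free_run_lengths(arch)
      nj <- sum(neutral_junction_flags(arch))
      cnt <- size_counts_from_runs(seg, max(seg))
      hist <- if (length(cnt)) stats::setNames(as.numeric(cnt) * nj, seq_along(cnt)) else NULL
      report(L^3, sum(as.numeric(cnt)) * nj, hist)
    },
    indel_plus = {
      nj <- sum(neutral_junction_flags(arch))
      hist <- stats::setNames(rep(nj, lm), seq_len(lm))
      report(L * lm, as.numeric(nj) * lm, hist)
    },
    inversion = {
      nj <- sum(neutral_junction_flags(arch))
      report(L^2, as.numeric(nj)^2, NULL)
    },
    point = {
      nc <- sum(!is_coding_pos(arch, 0:(L - 1)))
      report(L, nc, NULL)
    }
  )
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat(sprintf("Enumeration (%s): %g neutral of %g events (fraction %.8g)\n",
              x$type, x$neutral_events, x$total_events, x$neutral_fraction))
  invisible(x)
}

#' Per-start-position neutrality probabilities by enumeration
#'
#' For each of the `L` start positions (or junctions), the probability that an
#' event of the given type starting there is neutral, over the remaining
#' uniform draws (size uniform on `1..L` for structural types, `1..lm` for
#' indels; an independent uniform insertion junction for duplications).
#' Computed from the base-level layout; used as the independent oracle for the
#' grouped effective-fitness evaluation.
#'
#' @inheritParams enumerate_neutrality
#' @return Numeric vector of length `L`.
#' @export
position_neutrality <- function(arch, type, lm = 50) {
  stopifnot_arch(arch)
  type <- match.arg(type, MUTATION_TYPES)
  check_enumerable(arch, 1e5, type)
  L <- arch$L
  switch(type,
    deletion    = noncoding_run_lengths(arch) / L,
    indel_minus = pmin(noncoding_run_lengths(arch), lm) / lm,
    duplication = {
      nj <- sum(neutral_junction_flags(arch))
      (promoter_free_run_lengths(arch) / L) * (nj / L)
    },
    indel_plus  = as.numeric(neutral_junction_flags(arch)),
    inversion   = {
      nj <- sum(neutral_junction_flags(arch))
      as.numeric(neutral_junction_flags(arch)) * nj / L
    },
    point       = as.numeric(!is_coding_pos(arch, 0:(L - 1)))
  )
}

#' Mean signed genome-size change per structural mutation event
#'
#' Enumerates every deletion event (`L^2` ordered (start, size) pairs, signed
#' change `-size`) and every duplication event (`L^3` triples, signed change
#' `+size`) — neutral and lethal alike — and averages the signed change over
#' the two equally weighted event classes. Because the two classes share the
#' same uniform size measure, the expected raw change of genome size upon one
#' mutation is exactly zero: the growth bias of the model is a neutrality
#' bias, not a mutational input bias.
#'
#' @param arch an enumerable-mode [genome_architecture()] with `L <= 200`.
#' @return A list with the per-class means (`mean_deletion`,
#'   `mean_duplication`, in bp) and their equal-weight average
#'   `mean_signed_change`.
#' @export
enumerate_size_change <- function(arch) {
  stopifnot_arch(arch)
  check_enumerable(arch, 200, "size-change")
  L <- arch$L
  sizes <- rep(seq_len(L), each = L)          # all (start, size) pairs
  mean_del <- mean(-sizes)
  # duplications: each (start, size) pair combines with L insertion junctions
  mean_dup <- sum(as.numeric(sizes) * L) / (as.numeric(L)^3)
  list(mean_deletion = mean_del,
       mean_duplication = mean_dup,
       mean_signed_change = (mean_del + mean_dup) / 2)
}

#' Monte-Carlo estimate of a neutrality probability
#'
#' Draws events of the given type with uniform breakpoints, classifies each
#' with the base-level rules, and returns the unbiased estimate of the
#' neutrality probability with its binomial standard error. Scales the
#' enumeration oracle to architectures too large to enumerate.
#'
#' @param arch an enumerable-mode [genome_architecture()].
#' @param type mutation type.
#' @param draws number of Monte-Carlo draws (>= 1000).
#' @param seed RNG seed (results are reproducible from seed + parameters).
#' @param lm maximum indel size.
#' @return A list with `estimate`, `stderr`, `draws`, `seed`, `type`.
#' @export
sample_neutrality <- function(arch, type, draws, seed, lm = 50) {
  stopifnot_arch(arch)
  if (arch$mode != "enumerable")
    stop("sampling requires an enumerable-mode architecture")
  type <- match.arg(type, MUTATION_TYPES)
  if (draws < 1e3) stop("draws must be >= 1000")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- arch$L
  start <- floor(stats::runif(draws, 0, L))
  neutral <- switch(type,
    deletion = {
      size <- floor(stats::runif(draws, 0, L)) + 1
      count_coding_in_span(arch, start, size) == 0
    },
    indel_minus = {
      size <- floor(stats::runif(draws, 0, lm)) + 1
      count_coding_in_span(arch, start, size) == 0
    },
    duplication = {
      size <- floor(stats::runif(draws, 0, L)) + 1
      ins <- floor(stats::runif(draws, 0, L))
      count_promoters_in_span(arch, start, size) == 0 &
        !is_lethal_junction(arch, ins)
    },
    indel_plus = !is_lethal_junction(arch, start),
    inversion = {
      j2 <- floor(stats::runif(draws, 0, L))
      !is_lethal_junction(arch, start) & !is_lethal_junction(arch, j2)
    },
    point = !is_coding_pos(arch, start)
  )
  p <- mean(neutral)
  list(estimate = p, stderr = sqrt(p * (1 - p) / draws),
       draws = draws, seed = seed, type = type)
}

## save/restore the global RNG state so seeded oracles do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Forward Wright-Fisher fixation Monte-Carlo
#'
#' Simulates the fate of a single mutant lineage in a haploid Wright-Fisher
#' population of size `N`: each generation the `N` offspring are resampled
#' binomially from parental weights, the mutant carrying relative sampling
#' weight equal to its effective-fitness ratio `fe_mut / fe_wt`. Repeats
#' `replicates` independent introductions (one copy each) and returns the
#' empirical fixation rate. The analytic counterpart is
#' [fixation_probability()]: with `r = fe_wt/fe_mut`, the diffusion limit of
#' this process is `(1 - r^2)/(1 - r^(2N))`.
#'
#' @param N population size (integer, `2 <= N <= 1000`).
#' @param fitness_ratio mutant-to-wild-type effective-fitness ratio (> 0).
#' @param replicates number of replicate introductions (`<= 10^6`).
#' @param seed RNG seed.
#' @return A list of class `"wf_run"`: `N`, `fitness_ratio`, `replicates`,
#'   `seed`, `fixations`, `rate`, `stderr` and `ci95` (the 95% binomial
#'   confidence half-width).
#' @export
wf_fixation_mc <- function(N, fitness_ratio, replicates, seed) {
  if (N < 2 || N > 1e3 || N != round(N)) stop("N must be an integer in [2, 1000]")
  if (replicates < 1 || replicates > 1e6) stop("replicates must be in [1, 1e6]")
  if (fitness_ratio <= 0) stop("fitness_ratio must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- fitness_ratio
  counts <- rep(1L, replicates)
  fixed <- 0L
  active <- seq_len(replicates)
  while (length(active)) {
    i <- counts[active]
    pr <- (w * i) / (w * i + (N - i))
    counts[active] <- stats::rbinom(length(active), N, pr)
    i2 <- counts[active]
    fixed <- fixed + sum(i2 == N)
    active <- active[i2 > 0L & i2 < N]
  }
  rate <- fixed / replicates
  se <- sqrt(rate * (1 - rate) / replicates)
  structure(list(N = N, fitness_ratio = fitness_ratio, replicates = replicates,
                 seed = seed, fixations = fixed, rate = rate,
                 stderr = se, ci95 = 1.96 * se),
            class = "wf_run")
}

#' @export
print.wf_run <- function(x, ...) {
  cat(sprintf("WF fixation MC: %d/%d fixed (rate %.6g +- %.2g SE), N = %d, w = %.6g\n",
              x$fixations, x$replicates, x$rate, x$stderr, x$N, x$fitness_ratio))
  invisible(x)
}

## conditional neutral size draw for a trajectory event at current znc
draw_neutral_size <- function(type, z, g, zc, lm) {
  m <- z / g; p <- (z + zc) / g
  switch(type,
    deletion = {
      kmax <- ceiling(m + 1) - 1
      -sample.int(kmax, 1, prob = pmax(m - seq_len(kmax) + 1, 0))
    },
    duplication = {
      kmax <- ceiling(p) - 1
      sample.int(kmax, 1, prob = pmax(p - seq_len(kmax), 0))
    },
    indel_plus = sample.int(lm, 1),
    indel_minus = {
      kmax <- min(lm, ceiling(m + 1) - 1)
      -sample.int(kmax, 1, prob = pmax(m - seq_len(kmax) + 1, 0))
    },
    point = 0,
    inversion = 0
  )
}

#' Forward Wright-Fisher trajectory of the noncoding genome size
#'
#' Small-scale forward simulation used for qualitative mean-reversion checks:
#' a population of `N` genomes (described only by their noncoding size; the
#' equal-spacing idealization is re-imposed after every event) reproduces by
#' Wright-Fisher resampling. Each offspring draws, per active mutation type, a
#' binomial number of events over its genome length; each event is neutral
#' with the architecture's neutrality probability at the offspring's current
#' size and otherwise lethal, in which case the offspring is redrawn from a
#' new random parent. Neutral size-changing events shift the noncoding size by
#' a draw from the conditional neutral size distribution. Intended for tiny
#' configurations (`N <= 200`, `L <= ~10^3`, inflated `mu`); it validates the
#' direction of the flux balance, not its magnitude.
#'
#' @param config list with elements `N`, `g`, `zc`, `znc0` and `rates` (a
#'   [mutation_rates()] object).
#' @param generations number of generations to simulate.
#' @param seed RNG seed.
#' @param max_attempts rejection cap per generation before the run is declared
#'   extinct (all offspring lethal).
#' @return A list of class `"wf_trajectory"`: `mean_znc` (length
#'   `generations + 1`, starting value included), `terminated`,
#'   `generations_run`, `seed`.
#' @export
wf_genome_trajectory <- function(config, generations, seed, max_attempts = 1000L) {
  stopifnot(is.list(config))
  rates <- config$rates; stopifnot_rates(rates)
  N <- config$N; g <- config$g; zc <- config$zc
  if (N > 1000) stop("trajectory simulation is desk-scale: N <= 1000")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  znc <- rep(as.numeric(config$znc0), N)
  mean_znc <- numeric(generations + 1)
  mean_znc[1] <- mean(znc)
  act <- active_types(rates)
  lam <- rates$lambda
  terminated <- FALSE
  gen_done <- 0L
  for (gen in seq_len(generations)) {
    child <- numeric(N)
    for (s in seq_len(N)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        z <- znc[sample.int(N, 1)]
        Lp <- round(z + zc)
        dead <- FALSE
        for (type in act) {
          nev <- stats::rbinom(1, Lp, lam[[type]] * rates$mu)
          if (nev == 0) next
          for (e in seq_len(nev)) {
            arch_e <- genome_architecture(g, zc, z, mode = "analytic")
            nu <- neutral_prob(arch_e, type, lm = rates$lm)
            if (stats::runif(1) > nu) { dead <- TRUE; break }
            z <- z + draw_neutral_size(type, z, g, zc, rates$lm)
          }
          if (dead) break
        }
        if (!dead) { child[s] <- z; ok <- TRUE; break }
      }
      if (!ok) { terminated <- TRUE; break }
    }
    if (terminated) break
    znc <- child
    mean_znc[gen + 1] <- mean(znc)
    gen_done <- gen
  }
  structure(list(mean_znc = mean_znc[seq_len(gen_done + 1)],
                 terminated = terminated,
                 generations_run = gen_done, seed = seed),
            class = "wf_trajectory")
}
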