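#' Neutrality probability of a mutation type
#'
#' Exact probability that a uniformly drawn mutation of the given type is
#' neutral (does not touch the coding genome), under the uniform-breakpoint
#' event measure: a deletion is an ordered pair (start, size) with start
#' uniform over the `L` bases and size uniform over `1..L` (`L^2` equiprobable
#' events); a duplication additionally draws an independent uniform insertion
#' junction (`L^3` events); an inversion draws two independent uniform
#' junctions; a point mutation draws one base; an indel draws a start (or
#' junction) uniform over `L` and a size uniform over `1..lm`.
#'
#' Closed forms (all derivable by counting neutral breakpoint combinations):
#' \describe{
#'   \item{deletion}{`znc (znc + g) / (2 g L^2)` — all removed bases must lie
#'     in one intergenic tract.}
#'   \item{duplication}{`(znc + zc - g)(znc + g) / (2 g L^2)` — the copied
#'     segment must avoid every promoter and the insertion junction must not
#'     fall strictly inside a gene.}
#'   \item{inversion}{`((znc + g)/L)^2` — both breakpoint junctions must lie
#'     outside genes.}
#'   \item{point}{`znc / L`.}
#'   \item{indel_plus}{`(znc + g)/L` — only the insertion junction matters;
#'     sizes up to `lm` are never architecturally blocked.}
#'   \item{indel_minus}{`(1/lm) * sum_j g * max(znc/g - j + 1, 0) / L` over
#'     sizes `j = 1..lm`.}
#' }
#'
#' @param arch a [genome_architecture()].
#' @param type mutation type (see [mutation_rates()]).
#' @param lm maximum indel size (only used for `"indel_minus"`).
#' @return Neutrality probability in `[0, 1]`.
#' @references The deletion/duplication ratio satisfies
#'   `nu_del/nu_dupl = znc/(znc + zc - g) <= 1` whenever `zc > g`:
#'   duplications are more often neutral than deletions.
#' @examples
#' a <- genome_architecture(g = 2, zc = 6, znc = 4)
#' neutral_prob(a, "deletion")     # 0.06
#' neutral_prob(a, "duplication")  # 0.12
#' @export
neutral_prob <- function(arch, type, lm = 50) {
  stopifnot_arch(arch)
  type <- match.arg(type, MUTATION_TYPES)
  g <- arch$g; zc <- arch$zc; znc <- arch$znc; L <- arch$L
  switch(type,
    deletion    = znc * (znc + g) / (2 * g * L^2),
    duplication = (znc + zc - g) * (znc + g) / (2 * g * L^2),
    inversion   = ((znc + g) / L)^2,
    point       = znc / L,
    indel_plus  = (znc + g) / L,
    indel_minus = {
      j <- seq_len(lm)
      sum(g * pmax(arch$intergene_len - j + 1, 0) / L) / lm
    }
  )
}

#' Neutrality probability of a mutation of given size
#'
#' Probability that a mutation of the given type and fixed size `k` is
#' neutral, over the remaining uniform breakpoints. For deletions this is the
#' probability over the `L` start positions, `g * max(znc/g - k + 1, 0) / L`;
#' for duplications it also includes the insertion-junction factor,
#' `g * max(period - k, 0) * (znc + g) / L^2`. Both vanish above the
#' architectural cutoffs (`znc/g` for deletions, `period - 1` for
#' duplications): larger mutations necessarily hit a gene or copy a promoter.
#' Indels behave like deletions (`indel_minus`) or like a bare junction draw
#' (`indel_plus`, probability `(znc+g)/L` for any `k <= lm`).
#'
#' @param arch a [genome_architecture()].
#' @param type `"deletion"`, `"duplication"`, `"indel_plus"` or
#'   `"indel_minus"`.
#' @param k mutation size in bp (vectorized, `k >= 1`).
#' @return Vector of neutrality probabilities.
#' @export
neutral_prob_given_size <- function(arch, type, k) {
  stopifnot_arch(arch)
  type <- match.arg(type, c("deletion", "duplication", "indel_plus", "indel_minus"))
  if (any(k < 1)) stop("k must be >= 1")
  g <- arch$g; L <- arch$L; znc <- arch$znc
  m <- arch$intergene_len; p <- arch$period
  switch(type,
    deletion    = g * pmax(m - k + 1, 0) / L,
    indel_minus = g * pmax(m - k + 1, 0) / L,
    duplication = g * pmax(p - k, 0) * (znc + g) / L^2,
    indel_plus  = rep((znc + g) / L, length(k))
  )
}

#' Mean size of a neutral mutation
#'
#' Expected size (bp) of a mutation of the given type conditional on being
#' neutral, under the uniform event measure. For deletions the neutral sizes
#' `k = 1..m` (with `m = znc/g`) carry weight `g (m - k + 1)`, giving mean
#' `(m + 2)/3`; for duplications sizes `k = 1..p-1` carry weight `g (p - k)`,
#' giving `(p + 1)/3`. Since `p = m + zc/g`, neutral duplications are on
#' average larger than neutral deletions whenever `zc > g`.
#'
#' @param arch a [genome_architecture()].
#' @param type `"deletion"`, `"duplication"`, `"point"`, `"indel_plus"` or
#'   `"indel_minus"` (point mutations have size 0; inversions do not change
#'   genome size and have no size in this sense).
#' @param lm maximum indel size (indel types only).
#' @return Expected neutral size in bp.
#' @export
mean_neutral_size <- function(arch, type, lm = 50) {
  stopifnot_arch(arch)
  type <- match.arg(type, c("deletion", "duplication", "point",
                            "indel_plus", "indel_minus"))
  m <- arch$intergene_len; p <- arch$period
  out <- switch(type,
    point = 0,
    deletion = {
      if (m <= 0) stop("no neutral deletions exist (znc = 0)")
      (m + 2) / 3
    },
    duplication = {
      if (p <= 1) stop("no neutral duplications exist (period <= 1)")
      (p + 1) / 3
    },
    indel_plus = (lm + 1) / 2,
    indel_minus = {
      if (m <= 0) stop("no neutral small deletions exist (znc = 0)")
      j <- seq_len(min(lm, ceiling(m)))
      w <- pmax(m - j + 1, 0)
      sum(j * w) / sum(w)
    }
  )
  out
}

## ---- event-level classification -------------------------------------------
## Layout convention (0-based, circular): unit u = [u*period, (u+1)*period);
## the gene occupies the first gene_len bases of each unit, its promoter being
## the unit's first base; the intergenic tract occupies the rest.

offset_in_period <- function(arch, pos) pos %% arch$period

is_coding_pos <- function(arch, pos) offset_in_period(arch, pos) < arch$gene_len

is_promoter_pos <- function(arch, pos) offset_in_period(arch, pos) == 0

## junction j sits immediately before base j; it is strictly inside a gene iff
## bases j-1 and j are consecutive bases of the same gene.
is_lethal_junction <- function(arch, j) {
  off <- offset_in_period(arch, j)
  off >= 1 & off <= arch$gene_len - 1
}

## number of coding bases among size consecutive bases starting at start
## (circular). Vectorized over start/size.
count_coding_in_span <- function(arch, start, size) {
  count_class_in_span(start, size, arch$L, arch$period, arch$gene_len, 0)
}

count_promoters_in_span <- function(arch, start, size) {
  count_class_in_span(start, size, arch$L, arch$period, 1, 0)
}

## counts positions with (pos %% period) in [lo, lo + width) over a circular
## span of `size` bases starting at `start`; assumes integer coordinates.
count_class_in_span <- function(start, size, L, period, width, lo) {
  # positions start .. start+size-1 (mod L); count per full period plus edges
  n_full <- size %/% period
  rem <- size %% period
  base <- n_full * width
  off <- start %% period
  # remaining rem positions have offsets off, off+1, ..., off+rem-1 (mod period)
  # count those with offset in [lo, lo+width)
  extra <- count_offsets_in_window(off, rem, period, lo, width)
  base + extra
}

## among offsets off, off+1, ..., off+n-1 (mod period), count in [lo, lo+width)
count_offsets_in_window <- function(off, n, period, lo, width) {
  a <- (off - lo) %% period        # window start relative to off
  # count over a run of n consecutive offsets starting at `off`:
  # shift so window is [0, width): offsets become (i - lo) mod period for
  # i = off..off+n-1, i.e. a, a+1, ..., a+n-1 (mod period); count < width.
  n_full <- n %/% period
  rem <- n %% period
  cnt <- n_full * width
  # remaining offsets a..a+rem-1 (mod period): how many are < width?
  end <- a + rem
  cnt + ifelse(end <= period,
               pmin(end, width) - pmin(a, width),
               (pmin(period, width) - pmin(a, width)) + pmin(end - period, width))
}

#' Classify a mutation event as neutral or lethal
#'
#' Deterministic lethal/neutral classification from the event coordinates and
#' the architecture: deletions (and small deletions) are lethal iff any
#' removed base is coding; duplications are lethal iff the copied segment
#' contains a promoter or the insertion junction lies strictly inside a gene;
#' insertions are lethal iff the junction is strictly inside a gene; point
#' mutations are lethal iff the target base is coding; inversions are lethal
#' iff either breakpoint junction is strictly inside a gene (genes inside a
#' neutral inverted segment are assumed re-orientable without effect).
#'
#' @param arch an enumerable-mode [genome_architecture()].
#' @param event a [mutation_event()].
#' @return `TRUE` if the event is neutral, `FALSE` if lethal.
#' @export
classify_event <- function(arch, event) {
  stopifnot_arch(arch)
  if (!inherits(event, "mutation_event")) stop("expected a 'mutation_event'")
  if (arch$mode != "enumerable")
    stop("event classification requires an enumerable-mode architecture")
  L <- arch$L
  chk <- function(x, what, n = L) {
    if (any(!is.finite(x)) || any(x < 0) || any(x >= n) || any(x != round(x)))
      stop(sprintf("%s out of range [0, %d)", what, as.integer(n)))
  }
  type <- event$type
  st <- event$start; sz <- event$size; ip <- event$insertion_point
  switch(type,
    deletion = {
      chk(st, "start")
      if (sz < 1 || sz > L || sz != round(sz)) stop("deletion size out of range [1, L]")
      count_coding_in_span(arch, st, sz) == 0
    },
    indel_minus = {
      chk(st, "start")
      if (sz < 1 || sz != round(sz)) stop("indel size must be a positive integer")
      count_coding_in_span(arch, st, sz) == 0
    },
    duplication = {
      chk(st, "start"); chk(ip, "insertion_point")
      if (sz < 1 || sz > L || sz != round(sz)) stop("duplication size out of range [1, L]")
      count_promoters_in_span(arch, st, sz) == 0 && !is_lethal_junction(arch, ip)
    },
    indel_plus = {
      chk(ip, "insertion_point")
      !is_lethal_junction(arch, ip)
    },
    point = {
      chk(st, "start")
      !is_coding_pos(arch, st)
    },
    inversion = {
      chk(st, "start (first breakpoint)")
      j2 <- (st + sz) %% L
      !is_lethal_junction(arch, st) && !is_lethal_junction(arch, j2)
    }
  )
}
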