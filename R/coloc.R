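#' Poisson presence probability of a locus class in a region
#'
#' Under a homogeneous Poisson model with `m` loci per cM, the probability
#' that a region of length `s` cM contains at least one locus is
#' `1 - exp(-m * s)`.
#'
#' @param m rate, loci per cM (`>= 0`); vectorized.
#' @param s region length in cM (`>= 0`); vectorized.
#' @return Probability in `[0, 1)`.
#' @examples
#' presence_probability(0.0222, 20)
#' @export
presence_probability <- function(m, s) {
  if (any(m < 0)) stop("rate m must be non-negative")
  if (any(s < 0)) stop("region length s must be non-negative")
  -expm1(-m * s)
}

#' Poisson rate of detected loci per tested cM
#'
#' The rate parameter of a locus class is the number of detected loci divided
#' by the total genetic length screened for that class.
#'
#' @param count number of detected loci.
#' @param tested_length_cM total tested length, cM.
#' @return An object of class `poisson_rate`: list with `m` (loci/cM),
#'   `count` and `tested_length_cM` (provenance).
#' @export
poisson_rate <- function(count, tested_length_cM) {
  stopifnot(count >= 0, tested_length_cM > 0)
  structure(list(m = count / tested_length_cM, count = count,
                 tested_length_cM = tested_length_cM),
            class = "poisson_rate")
}

#' @export
print.poisson_rate <- function(x, ...) {
  cat(sprintf("Poisson rate: %d loci / %.0f cM = %.5f per cM\n",
              x$count, x$tested_length_cM, x$m))
  invisible(x)
}

#' Joint presence-pattern probabilities for two independent locus classes
#'
#' For locus classes A and B with Poisson rates `m_a` and `m_b`, independently
#' distributed over the genome, a region of length `s` shows pattern
#' * both:   `(1 - exp(-m_a s)) (1 - exp(-m_b s))`
#' * none:   `exp(-m_a s) exp(-m_b s)`
#' * A only: `(1 - exp(-m_a s)) exp(-m_b s)`
#' * B only: `exp(-m_a s) (1 - exp(-m_b s))`
#'
#' The four probabilities sum to one.
#'
#' @param m_a,m_b rates (loci per cM) or [poisson_rate()] objects.
#' @param s region length(s), cM; vectorized.
#' @return Matrix with one row per element of `s` and columns
#'   `both`, `none`, `a_only`, `b_only`.
#' @export
pattern_probabilities <- function(m_a, m_b, s) {
  if (inherits(m_a, "poisson_rate")) m_a <- m_a$m
  if (inherits(m_b, "poisson_rate")) m_b <- m_b$m
  pa <- presence_probability(m_a, s)
  pb <- presence_probability(m_b, s)
  cbind(both = pa * pb, none = (1 - pa) * (1 - pb),
        a_only = pa * (1 - pb), b_only = (1 - pa) * pb)
}

#' Classify overlap regions by locus presence pattern
#'
#' Assigns each region of an overlap region set exactly one of the four
#' presence patterns according to boundary-inclusive containment of the two
#' locus classes.
#'
#' @param overlaps a [region_set()] (typically from [region_intersect()]).
#' @param loci_a,loci_b data frames of locus records (`chrom`, `pos_cM`).
#' @return Named integer vector with elements `both`, `none`, `a_only`,
#'   `b_only` summing to `nrow(overlaps)`; the per-region pattern is attached
#'   as attribute `"pattern"`.
#' @export
classify_overlaps <- function(overlaps, loci_a, loci_b) {
  stopifnot(inherits(overlaps, "region_set"))
  contains <- function(loci, i) {
    if (is.null(loci) || !nrow(loci)) return(FALSE)
    any(loci$chrom == overlaps$chrom[i] &
          loci$pos_cM >= overlaps$start[i] &
          loci$pos_cM <= overlaps$end[i])
  }
  pat <- character(nrow(overlaps))
  for (i in seq_len(nrow(overlaps))) {
    a <- contains(loci_a, i)
    b <- contains(loci_b, i)
    pat[i] <- if (a && b) "both" else if (!a && !b) "none"
      else if (a) "a_only" else "b_only"
  }
  out <- vapply(c("both", "none", "a_only", "b_only"),
                function(p) sum(pat == p), integer(1))
  attr(out, "pattern") <- pat
  out
}

#' Concordance test of observed presence patterns against Poisson independence
#'
#' Compares the observed counts of the four presence patterns (both / none /
#' A only / B only) across overlap regions with the counts expected if the
#' two locus classes were scattered independently with their Poisson rates.
#' Expected counts are summed region by region from
#' [pattern_probabilities()] at each region's own length.  The chi-square
#' statistic `sum (O - E)^2 / E` over the four cells is referred to a
#' chi-square distribution (`df` = 3 by default: four categories with
#' probabilities fixed a priori), and additionally to a Monte-Carlo null in
#' which each region's pattern is redrawn from its own four-probability
#' multinomial.  The Monte-Carlo p-value is the authoritative one; the
#' analytic p is suppressed (`NA`) when any expected cell drops below
#' `floor`.
#'
#' @param observed named vector from [classify_overlaps()] (or any vector
#'   with elements `both`, `none`, `a_only`, `b_only`).
#' @param rate_a,rate_b [poisson_rate()] objects (or bare rates, loci/cM).
#' @param sizes numeric vector of region lengths (cM); its length must equal
#'   the observed total.
#' @param df degrees of freedom of the analytic reference distribution.
#' @param nsim Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param floor minimum expected cell count for the analytic p.
#' @return Object of class `concordance_test` with fields `observed`,
#'   `expected`, `statistic`, `df`, `p.value` (analytic), `p.mc`,
#'   `nsim`, `seed`, `rates`.
#' @export
concordance_test <- function(observed, rate_a, rate_b, sizes, df = 3,
                             nsim = 10000, seed = NULL, floor = 0.5) {
  cells <- c("both", "none", "a_only", "b_only")
  if (!all(cells %in% names(observed))) {
    stop("observed must have elements ", paste(cells, collapse = ", "))
  }
  obs <- as.numeric(observed[cells])
  n_regions <- sum(obs)
  if (length(sizes) != n_regions) {
    stop(sprintf("length(sizes) = %d but observed counts total %d",
                 length(sizes), n_regions))
  }
  probs <- pattern_probabilities(rate_a, rate_b, sizes)  # n_regions x 4
  expected <- colSums(probs)
  stat <- sum((obs - expected)^2 / expected)
  p_analytic <- if (any(expected < floor)) {
    NA_real_
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  # Monte-Carlo: redraw each region's pattern from its own multinomial
  p_mc <- NA_real_
  if (nsim > 0) {
    p_mc <- .with_seed(seed, {
      cum <- t(apply(probs, 1, cumsum))
      u <- matrix(stats::runif(nsim * n_regions), nrow = nsim)
      counts <- matrix(0, nrow = nsim, ncol = 4)
      for (k in 1:4) {
        lo <- if (k == 1) 0 else rep(cum[, k - 1], each = nsim)
        hi <- if (k == 4) Inf else rep(cum[, k], each = nsim)
        counts[, k] <- rowSums(matrix(u >= lo & u < hi, nrow = nsim))
      }
      stat_sim <- colSums((t(counts) - expected)^2 / expected)
      (1 + sum(stat_sim >= stat - 1e-12)) / (nsim + 1)
    })
  }
  structure(list(observed = stats::setNames(obs, cells),
                 expected = stats::setNames(expected, cells),
                 statistic = stat, df = df, p.value = p_analytic,
                 p.mc = p_mc, nsim = nsim, seed = seed,
                 rates = list(a = rate_a, b = rate_b),
                 sizes = sizes),
            class = "concordance_test")
}

#' @export
print.concordance_test <- function(x, ...) {
  cat("Poisson-independence concordance test\n\n")
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  cat(sprintf("\nX-squared = %.3f, df = %s, analytic p = %s\n",
              x$statistic, format(x$df),
              if (is.na(x$p.value)) "NA (small expected cell)"
              else format.pval(x$p.value, digits = 3)))
  if (!is.na(x$p.mc)) {
    cat(sprintf("Monte-Carlo p = %s (%d replicates)\n",
                format.pval(x$p.mc, digits = 3), x$nsim))
  }
  for (nm in names(x$rates)) {
    r <- x$rates[[nm]]
    if (inherits(r, "poisson_rate")) {
      cat(sprintf("rate %s: %d loci / %.0f cM = %.5f per cM\n",
                  nm, r$count, r$tested_length_cM, r$m))
    }
  }
  invisible(x)
}

#' Sensitivity of the concordance test to the assumed tested lengths
#'
#' The tested genome lengths behind the Poisson rates are only known
#' approximately ("about 40-50% of the genome").  This helper re-runs the
#' analytic and Monte-Carlo test over a grid of assumed lengths and tabulates
#' the resulting p-values.
#'
#' @param observed,sizes as in [concordance_test()].
#' @param count_a,count_b detected locus counts for the two classes.
#' @param lengths_cM grid of assumed tested lengths (applied to both classes).
#' @param ... passed to [concordance_test()].
#' @return Data frame with columns `tested_length_cM`, `m_a`, `m_b`,
#'   `statistic`, `p_analytic`, `p_mc`.
#' @export
concordance_sensitivity <- function(observed, sizes, count_a, count_b,
                                    lengths_cM = seq(560, 700, by = 20),
                                    ...) {
  rows <- lapply(lengths_cM, function(L) {
    ct <- concordance_test(observed, poisson_rate(count_a, L),
                           poisson_rate(count_b, L), sizes, ...)
    data.frame(tested_length_cM = L, m_a = count_a / L, m_b = count_b / L,
               statistic = ct$statistic, p_analytic = ct$p.value,
               p_mc = ct$p.mc)
  })
  do.call(rbind, rows)
}
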