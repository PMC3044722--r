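#' Distance from a query locus to its nearest anchor locus
#'
#' Minimum absolute cM distance between a query position and any anchor on
#' the same chromosome; `NA` when no anchor shares the chromosome.
#'
#' @param chrom,pos_cM query chromosome and position (scalars).
#' @param anchors data frame of anchor loci (`chrom`, `pos_cM`).
#' @return Distance in cM, or `NA_real_`.
#' @export
nearest_anchor_distance <- function(chrom, pos_cM, anchors) {
  stopifnot(length(chrom) == 1L, length(pos_cM) == 1L)
  d <- anchors$pos_cM[anchors$chrom == chrom]
  if (!length(d)) return(NA_real_)
  min(abs(d - pos_cM))
}

#' Null probability that a random locus falls near an anchor
#'
#' Under uniform placement over the tested regions, the probability that a
#' locus lands within `w` cM of some anchor is the total length of the
#' anchor windows `[pos - w, pos + w]` -- merged so that overlapping windows
#' are not double counted, and clipped to the tested regions -- divided by
#' the total tested length.
#'
#' @param anchors data frame of anchor loci (`chrom`, `pos_cM`).
#' @param w window half-width, cM (> 0).
#' @param tested a [region_set()] of informative regions.
#' @return Probability in `[0, 1]`.
#' @export
hit_probability <- function(anchors, w, tested) {
  stopifnot(inherits(tested, "region_set"))
  if (!nrow(tested) || region_total_length(tested) <= 0) {
    stop("hit_probability: empty tested region set")
  }
  if (!nrow(anchors)) return(0)
  win <- anchor_windows(anchors$chrom, anchors$pos_cM, w, tested)
  region_total_length(win) / region_total_length(tested)
}

#' Binomial proximity test for clustering of query loci near anchors
#'
#' Tests whether more query loci than expected by chance lie within `w` cM of
#' an anchor locus.  All query loci must be informative, i.e. inside the
#' tested regions.  A query is a hit when its nearest same-chromosome anchor
#' is at distance `<= w`.  Under the uniform null each query is a hit with
#' probability `p0 = ` [hit_probability()], so the number of hits is
#' `Binomial(n_total, p0)` and the reported p-value is the upper tail
#' `P(X >= n_hit)`.  A permutation p-value -- re-placing the queries
#' uniformly over the tested regions -- is computed alongside as a check on
#' the binomial null.
#'
#' @param query data frame of query loci (`chrom`, `pos_cM`).
#' @param anchors data frame of anchor loci (`chrom`, `pos_cM`).
#' @param tested a [region_set()] of informative regions.
#' @param w window half-width, cM; default 3.3.
#' @param nperm permutation replicates (0 to skip).
#' @param seed integer seed for the permutation draw.
#' @return Object of class `proximity_test`: fields `n_total`, `n_hit`,
#'   `distances` (per-query nearest-anchor distance), `mean_hit_distance`,
#'   `w`, `p0`, `p.value` (binomial tail), `p.perm`, `nperm`, `seed`.
#' @export
binomial_proximity_test <- function(query, anchors, tested, w = 3.3,
                                    nperm = 10000, seed = NULL) {
  stopifnot(inherits(tested, "region_set"), w > 0)
  n_total <- nrow(query)
  if (!n_total) stop("binomial_proximity_test: no query loci")
  inside <- vapply(seq_len(n_total), function(i) {
    !is.null(locate_locus(query$chrom[i], query$pos_cM[i], tested))
  }, logical(1))
  if (!all(inside)) {
    stop("query loci outside tested regions (not informative): ",
         paste(query$symbol[!inside], collapse = ", "))
  }
  d <- vapply(seq_len(n_total), function(i) {
    nearest_anchor_distance(query$chrom[i], query$pos_cM[i], anchors)
  }, numeric(1))
  hit <- !is.na(d) & d <= w
  n_hit <- sum(hit)
  p0 <- hit_probability(anchors, w, tested)
  p_binom <- stats::pbinom(n_hit - 1, n_total, p0, lower.tail = FALSE)
  p_perm <- NA_real_
  if (nperm > 0) {
    p_perm <- .with_seed(seed, {
      hits_sim <- vapply(seq_len(nperm), function(r) {
        q <- simulate_locus_placement(tested, n_fixed = n_total)
        dd <- vapply(seq_len(n_total), function(i) {
          nearest_anchor_distance(q$chrom[i], q$pos_cM[i], anchors)
        }, numeric(1))
        sum(!is.na(dd) & dd <= w)
      }, numeric(1))
      (1 + sum(hits_sim >= n_hit)) / (nperm + 1)
    })
  }
  structure(list(n_total = n_total, n_hit = n_hit, distances = d,
                 mean_hit_distance = if (n_hit) mean(d[hit]) else NA_real_,
                 w = w, p0 = p0, p.value = p_binom, p.perm = p_perm,
                 nperm = nperm, seed = seed),
            class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  cat("Binomial proximity test\n")
  cat(sprintf("  %d of %d query loci within %.1f cM of an anchor\n",
              x$n_hit, x$n_total, x$w))
  cat(sprintf("  mean distance of hits: %.2f cM\n", x$mean_hit_distance))
  cat(sprintf("  null hit probability p0 = %.3f\n", x$p0))
  cat(sprintf("  binomial tail p = %s\n", format.pval(x$p.value, digits = 3)))
  if (!is.na(x$p.perm)) {
    cat(sprintf("  permutation p = %s (%d replicates)\n",
                format.pval(x$p.perm, digits = 3), x$nperm))
  }
  invisible(x)
}

#' Assemble multi-locus clusters by single-linkage grouping
#'
#' Groups loci (possibly from several species, all on mouse-map coordinates)
#' per chromosome by single linkage: two loci join the same cluster when
#' their positions differ by at most `threshold` cM, directly or through a
#' chain.  Only groups of two or more loci are emitted.  Clusters containing
#' at least one lung and one colon locus are flagged, and tight clusters --
#' where some lung/colon pair lies within `flag_within` cM -- are marked.
#'
#' @param loci data frame of locus records (`symbol`, `species`, `trait`,
#'   `chrom`, `pos_cM`).
#' @param threshold single-linkage joining distance, cM.
#' @param flag_within tight-pair distance, cM (default 2.5).
#' @return Data frame with one row per cluster: `chrom`, `start`, `end`,
#'   `span`, `n_members`, `members`, `species`, `mixed_trait`,
#'   `tight_pair`; the per-cluster member tables are attached as attribute
#'   `"members"`.
#' @export
assemble_clusters <- function(loci, threshold = 10, flag_within = 2.5) {
  if (!nrow(loci)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), span = numeric(),
                      n_members = integer(), members = character(),
                      species = character(), mixed_trait = logical(),
                      tight_pair = logical(), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  loci <- loci[order(loci$chrom, loci$pos_cM), , drop = FALSE]
  rows <- list()
  members <- list()
  for (ch in unique(loci$chrom)) {
    li <- loci[loci$chrom == ch, , drop = FALSE]
    gap <- c(Inf, diff(li$pos_cM))
    grp <- cumsum(gap > threshold)
    for (g in unique(grp)) {
      mem <- li[grp == g, , drop = FALSE]
      if (nrow(mem) < 2) next
      lung <- mem$pos_cM[mem$trait == "lung"]
      colon <- mem$pos_cM[mem$trait == "colon"]
      tight <- length(lung) > 0 && length(colon) > 0 &&
        min(abs(outer(lung, colon, "-"))) <= flag_within
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = min(mem$pos_cM), end = max(mem$pos_cM),
        span = diff(range(mem$pos_cM)), n_members = nrow(mem),
        members = paste(mem$symbol, collapse = "/"),
        species = paste(sort(unique(mem$species)), collapse = "/"),
        mixed_trait = length(lung) > 0 && length(colon) > 0,
        tight_pair = tight, stringsAsFactors = FALSE
      )
      members[[length(members) + 1L]] <- mem
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    assemble_clusters(loci[0, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}
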