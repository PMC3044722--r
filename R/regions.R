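#' Region sets on a genetic map
#'
#' A `region_set` is a collection of closed intervals `[start, end]` in
#' centimorgan (cM) coordinates on named chromosomes, sorted and pairwise
#' disjoint within each chromosome.  Region sets represent the donor-strain
#' chromosomal segments of recombinant congenic strains that were tested for
#' linkage, and the "overlap" segments tested for two traits at once.
#'
#' Membership is boundary-inclusive throughout: a locus lying exactly on a
#' region endpoint counts as inside the region.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors of interval bounds in cM, `0 <= start <= end`.
#' @param merge if `TRUE`, overlapping or duplicated input intervals on the
#'   same chromosome are unioned instead of raising an error.  Printed region
#'   tables often repeat a tested segment on several rows; merging recovers the
#'   disjoint set.
#' @return An object of class `region_set`: a data frame with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' rs <- region_set(c("1", "1", "2"), c(32.8, 81.6, 5), c(41, 127, 41.4))
#' region_total_length(rs)
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       merge = FALSE) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("region_set: missing coordinates")
  }
  if (any(start < 0)) stop("region_set: negative start coordinate")
  if (any(start > end)) {
    bad <- which(start > end)[1L]
    stop(sprintf("region_set: start > end on chromosome %s (%s-%s)",
                 chrom[bad], format(start[bad]), format(end[bad])))
  }
  x <- data.frame(chrom = chrom, start = start, end = end,
                  stringsAsFactors = FALSE)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  if (merge) {
    x <- .merge_intervals(x)
  } else if (nrow(x) > 1) {
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    touch <- x$start[-1] < x$end[-nrow(x)]
    if (any(same & touch)) {
      i <- which(same & touch)[1L] + 1L
      stop(sprintf("region_set: intervals overlap on chromosome %s near %s cM",
                   x$chrom[i], format(x$start[i])))
    }
  }
  class(x) <- c("region_set", "data.frame")
  x
}

# union of possibly-overlapping sorted intervals, per chromosome
.merge_intervals <- function(x) {
  if (nrow(x) < 2) return(x)
  out <- x[1, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1]) {
    j <- nrow(out)
    if (x$chrom[i] == out$chrom[j] && x$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], x$end[i])
    } else {
      out <- rbind(out, x[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set: %d interval(s), %.1f cM total\n",
              nrow(x), region_total_length(x)))
  if (nrow(x)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Total genetic length of a region set
#'
#' @param x a [region_set()].
#' @return Sum of interval lengths `end - start`, in cM.
#' @export
region_total_length <- function(x) {
  if (!nrow(x)) return(0)
  sum(x$end - x$start)
}

#' Intersect two region sets
#'
#' Computes the per-chromosome intersection of two sets of closed cM
#' intervals.  Applied to the colon-tested and lung-tested donor segments this
#' yields the "overlap" regions informative for both traits.  The operation is
#' commutative and idempotent; zero-length intersections at a single shared
#' boundary point are kept (closed intervals).
#'
#' @param a,b [region_set()] objects.
#' @return A [region_set()] of the intersections (possibly empty).
#' @examples
#' colon <- region_set("1", 32.8, 41)
#' lung  <- region_set("1", 0, 59)
#' region_intersect(colon, lung)  # 32.8-41
#' @export
region_intersect <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  chrom <- character()
  start <- numeric()
  end <- numeric()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      lo <- pmax(ai$start[i], bi$start)
      hi <- pmin(ai$end[i], bi$end)
      keep <- lo <= hi
      if (any(keep)) {
        chrom <- c(chrom, rep(ch, sum(keep)))
        start <- c(start, lo[keep])
        end <- c(end, hi[keep])
      }
    }
  }
  region_set(chrom, start, end, merge = TRUE)
}

#' Locate a locus within a region set
#'
#' Finds the unique interval of `regions` containing a map position,
#' boundary-inclusive.  Used to classify susceptibility loci as inside or
#' outside the jointly tested overlap regions.
#'
#' @param chrom chromosome name of the locus.
#' @param pos_cM locus position in cM.
#' @param regions a [region_set()].
#' @return A one-row data frame (`chrom`, `start`, `end`) if contained,
#'   otherwise `NULL`.
#' @export
locate_locus <- function(chrom, pos_cM, regions) {
  stopifnot(inherits(regions, "region_set"), length(chrom) == 1L,
            length(pos_cM) == 1L)
  hit <- regions$chrom == chrom & regions$start <= pos_cM &
    regions$end >= pos_cM
  if (!any(hit)) return(NULL)
  out <- as.data.frame(regions[which(hit)[1L], , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Clip windows around anchor positions to a tested region set
#'
#' Builds the union of symmetric windows `[pos - w, pos + w]` around anchor
#' positions, merges overlapping windows, and intersects the result with the
#' tested regions.  This is the geometric measure behind the null hit
#' probability of the proximity test.
#'
#' @param chrom,pos_cM anchor chromosome names and positions (vectors).
#' @param w half-width of the window, cM.
#' @param tested a [region_set()] to clip against.
#' @return A [region_set()] of merged, clipped windows.
#' @export
anchor_windows <- function(chrom, pos_cM, w, tested) {
  stopifnot(w > 0, inherits(tested, "region_set"))
  win <- region_set(chrom, pmax(0, pos_cM - w), pos_cM + w, merge = TRUE)
  region_intersect(win, tested)
}
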