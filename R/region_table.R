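#' Read a tested-region / locus table
#'
#' Parses a CSV region table in the layout of the packaged `table1_regions.csv`
#' fixture: one row per tested donor-strain segment, with the susceptibility
#' locus mapped in that segment (if any).  Columns:
#'
#' * `chrom` - chromosome name,
#' * `trait` - `"colon"` or `"lung"`,
#' * `region_start_cM`, `region_end_cM` - closed interval bounds in cM,
#' * `locus_symbol` - locus name, or `"none"`/blank when the segment showed
#'   no linkage,
#' * `locus_cM` - locus position in cM (blank when no locus),
#' * `species`, `source` - free-text provenance.
#'
#' Tested segments may be repeated across rows (a segment harbouring two loci
#' is printed twice); the per-trait region sets returned are union-normalized
#' and therefore disjoint, while the raw rows are preserved for round-trip
#' output via [write_region_table()].
#'
#' @param path CSV file path.
#' @return An object of class `region_table`: list with elements
#'   `regions` (named list of [region_set()] per trait), `loci` (data frame of
#'   locus records with columns `symbol`, `species`, `trait`, `chrom`,
#'   `pos_cM`, `source`), and `table` (the raw rows as read).
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("chrom", "trait", "region_start_cM", "region_end_cM",
            "locus_symbol", "locus_cM", "species", "source")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("region table is missing column(s): ", paste(miss, collapse = ", "))
  }
  traits <- c("colon", "lung")
  n <- nrow(raw)
  start <- suppressWarnings(as.numeric(raw$region_start_cM))
  end <- suppressWarnings(as.numeric(raw$region_end_cM))
  for (i in seq_len(n)) {
    if (!(raw$trait[i] %in% traits)) {
      stop(sprintf("row %d: unknown trait '%s'", i, raw$trait[i]))
    }
    if (is.na(start[i]) || is.na(end[i])) {
      stop(sprintf("row %d: malformed region coordinates", i))
    }
    if (start[i] > end[i]) {
      stop(sprintf("row %d: region start %s > end %s", i,
                   raw$region_start_cM[i], raw$region_end_cM[i]))
    }
  }
  regions <- lapply(traits, function(tr) {
    sel <- raw$trait == tr
    region_set(raw$chrom[sel], start[sel], end[sel], merge = TRUE)
  })
  names(regions) <- traits

  has_locus <- !(raw$locus_symbol %in% c("", "none", "NA")) &
    !is.na(raw$locus_symbol)
  pos <- suppressWarnings(as.numeric(raw$locus_cM))
  if (any(has_locus & is.na(pos))) {
    stop(sprintf("row %d: locus '%s' has malformed position",
                 which(has_locus & is.na(pos))[1L],
                 raw$locus_symbol[which(has_locus & is.na(pos))[1L]]))
  }
  loci <- data.frame(
    symbol = raw$locus_symbol[has_locus],
    species = ifelse(nzchar(raw$species[has_locus]), raw$species[has_locus],
                     "mouse"),
    trait = raw$trait[has_locus],
    chrom = raw$chrom[has_locus],
    pos_cM = pos[has_locus],
    source = raw$source[has_locus],
    stringsAsFactors = FALSE
  )
  rownames(loci) <- NULL
  structure(list(regions = regions, loci = loci, table = raw),
            class = "region_table")
}

#' Write a region table back to CSV
#'
#' Writes the raw rows of a [read_region_table()] object field-for-field, so
#' that reading and writing round-trips the file.
#'
#' @param x a `region_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(x, path) {
  stopifnot(inherits(x, "region_table"))
  utils::write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.region_table <- function(x, ...) {
  cat("Region table:\n")
  for (tr in names(x$regions)) {
    cat(sprintf("  %s: %d tested interval(s), %.1f cM; %d locus record(s)\n",
                tr, nrow(x$regions[[tr]]),
                region_total_length(x$regions[[tr]]),
                sum(x$loci$trait == tr)))
  }
  invisible(x)
}

#' Overlap regions tested for both traits
#'
#' Derives the set of "overlap" regions -- segments screened for both locus
#' classes -- from a [read_region_table()] object.  When the table carries a
#' `pair_id` column (as the packaged fixture does), rows of the two traits
#' sharing a `pair_id` transcribe corresponding donor segments of the two
#' strain panels as printed, and the overlap is the union of the per-pair
#' intersections with duplicates removed.  Without pairing information the
#' global [region_intersect()] of the two traits' tested sets is returned.
#'
#' The two derivations can differ at segment boundaries: a global coordinate
#' intersection may add short slivers where non-corresponding donor segments
#' of the two panels happen to abut, which per-pair intersection (like the
#' published tables) does not count.
#'
#' @param x a `region_table`.
#' @param traits length-2 character: which traits to intersect.
#' @param use_pairs use the `pair_id` column when available.
#' @return A [region_set()].
#' @export
overlap_regions <- function(x, traits = c("colon", "lung"),
                            use_pairs = TRUE) {
  stopifnot(inherits(x, "region_table"), length(traits) == 2)
  tab <- x$table
  if (use_pairs && "pair_id" %in% names(tab) &&
      any(nzchar(tab$pair_id))) {
    pieces <- lapply(unique(tab$pair_id[nzchar(tab$pair_id)]), function(p) {
      rows <- tab[tab$pair_id == p, , drop = FALSE]
      rs <- lapply(traits, function(tr) {
        sel <- rows$trait == tr
        region_set(rows$chrom[sel], as.numeric(rows$region_start_cM[sel]),
                   as.numeric(rows$region_end_cM[sel]), merge = TRUE)
      })
      as.data.frame(region_intersect(rs[[1]], rs[[2]]))
    })
    all <- unique(do.call(rbind, pieces))
    return(region_set(all$chrom, all$start, all$end))
  }
  region_intersect(x$regions[[traits[1]]], x$regions[[traits[2]]])
}

#' Read a locus table
#'
#' Reads a CSV of susceptibility locus records (columns `symbol`, `species`,
#' `trait`, `chrom`, `pos_cM`, plus free extra columns such as `source` or
#' `informative`).
#'
#' @param path CSV file path.
#' @return Data frame of locus records.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("locus table not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("symbol", "species", "trait", "chrom", "pos_cM")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("locus table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$chrom <- as.character(x$chrom)
  bad_sp <- setdiff(unique(x$species), c("mouse", "human", "rat"))
  if (length(bad_sp)) stop("unknown species: ", paste(bad_sp, collapse = ", "))
  bad_tr <- setdiff(unique(x$trait), c("colon", "lung"))
  if (length(bad_tr)) stop("unknown trait: ", paste(bad_tr, collapse = ", "))
  if (any(x$pos_cM < 0)) stop("locus positions must be non-negative")
  x
}
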