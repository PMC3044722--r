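#' Genetic map of markers on named chromosomes
#'
#' Bundles chromosome lengths and marker positions (all in cM) into a
#' validated `genome_map` object used by the F2 simulator and the QTL scan.
#'
#' @param markers data frame with columns `marker`, `chrom`, `pos_cM`.
#' @param chromosomes optional data frame with columns `chrom`, `length_cM`.
#'   When omitted, lengths are taken from [mouse_chromosome_lengths()] for
#'   chromosomes named there, else from the largest marker position.
#' @return An object of class `genome_map`: list with elements `chromosomes`
#'   and `markers`, both data frames.
#' @examples
#' gm <- genome_map(data.frame(marker = c("m1", "m2"), chrom = "1",
#'                             pos_cM = c(10, 18)))
#' @export
genome_map <- function(markers, chromosomes = NULL) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "chrom", "pos_cM") %in% names(markers)))
  markers <- data.frame(marker = as.character(markers$marker),
                        chrom = as.character(markers$chrom),
                        pos_cM = as.numeric(markers$pos_cM),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(markers$marker)) {
    stop("genome_map: duplicated marker names")
  }
  if (any(markers$pos_cM < 0) || any(is.na(markers$pos_cM))) {
    stop("genome_map: marker positions must be non-negative")
  }
  if (is.null(chromosomes)) {
    std <- mouse_chromosome_lengths()
    chroms <- unique(markers$chrom)
    len <- std$length_cM[match(chroms, std$chrom)]
    mx <- vapply(chroms, function(ch) {
      max(markers$pos_cM[markers$chrom == ch])
    }, numeric(1))
    len[is.na(len)] <- mx[is.na(len)]
    len <- pmax(len, mx)
    chromosomes <- data.frame(chrom = chroms, length_cM = len,
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "length_cM") %in% names(chromosomes)))
  chromosomes <- data.frame(chrom = as.character(chromosomes$chrom),
                            length_cM = as.numeric(chromosomes$length_cM),
                            stringsAsFactors = FALSE)
  if (anyDuplicated(chromosomes$chrom)) {
    stop("genome_map: duplicated chromosome names")
  }
  miss <- setdiff(markers$chrom, chromosomes$chrom)
  if (length(miss)) {
    stop("genome_map: markers on unknown chromosome(s): ",
         paste(miss, collapse = ", "))
  }
  lim <- chromosomes$length_cM[match(markers$chrom, chromosomes$chrom)]
  if (any(markers$pos_cM > lim)) {
    bad <- markers$marker[markers$pos_cM > lim][1L]
    stop("genome_map: marker beyond chromosome end: ", bad)
  }
  markers <- markers[order(markers$chrom, markers$pos_cM), , drop = FALSE]
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d marker(s) on %d chromosome(s), %.0f cM total\n",
              nrow(x$markers), nrow(x$chromosomes),
              sum(x$chromosomes$length_cM)))
  invisible(x)
}

#' Approximate genetic lengths of the mouse autosomes
#'
#' Autosomal chromosome lengths (cM) of the laboratory mouse linkage map,
#' rounded to whole centimorgans; the total is about 1490 cM.  Used as the
#' default chromosome sizes for simulated crosses.
#'
#' @return Data frame with columns `chrom`, `length_cM` (autosomes 1-19).
#' @export
mouse_chromosome_lengths <- function() {
  data.frame(
    chrom = as.character(1:19),
    length_cM = c(112, 114, 95, 89, 92, 79, 89, 76, 75, 77,
                  88, 64, 74, 71, 74, 59, 58, 44, 57),
    stringsAsFactors = FALSE
  )
}

#' Read a marker map from a three-column CSV
#'
#' @param path CSV file with columns `marker`, `chrom`, `cM` (or `pos_cM`).
#' @param chromosomes optional chromosome table, see [genome_map()].
#' @return A [genome_map()].
#' @export
read_marker_map <- function(path, chromosomes = NULL) {
  if (!file.exists(path)) stop("marker map file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("cM" %in% names(x) && !"pos_cM" %in% names(x)) {
    names(x)[names(x) == "cM"] <- "pos_cM"
  }
  genome_map(x[, c("marker", "chrom", "pos_cM")], chromosomes = chromosomes)
}

#' Read a region set from CSV
#'
#' @param path CSV file with columns `chrom`, `start`, `end` (cM).
#' @param merge union overlapping rows, see [region_set()].
#' @return A [region_set()].
#' @export
read_region_set <- function(path, merge = TRUE) {
  if (!file.exists(path)) stop("region file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_set(x$chrom, x$start, x$end, merge = merge)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; when
#'   missing, the available files are listed.
#' @return Full path to the file.
#' @export
qtlcoloc_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "qtlcoloc")))
  }
  path <- system.file("extdata", file, package = "qtlcoloc")
  if (!nzchar(path)) stop("no packaged file called ", file)
  path
}
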