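#' Convert the published mapping spreadsheet to the tidy F2 layout
#'
#' The cross's mapping spreadsheet (one row per mouse: sex, 23 marker
#' genotypes, tumor number, size and load) is distributed as an Excel file.
#' After a one-time export to CSV, this reader renames columns and recodes
#' genotypes into the layout used throughout this package (see
#' [read_f2_csv()]).  Genotype codes are mapped case-insensitively via
#' `genotype_codes`; any value not in the map becomes `NA`.
#'
#' This input is optional: every analysis in the package runs on simulated
#' or packaged data without it.
#'
#' @param path CSV export of the spreadsheet.
#' @param columns named character vector mapping tidy names (`id`, `sex`,
#'   `tumor_number`, `tumor_size_mm3`, `tumor_load_mm3`) to the spreadsheet's
#'   column names; unmapped names are assumed to match already.
#' @param genotype_codes named character vector mapping spreadsheet genotype
#'   codes to `cc`/`cs`/`ss`.
#' @param sex_codes named character vector mapping spreadsheet sex codes to
#'   `F`/`M`.
#' @return An `f2_dataset` data frame.
#' @export
read_dataset_s1 <- function(path,
                            columns = character(),
                            genotype_codes = c(cc = "cc", cs = "cs",
                                               sc = "cs", ss = "ss",
                                               bb = "cc", bs = "cs",
                                               sb = "cs"),
                            sex_codes = c(f = "F", female = "F", "1" = "F",
                                          m = "M", male = "M", "2" = "M")) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (tidy in names(columns)) {
    if (columns[[tidy]] %in% names(x)) {
      names(x)[names(x) == columns[[tidy]]] <- tidy
    }
  }
  need <- c("sex", "tumor_number", "tumor_size_mm3", "tumor_load_mm3")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("converted spreadsheet is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"id" %in% names(x)) x$id <- sprintf("mouse_%04d", seq_len(nrow(x)))
  sx <- tolower(as.character(x$sex))
  x$sex <- unname(sex_codes[sx])
  marker_cols <- setdiff(names(x),
                         c("id", "sex", "tumor_number", "tumor_size_mm3",
                           "tumor_load_mm3"))
  names(genotype_codes) <- tolower(names(genotype_codes))
  for (m in marker_cols) {
    v <- tolower(trimws(as.character(x[[m]])))
    x[[m]] <- unname(genotype_codes[v])
  }
  x$tumor_number <- as.numeric(x$tumor_number)
  x$tumor_size_mm3 <- as.numeric(x$tumor_size_mm3)
  x$tumor_load_mm3 <- as.numeric(x$tumor_load_mm3)
  x <- x[, c("id", "sex", marker_cols, "tumor_number", "tumor_size_mm3",
             "tumor_load_mm3")]
  class(x) <- c("f2_dataset", "data.frame")
  x
}

#' Whole-cross phenotype summary
#'
#' Means and standard errors of tumor number, size and load, overall and by
#' sex, plus the total tumor count -- the descriptive statistics customarily
#' reported for a mapped cross.
#'
#' @param data an `f2_dataset`.
#' @return List with `n`, `total_tumors` and a data frame `means`
#'   (rows all/F/M; columns mean and SEM per phenotype).
#' @export
cross_summary <- function(data) {
  phen <- c("tumor_number", "tumor_size_mm3", "tumor_load_mm3")
  groups <- list(all = rep(TRUE, nrow(data)),
                 F = data$sex == "F", M = data$sex == "M")
  rows <- lapply(names(groups), function(g) {
    d <- data[groups[[g]], phen, drop = FALSE]
    stats_ <- unlist(lapply(phen, function(p) {
      v <- d[[p]][!is.na(d[[p]])]
      c(mean(v), stats::sd(v) / sqrt(length(v)))
    }))
    names(stats_) <- as.vector(t(outer(phen, c("mean", "sem"), paste,
                                       sep = "_")))
    data.frame(group = g, t(stats_), stringsAsFactors = FALSE)
  })
  list(n = nrow(data),
       total_tumors = sum(data$tumor_number, na.rm = TRUE),
       means = do.call(rbind, rows))
}
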