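#' Planted QTL and epistasis specifications
#'
#' `qtl_spec()` describes an additive/dominance effect of a single marker on a
#' tumor phenotype; effects are fractions of the phenotype mean, applied
#' multiplicatively (log link), so a `+0.30` additive effect raises the mean by
#' 30% per donor (s) allele and the s/s vs c/c contrast is
#' `1.3^2 - 1 = +69%`.
#'
#' `interaction_spec()` describes a marker-by-marker interaction as a 3x3
#' matrix of fractional deviations indexed by (genotype of `marker_a`,
#' genotype of `marker_b`) in the order c/c, c/s, s/s.  The scalar shortcut
#' `effect` builds a marginal-free epistatic pattern
#' `(1 + effect)^(x_a * x_b)` with allele dosages coded -1, 0, +1, whose row
#' and column means are zero on the log scale under 1:2:1 segregation.
#'
#' @param marker,marker_a,marker_b marker names (must exist in the map).
#' @param additive,dominance fractional effects (additive per donor allele;
#'   dominance applied to heterozygotes).
#' @param trait one of `"number"`, `"size"`, `"load"`.
#' @param effect scalar fraction for the marginal-free pattern; ignored when
#'   `matrix` is supplied.
#' @param matrix 3x3 numeric matrix of fractional deviations.
#' @return A `qtl_spec` / `interaction_spec` object (a list).
#' @export
qtl_spec <- function(marker, additive = 0, dominance = 0, trait = "number") {
  trait <- match.arg(trait, c("number", "size", "load"))
  stopifnot(is.finite(additive), is.finite(dominance), additive > -1,
            dominance > -1)
  structure(list(marker = marker, additive = additive, dominance = dominance,
                 trait = trait),
            class = "qtl_spec")
}

#' @rdname qtl_spec
#' @export
interaction_spec <- function(marker_a, marker_b, effect = 0, matrix = NULL,
                             trait = "number") {
  trait <- match.arg(trait, c("number", "size", "load"))
  if (marker_a == marker_b) stop("interaction_spec: markers must differ")
  if (is.null(matrix)) {
    x <- c(-1, 0, 1)
    matrix <- outer(x, x, function(a, b) (1 + effect)^(a * b) - 1)
  }
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)),
            all(is.finite(matrix)), all(matrix > -1))
  dimnames(matrix) <- list(c("cc", "cs", "ss"), c("cc", "cs", "ss"))
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 effects = matrix, trait = trait),
            class = "interaction_spec")
}

.geno_levels <- c("cc", "cs", "ss")

# seed-scoped RNG: run expr under set.seed(seed), restoring the global state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate F2 intercross genotypes
#'
#' Simulates marker genotypes for an F2 intercross between two recombinant
#' congenic strains.  Only the donor-strain segments that differ between the
#' two parents segregate; every marker must lie inside one of these
#' `segregating` regions.  Each individual is formed from two independent
#' gametes.  Along a chromosome, a gamete's allele at the first marker is
#' drawn at random and recombination between adjacent markers `d` cM apart
#' occurs with the Haldane (no-interference) probability
#' `r = (1 - exp(-2 d / 100)) / 2`; different chromosomes assort
#' independently.  Sex is assigned 1:1.
#'
#' @param map a [genome_map()].
#' @param segregating optional [region_set()] of donor segments; when given,
#'   a marker outside every segment is a configuration error.
#' @param n number of F2 individuals.
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @param missing_rate fraction of genotype calls replaced by `NA`
#'   (default 0), to exercise missing-data handling downstream.
#' @param return_gametes if `TRUE` the two gamete allele matrices (0 = c,
#'   1 = s) are attached as attribute `"gametes"`, which makes recombination
#'   fractions directly observable.
#' @return Data frame with columns `id`, `sex` (`"F"`/`"M"`) and one column
#'   per marker with genotype codes `cc`, `cs`, `ss`; attribute `"map"` holds
#'   the map used.
#' @export
simulate_f2 <- function(map, segregating = NULL, n, seed = NULL,
                        missing_rate = 0, return_gametes = FALSE) {
  stopifnot(inherits(map, "genome_map"), n >= 1)
  mk <- map$markers
  if (!is.null(segregating)) {
    stopifnot(inherits(segregating, "region_set"))
    for (i in seq_len(nrow(mk))) {
      if (is.null(locate_locus(mk$chrom[i], mk$pos_cM[i], segregating))) {
        stop("marker outside segregating regions: ", mk$marker[i])
      }
    }
  }
  .with_seed(seed, {
    gam <- function() {
      g <- matrix(0L, nrow = n, ncol = nrow(mk))
      for (ch in unique(mk$chrom)) {
        idx <- which(mk$chrom == ch)
        a <- matrix(0L, nrow = n, ncol = length(idx))
        a[, 1] <- stats::rbinom(n, 1L, 0.5)
        if (length(idx) > 1) {
          for (j in 2:length(idx)) {
            d <- mk$pos_cM[idx[j]] - mk$pos_cM[idx[j - 1]]
            r <- (1 - exp(-2 * d / 100)) / 2
            flip <- stats::rbinom(n, 1L, r)
            a[, j] <- (a[, j - 1] + flip) %% 2L
          }
        }
        g[, idx] <- a
      }
      g
    }
    g1 <- gam()
    g2 <- gam()
    geno <- matrix(.geno_levels[g1 + g2 + 1L], nrow = n)
    colnames(geno) <- mk$marker
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(geno)) < missing_rate, nrow = n)
      geno[drop] <- NA_character_
    }
    sex <- sample(rep_len(c("F", "M"), n))
    out <- data.frame(id = sprintf("F2_%04d", seq_len(n)), sex = sex,
                      geno, stringsAsFactors = FALSE, check.names = FALSE)
    attr(out, "map") <- map
    if (return_gametes) attr(out, "gametes") <- list(g1 = g1, g2 = g2)
    out
  })
}

# multiplicative genotype effect on the log scale for one trait
.effect_log_mult <- function(geno, qtls, interactions, trait) {
  n <- nrow(geno)
  eta <- numeric(n)
  for (q in qtls) {
    if (q$trait != trait) next
    g <- geno[[q$marker]]
    if (is.null(g)) stop("qtl_spec marker not in genotypes: ", q$marker)
    dose <- match(g, .geno_levels) - 1L
    het <- as.numeric(g == "cs")
    dose[is.na(dose)] <- 1  # missing genotype: population-average dosage
    het[is.na(het)] <- 0
    eta <- eta + dose * log1p(q$additive) + het * log1p(q$dominance)
  }
  for (sp in interactions) {
    if (sp$trait != trait) next
    ga <- match(geno[[sp$marker_a]], .geno_levels)
    gb <- match(geno[[sp$marker_b]], .geno_levels)
    ok <- !is.na(ga) & !is.na(gb)
    add <- numeric(n)
    add[ok] <- log1p(sp$effects[cbind(ga[ok], gb[ok])])
    eta <- eta + add
  }
  eta
}

#' Simulate tumor phenotypes on F2 genotypes
#'
#' Adds per-mouse tumor phenotypes to a simulated genotype table.  Tumor
#' counts are negative-binomial with
#' `log(mean) = log(baseline number) + genotype, interaction and sex terms`;
#' per-tumor volumes are lognormal with mean equal to the (effect-adjusted)
#' baseline per-tumor size; tumor load is the exact sum of the per-tumor
#' volumes and tumor size is `load / max(number, 1)`.  Effects declared for
#' trait `"number"` act on the count mean; effects for `"size"` or `"load"`
#' act on the per-tumor volume mean (with number unchanged, a pure load
#' effect is a volume effect).
#'
#' The sex effect is symmetric on the log scale: females get multiplier
#' `(1 + sex_effect)^(1/2)` and males `(1 + sex_effect)^(-1/2)`, so
#' `1 + sex_effect` is the female/male mean ratio and the whole-cross mean
#' stays at the baseline.
#'
#' Defaults reproduce the regime of the mapped cross: whole-cross means of
#' 4.48 tumors and 2.15 mm^3 per-tumor size and a female/male count ratio of
#' 4.78/4.18.  The default dispersion `theta = 5` is the residual
#' (genetics-free) dispersion: the cross's printed phenotypic SD
#' (`0.24 * sqrt(226) = 3.6`, variance 13) includes the variance of the
#' segregating QTLs and interactions, so a generator that adds planted
#' architecture on top of the noise must use a smaller residual dispersion;
#' with `theta = 5` a representative planted architecture brings the total
#' variance close to the printed value.
#'
#' @param geno genotype table from [simulate_f2()].
#' @param qtls list of [qtl_spec()] objects.
#' @param interactions list of [interaction_spec()] objects.
#' @param sex_effect fractional female/male ratio minus one (default 0.144).
#' @param baseline length-2 numeric: mean tumor number and mean per-tumor
#'   size (mm^3) of the whole cross.
#' @param dispersion negative-binomial size parameter `theta` (> 0); counts
#'   have variance `mu + mu^2 / theta`.
#' @param sdlog lognormal log-scale SD of per-tumor volumes.
#' @param seed integer seed.
#' @return Data frame (class `f2_dataset`): the genotype columns plus
#'   `tumor_number`, `tumor_size_mm3`, `tumor_load_mm3`; the per-tumor
#'   volumes are attached as list attribute `"tumor_sizes"`.
#' @export
simulate_phenotypes <- function(geno, qtls = list(), interactions = list(),
                                sex_effect = 0.144,
                                baseline = c(number = 4.48, size = 2.15),
                                dispersion = 5, sdlog = 1, seed = NULL) {
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  if (inherits(interactions, "interaction_spec")) {
    interactions <- list(interactions)
  }
  baseline <- as.numeric(baseline)
  if (length(baseline) != 2 || any(baseline <= 0)) {
    stop("baseline must be two positive numbers (mean number, mean size)")
  }
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("dispersion must be a positive number")
  }
  if (sex_effect <= -1) stop("sex_effect must exceed -1")
  n <- nrow(geno)
  sexmult <- ifelse(geno$sex == "F", sqrt(1 + sex_effect),
                    1 / sqrt(1 + sex_effect))
  .with_seed(seed, {
    eta_n <- .effect_log_mult(geno, qtls, interactions, "number")
    eta_s <- .effect_log_mult(geno, qtls, interactions, "size") +
      .effect_log_mult(geno, qtls, interactions, "load")
    mu_n <- baseline[1] * exp(eta_n) * sexmult
    count <- stats::rnbinom(n, size = dispersion, mu = mu_n)
    mu_s <- baseline[2] * exp(eta_s)
    meanlog <- log(mu_s) - sdlog^2 / 2
    sizes <- lapply(seq_len(n), function(i) {
      if (count[i] == 0) return(numeric(0))
      stats::rlnorm(count[i], meanlog = meanlog[i], sdlog = sdlog)
    })
    load <- vapply(sizes, sum, numeric(1))
    out <- geno
    out$tumor_number <- count
    out$tumor_load_mm3 <- load
    out$tumor_size_mm3 <- load / pmax(count, 1)
    attr(out, "tumor_sizes") <- sizes
    attr(out, "map") <- attr(geno, "map")
    class(out) <- c("f2_dataset", "data.frame")
    out
  })
}

#' Simulate a full F2 cross in one call
#'
#' Convenience wrapper chaining [simulate_f2()] and [simulate_phenotypes()].
#'
#' @inheritParams simulate_f2
#' @inheritParams simulate_phenotypes
#' @param ... passed to [simulate_phenotypes()].
#' @return An `f2_dataset`, see [simulate_phenotypes()].
#' @export
simulate_cross <- function(map, segregating = NULL, n = 226, seed = NULL,
                           qtls = list(), interactions = list(), ...) {
  geno <- simulate_f2(map, segregating, n,
                      seed = if (is.null(seed)) NULL else seed)
  simulate_phenotypes(geno, qtls = qtls, interactions = interactions,
                      seed = if (is.null(seed)) NULL else seed + 1L, ...)
}

#' Write / read the tidy genotype-phenotype CSV
#'
#' One row per mouse: `id`, `sex`, one column per marker (`cc`/`cs`/`ss`),
#' `tumor_number`, `tumor_size_mm3`, `tumor_load_mm3`.
#'
#' @param x an `f2_dataset` (or compatible data frame).
#' @param path CSV file path.
#' @return `read_f2_csv` returns the data frame; `write_f2_csv` returns
#'   `path` invisibly.
#' @export
write_f2_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_f2_csv
#' @export
read_f2_csv <- function(path) {
  if (!file.exists(path)) stop("F2 dataset not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "sex", "tumor_number", "tumor_size_mm3", "tumor_load_mm3")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("F2 dataset is missing column(s): ", paste(miss, collapse = ", "))
  }
  class(x) <- c("f2_dataset", "data.frame")
  x
}

#' Scatter loci over tested regions under a homogeneous Poisson model
#'
#' Places loci over a region set as a homogeneous Poisson process with rate
#' `m` loci per cM: each interval of length `s` receives `Poisson(m * s)`
#' loci at positions uniform within the interval.  This is the independence
#' null of the concordance test and the uniform null of the proximity test.
#'
#' @param tested a [region_set()].
#' @param m rate, loci per cM (`>= 0`).
#' @param seed integer seed.
#' @param n_fixed if supplied, exactly `n_fixed` loci are placed uniformly
#'   over the tested length instead of drawing Poisson counts (the
#'   conditional/binomial version, used for permutation nulls).
#' @param trait,species labels written into the records.
#' @return Data frame of locus records (`symbol`, `species`, `trait`,
#'   `chrom`, `pos_cM`, `source`); zero rows when nothing is placed.
#' @export
simulate_locus_placement <- function(tested, m = NULL, seed = NULL,
                                     n_fixed = NULL, trait = "colon",
                                     species = "mouse") {
  stopifnot(inherits(tested, "region_set"))
  if (is.null(n_fixed)) {
    if (is.null(m) || m < 0) stop("rate m must be non-negative")
  }
  .with_seed(seed, {
    len <- tested$end - tested$start
    if (is.null(n_fixed)) {
      k <- stats::rpois(nrow(tested), m * len)
    } else {
      if (!nrow(tested) || sum(len) == 0) stop("empty tested region set")
      k <- as.vector(stats::rmultinom(1, n_fixed, prob = len))
    }
    idx <- rep(seq_len(nrow(tested)), k)
    if (!length(idx)) {
      return(data.frame(symbol = character(), species = character(),
                        trait = character(), chrom = character(),
                        pos_cM = numeric(), source = character(),
                        stringsAsFactors = FALSE))
    }
    pos <- tested$start[idx] + stats::runif(length(idx)) * len[idx]
    data.frame(
      symbol = sprintf("sim%03d", seq_along(idx)),
      species = species, trait = trait,
      chrom = tested$chrom[idx], pos_cM = pos,
      source = "simulated", stringsAsFactors = FALSE
    )
  })
}
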