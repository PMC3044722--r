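#' Genome-wide multiple-testing correction (Lander-Kruglyak)
#'
#' Converts a nominal (pointwise) p-value from a marker test into a
#' genome-wide adjusted p-value using the Ornstein-Uhlenbeck excursion
#' approximation for a genome scan: the expected number of chance
#' exceedances of the observed statistic is
#' `mu = (C + 2 * rho * G * X) * p`, where `X` is the chi-square statistic
#' corresponding to `p` on `df` degrees of freedom, `C` is the number of
#' chromosome segments scanned, `G` the scanned genetic length in Morgans
#' and `rho` the rate of the process (1.5 for an F2 intercross).  The
#' adjusted p-value is `min(1, mu)`; with `C = 1, G = 0` it reduces to the
#' nominal p (single test).
#'
#' With a whole-genome intercross geometry (`C = 20`, `G = 14`,
#' `rho = 1.5`) the formula reproduces the classical genome-wide 0.05
#' threshold of LOD ~ 4.3.
#'
#' @param p nominal p-value(s) in `[0, 1]`.
#' @param C number of scanned segments (>= 1).
#' @param G_morgans scanned genetic length, Morgans.
#' @param rho process rate per Morgan (1.5 for an intercross).
#' @param df degrees of freedom of the marker test (2 for a 3-genotype
#'   main effect).
#' @return Genome-wide adjusted p-value(s), monotone in `p` and never below
#'   the nominal value.
#' @export
genomewide_correct <- function(p, C = 21, G_morgans = 3.29, rho = 1.5,
                               df = 2) {
  stopifnot(all(p >= 0, na.rm = TRUE), all(p <= 1, na.rm = TRUE),
            C >= 1, G_morgans >= 0, rho >= 0)
  X <- stats::qchisq(p, df = df, lower.tail = FALSE)
  mu <- (C + 2 * rho * G_morgans * X) * p
  mu[!is.na(p) & p == 0] <- 0
  pmin(1, mu)
}

#' Scan geometry for the genome-wide correction
#'
#' The default is the sparse-map limit appropriate for a scan that tests
#' markers only: `C = NULL` means "the number of polymorphic markers
#' scanned" (filled in by [qtl_scan()]) and `G_morgans = 0`, so the
#' correction is Bonferroni over the marker tests, which a permutation null
#' closely matches.  For a dense/interval scan set `C` to the number of
#' chromosome segments and `G_morgans` to the scanned length (e.g.
#' `gw_params(C = 21, G_morgans = 0.235 * 14)` for 21 donor segments
#' covering 23.5% of a 14-Morgan genome).
#'
#' @param C number of discrete tests (segments or markers); `NULL` to use
#'   the number of markers in the scan.
#' @param G_morgans continuously scanned length, Morgans (0 for
#'   marker-only scans).
#' @param rho process rate per Morgan.
#' @return List with elements `C`, `G_morgans`, `rho`.
#' @export
gw_params <- function(C = NULL, G_morgans = 0, rho = 1.5) {
  stopifnot(is.null(C) || C >= 1, G_morgans >= 0, rho >= 0)
  list(C = C, G_morgans = G_morgans, rho = rho)
}

.trait_cols <- c(number = "tumor_number", size = "tumor_size_mm3",
                 load = "tumor_load_mm3")

.transform_y <- function(y, transform) {
  switch(transform,
         log1p = log1p(y),
         log = log(y),
         sqrt = sqrt(y),
         identity = y,
         stop("unknown transform: ", transform))
}

.back_transform <- function(y, transform) {
  switch(transform, log1p = expm1(y), log = exp(y), sqrt = y^2,
         identity = y)
}

# per-trait analysis scale: variance-stabilizing sqrt for counts, log1p for
# the right-skewed volume phenotypes
.resolve_transform <- function(transform, trait) {
  if (transform != "auto") return(transform)
  if (trait == "number") "sqrt" else "log1p"
}

# genotype column detection: character columns whose values are cc/cs/ss
.detect_markers <- function(data) {
  cand <- setdiff(names(data),
                  c("id", "sex", .trait_cols))
  keep <- vapply(cand, function(nm) {
    v <- data[[nm]]
    is.character(v) && all(v %in% c(.geno_levels, NA))
  }, logical(1))
  cand[keep]
}

#' Single-marker ANOVA
#'
#' Fits a linear model of a (transformed) tumor phenotype on one marker's
#' genotype, coded as an unordered factor, plus optional covariates, and
#' tests the marker by a partial F-test.  Least-squares (model-adjusted)
#' genotype means are returned on the analysis scale and back-transformed
#' to the response scale.
#'
#' @param data an `f2_dataset` (or any data frame with the marker, trait and
#'   covariate columns).
#' @param marker marker column name.
#' @param trait `"number"`, `"size"` or `"load"`, or a raw column name.
#' @param covariates character vector of covariate column names
#'   (default `"sex"`; ignored when absent or constant).
#' @param transform analysis scale: `"auto"` (the default: `"sqrt"` for
#'   tumor number, `"log1p"` for size and load), `"sqrt"`, `"log1p"`,
#'   `"log"` or `"identity"`.
#' @return List with elements `marker`, `F`, `p.value`, `df`, `ls_means`
#'   (data frame: genotype, lsmean, response), `n`, `monomorphic`.
#' @export
single_marker_anova <- function(data, marker, trait = "number",
                                covariates = "sex", transform = "auto") {
  transform <- .resolve_transform(transform, trait)
  ycol <- if (trait %in% names(.trait_cols)) .trait_cols[[trait]] else trait
  stopifnot(ycol %in% names(data), marker %in% names(data))
  covariates <- intersect(covariates, names(data))
  covariates <- covariates[vapply(covariates, function(cv) {
    length(unique(stats::na.omit(data[[cv]]))) > 1
  }, logical(1))]
  keep <- stats::complete.cases(data[, c(ycol, marker, covariates),
                                     drop = FALSE])
  d <- data[keep, , drop = FALSE]
  g <- factor(d[[marker]], levels = intersect(.geno_levels, d[[marker]]))
  if (nlevels(g) < 2) {
    warning("monomorphic marker: ", marker)
    return(list(marker = marker, F = NA_real_, p.value = NA_real_,
                df = c(0, nrow(d) - 1), ls_means = NULL, n = nrow(d),
                monomorphic = TRUE))
  }
  y <- .transform_y(d[[ycol]], transform)
  if (stats::var(y) == 0) {
    lsm <- data.frame(genotype = levels(g), lsmean = y[1],
                      response = .back_transform(y[1], transform))
    return(list(marker = marker, F = 0, p.value = 1,
                df = c(nlevels(g) - 1, nrow(d) - nlevels(g)),
                ls_means = lsm, n = nrow(d), monomorphic = FALSE))
  }
  df_fit <- data.frame(.y = y, .g = g, stringsAsFactors = FALSE)
  for (cv in covariates) df_fit[[cv]] <- factor(d[[cv]])
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ")
          else "1"
  fit0 <- stats::lm(stats::reformulate(rhs0, ".y"), data = df_fit)
  fit1 <- stats::lm(stats::reformulate(c(covariates, ".g"), ".y"),
                    data = df_fit)
  an <- stats::anova(fit0, fit1)
  Fval <- an$F[2]
  pval <- an$`Pr(>F)`[2]
  em <- summary(emmeans::emmeans(fit1, ".g"))
  lsm <- data.frame(genotype = as.character(em$.g), lsmean = em$emmean,
                    response = .back_transform(em$emmean, transform),
                    stringsAsFactors = FALSE)
  list(marker = marker, F = Fval, p.value = pval,
       df = c(an$Df[2], an$Res.Df[2]), ls_means = lsm, n = nrow(d),
       monomorphic = FALSE)
}

#' Direction of the allelic effect from least-squares means
#'
#' Classifies a locus as susceptible or resistant from the percent
#' difference of the alternative genotype's least-squares mean relative to
#' the reference genotype: susceptible when the difference exceeds
#' `+threshold` percent, resistant when below `-threshold` (strict
#' inequalities), otherwise none.
#'
#' @param means named numeric vector of (response-scale) least-squares means,
#'   names are genotype codes.
#' @param reference reference genotype (the resistant-parent-like genotype;
#'   default `"cc"`).
#' @param alt alternative genotype compared against the reference
#'   (default `"ss"`).
#' @param threshold percent difference required for a call (default 30).
#' @return List with `label` (`"susceptible"`, `"resistant"` or `"none"`)
#'   and `percent` (the percent difference).
#' @export
allele_direction <- function(means, reference = "cc", alt = "ss",
                             threshold = 30) {
  if (!(reference %in% names(means)) || !(alt %in% names(means))) {
    return(list(label = "none", percent = NA_real_))
  }
  ref <- means[[reference]]
  alt_mean <- means[[alt]]
  if (!is.finite(ref) || !is.finite(alt_mean) || ref == 0) {
    if (is.finite(alt_mean) && identical(ref, 0)) {
      warning("reference mean is zero; direction undefined")
    }
    return(list(label = "none", percent = NA_real_))
  }
  pct <- (alt_mean - ref) / ref * 100
  label <- if (pct > threshold) "susceptible"
    else if (pct < -threshold) "resistant" else "none"
  list(label = label, percent = pct)
}

# ---- internal fast linear-model engine on column blocks -------------------

# returns list(rss, rank) for response y and design X
.fit_rss <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  list(rss = sum(f$residuals^2), rank = f$rank)
}

.partial_F <- function(rss_red, rank_red, rss_full, rank_full, n) {
  q <- rank_full - rank_red
  df2 <- n - rank_full
  if (q <= 0 || df2 <= 0 || rss_full <= 0) return(c(F = NA, p = NA, q = q))
  Fv <- ((rss_red - rss_full) / q) / (rss_full / df2)
  c(F = Fv, p = stats::pf(Fv, q, df2, lower.tail = FALSE), q = q)
}

#' Multi-marker ANOVA scan with epistasis search and backward elimination
#'
#' The mapping engine for an F2 recombinant-congenic cross.  The starting
#' model contains all marker main effects (3-level genotype factors) plus
#' sex; marker-by-marker and marker-by-sex interactions are pre-screened one
#' pair at a time against this base model and kept as candidates at
#' `p < screen_alpha` (fitting all pairs jointly is singular at realistic
#' sample sizes).  The joint model then undergoes backward elimination:
#' the term with the largest partial-F p-value above `alpha` is dropped,
#' respecting marginality (a main effect is never dropped while it
#' participates in a retained interaction), until every remaining term is
#' significant.
#'
#' All partial F-tests (screening, elimination, and the reported term
#' statistics) use the error variance of the fixed base model, which no
#' selection step touches; the selected model's own residual would
#' understate the error after screening hundreds of candidates and deflate
#' every p-value.  Retained marker-involving terms receive genome-wide
#' adjusted p-values via [genomewide_correct()] over the scan's whole test
#' family (marker tests plus screened interaction tests); the sex main
#' effect is a fixed covariate, not a genome-scan term, and keeps its
#' nominal p.  Least-squares means per genotype (or genotype combination,
#' or genotype-by-sex) and allele direction calls are computed for the
#' retained terms.
#'
#' Tumor counts are analyzed on the square-root scale, sizes and loads on
#' the `log(x + 1)` scale by default (see `transform`).
#'
#' @param data an `f2_dataset` (see [simulate_phenotypes()] /
#'   [read_f2_csv()]).
#' @param trait `"number"`, `"size"` or `"load"`.
#' @param markers marker column names; auto-detected when `NULL`.
#' @param alpha retention level for backward elimination (default 0.05).
#' @param transform analysis scale, see [single_marker_anova()].
#' @param interactions search marker-by-marker interactions (default TRUE).
#' @param sex_interactions search marker-by-sex interactions (default TRUE).
#' @param screen_alpha screening level for candidate interactions.
#' @param correction scan geometry from [gw_params()].
#' @param ls_means which retained terms get least-squares means and
#'   direction calls: `"significant"` (genome-wide p < 0.05, the default),
#'   `"all"`, or `"none"` (`TRUE`/`FALSE` are accepted aliases for
#'   `"all"`/`"none"`).
#' @param profile compute the per-marker single-marker profile (turn off in
#'   large simulation loops).
#' @return Object of class `qtl_scan`; see [print.qtl_scan()].  Main fields:
#'   `terms` (data frame of retained terms with F, nominal and genome-wide
#'   p), `ls_means`, `direction`, `profile` (per-marker single-marker F/p),
#'   `dropped`, `model` (the final `lm`).
#' @export
qtl_scan <- function(data, trait = "number", markers = NULL, alpha = 0.05,
                     transform = "auto", interactions = TRUE,
                     sex_interactions = TRUE, screen_alpha = 0.05,
                     correction = gw_params(), ls_means = "significant",
                     profile = TRUE) {
  if (isTRUE(ls_means)) ls_means <- "all"
  if (isFALSE(ls_means)) ls_means <- "none"
  ls_means <- match.arg(ls_means, c("significant", "all", "none"))
  transform <- .resolve_transform(transform, trait)
  ycol <- if (trait %in% names(.trait_cols)) .trait_cols[[trait]] else trait
  stopifnot(ycol %in% names(data))
  if (is.null(markers)) markers <- .detect_markers(data)
  if (length(markers) < 1) stop("no marker columns found")
  keep <- stats::complete.cases(data[, c(ycol, "sex", markers),
                                     drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  y <- .transform_y(d[[ycol]], transform)

  # genotype factors; drop monomorphic markers
  fac <- list()
  mono <- character()
  for (m in markers) {
    g <- factor(d[[m]], levels = intersect(.geno_levels, unique(d[[m]])))
    if (nlevels(g) < 2) mono <- c(mono, m) else fac[[m]] <- g
  }
  if (length(mono)) {
    warning("monomorphic marker(s) excluded from scan: ",
            paste(mono, collapse = ", "))
  }
  markers <- names(fac)
  if (length(markers) < 1) stop("all markers monomorphic")
  has_sex <- "sex" %in% names(d) && length(unique(d$sex)) > 1
  sexf <- if (has_sex) factor(d$sex) else NULL
  if (is.null(correction$C)) correction$C <- length(markers)

  # dummy column blocks, sum-to-zero coded: interaction columns are then
  # near-orthogonal to main-effect columns at 1:2:1 segregation, so the
  # partial F of a main effect alongside its interaction is the marginal
  # (Type III) main-effect test
  blk <- lapply(fac, function(g) {
    X <- stats::model.matrix(~g, contrasts.arg =
                               list(g = "contr.sum"))[, -1, drop = FALSE]
    colnames(X) <- paste0("g", seq_len(ncol(X)))
    X
  })
  sex_blk <- if (has_sex) {
    stats::model.matrix(~sexf, contrasts.arg =
                          list(sexf = "contr.sum"))[, -1, drop = FALSE]
  }
  int_block <- function(a, b) {
    A <- blk[[a]]; B <- blk[[b]]
    out <- matrix(0, n, ncol(A) * ncol(B))
    k <- 0
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      k <- k + 1
      out[, k] <- A[, i] * B[, j]
    }
    out
  }
  sexint_block <- function(a) blk[[a]] * as.vector(sex_blk)

  terms <- list()  # name -> list(kind, cols (matrix), label)
  add_term <- function(name, kind, cols) {
    terms[[name]] <<- list(kind = kind, cols = cols)
  }
  for (m in markers) add_term(m, "marker", blk[[m]])
  if (has_sex) add_term("sex", "sex", sex_blk)

  base_names <- names(terms)
  Xof <- function(nms) {
    cbind(`(Intercept)` = rep(1, n),
          do.call(cbind, unname(lapply(terms[nms], `[[`, "cols"))))
  }
  base_fit <- .fit_rss(Xof(base_names), y)
  # selection-free error variance: residual MSE of the fixed base model
  df_err <- n - base_fit$rank
  sigma2 <- if (df_err > 0) base_fit$rss / df_err else 0
  .pF <- function(rss_red, rank_red, rss_full, rank_full) {
    q <- rank_full - rank_red
    if (q <= 0 || df_err <= 0) return(c(F = NA, p = NA, q = q))
    if (sigma2 <= 0) return(c(F = 0, p = 1, q = q))
    Fv <- ((rss_red - rss_full) / q) / sigma2
    c(F = Fv, p = stats::pf(Fv, q, df_err, lower.tail = FALSE), q = q)
  }

  # -- interaction screening, one pair at a time against the base model
  n_screened <- 0
  if (interactions && length(markers) >= 2) {
    prs <- utils::combn(markers, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      n_screened <- n_screened + 1
      cols <- int_block(a, b)
      f <- .fit_rss(cbind(Xof(base_names), cols), y)
      pf <- .pF(base_fit$rss, base_fit$rank, f$rss, f$rank)
      if (!is.na(pf["p"]) && pf["p"] < screen_alpha) {
        add_term(paste0(a, ":", b), "marker:marker", cols)
      }
    }
  }
  if (sex_interactions && has_sex) {
    for (m in markers) {
      n_screened <- n_screened + 1
      cols <- sexint_block(m)
      f <- .fit_rss(cbind(Xof(base_names), cols), y)
      pf <- .pF(base_fit$rss, base_fit$rank, f$rss, f$rank)
      if (!is.na(pf["p"]) && pf["p"] < screen_alpha) {
        add_term(paste0(m, ":sex"), "marker:sex", cols)
      }
    }
  }

  # -- drop aliased interaction candidates (singular joint design)
  repeat {
    full <- .fit_rss(Xof(names(terms)), y)
    Xfull <- Xof(names(terms))
    if (full$rank == ncol(Xfull)) break
    ints <- names(terms)[vapply(terms, function(t)
      t$kind %in% c("marker:marker", "marker:sex"), logical(1))]
    if (!length(ints)) break
    dropped_one <- FALSE
    for (nm in rev(ints)) {
      f <- .fit_rss(Xof(setdiff(names(terms), nm)), y)
      if (f$rank == full$rank) {  # term adds no rank: aliased
        warning("dropping aliased term: ", nm)
        terms[[nm]] <- NULL
        dropped_one <- TRUE
        break
      }
    }
    if (!dropped_one) break
  }

  # -- backward elimination (largest p > alpha first; marginality respected)
  droppable <- function() {
    nms <- names(terms)
    kinds <- vapply(terms, `[[`, character(1), "kind")
    in_int <- unique(unlist(strsplit(nms[kinds %in%
                                           c("marker:marker", "marker:sex")],
                                     ":", fixed = TRUE)))
    ok <- vapply(seq_along(nms), function(i) {
      if (kinds[i] %in% c("marker:marker", "marker:sex")) return(TRUE)
      !(nms[i] %in% in_int)
    }, logical(1))
    nms[ok]
  }
  dropped_log <- data.frame(term = character(), p = numeric(),
                            stringsAsFactors = FALSE)
  repeat {
    full <- .fit_rss(Xof(names(terms)), y)
    cand <- droppable()
    if (!length(cand)) break
    ps <- vapply(cand, function(nm) {
      f <- .fit_rss(Xof(setdiff(names(terms), nm)), y)
      .pF(f$rss, f$rank, full$rss, full$rank)["p"]
    }, numeric(1))
    over <- which(!is.na(ps) & ps > alpha)
    if (!length(over)) break
    # tie-break: largest p; then interactions before mains; then by name
    sel <- cand[over]
    pv <- ps[over]
    kinds <- vapply(terms[sel], `[[`, character(1), "kind")
    is_int <- kinds %in% c("marker:marker", "marker:sex")
    ord <- order(-pv, !is_int, sel)
    victim <- sel[ord[1]]
    dropped_log <- rbind(dropped_log,
                         data.frame(term = victim, p = pv[ord[1]],
                                    stringsAsFactors = FALSE))
    terms[[victim]] <- NULL
    if (!length(terms)) break
  }

  # -- final term statistics
  full <- .fit_rss(Xof(names(terms)), y)
  tstats <- lapply(names(terms), function(nm) {
    f <- .fit_rss(Xof(setdiff(names(terms), nm)), y)
    pf <- .pF(f$rss, f$rank, full$rss, full$rank)
    kind <- terms[[nm]]$kind
    p_nom <- unname(pf["p"])
    p_gw <- if (kind == "sex") {
      p_nom
    } else {
      # one family for every genome-scan test: marker main-effect tests
      # plus all screened interaction tests
      genomewide_correct(p_nom, C = correction$C + n_screened,
                         G_morgans = correction$G_morgans,
                         rho = correction$rho, df = unname(pf["q"]))
    }
    data.frame(term = nm, kind = kind, df = unname(pf["q"]),
               F = unname(pf["F"]), p_nominal = p_nom, p_genomewide = p_gw,
               stringsAsFactors = FALSE)
  })
  term_tab <- if (length(tstats)) do.call(rbind, tstats) else
    data.frame(term = character(), kind = character(), df = numeric(),
               F = numeric(), p_nominal = numeric(),
               p_genomewide = numeric(), stringsAsFactors = FALSE)
  rownames(term_tab) <- NULL

  # -- per-marker single-marker profile (for plotting / reporting)
  profile_tab <- NULL
  if (profile) {
    prof <- lapply(markers, function(m) {
      sm <- single_marker_anova(d, m, trait = trait, transform = transform)
      data.frame(marker = m, F = sm$F, p_nominal = sm$p.value,
                 p_genomewide = genomewide_correct(
                   sm$p.value, C = correction$C,
                   G_morgans = correction$G_morgans, rho = correction$rho,
                   df = sm$df[1]),
                 stringsAsFactors = FALSE)
    })
    profile_tab <- do.call(rbind, prof)
  }

  # -- least-squares means and direction calls for retained terms
  lsm <- list()
  dir_rows <- list()
  model <- NULL
  if (length(terms)) {
    fdat <- data.frame(.y = y)
    for (m in markers) fdat[[m]] <- fac[[m]]
    if (has_sex) fdat$sex <- sexf
    rhs <- vapply(names(terms), function(nm) gsub(":", ":", nm),
                  character(1))
    model <- stats::lm(stats::reformulate(rhs, ".y"), data = fdat)
    ls_sel <- switch(ls_means,
                     none = character(),
                     all = names(terms),
                     significant = term_tab$term[!is.na(term_tab$p_genomewide) &
                                                   term_tab$p_genomewide < 0.05])
    if (length(ls_sel)) {
      kinds_all <- vapply(terms, `[[`, character(1), "kind")
      interacting <- unique(unlist(strsplit(
        names(terms)[kinds_all %in% c("marker:marker", "marker:sex")],
        ":", fixed = TRUE)))
      model_factors <- c(markers, if (has_sex) "sex")
      aliased <- any(is.na(stats::coef(model)))
      for (nm in ls_sel) {
        kind <- terms[[nm]]$kind
        involved <- if (kind == "sex") "sex"
                    else strsplit(nm, ":", fixed = TRUE)[[1]]
        # factors independent of the term and of every retained interaction
        # are averaged analytically as nuisance factors (keeps the reference
        # grid tractable with many retained markers)
        nuis <- setdiff(intersect(model_factors, names(terms)),
                        union(involved, interacting))
        spec <- if (kind == "marker:sex") involved[1] else involved
        by <- if (kind == "marker:sex") "sex" else NULL
        emm_call <- function(weights) {
          args <- list(model, spec, by = by, rg.limit = 1e6,
                       weights = weights)
          if (length(nuis)) args$nuisance <- nuis
          summary(do.call(emmeans::emmeans, args))
        }
        # equal-weight LS means; with empty genotype cells (tightly linked
        # interacting markers, aliased coefficients) those are non-estimable
        # and observed-margin weights are used instead
        em <- if (!aliased) {
          tryCatch(suppressMessages(emm_call("equal")),
                   error = function(e) NULL)
        }
        if (is.null(em) || any(!is.finite(em$emmean))) {
          em2 <- tryCatch(suppressMessages(emm_call("cells")),
                          error = function(e) NULL)
          if (!is.null(em2) && all(is.finite(em2$emmean))) em <- em2
        }
        if (is.null(em)) next
        em <- as.data.frame(em)
        em$response <- .back_transform(em$emmean, transform)
        lsm[[nm]] <- em
        if (kind == "marker") {
          means <- stats::setNames(em$response, em[[nm]])
          dc <- allele_direction(means)
          dir_rows[[nm]] <- data.frame(term = nm, label = dc$label,
                                       percent = dc$percent,
                                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  direction <- if (length(dir_rows)) do.call(rbind, dir_rows) else
    data.frame(term = character(), label = character(), percent = numeric(),
               stringsAsFactors = FALSE)
  rownames(direction) <- NULL

  structure(list(trait = trait, transform = transform, n = n,
                 markers = markers, monomorphic = mono,
                 terms = term_tab, ls_means = lsm, direction = direction,
                 profile = profile_tab, dropped = dropped_log, model = model,
                 alpha = alpha, screen_alpha = screen_alpha,
                 n_screened = n_screened, correction = correction),
            class = "qtl_scan")
}

#' @describeIn qtl_scan Compact display of the retained model.
#' @param x,object a `qtl_scan` object.
#' @param ... ignored.
#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("QTL scan: trait '%s' (%s scale), n = %d, %d marker(s)\n",
              x$trait, x$transform, x$n, length(x$markers)))
  cat(sprintf("Screened %d interaction pair(s); retained %d term(s) at alpha = %g\n",
              x$n_screened, nrow(x$terms), x$alpha))
  if (nrow(x$terms)) {
    tab <- x$terms
    tab$F <- round(tab$F, 2)
    tab$p_nominal <- signif(tab$p_nominal, 3)
    tab$p_genomewide <- signif(tab$p_genomewide, 3)
    print(tab)
  } else {
    cat("(no terms retained)\n")
  }
  invisible(x)
}

#' @describeIn qtl_scan Full summary including least-squares means and
#'   direction calls.
#' @export
summary.qtl_scan <- function(object, ...) {
  print(object)
  if (nrow(object$direction)) {
    cat("\nAllele direction (s/s vs c/c, response scale):\n")
    print(object$direction)
  }
  if (length(object$ls_means)) {
    cat("\nLeast-squares means:\n")
    for (nm in names(object$ls_means)) {
      cat(" ", nm, "\n")
      print(object$ls_means[[nm]], row.names = FALSE)
    }
  }
  invisible(object)
}

#' @describeIn qtl_scan Coefficients of the final linear model.
#' @export
coef.qtl_scan <- function(object, ...) {
  if (is.null(object$model)) return(numeric(0))
  stats::coef(object$model)
}

#' @describeIn qtl_scan Marker profile plot: -log10 nominal p per marker,
#'   retained main effects highlighted.
#' @export
plot.qtl_scan <- function(x, ...) {
  pr <- x$profile
  if (is.null(pr)) stop("scan was run with profile = FALSE")
  lp <- -log10(pmax(pr$p_nominal, 1e-16))
  bp <- graphics::barplot(lp, names.arg = pr$marker, las = 2,
                          ylab = expression(-log[10] ~ p),
                          main = sprintf("Single-marker profile (%s)",
                                         x$trait),
                          col = ifelse(pr$marker %in%
                                         x$terms$term[x$terms$kind ==
                                                        "marker"],
                                       "firebrick", "grey70"), ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(bp)
}

#' Permutation null for the genome-wide maximum marker statistic
#'
#' Shuffles the phenotype across individuals, recomputes the single-marker
#' F statistic at every marker, and records the maximum.  The empirical
#' upper tail of these maxima is the reference ("gold standard") genome-wide
#' null against which [genomewide_correct()] can be checked: the genome-wide
#' p of an observed F is the fraction of permutation maxima at least as
#' large.
#'
#' @inheritParams qtl_scan
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return Numeric vector of `nperm` maximum F statistics, with attribute
#'   `"df"` (the common test df) when all markers share it.
#' @export
qtl_permutation_null <- function(data, trait = "number", markers = NULL,
                                 transform = "log1p", nperm = 1000,
                                 seed = NULL) {
  ycol <- if (trait %in% names(.trait_cols)) .trait_cols[[trait]] else trait
  if (is.null(markers)) markers <- .detect_markers(data)
  keep <- stats::complete.cases(data[, c(ycol, markers), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  y <- .transform_y(d[[ycol]], transform)
  Xs <- lapply(markers, function(m) {
    g <- factor(d[[m]], levels = intersect(.geno_levels, unique(d[[m]])))
    stats::model.matrix(~g)
  })
  ranks <- vapply(Xs, ncol, integer(1))
  .with_seed(seed, {
    vapply(seq_len(nperm), function(r) {
      yp <- sample(y)
      tss <- sum((yp - mean(yp))^2)
      max(vapply(seq_along(Xs), function(k) {
        f <- stats::.lm.fit(Xs[[k]], yp)
        rss <- sum(f$residuals^2)
        q <- f$rank - 1
        ((tss - rss) / q) / (rss / (n - f$rank))
      }, numeric(1)))
    }, numeric(1))
  })
}
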