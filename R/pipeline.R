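#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order -- `simulate`, `scan`, `coloc`,
#' `proximity`, `clusters` -- and writes a versioned report bundle (CSV and
#' JSON, no timestamps, so identical configurations and seeds give
#' byte-identical outputs).  The configuration is a YAML file or an
#' equivalent named list:
#'
#' ```yaml
#' seed: 1
#' output_dir: out
#' coloc:
#'   region_table: table1_regions.csv   # path or packaged file name
#'   count_a: 14        # detected colon loci
#'   count_b: 30        # detected lung loci
#'   tested_length_cM: 630
#'   df: 3
#'   nsim: 10000
#' proximity:
#'   query: fig6_loci_synthetic.csv
#'   anchors: sluc_anchors_synthetic.csv
#'   tested: ocb_tested_synthetic.csv
#'   w: 7
#' clusters:
#'   loci: [fig6_loci_synthetic.csv, sluc_anchors_synthetic.csv]
#'   threshold: 10
#' simulate:
#'   map: marker_map_synthetic.csv
#'   regions: segregating_regions_synthetic.csv
#'   n: 226
#' scan:
#'   trait: number
#' ```
#'
#' File references are resolved against the configuration file's directory,
#' the working directory, and the packaged `extdata` files, in that order.
#'
#' @param config path to a YAML file, or a named list.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a named list of stage results; reports are written to
#'   the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- output_dir %||% config$output_dir %||% "qtlcoloc-out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resolve <- function(f) {
    for (p in c(file.path(cfg_dir, f), f)) if (file.exists(p)) return(p)
    pk <- system.file("extdata", f, package = "qtlcoloc")
    if (nzchar(pk)) return(pk)
    stop("input file not found: ", f)
  }
  results <- list(seed = seed)

  sim_data <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    map <- read_marker_map(resolve(sc$map))
    regions <- if (!is.null(sc$regions)) read_region_set(resolve(sc$regions))
    qtls <- lapply(sc$qtls, function(q) {
      do.call(qtl_spec, q)
    })
    ints <- lapply(sc$interactions, function(q) do.call(interaction_spec, q))
    sim_data <- simulate_cross(map, regions, n = sc$n %||% 226, seed = seed,
                               qtls = qtls, interactions = ints)
    write_f2_csv(sim_data, file.path(out_dir, "simulated_cross.csv"))
    results$simulate <- cross_summary(sim_data)
    message("simulate: wrote ", file.path(out_dir, "simulated_cross.csv"))
  }

  if (!is.null(config$scan)) {
    sc <- config$scan
    data <- if (!is.null(sc$data)) read_f2_csv(resolve(sc$data)) else
      sim_data
    if (is.null(data)) stop("scan stage: no data (configure simulate or scan$data)")
    scan <- qtl_scan(data, trait = sc$trait %||% "number",
                     alpha = sc$alpha %||% 0.05,
                     transform = sc$transform %||% "log1p")
    utils::write.csv(scan$terms, file.path(out_dir, "scan_terms.csv"),
                     row.names = FALSE)
    dump <- list(trait = scan$trait, n = scan$n,
                 alpha = scan$alpha, transform = scan$transform,
                 seed = seed, terms = scan$terms,
                 direction = scan$direction, profile = scan$profile)
    jsonlite::write_json(dump, file.path(out_dir, "scan_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$scan <- scan
    message("scan: retained ", nrow(scan$terms), " term(s)")
  }

  if (!is.null(config$coloc)) {
    cc <- config$coloc
    rt <- read_region_table(resolve(cc$region_table))
    overlap <- overlap_regions(rt)
    obs <- classify_overlaps(overlap,
                             rt$loci[rt$loci$trait == "colon", ],
                             rt$loci[rt$loci$trait == "lung", ])
    L <- cc$tested_length_cM %||% (0.45 * 1400)
    ct <- concordance_test(obs,
                           poisson_rate(cc$count_a %||% 14, L),
                           poisson_rate(cc$count_b %||% 30, L),
                           sizes = overlap$end - overlap$start,
                           df = cc$df %||% 3, nsim = cc$nsim %||% 10000,
                           seed = seed)
    report <- list(seed = seed,
                   n_overlap_regions = nrow(overlap),
                   overlap_total_cM = region_total_length(overlap),
                   observed = as.list(ct$observed),
                   expected = as.list(ct$expected),
                   statistic = ct$statistic, df = ct$df,
                   p_analytic = ct$p.value, p_mc = ct$p.mc,
                   rates = list(
                     a = list(count = ct$rates$a$count,
                              tested_length_cM = ct$rates$a$tested_length_cM,
                              m = ct$rates$a$m),
                     b = list(count = ct$rates$b$count,
                              tested_length_cM = ct$rates$b$tested_length_cM,
                              m = ct$rates$b$m)))
    jsonlite::write_json(report, file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(overlap, pattern = attr(obs, "pattern")),
                     file.path(out_dir, "overlap_regions.csv"),
                     row.names = FALSE)
    results$coloc <- ct
    print(ct)
  }

  if (!is.null(config$proximity)) {
    pc <- config$proximity
    query <- read_locus_table(resolve(pc$query))
    if (!is.null(pc$species)) query <- query[query$species %in% pc$species, ]
    if (!is.null(pc$trait)) query <- query[query$trait %in% pc$trait, ]
    if ("informative" %in% names(query)) {
      query <- query[tolower(query$informative) %in% c("yes", "true"), ]
    }
    anchors <- read_locus_table(resolve(pc$anchors))
    tested <- read_region_set(resolve(pc$tested))
    pt <- binomial_proximity_test(query, anchors, tested,
                                  w = pc$w %||% 3.3,
                                  nperm = pc$nperm %||% 10000, seed = seed)
    report <- list(seed = seed, n_total = pt$n_total, n_hit = pt$n_hit,
                   w = pt$w, p0 = pt$p0,
                   mean_hit_distance_cM = pt$mean_hit_distance,
                   p_binomial = pt$p.value, p_permutation = pt$p.perm)
    jsonlite::write_json(report, file.path(out_dir, "proximity.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$proximity <- pt
    print(pt)
  }

  if (!is.null(config$clusters)) {
    kc <- config$clusters
    files <- unlist(kc$loci)
    loci <- do.call(rbind, lapply(files, function(f) {
      x <- read_locus_table(resolve(f))
      x[, c("symbol", "species", "trait", "chrom", "pos_cM")]
    }))
    cl <- assemble_clusters(loci, threshold = kc$threshold %||% 10,
                            flag_within = kc$flag_within %||% 2.5)
    utils::write.csv(cl, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    results$clusters <- cl
    message(sprintf("clusters: %d cluster(s), %d with a lung/colon pair within %.1f cM",
                    nrow(cl), sum(cl$mixed_trait & cl$tight_pair),
                    kc$flag_within %||% 2.5))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
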