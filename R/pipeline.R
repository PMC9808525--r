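#' A small self-contained demonstration run configuration
#'
#' Two tissues x one population x two timepoints, 60 engrafted clones, one
#' planted liver-biased clone, shallow sequencing. Completes in seconds;
#' meant for examples and smoke tests, not for power.
#'
#' @param out_dir output directory for [run_pipeline()].
#' @param seed integer seed for the whole run.
#' @return A run-config list.
#' @export
demo_run_config <- function(out_dir = tempfile("ct_run_"), seed = 1) {
  tissues <- c("PB", "liver")
  tps <- c(12, 14)
  grid <- expand.grid(tissue = tissues, timepoint = tps,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  sheet <- sample_sheet(
    sample_id = sprintf("%s_T_%dm", grid$tissue, grid$timepoint),
    animal = "SIM01",
    tissue = grid$tissue,
    population = "T",
    timepoint_months = grid$timepoint,
    index_seq = generate_indices(n, len = 8, min_dist = 3, seed = seed),
    genomes_sampled = 400)
  list(seed = seed,
       out_dir = out_dir,
       library = list(D = 2000, L = 35),
       transduction = list(k = 150),
       dynamics = dynamics_config(
         n_clones = 60, alpha = 0.5, temporal_sigma = 0.2,
         tissue_bias = data.frame(baseline_rank = c(8, 12),
                                  tissue = "liver", fold = 10)),
       sheet = sheet,
       protocol = sequencing_protocol(genomes_sampled = 400,
                                      pcr_sigma = 0.3,
                                      reads_per_sample = 4000,
                                      error_rate = 0.001),
       design = barcode_design(),
       policy = threshold_policy(),
       tracking = list(top_n = 10, bias_threshold = 5, bias_compare = "max"),
       multivariate = list(linkage = "complete"))
}

#' Run the full pipeline: simulate, extract, normalize, track, compare
#'
#' Executes every stage in order, writing all intermediate artifacts under
#' `config$out_dir` and a manifest JSON with the seed, parameter echo and
#' md5 checksums of every output. Reruns with the same seed and config are
#' byte-identical for all tabular outputs.
#'
#' @param config a run-config list as produced by [demo_run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sheet <- if (is.character(config$sheet)) {
    load_sample_sheet(config$sheet)
  } else {
    validate_sample_sheet(as.data.frame(config$sheet))
  }
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(
    list(seed = seed,
         library = config$library,
         transduction = config$transduction,
         dynamics = unclass(config$dynamics),
         protocol = unclass(config$protocol),
         design = unclass(config$design),
         policy = unclass(config$policy),
         tracking = config$tracking,
         multivariate = config$multivariate),
    cfg_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  prov <- prov_lines(cfg_hash)
  paths <- list(config = cfg_path)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_ct("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # -- simulate ------------------------------------------------------------
  truth <- stage("simulate", {
    lib <- generate_library(config$library$D, config$library$L,
                            seed = seed + 1L)
    assign <- simulate_transduction(lib, config$transduction$k,
                                    seed = seed + 2L)
    simulate_clonal_dynamics(assign, config$dynamics, sheet,
                             seed = seed + 3L)
  })
  paths$truth_tsv <- file.path(out, "truth_fractions.tsv")
  paths$truth_json <- file.path(out, "truth.json")
  write_truth(truth, paths$truth_tsv, paths$truth_json)

  # -- sequence ------------------------------------------------------------
  sim <- stage("sequence", {
    simulate_sequencing(truth, sheet, config$protocol, config$design,
                        fastq = file.path(out, "reads.fastq"),
                        seed = seed + 4L)
  })
  paths$fastq <- sim$fastq
  paths$sheet <- file.path(out, "sample_sheet.tsv")
  write_sample_sheet(sheet, paths$sheet, provenance = prov)

  # -- extract -------------------------------------------------------------
  counts <- stage("extract", {
    call_barcodes(paths$fastq, config$design, sheet, config$policy)
  })
  paths$counts <- file.path(out, "counts.tsv")
  write_counts_matrix(counts, paths$counts, provenance = prov)
  paths$stats <- file.path(out, "extraction_stats.json")
  jsonlite::write_json(unclass(attr(counts, "extraction_stats")),
                       paths$stats, auto_unbox = TRUE, digits = NA)

  # -- normalize -----------------------------------------------------------
  frac <- stage("normalize", to_fractional_abundance(counts))
  cpm <- to_cpm(counts)
  logf <- log_fractional_abundance(frac)
  paths$fraction <- file.path(out, "fraction.tsv")
  paths$cpm <- file.path(out, "cpm.tsv")
  paths$log_fraction <- file.path(out, "log_fraction.tsv")
  write_abundance(frac, paths$fraction, provenance = prov)
  write_abundance(cpm, paths$cpm, provenance = prov)
  write_abundance(logf, paths$log_fraction, provenance = prov)

  # -- track ---------------------------------------------------------------
  trk <- config$tracking
  track_out <- stage("track", {
    avg <- timepoint_average(frac, sheet)
    tc <- top_clones(frac, trk$top_n)
    biased <- detect_biased_clones(avg, threshold = trk$bias_threshold,
                                   compare = trk$bias_compare,
                                   counts = counts, top_n = trk$top_n)
    aggs <- lapply(colnames(avg), function(l) {
      parts <- strsplit(l, ":", fixed = TRUE)[[1L]]
      a <- aggregate_top_contribution(frac, sheet, parts[1], parts[2],
                                      n = trk$top_n)
      data.frame(index_location = l, a$contributions,
                 stringsAsFactors = FALSE)
    })
    list(avg = avg, tc = tc, biased = biased, agg = do.call(rbind, aggs))
  })
  paths$biased <- file.path(out, "biased_clones.tsv")
  write_tsv_prov(track_out$biased, paths$biased, prov)
  star_df <- data.frame(barcode = rownames(track_out$tc$star),
                        ifelse(track_out$tc$star, "*", ""),
                        check.names = FALSE, stringsAsFactors = FALSE)
  paths$top_clones <- file.path(out, "top_clone_membership.tsv")
  write_tsv_prov(star_df, paths$top_clones, prov)
  paths$aggregate <- file.path(out, "aggregate_contributions.tsv")
  write_tsv_prov(track_out$agg, paths$aggregate, prov)

  # -- compare -------------------------------------------------------------
  cmp <- stage("compare", {
    un <- track_out$tc$union
    heat <- unclass(logf)[un, , drop = FALSE]
    cl <- if (length(un) >= 2) {
      cluster_rows(heat, linkage = config$multivariate$linkage)
    }
    pca <- if (ncol(frac) >= 3 && nrow(frac) > 2) {
      pca_project(cpm, n_components = 2)
    }
    corr <- pearson_pairwise(frac)
    list(cl = cl, pca = pca, corr = corr, heat = heat)
  })
  if (!is.null(cmp$cl)) {
    paths$dendrogram <- file.path(out, "dendrogram.newick")
    write_dendrogram_newick(cmp$cl, paths$dendrogram)
    ordered <- cmp$heat[cmp$cl$order, , drop = FALSE]
    bias_of <- vapply(rownames(ordered), function(b) {
      paste(track_out$biased$location[track_out$biased$barcode == b],
            collapse = ",")
    }, character(1))
    star <- track_out$tc$star[rownames(ordered), , drop = FALSE]
    heat_df <- data.frame(barcode = rownames(ordered),
                          biased_location = bias_of,
                          ordered,
                          stats::setNames(
                            as.data.frame(ifelse(star, "*", "")),
                            paste0("star_", colnames(star))),
                          check.names = FALSE, stringsAsFactors = FALSE)
    paths$heatmap <- file.path(out, "heatmap_table.tsv")
    write_tsv_prov(heat_df, paths$heatmap, prov)
  }
  if (!is.null(cmp$pca)) {
    pca_df <- data.frame(sample_id = rownames(cmp$pca$coords),
                         cmp$pca$coords, check.names = FALSE,
                         stringsAsFactors = FALSE)
    paths$pca <- file.path(out, "pca_coords.tsv")
    write_tsv_prov(pca_df, paths$pca, prov)
  }
  corr_df <- data.frame(sample_id = rownames(cmp$corr), cmp$corr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  paths$correlation <- file.path(out, "correlation.tsv")
  write_tsv_prov(corr_df, paths$correlation, prov)

  # -- manifest ------------------------------------------------------------
  files <- unlist(paths)
  manifest <- list(tool = "clonaltracker",
                   version = pkg_version(),
                   seed = seed,
                   config_hash = cfg_hash,
                   outputs = lapply(stats::setNames(files, names(paths)),
                                    function(f)
                                      list(path = basename(f),
                                           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
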