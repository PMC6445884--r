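#' Read a flat key = value pipeline configuration file
#'
#' TOML-style flat file: one `key = value` per line, `#` comments, optional
#' quotes around strings. Values that parse as numbers become numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop_validation("malformed config line: '%s'", lines[bad][1])
  vals <- lapply(kv, function(m) {
    v <- gsub('^["\']|["\']$', "", trimws(m[3]))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[`, character(1), 2))
}

default_config <- function() {
  list(cutoff = 60, n_bins = 20, kmin = 3, kmax = 10,
       n_disease = 100, n_network = 1000, seed = 1,
       namespace = "BP", exclude_evidence = "IEA")
}

log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full prion-like characterization pipeline
#'
#' Orchestrates detect -> localize -> enrich -> express -> disease -> network
#' over a configuration naming the input files, writing one artifact per stage
#' plus a consolidated JSON report. The master seed is split into fixed
#' per-stage seeds, so each stage is individually reproducible. Any stage
#' failure aborts with the failing stage named; artifacts already written are
#' retained.
#'
#' @param config Named list or path to a flat key = value file. Required keys:
#'   `fasta`, `annotations`, `expression`, `disease`, `edges`, `mapping`,
#'   `outdir`. Optional: `cutoff` (60), `n_bins` (20), `kmin` (3), `kmax`
#'   (10), `n_disease` (100), `n_network` (1000), `seed` (1), `namespace`
#'   ("BP"), `exclude_evidence` ("IEA").
#' @return List of class `pipeline_report` (also written as `report.json`).
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile(); simulate_bundle("full", seed = 1, n_proteins = 80,
#'                                    outdir = dir)
#' cfg <- list(fasta = file.path(dir, "proteome.fasta"),
#'             annotations = file.path(dir, "annotations.tsv"),
#'             expression = file.path(dir, "expression.tsv"),
#'             disease = file.path(dir, "disease.tsv"),
#'             edges = file.path(dir, "edges.tsv"),
#'             mapping = file.path(dir, "mapping.tsv"),
#'             outdir = file.path(dir, "out"), n_network = 100)
#' rep <- run_pipeline(cfg)
#' }
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_config(), config)
  need <- c("fasta", "annotations", "expression", "disease", "edges",
            "mapping", "outdir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop_validation("config misses keys: %s",
                                    paste(miss, collapse = ", "))
  for (k in setdiff(need, "outdir")) {
    if (!file.exists(cfg[[k]])) stop_validation("input '%s' not found: %s",
                                                k, cfg[[k]])
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(cfg$outdir, "pipeline.log"), open = "wt")
  on.exit(close(logfile))
  seed <- as.integer(cfg$seed)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # detect
  calls <- run_stage("detect", {
    mat <- amyloid_matrix(cutoff = cfg$cutoff)
    call_prionlike(cfg$fasta, matrix = mat)
  })
  write_calls(calls, file.path(cfg$outdir, "calls.tsv"))
  positives <- calls$protein_id[calls$positive]
  log_stage(logfile, "detect",
            sprintf("%d proteins scanned -> %d stage-1 candidates -> %d positives",
                    attr(calls, "n_scanned"), nrow(calls), length(positives)))
  if (length(positives) == 0) {
    stop("pipeline stage 'detect' produced no positive calls", call. = FALSE)
  }

  # localize
  loc <- run_stage("localize", localize_calls(calls))
  write_tsv(loc$per_call, file.path(cfg$outdir, "localization.tsv"))
  hist20 <- position_histogram(calls, n_bins = cfg$n_bins)
  write_tsv(data.frame(bin = seq_len(cfg$n_bins),
                       start_count = hist20$start_bins,
                       end_count = hist20$end_bins),
            file.path(cfg$outdir, "position_histogram.tsv"))
  log_stage(logfile, "localize",
            sprintf("N %d / internal %d / C %d, C:N ratio %.2f (p = %.3g)",
                    loc$tallies["N"], loc$tallies["internal"],
                    loc$tallies["C"], loc$c_to_n_ratio, loc$p_value))

  # enrich
  mapping <- read_tsv(cfg$mapping)
  all_proteins <- names(as_sequences(cfg$fasta))
  enr <- run_stage("enrich", {
    ann <- filter_annotations(read_annotations(cfg$annotations),
                              excluded_evidence = cfg$exclude_evidence)
    term_enrichment(positives, all_proteins, ann, namespace = cfg$namespace)
  })
  write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
  n_sig <- sum(enr$adjusted_p < 0.05)
  log_stage(logfile, "enrich",
            sprintf("%d terms tested, %d significant after Bonferroni",
                    nrow(enr), n_sig))

  # express
  set_genes <- collapse_to_genes(positives, mapping)
  cl <- run_stage("express", {
    tab <- code_expression(cfg$expression)
    v <- deviation_vectors(set_genes, tab, tab)
    cluster_genes(v, k_min = cfg$kmin, k_max = cfg$kmax,
                  seed = derive_seed(seed, "express"))
  })
  write_tsv(data.frame(gene_id = names(cl$labels), cluster = unname(cl$labels)),
            file.path(cfg$outdir, "clusters.tsv"))
  write_tsv(data.frame(k = as.integer(names(cl$silhouette_by_k)),
                       mean_silhouette = unname(cl$silhouette_by_k)),
            file.path(cfg$outdir, "silhouette.tsv"))
  log_stage(logfile, "express",
            sprintf("%d genes clustered, chosen k = %d", length(cl$labels),
                    cl$chosen_k))

  # disease
  all_genes <- unique(mapping$gene_id)
  dis <- run_stage("disease", disease_association_test(
    set_genes, all_genes, cfg$disease,
    n_samples = cfg$n_disease, seed = derive_seed(seed, "disease")))
  log_stage(logfile, "disease",
            sprintf("observed fraction %.3f vs null %.3f +/- %.3f (above 95th: %s)",
                    dis$observed, dis$null_mean, dis$null_sd, dis$above_95th))

  # network
  net <- run_stage("network", {
    graph <- read_interactome(cfg$edges, nodes = all_genes)
    network_set_stats(graph, set_genes, n_samples = cfg$n_network,
                      seed = derive_seed(seed, "network"))
  })
  log_stage(logfile, "network",
            sprintf("LCC %d (Z = %.2f), MSD %.2f (Z = %.2f)",
                    net$lcc_size, net$lcc$z, net$msd_value, net$msd$z))

  report <- structure(
    list(n_scanned = attr(calls, "n_scanned"),
         n_candidates = nrow(calls),
         n_positive = length(positives),
         positives = positives,
         localization = list(tallies = as.list(loc$tallies),
                             terminal_fraction = loc$terminal_fraction,
                             c_to_n_ratio = loc$c_to_n_ratio,
                             z = loc$z, p_value = loc$p_value),
         top_terms = utils::head(enr[enr$direction == "enriched", "term_id"], 5),
         n_significant_terms = n_sig,
         chosen_k = cl$chosen_k,
         disease = list(observed = dis$observed, null_mean = dis$null_mean,
                        z = dis$z, empirical_p = dis$empirical_p,
                        above_95th = dis$above_95th,
                        fold_enrichment = dis$fold_enrichment),
         network = list(
           mean_degree = net$mean_degree, intra_edges = net$intra,
           lcc_size = net$lcc_size, msd = net$msd_value,
           z = list(degree = net$degree$z, intra_edges = net$intra_edges$z,
                    lcc = net$lcc$z, msd = net$msd$z)),
         seed = seed),
    class = "pipeline_report")
  jsonlite::write_json(unclass(report), file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    paste0("pipeline report: %d scanned -> %d candidates -> %d positives\n",
           " terminal split N/int/C = %d/%d/%d (C:N %.2f), chosen k = %d\n",
           " disease fraction %.3f (empirical p %.3g), network LCC %d (Z %.2f)\n"),
    x$n_scanned, x$n_candidates, x$n_positive,
    x$localization$tallies$N, x$localization$tallies$internal,
    x$localization$tallies$C, x$localization$c_to_n_ratio, x$chosen_k,
    x$disease$observed, x$disease$empirical_p,
    x$network$lcc_size, x$network$z$lcc))
  invisible(x)
}
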