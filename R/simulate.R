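#' Generate a synthetic proteome with planted prion-like domains
#'
#' Background proteins are i.i.d. draws from the reference background
#' composition ([background_frequencies()]). A `prion_fraction` of proteins
#' receives a planted contiguous prion-like segment of `core_length` residues
#' drawn from the Q/N-biased prion composition ([prion_frequencies()]), with
#' one embedded 21-mer soft amyloid core drawn from a high-propensity
#' composition and rejected until its [amyloid_core_score()] is at least five
#' points above the calling cutoff — so every planted protein is separable by
#' the default two-stage caller. The planted segment itself is redrawn until
#' its compositional window score clearly exceeds what background windows
#' attain.
#'
#' Planted domains are placed at the N-terminus, the C-terminus (centred
#' inside a terminal quarter when the protein is long enough) or mid-sequence,
#' controlled by `terminal_bias` and `c_vs_n`.
#'
#' @param n_proteins Number of proteins.
#' @param prion_fraction Fraction of proteins with a planted PrLD, in `[0,1]`.
#' @param length_range Integer 2-vector, protein length bounds; the lower
#'   bound must be at least 80 so a 60-residue domain plus flanks fits
#'   (default `c(140, 600)`, chosen so a terminal 60-mer holds the plurality
#'   of its quarter under the 25/50/25 classifier).
#' @param terminal_bias Proportion of planted domains placed at a terminus.
#' @param c_vs_n Probability that a terminal placement is C-terminal
#'   (default 0.625, the imbalance regime reported for human prion-like
#'   proteins).
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @param model,matrix Scoring parameters used to certify planted signals.
#' @return Object of class `synthetic_proteome`: list with `records`
#'   (data frame `protein_id`, `gene_id`, `sequence`) and `truth` (data frame
#'   `protein_id`, `gene_id`, `is_planted`, `domain_start`, `domain_end`,
#'   `placement`).
#' @export
#' @examples
#' p <- generate_proteome(20, prion_fraction = 0.2, seed = 1)
#' sum(p$truth$is_planted)
generate_proteome <- function(n_proteins, prion_fraction = 0.1,
                              length_range = c(140L, 600L),
                              terminal_bias = 0.8, c_vs_n = 0.625,
                              seed = 1L,
                              model = composition_model(),
                              matrix = amyloid_matrix()) {
  if (n_proteins < 1) stop_validation("`n_proteins` must be positive")
  check_proportion(prion_fraction, "prion_fraction")
  check_proportion(terminal_bias, "terminal_bias")
  check_proportion(c_vs_n, "c_vs_n")
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    stop_validation("`length_range` must be c(lower, upper) with lower <= upper")
  }
  if (length_range[1] < 80) {
    stop_validation("`length_range` lower bound must be >= 80 (domain + flanks)")
  }
  bg <- model$background_freqs
  pr <- model$prion_freqs
  core_f <- core_frequencies()
  L_core <- model$core_length
  llr <- log(pr / bg)

  draw_core <- function() {
    # rejection draw: planted 21-mer must clear the cutoff with margin
    for (i in seq_len(200)) {
      core <- sample(AMINO_ACIDS, 21, replace = TRUE, prob = core_f)
      sc <- amyloid_core_score(paste(core, collapse = ""), matrix)$score
      if (sc >= matrix$cutoff + 5) return(core)
    }
    # fallback: per-position argmax of the weight matrix (score 100)
    AMINO_ACIDS[apply(matrix$weights, 1, which.max)]
  }
  draw_segment <- function() {
    # prion-composition segment with the amyloid core embedded mid-segment;
    # redrawn until its compositional window sum is far above background noise
    for (i in seq_len(200)) {
      seg <- sample(AMINO_ACIDS, L_core, replace = TRUE, prob = pr)
      # keep a >= 9-residue prion-composition margin on both sides of the
      # core so small shifts of the best compositional window cannot clip it
      core_at <- sample(seq.int(10L, L_core - 29L), 1)
      seg[core_at:(core_at + 20L)] <- draw_core()
      if (sum(llr[seg]) >= 25) return(seg)
    }
    stop("could not draw a separable prion-like segment")  # nocov
  }

  with_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    n_planted <- round(n_proteins * prion_fraction)
    planted <- rep(FALSE, n_proteins)
    if (n_planted > 0) planted[sample.int(n_proteins, n_planted)] <- TRUE
    placement <- rep(NA_character_, n_proteins)
    dom_start <- rep(NA_integer_, n_proteins)
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      s <- sample(AMINO_ACIDS, lens[i], replace = TRUE, prob = bg)
      if (planted[i]) {
        where <- if (runif(1) < terminal_bias) {
          if (runif(1) < c_vs_n) "C" else "N"
        } else {
          "internal"
        }
        start <- switch(where,
                        N = 1L,
                        C = lens[i] - L_core + 1L,
                        internal = as.integer(floor(lens[i] / 2 - L_core / 2)) + 1L)
        s[start:(start + L_core - 1L)] <- draw_segment()
        placement[i] <- where
        dom_start[i] <- start
      }
      seqs[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("P%05d", seq_len(n_proteins))
    genes <- sprintf("G%05d", seq_len(n_proteins))
    structure(
      list(records = data.frame(protein_id = ids, gene_id = genes,
                                sequence = seqs, stringsAsFactors = FALSE),
           truth = data.frame(protein_id = ids, gene_id = genes,
                              is_planted = planted,
                              domain_start = dom_start,
                              domain_end = dom_start + L_core - 1L,
                              placement = placement,
                              stringsAsFactors = FALSE),
           params = list(n_proteins = n_proteins,
                         prion_fraction = prion_fraction,
                         length_range = length_range,
                         terminal_bias = terminal_bias, c_vs_n = c_vs_n,
                         seed = as.integer(seed))),
      class = "synthetic_proteome")
  })
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("synthetic proteome: %d proteins (%d with planted PrLD), seed %d\n",
              nrow(x$records), sum(x$truth$is_planted), x$params$seed))
  invisible(x)
}

#' Write a synthetic proteome as FASTA (plus a truth sidecar)
#'
#' Headers are `>protein_id|gene_id`; sequences wrapped at 62 columns. The
#' ground truth is written next to the FASTA as `<path>.truth.tsv`.
#'
#' @param proteome A `synthetic_proteome`.
#' @param path Output FASTA path.
#' @param truth Write the truth sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path, truth = TRUE) {
  ss <- Biostrings::AAStringSet(setNames(
    proteome$records$sequence,
    paste(proteome$records$protein_id, proteome$records$gene_id, sep = "|")))
  Biostrings::writeXStringSet(ss, path, width = 62L)
  if (truth) write_tsv(proteome$truth, paste0(path, ".truth.tsv"))
  invisible(path)
}

#' Generate a synthetic annotation table with planted term enrichments
#'
#' Each term gets a background membership probability; for terms named in
#' `enriched`, membership odds in the planted protein subset are the
#' background odds multiplied by the planted odds ratio. A configurable
#' fraction of rows carries the electronic evidence code `IEA` so the evidence
#' filter is exercised.
#'
#' @param proteome A `synthetic_proteome` (its truth defines the planted set).
#' @param n_terms Number of terms.
#' @param enriched Named numeric vector: term id -> planted odds ratio (> 0).
#'   Names must be among the generated term ids `T0001..`.
#' @param base_rate_range Range of per-term background membership
#'   probabilities (default `c(0.02, 0.2)`).
#' @param iea_fraction Fraction of rows assigned evidence `IEA`
#'   (default 0.3).
#' @param namespace Namespace label for all terms (default `"BP"`).
#' @param seed Integer seed.
#' @return An `annotation_table` with attribute `truth` (data frame `term_id`,
#'   `base_rate`, `odds_ratio`).
#' @export
generate_annotations <- function(proteome, n_terms = 50L, enriched = NULL,
                                 base_rate_range = c(0.02, 0.2),
                                 iea_fraction = 0.3, namespace = "BP",
                                 seed = 1L) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  if (!is.null(enriched)) {
    if (is.null(names(enriched)) || any(enriched <= 0)) {
      stop_validation("`enriched` must be a named vector of odds ratios > 0")
    }
  }
  check_proportion(iea_fraction, "iea_fraction")
  terms <- sprintf("T%04d", seq_len(n_terms))
  if (!is.null(enriched) && !all(names(enriched) %in% terms)) {
    stop_validation("enriched term ids must be among %s..%s",
                    terms[1], terms[n_terms])
  }
  ids <- proteome$records$protein_id
  planted <- proteome$truth$is_planted
  with_seed(seed, {
    base <- runif(n_terms, base_rate_range[1], base_rate_range[2])
    names(base) <- terms
    or <- setNames(rep(1, n_terms), terms)
    if (!is.null(enriched)) or[names(enriched)] <- enriched
    rows <- lapply(seq_len(n_terms), function(j) {
      p_bg <- base[j]
      odds <- p_bg / (1 - p_bg) * or[j]
      p_set <- odds / (1 + odds)
      p <- ifelse(planted, p_set, p_bg)
      member <- runif(length(ids)) < p
      if (!any(member)) return(NULL)
      data.frame(protein_id = ids[member], term_id = terms[j],
                 namespace = namespace, evidence = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(protein_id = character(), term_id = character(),
                        namespace = character(), evidence = character(),
                        stringsAsFactors = FALSE)
    }
    codes <- c("EXP", "IDA", "IMP", "TAS")
    is_iea <- runif(nrow(out)) < iea_fraction
    out$evidence <- ifelse(is_iea, "IEA",
                           sample(codes, nrow(out), replace = TRUE))
    out <- out[order(out$term_id, out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("annotation_table", "data.frame")
    attr(out, "truth") <- data.frame(term_id = terms, base_rate = unname(base),
                                     odds_ratio = unname(or),
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate an ordinal gene x tissue expression table with planted clusters
#'
#' Genes are partitioned into `k_true` groups; each group has its own latent
#' tissue-profile offset of per-tissue magnitude `effect` (random sign per
#' tissue) around a common baseline, plus Gaussian noise, then the latent
#' values are discretized to ranks 0-3 at fixed quartile cut-points of the
#' 0-3 latent scale (0.75, 1.5, 2.25).
#'
#' @param genes Character vector of gene ids.
#' @param tissues Character vector of tissue labels.
#' @param k_true Number of planted clusters (>= 1).
#' @param effect Latent per-tissue mean shift distinguishing clusters; 0 means
#'   no signal.
#' @param noise_sd Latent Gaussian noise (default 0.6).
#' @param seed Integer seed.
#' @return List of class `synthetic_expression`: `table` (coded matrix, genes
#'   x tissues, values 0-3) and `truth` (named integer vector of planted
#'   cluster labels).
#' @export
generate_expression <- function(genes, tissues, k_true = 4L, effect = 1.5,
                                noise_sd = 0.6, seed = 1L) {
  if (k_true < 1) stop_validation("`k_true` must be >= 1")
  if (length(genes) < k_true) {
    stop_validation("fewer genes (%d) than clusters (%d)", length(genes), k_true)
  }
  n <- length(genes)
  m <- length(tissues)
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(k_true), n))
    labels <- labels[sample.int(n)]           # random assignment, balanced sizes
    centers <- matrix(
      effect * sample(c(-1, 1), k_true * m, replace = TRUE),
      nrow = k_true)
    if (effect == 0) centers[] <- 0
    latent <- 1.5 + centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * m, sd = noise_sd), nrow = n)
    coded <- matrix(findInterval(latent, c(0.75, 1.5, 2.25)), nrow = n,
                    dimnames = list(genes, tissues))
    structure(list(table = coded, truth = setNames(labels, genes),
                   seed = as.integer(seed)),
              class = "synthetic_expression")
  })
}

#' Generate gene-disease association labels with a planted rate difference
#'
#' Background genes are disease-labelled independently with probability
#' `base_rate`; genes in `set_ids` with probability `set_rate`. Labelled genes
#' receive one synthetic disease id each.
#'
#' @param genes All gene ids (the background universe).
#' @param set_ids Subset of `genes` with the planted rate.
#' @param base_rate,set_rate Label probabilities in `[0, 1]`.
#' @param source Source label written to the table (default `"SYN"`).
#' @param seed Integer seed.
#' @return Data frame (`gene_id`, `disease_id`, `source`) with attribute
#'   `truth` = `list(base_rate, set_rate, set_ids)`.
#' @export
generate_disease_labels <- function(genes, set_ids = character(),
                                    base_rate = 0.024, set_rate = base_rate,
                                    source = "SYN", seed = 1L) {
  check_proportion(base_rate, "base_rate")
  check_proportion(set_rate, "set_rate")
  if (!all(set_ids %in% genes)) {
    stop_validation("`set_ids` must be a subset of `genes`")
  }
  with_seed(seed, {
    p <- ifelse(genes %in% set_ids, set_rate, base_rate)
    hit <- runif(length(genes)) < p
    out <- data.frame(gene_id = genes[hit],
                      disease_id = sprintf("D%05d", seq_len(sum(hit))),
                      source = rep_len(source, sum(hit)),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(base_rate = base_rate, set_rate = set_rate,
                               set_ids = set_ids)
    out
  })
}

#' Generate a synthetic interactome with a planted module
#'
#' Erdős–Rényi background: every node pair is an edge with probability
#' `p_background`, except pairs within `module`, connected with probability
#' `p_module` (>= `p_background`). The result is a simple undirected graph.
#'
#' @param n_nodes Number of nodes; ids `g00001..` unless `nodes` is given.
#' @param p_background Background edge probability.
#' @param module Character vector of module node ids (subset of nodes).
#' @param p_module Edge probability within the module.
#' @param nodes Optional explicit node ids (length `n_nodes`).
#' @param seed Integer seed.
#' @return List of class `synthetic_interactome`: `graph` (igraph), `nodes`,
#'   `module`.
#' @export
generate_interactome <- function(n_nodes, p_background, module = character(),
                                 p_module = p_background, nodes = NULL,
                                 seed = 1L) {
  check_proportion(p_background, "p_background")
  check_proportion(p_module, "p_module")
  if (p_module < p_background) {
    stop_validation("p_module must be >= p_background")
  }
  if (is.null(nodes)) nodes <- sprintf("g%05d", seq_len(n_nodes))
  if (length(nodes) != n_nodes) stop_validation("`nodes` must have length n_nodes")
  if (!all(module %in% nodes)) {
    stop_validation("`module` must be a subset of the graph nodes")
  }
  with_seed(seed, {
    g <- igraph::sample_gnp(n_nodes, p_background, directed = FALSE)
    igraph::V(g)$name <- nodes
    if (length(module) >= 2 && p_module > p_background) {
      # resample module-internal pairs at the elevated probability
      pairs <- utils::combn(module, 2)
      existing <- igraph::get_edge_ids(g, as.vector(pairs))
      g <- igraph::delete_edges(g, existing[existing > 0])
      keep <- runif(ncol(pairs)) < p_module
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      }
    }
    g <- igraph::simplify(g)
    structure(list(graph = g, nodes = nodes, module = module,
                   seed = as.integer(seed)),
              class = "synthetic_interactome")
  })
}

#' Generate a complete synthetic input bundle
#'
#' One call producing every pipeline input with consistent identifiers:
#' proteome with planted PrLDs, annotations with one planted enriched term,
#' expression with planted clusters, disease labels with a planted rate
#' difference for the planted genes, and an interactome in which the planted
#' genes form a module. The `"null"` preset keeps the planted PrLDs (so the
#' caller has work to do) but switches off every downstream effect.
#'
#' @param preset `"full"` (planted effects everywhere) or `"null"` (no
#'   downstream signal).
#' @param seed Master seed; per-generator seeds are derived deterministically.
#' @param n_proteins Proteome size (default 500).
#' @param outdir Optional directory: when given, all standard-format files and
#'   truth sidecars are written there.
#' @return List of class `synthetic_bundle` with elements `proteome`,
#'   `annotations`, `expression`, `disease`, `interactome`, `params`.
#' @export
#' @examples
#' b <- simulate_bundle("full", seed = 1, n_proteins = 60)
#' names(b)
simulate_bundle <- function(preset = c("full", "null"), seed = 1L,
                            n_proteins = 500L, outdir = NULL) {
  preset <- match.arg(preset)
  full <- preset == "full"
  prot <- generate_proteome(n_proteins, prion_fraction = 0.1,
                            seed = derive_seed(seed, "simulate"))
  genes <- prot$records$gene_id
  planted_genes <- prot$truth$gene_id[prot$truth$is_planted]
  ann <- generate_annotations(
    prot, n_terms = 50L,
    enriched = if (full) c(T0007 = 8) else NULL,
    seed = derive_seed(seed, "enrich"))
  expr <- generate_expression(genes, sprintf("tissue%02d", 1:30),
                              k_true = 4L, effect = if (full) 1.5 else 0,
                              seed = derive_seed(seed, "express"))
  dis <- generate_disease_labels(
    genes, set_ids = planted_genes, base_rate = 0.024,
    set_rate = if (full) 0.13 else 0.024,
    seed = derive_seed(seed, "disease"))
  net <- generate_interactome(
    length(genes), p_background = 0.01, module = planted_genes,
    p_module = if (full) 0.15 else 0.01, nodes = genes,
    seed = derive_seed(seed, "network"))
  bundle <- structure(
    list(proteome = prot, annotations = ann, expression = expr, disease = dis,
         interactome = net,
         params = list(preset = preset, seed = as.integer(seed),
                       n_proteins = n_proteins)),
    class = "synthetic_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write a synthetic bundle to standard-format files
#'
#' Emits `proteome.fasta` (+ truth sidecar), `annotations.tsv`,
#' `expression.tsv`, `disease.tsv`, `edges.tsv`, `mapping.tsv` and truth
#' sidecars under `outdir`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_proteome_fasta(bundle$proteome, p("proteome.fasta"))
  write_tsv(as.data.frame(bundle$annotations), p("annotations.tsv"))
  attr_truth <- attr(bundle$annotations, "truth")
  write_tsv(attr_truth, p("annotations.truth.tsv"))
  expr_df <- data.frame(gene_id = rownames(bundle$expression$table),
                        bundle$expression$table, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(expr_df, p("expression.tsv"))
  write_tsv(data.frame(gene_id = names(bundle$expression$truth),
                       cluster = unname(bundle$expression$truth)),
            p("expression.truth.tsv"))
  write_tsv(bundle$disease, p("disease.tsv"))
  el <- igraph::as_edgelist(bundle$interactome$graph)
  write_tsv(data.frame(id_a = el[, 1], id_b = el[, 2]), p("edges.tsv"))
  write_tsv(data.frame(gene_id = bundle$interactome$module,
                       in_module = TRUE), p("module.truth.tsv"))
  write_tsv(bundle$proteome$records[, c("protein_id", "gene_id")],
            p("mapping.tsv"))
  invisible(outdir)
}
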