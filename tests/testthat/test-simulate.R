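test_that("generators are deterministic under a fixed seed", {
  p1 <- generate_proteome(30, prion_fraction = 0.2, seed = 42)
  p2 <- generate_proteome(30, prion_fraction = 0.2, seed = 42)
  expect_identical(p1, p2)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_proteome_fasta(p1, f1)
  write_proteome_fasta(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(
    generate_expression(paste0("g", 1:30), paste0("t", 1:5), seed = 7),
    generate_expression(paste0("g", 1:30), paste0("t", 1:5), seed = 7))
  expect_identical(
    generate_interactome(40, 0.1, seed = 3)$graph[],
    generate_interactome(40, 0.1, seed = 3)$graph[])
  a1 <- generate_annotations(p1, n_terms = 10, seed = 5)
  a2 <- generate_annotations(p1, n_terms = 10, seed = 5)
  expect_identical(a1, a2)
  expect_identical(generate_disease_labels(paste0("g", 1:50), seed = 9),
                   generate_disease_labels(paste0("g", 1:50), seed = 9))
})

test_that("generate_proteome respects structural invariants and edge cases", {
  p <- generate_proteome(40, prion_fraction = 0, seed = 1)
  expect_equal(sum(p$truth$is_planted), 0)

  p <- generate_proteome(60, prion_fraction = 0.25, length_range = c(90, 200),
                         seed = 2)
  expect_false(anyDuplicated(p$records$protein_id) > 0)
  expect_true(all(strsplit(paste(p$records$sequence, collapse = ""), "")[[1]]
                  %in% prionscape:::AMINO_ACIDS))
  tr <- p$truth[p$truth$is_planted, ]
  lens <- nchar(p$records$sequence[match(tr$protein_id,
                                         p$records$protein_id)])
  expect_true(all(tr$domain_start >= 1 & tr$domain_end <= lens))
  expect_true(all(tr$domain_end - tr$domain_start + 1 == 60))
  expect_true(all(tr$placement %in% c("N", "C", "internal")))

  expect_error(generate_proteome(10, prion_fraction = 1.2, seed = 1),
               "prion_fraction")
  expect_error(generate_proteome(10, length_range = c(50, 100), seed = 1),
               "length_range")
  expect_error(generate_proteome(0, seed = 1), "n_proteins")
})

test_that("planted compositional windows dominate every background window", {
  # exhaustive scan: the best 60-residue LLR window of every planted protein
  # exceeds the best window of every non-planted protein
  p <- generate_proteome(500, prion_fraction = 0.1, seed = 1)
  model <- composition_model()
  best60 <- vapply(p$records$sequence, function(s) {
    prof <- llr_profile(s, model)
    cs <- c(0, cumsum(prof))
    n <- length(prof)
    max(cs[61:(n + 1)] - cs[1:(n - 59)])
  }, numeric(1))
  planted <- p$truth$is_planted
  expect_equal(sum(planted), 50)
  expect_gt(min(best60[planted]), max(best60[!planted]))
})

test_that("planted amyloid cores clear the calling cutoff", {
  p <- generate_proteome(50, prion_fraction = 0.3, seed = 11)
  mat <- amyloid_matrix()
  tr <- p$truth[p$truth$is_planted, ]
  seqs <- setNames(p$records$sequence, p$records$protein_id)
  scores <- vapply(seq_len(nrow(tr)), function(i) {
    dom <- substr(seqs[[tr$protein_id[i]]], tr$domain_start[i], tr$domain_end[i])
    amyloid_core_score(dom, mat)$score
  }, numeric(1))
  expect_true(all(scores >= mat$cutoff + 5))
})

test_that("generate_annotations plants odds ratios and validates input", {
  p <- generate_proteome(400, prion_fraction = 0.25, seed = 3)
  ann <- generate_annotations(p, n_terms = 20, enriched = c(T0004 = 6),
                              base_rate_range = c(0.1, 0.1), seed = 3)
  truth <- attr(ann, "truth")
  expect_equal(truth$odds_ratio[truth$term_id == "T0004"], 6)
  expect_true(all(ann$evidence %in% c("IEA", "EXP", "IDA", "IMP", "TAS")))
  expect_false(anyDuplicated(ann[, c("protein_id", "term_id")]) > 0)
  # OR = 1 term: planted and background frequencies agree (binomial noise)
  planted_ids <- p$truth$protein_id[p$truth$is_planted]
  f_rates <- vapply(c("T0001", "T0002", "T0003"), function(tm) {
    with_term <- ann$protein_id[ann$term_id == tm]
    mean(planted_ids %in% with_term) - mean(p$records$protein_id %in% with_term)
  }, numeric(1))
  expect_true(all(abs(f_rates) < 0.12))
  # planted OR = 6 term: clearly elevated in the planted set
  with_t4 <- ann$protein_id[ann$term_id == "T0004"]
  expect_gt(mean(planted_ids %in% with_t4), 0.25)
  expect_error(generate_annotations(p, enriched = c(BAD = -1), seed = 1),
               "odds ratios")
  expect_error(generate_annotations(p, n_terms = 5, enriched = c(T9999 = 2),
                                    seed = 1),
               "enriched term ids")
})

test_that("generate_expression codes ranks 0-3 with planted structure", {
  genes <- paste0("g", 1:80)
  e <- generate_expression(genes, paste0("t", 1:12), k_true = 4, effect = 2,
                           seed = 5)
  expect_true(all(e$table %in% 0:3))
  expect_identical(dim(e$table), c(80L, 12L))
  expect_setequal(unique(e$truth), 1:4)
  # effect = 0: per-cluster mean profiles coincide up to noise
  e0 <- generate_expression(genes, paste0("t", 1:12), k_true = 4, effect = 0,
                            seed = 5)
  profiles <- vapply(1:4, function(k) {
    colMeans(e0$table[e0$truth == k, , drop = FALSE])
  }, numeric(12))
  expect_lt(max(profiles) - min(profiles), 0.8)
  expect_error(generate_expression(paste0("g", 1:3), "t1", k_true = 5,
                                   seed = 1),
               "fewer genes")
})

test_that("generate_disease_labels plants rates and validates input", {
  genes <- paste0("g", 1:500)
  d0 <- generate_disease_labels(genes, base_rate = 0, seed = 1)
  expect_equal(nrow(d0), 0)
  d <- generate_disease_labels(genes, set_ids = genes[1:100], base_rate = 0.05,
                               set_rate = 0.6, seed = 2)
  expect_gt(disease_fraction(genes[1:100], d), 0.4)
  expect_lt(disease_fraction(genes[101:500], d), 0.15)
  expect_error(generate_disease_labels(genes, set_ids = "nope", seed = 1),
               "subset")
  expect_error(generate_disease_labels(genes, base_rate = 2, seed = 1),
               "base_rate")
})

test_that("generate_interactome builds simple graphs with a planted module", {
  mod <- sprintf("g%05d", 1:15)
  g0 <- generate_interactome(60, p_background = 0, module = mod,
                             p_module = 0.5, seed = 4)
  el <- igraph::as_edgelist(g0$graph)
  expect_true(all(el[, 1] %in% mod & el[, 2] %in% mod))
  g <- generate_interactome(100, 0.05, module = mod, p_module = 0.4, seed = 5)
  expect_false(igraph::any_multiple(g$graph))
  expect_equal(sum(igraph::which_loop(g$graph)), 0)
  expect_equal(igraph::vcount(g$graph), 100)
  expect_error(generate_interactome(10, 0.5, module = "zzz", seed = 1),
               "subset")
  expect_error(generate_interactome(10, 0.5, p_module = 0.1, seed = 1),
               "p_module")
})

test_that("write_bundle emits every standard-format file with truth sidecars", {
  dir <- tempfile()
  simulate_bundle("full", seed = 2, n_proteins = 40, outdir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "proteome.fasta", "proteome.fasta.truth.tsv", "annotations.tsv",
    "annotations.truth.tsv", "expression.tsv", "expression.truth.tsv",
    "disease.tsv", "edges.tsv", "module.truth.tsv", "mapping.tsv")))))
  # FASTA round-trips through the standard reader
  seqs <- as_sequences <- prionscape:::as_sequences(file.path(dir, "proteome.fasta"))
  expect_length(seqs, 40)
  expect_true(all(nchar(seqs) >= 140))
})
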