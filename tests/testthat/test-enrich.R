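test_that("filter_annotations handles evidence codes and slim maps", {
  tab <- data.frame(
    protein_id = c("p1", "p2", "p3", "p1"),
    term_id = c("t1", "t1", "t2", "t3"),
    namespace = "BP",
    evidence = c("EXP", "IEA", "IEA", "TAS"),
    stringsAsFactors = FALSE)
  # identity: nothing excluded, no slim
  out <- filter_annotations(tab, excluded_evidence = character())
  expect_equal(nrow(out), 4)
  # IEA rows removed
  out <- filter_annotations(tab)
  expect_equal(nrow(out), 2)
  expect_false(any(out$evidence == "IEA"))
  # all rows excluded warns
  all_iea <- tab
  all_iea$evidence <- "IEA"
  expect_warning(out <- filter_annotations(all_iea), "removed")
  expect_equal(nrow(out), 0)
  # multi-level slim map resolves transitively and collapses duplicates
  tab2 <- data.frame(
    protein_id = c("p1", "p1", "p2"),
    term_id = c("leaf1", "leaf2", "mid"),
    namespace = "BP", evidence = "EXP", stringsAsFactors = FALSE)
  slim <- c(leaf1 = "mid", leaf2 = "mid", mid = "top")
  out <- filter_annotations(tab2, excluded_evidence = character(),
                            slim_map = slim)
  expect_true(all(out$term_id == "top"))
  expect_equal(nrow(out), 2)  # p1 duplicates collapsed
  expect_error(
    filter_annotations(tab2, excluded_evidence = character(),
                       slim_map = c(a = "b", b = "a", leaf1 = "a")),
    "cycle")
})

test_that("random slim maps land in the codomain with correct collapse", {
  set.seed(61)
  for (rep in 1:20) {
    terms <- paste0("t", 1:30)
    # 3-level map: leaves -> mids -> tops
    tops <- paste0("TOP", 1:3)
    mids <- paste0("MID", 1:6)
    slim <- c(setNames(sample(mids, 30, replace = TRUE), terms),
              setNames(sample(tops, 6, replace = TRUE), mids))
    tab <- data.frame(
      protein_id = sample(paste0("p", 1:15), 60, replace = TRUE),
      term_id = sample(terms, 60, replace = TRUE),
      namespace = "BP", evidence = "EXP", stringsAsFactors = FALSE)
    out <- filter_annotations(tab, excluded_evidence = character(),
                              slim_map = slim)
    expect_true(all(out$term_id %in% tops))
    # independent grouping oracle for the collapsed pair count
    resolved <- slim[slim[tab$term_id]]
    expect_equal(nrow(out),
                 nrow(unique(data.frame(tab$protein_id, resolved))))
  }
})

test_that("term_enrichment computes Fisher tests with Bonferroni control", {
  bg <- paste0("p", 1:100)
  set <- bg[1:10]
  membership <- list(
    t_all = bg,                       # degenerate: annotates every protein
    t_hot = c(set[1:8], bg[11:12]),   # concentrated in the set
    t_flat = bg[seq(1, 100, by = 5)])
  tab <- make_annotation_table(membership)
  res <- term_enrichment(set, bg, tab, namespace = "BP")
  expect_equal(attr(res, "family_size"), 3)
  row_all <- res[res$term_id == "t_all", ]
  expect_true(is.na(row_all$odds_ratio))
  expect_equal(row_all$fisher_p, 1)
  row_hot <- res[res$term_id == "t_hot", ]
  # 2x2 (8, 2, 2, 88): two-sided Fisher equals hypergeometric enumeration
  expect_equal(row_hot$fisher_p, oracle_fisher_p(8, 2, 2, 88),
               tolerance = 1e-9)
  expect_equal(row_hot$adjusted_p, min(1, 3 * row_hot$fisher_p))
  expect_equal(row_hot$direction, "enriched")
  # adjusted p monotone in fisher p, bounded in [fisher_p, 1]
  expect_true(all(res$adjusted_p >= res$fisher_p - 1e-12))
  expect_true(all(res$adjusted_p <= 1))
  expect_equal(order(res$adjusted_p), seq_len(nrow(res)))
  expect_error(term_enrichment(character(), bg, tab), "empty")
  expect_error(term_enrichment("zz", bg, tab), "subset")
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(71)
  for (i in 1:40) {
    n_bg <- sample(20:30, 1)
    n_set <- sample(5:(n_bg - 5), 1)
    k_bg <- sample(1:n_bg, 1)
    bg <- paste0("p", seq_len(n_bg))
    set <- bg[seq_len(n_set)]
    with_term <- sample(bg, k_bg)
    tab <- make_annotation_table(list(tm = with_term))
    res <- term_enrichment(set, bg, tab)
    a <- sum(with_term %in% set)
    if (k_bg == n_bg) {
      expect_equal(res$fisher_p, 1)
    } else {
      expect_equal(res$fisher_p,
                   oracle_fisher_p(a, n_set - a, k_bg - a,
                                   n_bg - n_set - k_bg + a),
                   tolerance = 1e-9)
    }
  }
})

test_that("log_enrichment_score matches its closed form", {
  bg <- paste0("p", 1:40)
  set <- bg[1:10]
  # identical frequency: one annotation per protein for the same term
  tab <- make_annotation_table(list(t1 = bg))
  expect_equal(log_enrichment_score("t1", set, bg, tab), 0)
  # direct-formula oracle on random tables
  set.seed(83)
  for (i in 1:20) {
    tab <- read_annotations(data.frame(
      protein_id = sample(bg, 120, replace = TRUE),
      term_id = sample(paste0("t", 1:6), 120, replace = TRUE),
      namespace = "BP", evidence = "EXP"))
    term <- sample(unique(tab$term_id), 1)
    e <- log_enrichment_score(term, set, bg, tab)
    set_rows <- tab[tab$protein_id %in% set, ]
    a_set <- sum(set_rows$term_id == term)
    oracle <- if (a_set == 0) NA_real_ else {
      log(a_set / nrow(set_rows)) -
        log(sum(tab$term_id == term) / nrow(tab))
    }
    expect_equal(e, oracle)
  }
  # antisymmetry under swapping set and background roles
  g1 <- bg[1:20]
  g2 <- bg[21:40]
  tab <- read_annotations(data.frame(
    protein_id = sample(bg, 200, replace = TRUE),
    term_id = sample(paste0("t", 1:4), 200, replace = TRUE),
    namespace = "BP", evidence = "EXP"))
  for (term in unique(tab$term_id)) {
    e12 <- log_enrichment_score(term, g1, g2, tab)
    e21 <- log_enrichment_score(term, g2, g1, tab)
    if (!is.na(e12) && !is.na(e21)) expect_equal(e12, -e21)
  }
  expect_error(log_enrichment_score("absent", set, bg, tab), "background")
})

test_that("per-protein frequency mode is exposed as an option", {
  bg <- paste0("p", 1:30)
  set <- bg[1:6]
  tab <- make_annotation_table(list(t1 = bg[1:10], t2 = bg[5:30]))
  e <- log_enrichment_score("t1", set, bg, tab, freq_mode = "protein")
  k_set <- sum(bg[1:10] %in% set)
  expect_equal(e, log(k_set / 6) - log(10 / 30))
})
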