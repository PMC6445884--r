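test_that("estimate_background_frequencies tallies residues correctly", {
  f <- estimate_background_frequencies(c(x = "AAAA"))
  expect_gt(f[["A"]], 0.99)
  expect_equal(sum(f), 1)
  # pooling identity: frequencies of {s1, s2} equal frequencies of s1 + s2
  s1 <- "MKQQNNYV"
  s2 <- "GGSPAL"
  expect_equal(estimate_background_frequencies(c(a = s1, b = s2)),
               estimate_background_frequencies(c(ab = paste0(s1, s2))))
  # independent letter-count oracle on a synthetic proteome
  p <- generate_proteome(25, prion_fraction = 0.2, seed = 1)
  f <- estimate_background_frequencies(p)
  chars <- strsplit(paste(p$records$sequence, collapse = ""), "")[[1]]
  tally <- table(chars)[prionscape:::AMINO_ACIDS] / length(chars)
  expect_equal(unname(f), pmax(as.numeric(tally), 1e-6) /
                 sum(pmax(as.numeric(tally), 1e-6)), tolerance = 1e-12)
  # non-standard residues skipped with a message
  expect_message(estimate_background_frequencies(c(x = "AAXXBB")), "skipped")
  expect_error(estimate_background_frequencies(character()), "empty")
})

test_that("llr_profile is the elementwise log-ratio", {
  model <- composition_model()
  ident <- composition_model(prion_freqs = background_frequencies())
  expect_equal(llr_profile("MKQQN", ident), rep(0, 5))
  # unknown residues score 0
  expect_equal(llr_profile("QXQ", model)[2], 0)
  # elementwise oracle on a random 200-mer
  set.seed(31)
  s <- paste(sample(prionscape:::AMINO_ACIDS, 200, replace = TRUE),
             collapse = "")
  prof <- llr_profile(s, model)
  chars <- strsplit(s, "")[[1]]
  oracle <- log(model$prion_freqs[chars] / model$background_freqs[chars])
  expect_equal(prof, unname(oracle))
  # monotone in the prion frequency of a residue, background held fixed
  pf <- prion_frequencies()
  pf["Q"] <- pf["Q"] * 2
  m2 <- composition_model(prion_freqs = pf / sum(pf))
  expect_gt(llr_profile("Q", m2), llr_profile("Q", model))
})

test_that("find_prion_domain matches the exhaustive window oracle", {
  model <- composition_model()
  expect_null(find_prion_domain(rep(-1, 100), model))
  expect_null(find_prion_domain(rep(1, 30), model))  # shorter than core
  # constructed block: sixty +1 flanked by -1
  prof <- c(rep(-1, 20), rep(1, 60), rep(-1, 20))
  d <- find_prion_domain(prof, model)
  expect_equal(c(d$domain_start, d$domain_end), c(21, 80))
  expect_equal(d$core_score, 60)
  # 100 random profiles: core window equals the brute-force argmax
  set.seed(99)
  for (i in 1:100) {
    prof <- rnorm(300, mean = 0.02)
    d <- find_prion_domain(prof, model)
    o <- oracle_best_window(prof, 60)
    if (o$score <= 0) {
      expect_null(d)
    } else {
      expect_equal(d$core_start, o$start)
      expect_equal(d$core_score, o$score, tolerance = 1e-10)
      # the reported domain contains the core window
      expect_lte(d$domain_start, d$core_start)
      expect_gte(d$domain_end, d$core_end)
    }
  }
})

test_that("amyloid_core_score matches exhaustive 21-mer enumeration", {
  mat <- amyloid_matrix()
  # single-window domain
  set.seed(5)
  s21 <- paste(sample(prionscape:::AMINO_ACIDS, 21, replace = TRUE),
               collapse = "")
  r <- amyloid_core_score(s21, mat)
  expect_equal(c(r$start, r$end), c(1, 21))
  # short domain: sentinel with reason
  r <- amyloid_core_score("QQQ", mat)
  expect_true(is.na(r$score))
  expect_match(r$reason, "shorter")
  # degenerate all-zero matrix: constant score -min/(max-min)*100
  zero <- structure(list(
    weights = matrix(0, 21, 20,
                     dimnames = list(1:21, prionscape:::AMINO_ACIDS)),
    score_min = -2, score_max = 2, cutoff = 60), class = "amyloid_matrix")
  r <- amyloid_core_score(s21, zero)
  expect_equal(r$score, 50)
  # 50 random 80-mers against the enumeration oracle
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(prionscape:::AMINO_ACIDS, 80, replace = TRUE),
               collapse = "")
    r <- amyloid_core_score(s, mat)
    o <- oracle_best_21mer(s, mat$weights)
    expect_equal(r$start, o$start)
    expect_equal(r$raw, o$raw, tolerance = 1e-10)
  }
  # windows containing non-standard residues are excluded
  s <- paste0(strrep("Q", 30), "X", strrep("I", 30))
  r <- amyloid_core_score(s, mat)
  o <- oracle_best_21mer(s, mat$weights)
  expect_equal(r$start, o$start)
})

test_that("the amyloid matrix separates background windows from the cutoff", {
  # random background-composition 21-mers sit near mid-scale, clearly below
  # the 60/100 cutoff on average, so stage two carries real information
  mat <- amyloid_matrix()
  bg <- background_frequencies()
  set.seed(47)
  scores <- replicate(300, {
    s <- paste(sample(names(bg), 21, replace = TRUE, prob = bg),
               collapse = "")
    amyloid_core_score(s, mat)$score
  })
  expect_gt(mean(scores), 42)
  expect_lt(mean(scores), 56)
  expect_lt(mean(scores) + sd(scores), mat$cutoff)
})

test_that("call_prionlike composes the two stages with monotone cutoffs", {
  p <- generate_proteome(80, prion_fraction = 0.2, seed = 21)
  calls0 <- call_prionlike(p, matrix = amyloid_matrix(cutoff = 0))
  # vacuous second filter: positives = stage-1 candidates with a score
  expect_equal(calls0$positive, !is.na(calls0$amyloid_score))
  # raising the cutoff never adds a positive
  prev <- calls0$protein_id[calls0$positive]
  for (cut in c(40, 60, 80, 101)) {
    cur <- call_prionlike(p, matrix = amyloid_matrix(cutoff = cut))
    cur <- cur$protein_id[cur$positive]
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # identity composition model yields zero candidates
  ident <- composition_model(prion_freqs = background_frequencies())
  expect_equal(nrow(call_prionlike(p, model = ident)), 0)
  # output sorted by protein id, amyloid core inside the domain
  calls <- call_prionlike(p)
  expect_equal(calls$protein_id, sort(calls$protein_id))
  ok <- !is.na(calls$amyloid_start)
  expect_true(all(calls$amyloid_start[ok] >= calls$domain_start[ok]))
  expect_true(all(calls$amyloid_end[ok] <= calls$domain_end[ok]))
  expect_true(all(calls$amyloid_end[ok] - calls$amyloid_start[ok] == 20))
  expect_true(all(calls$amyloid_score[calls$positive] >= 60))
})

test_that("compositional window score depends only on window content", {
  # reversing a sequence reverses the profile but leaves the best window
  # sum unchanged (composition is order-free)
  model <- composition_model()
  set.seed(13)
  s <- paste(sample(prionscape:::AMINO_ACIDS, 150, replace = TRUE,
                    prob = prion_frequencies()), collapse = "")
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  d1 <- find_prion_domain(llr_profile(s, model), model)
  d2 <- find_prion_domain(llr_profile(rev_s, model), model)
  expect_equal(d1$core_score, d2$core_score, tolerance = 1e-10)
})

test_that("calls round-trip through TSV", {
  p <- generate_proteome(40, prion_fraction = 0.3, seed = 8)
  calls <- call_prionlike(p)
  f <- tempfile(fileext = ".tsv")
  write_calls(calls, f)
  back <- read_calls(f)
  expect_equal(as.data.frame(calls), as.data.frame(back), ignore_attr = TRUE)
})
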