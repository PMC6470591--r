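test_that("collect_candidates counts distinct records and excludes the query drug", {
  recs <- make_records(
    make_record("1", substances = c("simvastatin", "X", "Y")),
    make_record("2", substances = c("Simvastatin", "X")),
    make_record("3", substances = c("Y", "Z"))
  )
  cand <- collect_candidates(recs, "Simvastatin")
  expect_equal(cand$frequency[match(c("X", "Y", "Z"), cand$term)], c(2L, 2L, 1L))
  expect_false("simvastatin" %in% tolower(cand$term))

  only_drug <- make_records(make_record("1", substances = "Simvastatin"))
  expect_equal(nrow(collect_candidates(only_drug, "simvastatin")), 0)

  # a term listed twice in one record's substance lines counts once: the
  # parser de-duplicates, and the membership count is per distinct record
  dup_txt <- c("PMID- 5", "RN  - 0 (Aspirin)", "NM  - Aspirin")
  dup <- parse_medline(dup_txt)
  expect_equal(collect_candidates(dup, "x")$frequency, 1L)
})

test_that("null counts hit the degenerate bounds", {
  group_b <- make_records(
    make_record("1", substances = c("Everywhere", "drug")),
    make_record("2", substances = c("Everywhere")),
    make_record("3", substances = c("Everywhere", "Other"))
  )
  cand <- tibble::tibble(term = c("Everywhere", "Nowhere"), frequency = c(3L, 1L))
  nulls <- sample_null_counts(cand, group_b, n = 10, sample_times = 50, seed = 4)
  expect_true(all(nulls$counts[, "Everywhere"] == 10))
  expect_true(all(nulls$counts[, "Nowhere"] == 0))
  expect_true(all(nulls$counts >= 0 & nulls$counts <= nulls$n))
})

test_that("null counts are binomially calibrated at q = 0.5", {
  # 50% of Group B carries the term: counts ~ Binomial(100, 0.5),
  # mean 50, SD 5
  group_b <- dplyr::bind_rows(lapply(1:200, function(i) {
    make_record(as.character(i),
                substances = if (i <= 100) c("Half", "bg") else "bg")
  }))
  cand <- tibble::tibble(term = "Half", frequency = 1L)
  nulls <- sample_null_counts(cand, group_b, n = 100, sample_times = 1000,
                              seed = 9)
  col <- nulls$counts[, "Half"]
  expect_gt(mean(col), 48)
  expect_lt(mean(col), 52)
  expect_gt(sd(col), 4)
  expect_lt(sd(col), 6)
})

test_that("sampling matches a brute-force membership scan exactly under a shared seed", {
  group_b <- random_records(60, seed = 21)
  terms <- c("Cyclosporine", "Warfarin", "Digoxin", "Absent Term")
  cand <- tibble::tibble(term = terms, frequency = 1L)
  nulls <- sample_null_counts(cand, group_b, n = 25, sample_times = 40, seed = 123)
  brute <- null_counts_bruteforce(terms, group_b, n = 25, sample_times = 40,
                                  seed = 123)
  expect_identical(unname(nulls$counts), unname(brute))

  # identical seed => identical matrix; different seed differs
  again <- sample_null_counts(cand, group_b, n = 25, sample_times = 40, seed = 123)
  expect_identical(nulls$counts, again$counts)
  other <- sample_null_counts(cand, group_b, n = 25, sample_times = 40, seed = 124)
  expect_false(identical(nulls$counts, other$counts))
})

test_that("summarize_null computes mean and sample SD per term", {
  const <- structure(list(counts = matrix(7L, nrow = 5, ncol = 1,
                                          dimnames = list(NULL, "k")), n = 10),
                     class = "null_counts")
  s <- summarize_null(const)
  expect_equal(s$null_mean, 7)
  expect_equal(s$null_sd, 0)

  two <- structure(list(counts = matrix(c(0L, 2L), ncol = 1,
                                        dimnames = list(NULL, "t")), n = 2),
                   class = "null_counts")
  s2 <- summarize_null(two)
  expect_equal(s2$null_mean, 1)
  expect_equal(s2$null_sd, sqrt(2))

  # agrees with a naive two-pass loop to 12 significant digits
  set.seed(5)
  m <- matrix(rpois(500, 8), ncol = 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  s3 <- summarize_null(structure(list(counts = m, n = 20), class = "null_counts"))
  for (j in 1:5) {
    mu <- sum(m[, j]) / nrow(m)
    sdv <- sqrt(sum((m[, j] - mu)^2) / (nrow(m) - 1))
    expect_equal(s3$null_mean[j], mu, tolerance = 1e-12)
    expect_equal(s3$null_sd[j], sdv, tolerance = 1e-12)
  }

  one <- structure(list(counts = matrix(1L, nrow = 1), n = 1), class = "null_counts")
  expect_error(summarize_null(one), "at least 2")
})

test_that("compute_pvalues gives one-sided upper-tail normal p-values", {
  # f at the null mean: no evidence either way
  expect_equal(compute_pvalues(5, 5, 2), tibble::tibble(z = 0, p_raw = 0.5))
  # z = 3 against the standard normal upper tail
  r <- compute_pvalues(10, 4, 2)
  expect_equal(r$z, 3)
  expect_equal(r$p_raw, pnorm(3, lower.tail = FALSE))
  expect_equal(r$p_raw, 1.3499e-3, tolerance = 1e-4)
  # degenerate null: never seen in Group B samples
  zero_sd <- compute_pvalues(35, 0, 0)
  expect_equal(zero_sd$z, Inf)
  expect_equal(zero_sd$p_raw, 0)
  expect_equal(compute_pvalues(2, 5, 0)$p_raw, 1)
  expect_equal(compute_pvalues(5, 5, 0)$z, 0)
  expect_error(compute_pvalues(1, 0, -1), "non-negative")
})

test_that("p_raw is antitone in frequency at fixed null moments", {
  f <- 0:20
  p <- compute_pvalues(f, 10, 3)$p_raw
  expect_true(all(diff(p) < 0))
})

test_that("adjust_bh is the step-up procedure", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_bh(numeric(0)), "non-empty")
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjust_bh matches an independent reference implementation", {
  set.seed(77)
  for (k in 1:20) {
    p <- runif(50)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_reference(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # rank preservation
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  # and one big vector, elementwise
  p <- runif(1000)
  expect_equal(adjust_bh(p), bh_reference(p), tolerance = 1e-12)
  # permutation equivariance
  perm <- sample(1000)
  expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm], tolerance = 1e-12)
})

test_that("filter_significant applies cutoff and strict alpha with deterministic order", {
  params <- parameter_set(cutoff = 4, alpha = 0.05)
  empty <- tibble::tibble(term = character(0), frequency = integer(0),
                          p_raw = numeric(0), p_adjusted = numeric(0))
  expect_equal(nrow(filter_significant(empty, params)), 0)

  stats <- tibble::tibble(
    term = c("AtCutoff", "Below", "AtAlpha", "B", "A"),
    frequency = c(4L, 3L, 10L, 7L, 7L),
    p_raw = c(0.001, 0.0001, 0.01, 0.002, 0.002),
    p_adjusted = c(0.01, 0.001, 0.05, 0.02, 0.02)
  )
  out <- filter_significant(stats, params)
  # frequency 4 kept (cutoff 4 means "frequency > 3"); frequency 3 dropped
  expect_true("AtCutoff" %in% out$term)
  expect_false("Below" %in% out$term)
  # p_adjusted == alpha excluded (strict)
  expect_false("AtAlpha" %in% out$term)
  # order: frequency desc, then p_raw asc, then term
  expect_equal(out$term, c("A", "B", "AtCutoff"))
})

test_that("run_enrichment flags a strongly planted term and is seed-deterministic", {
  spec <- corpus_spec("simvastatin", n_a = 500, n_b = 2000,
                      term_catalog = default_catalog(), seed = 31)
  corpus <- generate_corpus(spec)
  grouped <- split_groups(corpus$records, "simvastatin")
  params <- parameter_set(sample_times = 1000, seed = 31)
  fit <- run_enrichment(grouped, params)

  planted <- dplyr::filter(tidy(fit), term == "PlantedTerm")
  expect_true(planted$significant)
  expect_lt(planted$p_adjusted, 0.01)
  # the query drug never appears among tested terms
  expect_false("simvastatin" %in% tolower(tidy(fit)$term))
  # adjusted >= raw everywhere
  expect_true(all(tidy(fit)$p_adjusted >= tidy(fit)$p_raw))

  fit2 <- run_enrichment(grouped, params)
  expect_identical(tidy(fit), tidy(fit2))

  g <- glance(fit)
  expect_equal(g$n_group_a, 500L)
  expect_equal(g$sample_size, 500L)
})
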