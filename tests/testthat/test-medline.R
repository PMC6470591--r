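test_that("parse_medline handles empty input and extracts substance names", {
  expect_equal(nrow(parse_medline(character(0))), 0)
  expect_equal(nrow(parse_medline("")), 0)

  txt <- c(
    "PMID- 200",
    "TI  - Interaction of cyclosporine with simvastatin through",
    "      CYP3A inhibition",
    "DP  - 2014 Mar 10",
    "MH  - Drug Interactions",
    "MH  - Humans",
    "RN  - 59865-13-3 (Cyclosporine)",
    "NM  - Cytochrome P-450 CYP3A",
    "RN  - 0 (Simvastatin)"
  )
  rec <- parse_medline(txt)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$pmid, "200")
  expect_setequal(rec$substances[[1]],
                  c("Cyclosporine", "Cytochrome P-450 CYP3A", "Simvastatin"))
  expect_equal(rec$mesh_headings[[1]], c("Drug Interactions", "Humans"))
  expect_match(rec$title, "CYP3A inhibition") # continuation line folded
  expect_equal(rec$pub_date, as.Date("2014-03-10"))
})

test_that("records without a PMID are rejected with a warning, parsing continues", {
  txt <- c(
    "PMID- 1", "RN  - 0 (Aspirin)", "",
    "TI  - orphan block with no identifier", "RN  - 0 (Warfarin)", "",
    "PMID- 2", "RN  - 0 (Digoxin)"
  )
  expect_warning(recs <- parse_medline(txt), "without a PMID")
  expect_equal(recs$pmid, c("1", "2"))
})

test_that("write_medline validates invariants and names the offending pmid", {
  bad <- make_record("77", substances = c("Aspirin", "Aspirin"))
  expect_error(write_medline(bad), "77")
  expect_error(write_medline(make_record("")), "empty PMID")
  expect_equal(write_medline(make_record("9")[0, ]), character(0))
  one <- write_medline(make_record("9"))
  expect_equal(sum(grepl("^PMID-", one)), 1)
})

test_that("parse after write is the identity on record content", {
  recs <- random_records(100, seed = 7)
  back <- parse_medline(write_medline(recs))
  expect_equal(back$pmid, recs$pmid)
  expect_equal(back$title, recs$title)
  expect_equal(back$pub_date, recs$pub_date)
  expect_equal(back$mesh_headings, recs$mesh_headings)
  expect_equal(back$substances, recs$substances)

  # and a second pass is stable
  expect_equal(parse_medline(write_medline(back)), back)
})

test_that("filter_by_end_date keeps the inclusive bound and preserves order", {
  recs <- dplyr::bind_rows(lapply(2010:2019, function(y) {
    make_record(as.character(y), dp = sprintf("%d Jun 15", y))
  }))
  kept <- filter_by_end_date(recs, "2015/12/31")
  expect_equal(kept$pmid, as.character(2010:2015))

  # record dated exactly at the bound is retained
  exact <- make_record("x", dp = "2015 Dec 31")
  expect_equal(nrow(filter_by_end_date(exact, "2015/12/31")), 1)

  # year-only dates complete to Jan 1
  yearly <- make_record("y", dp = "2016")
  expect_equal(nrow(filter_by_end_date(yearly, "2016/01/01")), 1)
  expect_equal(nrow(filter_by_end_date(yearly, "2015/12/31")), 0)

  # all records from 2014 pass a 2015/12/31 cutoff
  all2014 <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_record(paste0("a", i), dp = "2014 Feb 2")
  }))
  expect_equal(nrow(filter_by_end_date(all2014, "2015/12/31")), 5)
})

test_that("date filtering is idempotent and monotone, and keeps undated records", {
  recs <- random_records(50, seed = 3)
  f1 <- filter_by_end_date(recs, "2010/06/30")
  expect_equal(filter_by_end_date(f1, "2010/06/30"), f1)
  earlier <- filter_by_end_date(recs, "2007/06/30")
  expect_true(all(earlier$pmid %in% f1$pmid))

  undated <- make_record("u", dp = "in press")
  expect_true(is.na(undated$pub_date))
  expect_warning(kept <- filter_by_end_date(undated, "2000/01/01"),
                 "no interpretable publication date")
  expect_equal(kept$pmid, "u")
})

test_that("split_groups partitions by the MeSH interaction descriptor", {
  recs <- make_records(
    make_record("1", mesh = c("Drug Interactions", "Humans")),
    make_record("2", mesh = c("drug interactions/adverse effects")),
    make_record("3", mesh = "Humans")
  )
  grouped <- split_groups(recs, "simvastatin")
  expect_s3_class(grouped, "grouped_corpus")
  expect_equal(nrow(grouped$group_a), 2)
  expect_equal(nrow(grouped$group_b), 1)
  # partition: disjoint pmids, union = input
  expect_length(intersect(grouped$group_a$pmid, grouped$group_b$pmid), 0)
  expect_setequal(c(grouped$group_a$pmid, grouped$group_b$pmid), recs$pmid)
})

test_that("degenerate splits are fatal", {
  all_a <- make_records(
    make_record("1", mesh = "Drug Interactions"),
    make_record("2", mesh = "Drug Interactions")
  )
  expect_error(split_groups(all_a, "x"), "Group B empty")
  all_b <- make_records(make_record("1", mesh = "Humans"))
  expect_error(split_groups(all_b, "x"), "no DDI-related articles")
  expect_error(split_groups(make_records(), "x"), "no records")
})

test_that("split_groups recovers the generator's truth labels exactly", {
  spec <- corpus_spec("simvastatin", n_a = 500, n_b = 2000,
                      term_catalog = default_catalog(), seed = 11)
  corpus <- generate_corpus(spec)
  grouped <- split_groups(corpus$records, "simvastatin")
  expect_equal(nrow(grouped$group_a), 500)
  expect_equal(nrow(grouped$group_b), 2000)
  # generator puts Group A first with SYN ids 1..n_a
  expect_equal(grouped$group_a$pmid, sprintf("SYN%06d", 1:500))
})

test_that("fetch_pubmed is an injectable-transport interface", {
  expect_error(fetch_pubmed("Simvastatin", "2015/12/31", transport = NULL),
               "unavailable offline")
  canned <- write_medline(random_records(5, seed = 2))
  mock <- function(term, maxdate) {
    expect_equal(term, "Simvastatin")
    expect_equal(maxdate, "2015/12/31")
    canned
  }
  txt <- fetch_pubmed("Simvastatin", "2015/12/31", transport = mock)
  expect_equal(nrow(parse_medline(txt)), 5)
  expect_warning(
    out <- fetch_pubmed("Simvastatin", "2015/12/31",
                        transport = function(term, maxdate) character(0)),
    "no records"
  )
  expect_length(out, 0)
})
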