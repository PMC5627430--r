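# Conservation analysis over alignment hit tables.

hit_line <- function(q, s, pid, len, ev, bits, mism = 5, gaps = 0) {
  paste(q, s, pid, len, mism, gaps, 1, len, 1, len, ev, bits, sep = "\t")
}

test_that("parse_hits maps the 12 columns positionally", {
  path <- withr::local_tempfile()
  writeLines(c(hit_line("q1", "S01|p1", 80, 100, 1e-50, 200),
               hit_line("q1", "S02|p9", 45, 90, 1e-10, 80),
               hit_line("q2", "S01|p2", 30, 40, 1e-3, 40)), path)
  ql <- c(q1 = 100, q2 = 120)
  hits <- parse_hits(path, ql)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$subject_strain, c("S01", "S02", "S01"))
  expect_equal(hits$percent_identity, c(80, 45, 30))
  expect_equal(hits$e_value, c(1e-50, 1e-10, 1e-3))
  expect_equal(hits$query_length, c(100, 100, 120))
})

test_that("empty and malformed hit files are handled precisely", {
  empty <- withr::local_tempfile(); writeLines(character(), empty)
  expect_equal(nrow(parse_hits(empty, c(q1 = 10))), 0)
  bad <- withr::local_tempfile()
  writeLines(c(hit_line("q1", "S01|p1", 80, 100, 1e-50, 200),
               paste("q2", "S01|p2", "80", "oops", "5", "0", "1", "100",
                     "1", "100", "not_a_number", "40", sep = "\t")), bad)
  expect_error(parse_hits(bad, c(q1 = 100, q2 = 100)), "line 2")
  short <- withr::local_tempfile()
  writeLines("q1\tS01|p1\t80", short)
  expect_error(parse_hits(short, c(q1 = 100)), "12")
  path <- withr::local_tempfile()
  writeLines(hit_line("mystery", "S01|p1", 80, 100, 1e-50, 200), path)
  expect_error(parse_hits(path, c(q1 = 100)), "mystery")
})

test_that("best hit is lowest e-value, ties by bit score then subject
           id", {
  path <- withr::local_tempfile()
  writeLines(c(hit_line("q1", "S01|a", 50, 80, 1e-3, 60),
               hit_line("q1", "S01|b", 60, 90, 1e-10, 100),
               hit_line("q2", "S01|hi", 50, 80, 1e-8, 120),
               hit_line("q2", "S01|lo", 50, 80, 1e-8, 90),
               hit_line("q3", "S01|zzz", 50, 80, 1e-8, 90),
               hit_line("q3", "S01|aaa", 50, 80, 1e-8, 90)), path)
  ql <- c(q1 = 100, q2 = 100, q3 = 100, q4 = 100)
  best <- best_hit_per_query(parse_hits(path, ql), "S01")
  expect_equal(best$subject_id[best$query_id == "q1"], "S01|b")
  expect_equal(best$subject_id[best$query_id == "q2"], "S01|hi")
  expect_equal(best$subject_id[best$query_id == "q3"], "S01|aaa")
  expect_false("q4" %in% best$query_id)  # no hits -> absent from map
})

test_that("threshold boundaries: identity and coverage inclusive,
           e-value strict", {
  ql <- c(qa = 100, qb = 100, qc = 100, qd = 100)
  path <- withr::local_tempfile()
  writeLines(c(hit_line("qa", "S01|1", 40.0, 50, 1e-6, 100),
               hit_line("qb", "S01|2", 39.9, 50, 1e-6, 100),
               hit_line("qc", "S01|3", 40.0, 49, 1e-6, 100),
               hit_line("qd", "S01|4", 40.0, 50, 1e-5, 100)), path)
  calls <- call_conservation(best_hit_per_query(parse_hits(path, ql)), ql)
  got <- stats::setNames(calls$conserved, calls$query_id)
  expect_true(got[["qa"]])    # exactly at both inclusive thresholds
  expect_false(got[["qb"]])   # identity below
  expect_false(got[["qc"]])   # coverage below
  expect_false(got[["qd"]])   # e-value not strictly below 1e-5
})

test_that("planted conserved fraction is recovered exactly", {
  tab <- make_hit_table(n_queries = 200, strains = "S01",
                        planted_fraction = 0.75, seed = 7)
  ql_df <- read.delim(tab$query_lengths)
  ql <- stats::setNames(ql_df$length, ql_df$query_id)
  hits <- parse_hits(tab$hits, ql)
  calls <- call_conservation(best_hit_per_query(hits, "S01"), ql)
  expect_identical(mean(calls$conserved), 0.75)
  expect_setequal(calls$query_id[calls$conserved], tab$conserved$S01)
})

test_that("tightening any threshold never increases a conservation
           fraction", {
  for (seed in 1:10) {
    tab <- make_hit_table(n_queries = 40, strains = c("S01", "S02"),
                          planted_fraction = c(S01 = 0.5, S02 = 0.25),
                          seed = seed)
    ql_df <- read.delim(tab$query_lengths)
    ql <- stats::setNames(ql_df$length, ql_df$query_id)
    hits <- parse_hits(tab$hits, ql)
    for (s in c("S01", "S02")) {
      best <- best_hit_per_query(hits, s)
      base <- mean(call_conservation(best, ql)$conserved)
      for (th in list(list(min_identity = 90), list(min_coverage = 0.99),
                      list(max_e = 1e-60))) {
        frac <- mean(do.call(call_conservation,
                             c(list(best, ql), th))$conserved)
        expect_lte(frac, base)
      }
    }
  }
})

test_that("summarize_conservation aggregates per strain and subsystem
           with the weighted-mean identity", {
  # 2 strains x 2 subsystems, hand-set calls
  calls <- data.frame(
    query_id = rep(c("q1", "q2", "q3", "q4"), 2),
    subject_strain = rep(c("A", "B"), each = 4),
    conserved = c(TRUE, TRUE, FALSE, TRUE,   # A: s1 = 1.0, s2 = 0.5
                  FALSE, TRUE, FALSE, FALSE),# B: s1 = 0.5, s2 = 0.0
    stringsAsFactors = FALSE)
  smap <- c(q1 = "s1", q2 = "s1", q3 = "s2", q4 = "s2")
  summ <- summarize_conservation(calls, smap)
  expect_equal(summ$matrix["A", "s1"], 1.0)
  expect_equal(summ$matrix["A", "s2"], 0.5)
  expect_equal(summ$matrix["B", "s1"], 0.5)
  expect_equal(summ$matrix["B", "s2"], 0.0)
  expect_equal(unname(summ$per_strain_fraction["A"]), 0.75)
  expect_equal(unname(summ$per_strain_fraction["B"]), 0.25)
  # per-strain = query-count-weighted mean of the subsystem cells
  for (s in c("A", "B")) {
    rows <- summ$per_subsystem[summ$per_subsystem$strain == s, ]
    expect_equal(sum(rows$fraction * rows$n_queries) / sum(rows$n_queries),
                 unname(summ$per_strain_fraction[s]))
  }
  # permutation invariance in row order
  perm <- calls[sample(nrow(calls)), ]
  summ2 <- summarize_conservation(perm, smap)
  expect_equal(summ2$matrix, summ$matrix)
  expect_error(summarize_conservation(calls, smap[-1]), "q1")
})

test_that("all-conserved input yields fractions of exactly 1", {
  calls <- data.frame(query_id = sprintf("q%d", 1:6),
                      subject_strain = "A", conserved = TRUE,
                      stringsAsFactors = FALSE)
  smap <- stats::setNames(rep(c("s1", "s2"), 3), calls$query_id)
  summ <- summarize_conservation(calls, smap)
  expect_true(all(summ$per_subsystem$fraction == 1))
  expect_identical(unname(summ$per_strain_fraction[["A"]]), 1)
})

test_that("non-homolog classes are mutually exclusive, exhaustive and
           follow the rescue rule", {
  calls <- data.frame(
    query_id = c("e1", "e2", "e3", "e4"),
    subject_strain = "A",
    conserved = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  remap <- list(R1 = c("e1", "e2"),   # e2 rescued by conserved e1
                R2 = c("e3"),          # e3 alone, flagged similar
                R3 = c("e4"))          # e4 alone, no flag
  cls <- classify_nonhomologs(calls, remap,
                              annotation_similarity = c(e3 = TRUE))
  expect_equal(sum(cls$counts), nrow(calls))
  got <- stats::setNames(cls$calls$class, cls$calls$query_id)
  expect_equal(unname(got[c("e1", "e2", "e3", "e4")]),
               c("homolog", "isozyme_rescued", "annotation_similar",
                 "absent"))
  # all conserved -> only homologs
  all_cons <- within(calls, conserved <- TRUE)
  cls2 <- classify_nonhomologs(all_cons, remap)
  expect_equal(unname(cls2$counts["homolog"]), 4L)
  expect_equal(sum(cls2$counts[c("isozyme_rescued", "annotation_similar",
                                 "absent")]), 0L)
})

test_that("class counts sum to the query count on planted tables", {
  tab <- make_hit_table(n_queries = 60, strains = "S01",
                        planted_fraction = 0.5, seed = 3)
  ql_df <- read.delim(tab$query_lengths)
  ql <- stats::setNames(ql_df$length, ql_df$query_id)
  calls <- call_conservation(
    best_hit_per_query(parse_hits(tab$hits, ql), "S01"), ql)
  remap <- split(calls$query_id, rep(1:20, each = 3))
  cls <- classify_nonhomologs(calls, remap)
  expect_equal(sum(cls$counts), 60L)
})
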