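orf_row <- function(start, end, strand, family) {
  data.frame(start = start, end = end, strand = strand, family = family,
             stringsAsFactors = FALSE)
}

toy_fosmid <- function(id, families, strands = rep("+", length(families)),
                       lib = "LIBX") {
  n <- length(families)
  orfs <- orf_row(seq(1, by = 100, length.out = n),
                  seq(80, by = 100, length.out = n), strands, families)
  fosmid_record(id, lib, strrep("ACGT", 30 * n + 30), orfs)
}

test_that("fosmid records enforce their coordinate and label invariants", {
  expect_error(fosmid_record("f1", "L", "ACGT",
                             orf_row(1, 10, "+", "GH3")), "insert length")
  expect_error(fosmid_record("f1", "L", strrep("A", 100),
                             orf_row(5, 2, "+", "GH3")), "start <= end")
  expect_error(fosmid_record("f1", "L", strrep("A", 100),
                             orf_row(1, 10, "*", "GH3")), "strand")
  expect_error(fosmid_record("f1", "L", strrep("A", 100),
                             orf_row(1, 10, "+", "GHx")), "family")
  f <- fosmid_record("f1", "L", strrep("A", 100),
                     orf_row(c(50, 1), c(60, 10), c("+", "-"), c("GH3", "CE1")))
  expect_equal(f$orfs$start, c(1, 50))   # re-sorted by start
})

test_that("pairwise identity is exact on trivial pairs and orientation-invariant", {
  set.seed(61)
  a <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  expect_equal(pairwise_identity(a, a), list(identity = 1, coverage = 1))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  both <- pairwise_identity(a, rc)
  expect_equal(both$identity, 1)
  # symmetry
  b <- mutate_sequence(a, 0.05)
  expect_equal(pairwise_identity(a, b)$identity,
               pairwise_identity(b, a)$identity, tolerance = 1e-9)
})

test_that("identity on substituted copies matches the column-count oracle", {
  set.seed(62)
  for (rate in c(0.03, 0.08)) {
    a <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    b <- mutate_sequence(a, rate)
    impl <- pairwise_identity(a, b, orientation = "forward")
    expect_equal(impl$identity, oracle_alignment_identity(a, b),
                 tolerance = 1e-9)
    # substitution-only copies: identity also matches the direct
    # per-position mismatch count (no alignment involved)
    direct <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expect_equal(impl$identity, direct, tolerance = 0.002)
  }

  # an 8% substituted copy sits near 92% identity, below the 95% threshold
  set.seed(63)
  a <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  b <- mutate_sequence(a, 0.08)
  pid <- pairwise_identity(a, b, orientation = "forward")
  expect_lt(abs(pid$identity - 0.92), 0.015)
  expect_lt(pid$identity, 0.95)
  expect_equal(pid$coverage, 1)
})

test_that("redundancy clustering partitions by the identity/coverage relation", {
  set.seed(64)
  base <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  unrelated <- replicate(2, paste(sample(c("A", "C", "G", "T"), 900, TRUE),
                                  collapse = ""))
  fos <- list(
    fosmid_record("A1", "L", base, orf_row(1, 10, "+", "GH3")),
    fosmid_record("A2", "L", base, orf_row(1, 10, "+", "GH3")),
    fosmid_record("A3", "L", base, orf_row(1, 10, "+", "GH3")),
    fosmid_record("B1", "L", unrelated[1], orf_row(1, 10, "+", "GH3")),
    fosmid_record("B2", "L", unrelated[2], orf_row(1, 10, "+", "GH3")))
  cs <- cluster_redundant(fos)
  expect_equal(cs$n_clusters, 3)
  sizes <- sort(vapply(cs$clusters, length, integer(1)))
  expect_equal(sizes, c(1, 1, 3))
  # representatives belong to their cluster
  for (i in seq_along(cs$clusters))
    expect_true(cs$representatives[i] %in% cs$clusters[[i]])

  # thresholds of 1.0 make every distinct fosmid its own cluster
  cs2 <- cluster_redundant(fos[3:5], id_thresh = 1.0, cov_thresh = 1.0)
  expect_equal(cs2$n_clusters, 3)

  # input order does not matter
  cs3 <- cluster_redundant(rev(fos))
  expect_equal(cs3$n_clusters, 3)
  canon <- function(cs) lapply(cs$clusters, sort)[order(vapply(cs$clusters, min, ""))]
  expect_identical(canon(cs3), canon(cs))

  # idempotence: clustering the representatives leaves them apart
  reps <- fos[match(cs$representatives, vapply(fos, `[[`, "", "fosmid_id"))]
  expect_equal(cluster_redundant(reps)$n_clusters, 3)
})

test_that("PUL detection requires the adjacent same-strand SusC/SusD pairing", {
  hit <- toy_fosmid("P1", c("unannotated", "SusC", "SusD", "GH3", "GH16"))
  calls <- detect_puls(hit)
  expect_length(calls, 1)
  expect_true(calls[[1]]$gh3_following)
  expect_true(calls[[1]]$gh16_or_gh144_present)
  expect_equal(calls[[1]]$susC_index, 2)
  expect_equal(calls[[1]]$susD_index, 3)

  # minus-strand cassette: coordinate order SusD, SusC; GH3 upstream in
  # coordinates is downstream transcriptionally
  minus <- toy_fosmid("P2", c("GH3", "SusD", "SusC", "unannotated"),
                      strands = c("-", "-", "-", "+"))
  calls2 <- detect_puls(minus)
  expect_length(calls2, 1)
  expect_true(calls2[[1]]$gh3_following)

  # opposite strands or reversed transcriptional order: no call
  expect_length(detect_puls(toy_fosmid("P3", c("SusC", "SusD"),
                                       strands = c("+", "-"))), 0)
  expect_length(detect_puls(toy_fosmid("P4", c("SusD", "SusC"))), 0)
  expect_length(detect_puls(toy_fosmid("P5", c("GH3", "GH16", "CE1"))), 0)

  # one intervening ORF only counts when relaxation is requested
  gap <- toy_fosmid("P6", c("SusC", "unannotated", "SusD", "GH3"))
  expect_length(detect_puls(gap), 0)
  expect_length(detect_puls(gap, max_intervening = 1), 1)
})

test_that("multi-GH flagging counts only GH families, boundary inclusive", {
  expect_true(detect_gh_clusters(
    toy_fosmid("m1", c("GH3", "GH3", "GH5", "GH43", "GH2")))$flagged)
  expect_false(detect_gh_clusters(
    toy_fosmid("m2", c("GH3", "GH3", "GH5", "GH43", "CE1", "CE4")))$flagged)
  expect_true(detect_gh_clusters(
    toy_fosmid("m3", c("GH3", "GH16")), min_gh = 2)$flagged)
})

test_that("GH abundance tables report counts and percentages of all ORFs", {
  fos <- list(
    toy_fosmid("g1", c("GH3", "GH3", "unannotated", "CE1"), lib = "L1"),
    toy_fosmid("g2", c("GH5", "unannotated", "unannotated", "unannotated"),
               lib = "L2"))
  tab <- tabulate_gh_abundance(fos)
  all_rows <- tab[tab$library_id == "all", ]
  expect_equal(all_rows$count[all_rows$family == "GH3"], 2)
  expect_equal(all_rows$percent[all_rows$family == "GH3"], 25.0)  # 2 of 8
  expect_equal(all_rows$percent[all_rows$family == "GH5"], 12.5)
  # family percents add to the total GH percent
  expect_equal(sum(all_rows$percent), 37.5, tolerance = 0.1)

  empty <- tabulate_gh_abundance(list())
  expect_equal(nrow(empty), 0)
})

test_that("hit-rate and dual-screen arithmetic reproduce the bookkeeping identities", {
  expect_equal(hit_rate(309504, 164), 1887L)
  expect_equal(hit_rate(18432, 77), 239L)
  expect_identical(hit_rate(7680, 0), NA_integer_)
  expect_error(hit_rate(10, 11), ">=")

  expect_equal(dual_screen_accounting(90, 77, 35),
               list(unique = 132, single_substrate = 97))
  expect_equal(dual_screen_accounting(41, 0, 0),
               list(unique = 41, single_substrate = 41))
  expect_equal(dual_screen_accounting(50, 50, 50),
               list(unique = 50, single_substrate = 0))
  expect_error(dual_screen_accounting(10, 5, 6), "overlap")
})

test_that("screen summaries assemble per-library rates, overlap and ORF stats", {
  libs <- data.frame(library_id = c("FOSA", "FOSB", "FOSC"),
                     clones = c(18432, 7680, 3456),
                     hits = c(77, 0, 4))
  fos <- list(toy_fosmid("s1", c("GH3", "GH5", "GH9", "GH43", "GH2", "CE1")),
              toy_fosmid("s2", c("GH3", "unannotated")))
  s <- screen_summary(libs, dual = c(hits_a = 90, hits_b = 77, both = 35),
                      fosmids = fos)
  expect_equal(s$per_library$clones_per_hit, c(239L, NA_integer_, 864L))
  expect_equal(s$total_clones, 29568)
  expect_equal(s$total_hits, 81)
  expect_equal(s$total_clones_per_hit, hit_rate(29568, 81))
  expect_equal(s$dual$unique, 132)
  expect_equal(s$dual$single_substrate, 97)
  expect_equal(s$orf_stats$total_orfs, 8)
  expect_equal(s$orf_stats$orfs_per_fosmid, 4.0)
  expect_equal(s$orf_stats$gh_orfs, 6)
  expect_equal(s$orf_stats$gh_percent, 75.0)
  expect_equal(s$orf_stats$fosmids_with_min_gh, 1)
  expect_equal(s$orf_stats$fosmids_with_min_gh_percent, 50.0)
})
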