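# Counting and normalization: (n/m)/k sharing, optional factors,
# conservation, distributions, output tables.

simple_engine <- function(n_features = 3L) {
  feats <- feature_tbl(paste0("f", seq_len(n_features)), "chrI",
                       100, 130, "+")
  rules <- read_rules(write_test_rules(rule_line(classify = "c",
                                                 overlap = "Nested")))
  build_engine(feats, rules, c(chrI = 400L))
}

test_that("(n/m)/k sharing and its optional factors follow the formula", {
  cases <- list(list(n = 6L, m = 2L, k = 3L), list(n = 4L, m = 1L, k = 1L),
                list(n = 10L, m = 5L, k = 2L))
  for (cs in cases) {
    eng <- simple_engine(cs$k)
    a <- aln_row(105, 127, seq_count = cs$n, n_alignments = cs$m)
    both <- assign_alignment(a, eng)
    expect_identical(nrow(both), cs$k)
    expect_equal(both$weight, rep((cs$n / cs$m) / cs$k, cs$k))
    no_m <- assign_alignment(a, eng, normalize_by_alignments = FALSE)
    expect_equal(no_m$weight, rep(cs$n / cs$k, cs$k))
    no_k <- assign_alignment(a, eng, normalize_by_features = FALSE)
    expect_equal(no_k$weight, rep(cs$n / cs$m, cs$k))
    neither <- assign_alignment(a, eng, FALSE, FALSE)
    expect_equal(neither$weight, rep(cs$n, cs$k))
  }
})

test_that("a feature passing two minimum-hierarchy rules splits its share", {
  feats <- feature_tbl("f1", "chrI", 100, 130, "+")
  rules <- read_rules(write_test_rules(c(
    rule_line(classify = "a", overlap = "Nested"),
    rule_line(classify = "b", overlap = "Partial"))))
  eng <- build_engine(feats, rules, c(chrI = 400L))
  res <- assign_alignment(aln_row(105, 127, seq_count = 4L), eng)
  expect_identical(nrow(res), 2L)
  expect_equal(res$weight, c(2, 2))
  expect_equal(sum(res$weight), 4)   # feature total conserves n
})

test_that("count_library conserves read mass and tallies distributions", {
  sc <- make_scenario("rrna_vs_sirna", seed = 2, out_dir = tempfile())
  cfg <- read_config(sc$paths$config)
  eng <- build_engine(sc$features, read_rules(sc$paths$rules),
                      sc$axis_lengths)
  lc <- count_library(sc$paths$sam[["lib1"]], eng, cfg)
  s <- lc$stats
  expect_equal(s$assigned_reads + s$unassigned_mapped_reads,
               s$mapped_reads, tolerance = 1e-12)
  expect_lte(s$mapped_reads, s$total_reads)
  # distribution counts raw n over assigned sequences only
  book <- sc$libraries$lib1
  assigned_n <- sum(lc$nt_len$count)
  expect_lte(assigned_n, s$mapped_reads)
  expect_identical(sum(lc$counts) > 0, TRUE)
})

test_that("the distribution table accumulates raw counts per (nt, length) cell", {
  feats <- feature_tbl("f1", "chrI", 100, 200, "+")
  rules <- read_rules(write_test_rules(rule_line(classify = "c",
                                                 overlap = "Nested")))
  eng <- build_engine(feats, rules, c(chrI = 400L))
  seq22 <- paste0("G", strrep("A", 21))
  p <- write_test_sam(c(
    sam_line("seq1_x3", 0, "chrI", 111, seq22, nh = 1, nm = 0),
    sam_line("seq2_x2", 0, "chrI", 131, substr(strrep("T", 24), 1, 24),
             nh = 1, nm = 0)))
  cfg <- as_config(list(samples = p, rules = p,
                        collapsed_format = "tiny-collapse"))
  lc <- count_library(p, eng, cfg)
  g22 <- lc$nt_len[lc$nt_len$nt == "G" & lc$nt_len$length == 22, ]
  expect_identical(g22$count, 3L)
  t24 <- lc$nt_len[lc$nt_len$nt == "T" & lc$nt_len$length == 24, ]
  expect_identical(t24$count, 2L)
})

test_that("rpm and custom normalization follow their definitions", {
  stats <- list(mapped_reads = 2e6)
  expect_equal(normalize_library(50, stats, "rpm"), 25)
  expect_equal(normalize_library(c(1, 2), stats, "custom", factor = 1),
               c(1, 2))
  expect_equal(normalize_library(3, stats, "custom", factor = 2.5), 7.5)
  expect_error(normalize_library(1, list(mapped_reads = 0), "rpm"),
               "mapped")
  expect_error(normalize_library(1, stats, "custom"), "norm_factor")
})

test_that("rpm rescales class totals to 1e6 x assigned/mapped", {
  out <- run_scenario("g22_g26", seed = 4, config_override = list(rpm = TRUE))
  res <- out$result
  for (lib in c("lib1", "lib2")) {
    s <- res$per_lib[[lib]]$stats
    expect_equal(sum(res$class_totals[[lib]]),
                 1e6 * s$assigned_reads / s$mapped_reads,
                 tolerance = 1e-9)
  }
})

test_that("output tables land on disk with one row per feature-classifier pair", {
  out <- run_scenario("mirna_isomir", seed = 6)
  d <- out$result$out_dir
  expect_true(all(file.exists(file.path(d, c(
    "feature_counts.csv", "rule_totals.csv", "class_totals.csv",
    "summary_stats.csv", "nt_len_lib1.csv", "nt_len_lib2.csv",
    "config.effective.yml", "run.log")))))
  fc <- read.csv(file.path(d, "feature_counts.csv"))
  # a feature matched by several classifiers appears once per classifier
  expect_gte(sum(fc$feature_id == "mir-1"), 4)
  expect_false(any(duplicated(paste(fc$feature_id, fc$classifier))))
  # fractional counts carry fixed 6-decimal formatting
  raw <- readLines(file.path(d, "feature_counts.csv"))[2]
  expect_match(raw, "\\d\\.\\d{6}")
})

test_that("a library with zero assigned reads still yields stats and zero columns", {
  feats <- feature_tbl("f1", "chrI", 100, 130, "+")
  # rule that nothing satisfies (length 30 reads only)
  rules_path <- write_test_rules(rule_line(classify = "c", len = "30",
                                           overlap = "Nested"))
  sam <- write_test_sam(sam_line("seq1_x5", 0, "chrI", 101,
                                 strrep("A", 22), nh = 1, nm = 0))
  gff <- write_test_gff("chrI\t.\tgene\t101\t130\t.\t+\t.\tID=f1")
  samples <- tempfile(fileext = ".csv")
  writeLines(c("file,name", paste0(basename(sam), ",libZ")), samples)
  file.copy(sam, file.path(dirname(samples), basename(sam)))
  cfg <- as_config(list(samples = samples, rules = rules_path, gff = gff,
                        out_dir = tempfile(), collapsed_format = "tiny-collapse"),
                   base_dir = dirname(samples))
  res <- run_count(cfg)
  expect_equal(res$counts$libZ, 0)
  expect_equal(res$per_lib$libZ$stats$assigned_reads, 0)
  stats <- read.csv(file.path(res$out_dir, "summary_stats.csv"))
  expect_true("libZ" %in% names(stats))
})

test_that("trace mode writes a per-read diagnostic table", {
  out <- run_scenario("rrna_vs_sirna", seed = 5,
                      config_override = list(trace = TRUE))
  tr_file <- file.path(out$result$out_dir, "trace_lib1.tsv")
  expect_true(file.exists(tr_file))
  tr <- read.delim(tr_file)
  expect_named(tr, c("read_id", "feature", "rule", "stage"))
  expect_true(all(tr$stage %in% c("stage2", "stage3", "hierarchy",
                                  "assigned")))
  expect_true(any(tr$stage == "assigned"))
})

test_that("an unwritable output directory aborts before any counting", {
  sc <- make_scenario("gffless", seed = 1, out_dir = tempfile())
  cfg <- read_config(sc$paths$config)
  blocker <- tempfile()
  writeLines("x", blocker)        # a plain file where a directory is needed
  cfg$out_dir <- file.path(blocker, "sub")
  expect_error(run_count(cfg), "writable")
})
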