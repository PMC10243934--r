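# Three-stage selection engine: window geometry, per-mode overlap
# semantics, read-attribute matching, hierarchy resolution, and
# equivalence with a monolithic single-pass evaluator.

mk_rules <- function(...) read_rules(write_test_rules(c(...)))

test_that("stage 1 pairs features with rules by attribute filters", {
  feats <- feature_tbl(c("mir-1", "g1"), "chrI", c(100, 200), c(122, 400),
                       c("+", "+"), type = c("miRNA", "gene"))
  rules <- mk_rules(rule_line(select = "Type", value = "miRNA",
                              classify = "miRNA"),
                    rule_line(select = "Type", value = "gene",
                              classify = "gene"),
                    rule_line(classify = "all"))
  cands <- stage1_select(feats, rules)
  got <- split(cands$feature_id, cands$rule_idx)
  expect_identical(got[["1"]], "mir-1")
  expect_identical(got[["2"]], "g1")
  expect_setequal(got[["3"]], c("mir-1", "g1"))
  # GFF-less mode bypasses the filters entirely
  expect_identical(nrow(stage1_select(feats, rules[1], gffless = TRUE)),
                   2L)
})

test_that("shifted windows follow feature orientation, including minus strand", {
  feats <- feature_tbl(c("fp", "fm"), "chrI", c(100, 100), c(122, 122),
                       c("+", "-"))
  # upstream promoter window: -1000 toward the 5' side
  rules <- mk_rules(rule_line(classify = "prom", overlap = "Nested, -1000, 0"))
  cands <- stage1_select(feats, rules)
  plus <- cands[cands$feature_id == "fp", ]
  minus <- cands[cands$feature_id == "fm", ]
  expect_identical(c(plus$wstart, plus$wend), c(-900L, 122L))
  expect_identical(c(minus$wstart, minus$wend), c(100L, 1122L))
  # clamping happens at index build
  idx <- build_index(cands, c(chrI = 400L))
  expect_identical(srnacount:::sv_query(idx$vectors$chrI, 0, 1),
                   plus$cand_id)
  # 5'-anchored window on a minus-strand feature: left edge start-shift3,
  # right edge end-shift5
  rules2 <- mk_rules(rule_line(classify = "iso",
                               overlap = "5' anchored, -1, 4"))
  c2 <- stage1_select(feats, rules2)
  m2 <- c2[c2$feature_id == "fm", ]
  expect_identical(c(m2$wstart, m2$wend), c(96L, 123L))
})

test_that("5'-anchored matching enforces the anchor and bounds 3' slack", {
  feats <- feature_tbl("mir-1", "chrI", 100, 122, "+", type = "miRNA")
  r0 <- mk_rules(rule_line(classify = "miRNA",
                           overlap = "5' anchored, 0, 4"))
  rm1 <- mk_rules(rule_line(classify = "isomiR",
                            overlap = "5' anchored, -1, 4"))
  c0 <- stage1_select(feats, r0)
  cm1 <- stage1_select(feats, rm1)
  pass2 <- function(aln, cands, rules) stage2_match(aln, cands, rules)
  # anchor exact, 2 nt of 3' extension within the 4 nt slack
  expect_true(pass2(aln_row(100, 124), c0, r0))
  # 5' end off by +1
  expect_false(pass2(aln_row(101, 120), c0, r0))
  # 6 nt of 3' extension exceeds the slack
  expect_false(pass2(aln_row(100, 128), c0, r0))
  # shifted rule wants the 5' end 1 nt upstream
  expect_true(pass2(aln_row(99, 124), cm1, rm1))
  expect_false(pass2(aln_row(100, 124), cm1, rm1))
})

test_that("exact overlap tolerates no deviation at either end", {
  feats <- feature_tbl("f", "chrI", 100, 130, "+")
  rules <- mk_rules(rule_line(classify = "x", overlap = "Exact"))
  cands <- stage1_select(feats, rules)
  expect_true(stage2_match(aln_row(100, 130), cands, rules))
  for (iv in list(c(99, 130), c(101, 130), c(100, 129), c(100, 131)))
    expect_false(stage2_match(aln_row(iv[1], iv[2]), cands, rules))
})

test_that("mismatch ranges gate stage 2", {
  feats <- feature_tbl("f", "chrI", 100, 130, "+")
  rules <- mk_rules(rule_line(classify = "strict", overlap = "Nested",
                              mm = "0"),
                    rule_line(classify = "loose", overlap = "Nested",
                              mm = "0-2"))
  cands <- stage1_select(feats, rules)
  got <- stage2_match(aln_row(105, 127, mismatches = 1), cands, rules)
  expect_identical(got, c(FALSE, TRUE))
})

test_that("stage 3 matches 5' nt, length and strand relative to the feature", {
  feats <- feature_tbl("g", "chrI", 100, 400, "+")
  rules <- mk_rules(rule_line(classify = "22G", strand = "Antisense",
                              nt5 = "G", len = "22", overlap = "Nested"))
  cands <- stage1_select(feats, rules)
  expect_true(stage3_match(aln_row(150, 172, "-", "G"), cands, rules))
  expect_false(stage3_match(aln_row(150, 172, "+", "G"), cands, rules))
  expect_false(stage3_match(aln_row(150, 172, "-", "A"), cands, rules))
  expect_false(stage3_match(aln_row(150, 176, "-", "G"), cands, rules))
  # ambiguity code N never satisfies a concrete selector
  expect_false(stage3_match(aln_row(150, 172, "-", "N"), cands, rules))
})

test_that("strandless features satisfy only strand-agnostic rules", {
  feats <- feature_tbl("f", "chrI", 100, 200, ".")
  rules <- mk_rules(rule_line(classify = "s", strand = "Sense"),
                    rule_line(classify = "a", strand = "Antisense"),
                    rule_line(classify = "any", strand = "Any"))
  cands <- stage1_select(feats, rules)
  got <- stage3_match(aln_row(120, 142), cands, rules)
  expect_identical(got, c(FALSE, FALSE, TRUE))
})

test_that("hierarchy resolution keeps minimum-hierarchy rules and splits shares", {
  passing <- data.frame(
    feature_id = c("rrn-1", "gene-1"), rule_idx = c(1L, 2L),
    hierarchy = c(1L, 2L), stringsAsFactors = FALSE)
  kept <- resolve_hierarchy(passing)
  expect_identical(kept$feature_id, "rrn-1")
  expect_identical(kept$k, 1L)
  # two distinct features tie at the minimum: k = 2
  tie <- data.frame(feature_id = c("m1", "m2"), rule_idx = c(1L, 1L),
                    hierarchy = c(1L, 1L), stringsAsFactors = FALSE)
  kept2 <- resolve_hierarchy(tie)
  expect_identical(nrow(kept2), 2L)
  expect_identical(unique(kept2$k), 2L)
  # one feature passing two minimum-hierarchy rules: r = 2 for both rows
  two_rules <- data.frame(feature_id = "m1", rule_idx = c(1L, 2L),
                          hierarchy = c(1L, 1L), stringsAsFactors = FALSE)
  kept3 <- resolve_hierarchy(two_rules)
  expect_identical(kept3$r, c(2L, 2L))
  expect_identical(unique(kept3$k), 1L)
})

test_that("hierarchy monotonicity: lowering a passing rule's value never drops it", {
  set.seed(5)
  for (rep in 1:50) {
    nfeat <- sample(1:4, 1)
    npass <- sample(1:5, 1)
    passing <- data.frame(
      feature_id = paste0("f", sample(nfeat, npass, replace = TRUE)),
      rule_idx = seq_len(npass),
      hierarchy = sample(1:4, npass, replace = TRUE),
      stringsAsFactors = FALSE)
    kept <- resolve_hierarchy(passing)
    pick <- sample(nrow(passing), 1)
    if (!(passing$rule_idx[pick] %in% kept$rule_idx[
        kept$feature_id == passing$feature_id[pick]])) next
    passing2 <- passing
    passing2$hierarchy[pick] <- max(1L, passing2$hierarchy[pick] - 1L)
    kept2 <- resolve_hierarchy(passing2)
    expect_true(any(kept2$feature_id == passing$feature_id[pick] &
                    kept2$rule_idx == passing$rule_idx[pick]))
  }
})

test_that("anchored rules with distinct 5' offsets are mutually exclusive", {
  feats <- feature_tbl(c("fp", "fm"), "chrI", c(100, 200), c(122, 222),
                       c("+", "-"))
  rules <- mk_rules(
    rule_line(classify = "m1", overlap = "5' anchored, -1, 4"),
    rule_line(classify = "z", overlap = "5' anchored, 0, 4"),
    rule_line(classify = "p1", overlap = "5' anchored, 1, 4"))
  cands <- stage1_select(feats, rules)
  set.seed(31)
  for (rep in 1:200) {
    start <- sample(90:230, 1)
    len <- sample(16:30, 1)
    aln <- aln_row(start, start + len, sample(c("+", "-"), 1))
    for (fid in c("fp", "fm")) {
      sub <- cands[cands$feature_id == fid, , drop = FALSE]
      expect_lte(sum(stage2_match(aln, sub, rules)), 1L)
    }
  }
})

test_that("staged evaluation equals a monolithic all-predicate check", {
  set.seed(97)
  modes <- c("Partial", "Nested, -20, 5", "Exact", "5' anchored, 0, 4",
             "5' anchored, -1, 4", "3' anchored, -4, 0")
  for (rep in 1:300) {
    fstart <- sample(50:150, 1); fend <- fstart + sample(20:80, 1)
    fstrand <- sample(c("+", "-", "."), 1)
    feats <- feature_tbl("f", "chrI", fstart, fend, fstrand)
    strand_req <- sample(c("Sense", "Antisense", "Any"), 1)
    nt_req <- sample(c("Any", "G", "A,G"), 1)
    len_req <- sample(c("Any", "18-26", "22"), 1)
    mm_req <- sample(c("Any", "0", "0-1"), 1)
    ov <- sample(modes, 1)
    rules <- mk_rules(rule_line(classify = "c", strand = strand_req,
                                nt5 = nt_req, len = len_req, overlap = ov,
                                mm = mm_req))
    cands <- stage1_select(feats, rules)
    start <- sample(40:220, 1); len <- sample(16:30, 1)
    aln <- aln_row(start, start + len, sample(c("+", "-"), 1),
                   sample(c("A", "C", "G", "T", "N"), 1),
                   mismatches = sample(0:2, 1))
    staged <- stage2_match(aln, cands, rules) &
      stage3_match(aln, cands, rules)
    # monolithic re-derivation from first principles
    r <- rules[[1]]
    plus <- fstrand != "-"
    ws <- if (plus) fstart + r$shift5 else fstart - r$shift3
    we <- if (plus) fend + r$shift3 else fend - r$shift5
    read5 <- if (aln$strand == "+") aln$start else aln$end - 1L
    read3 <- if (aln$strand == "+") aln$end - 1L else aln$start
    pos <- switch(r$mode,
      partial = aln$start < fend && aln$end > fstart,
      nested = aln$start >= ws && aln$end <= we,
      exact = aln$start == fstart && aln$end == fend,
      anchor5 = read5 == (if (plus) fstart + r$shift5 else
                          fend - 1L - r$shift5) &&
        (if (plus) read3 <= fend - 1L + r$shift3 else
           read3 >= fstart - r$shift3),
      anchor3 = read3 == (if (plus) fend - 1L + r$shift3 else
                          fstart - r$shift3) &&
        (if (plus) read5 >= fstart + r$shift5 else
           read5 <= fend - 1L - r$shift5))
    mono <- pos &&
      (is.null(r$mm) ||
         (aln$mismatches >= r$mm[1] && aln$mismatches <= r$mm[2])) &&
      (is.null(r$lengths) || aln$length %in% r$lengths) &&
      (is.null(r$nt5) || aln$five_prime_nt %in% r$nt5) &&
      (r$strand == "*" ||
         (fstrand != "." &&
            (if (r$strand == "S") aln$strand == fstrand
             else aln$strand != fstrand)))
    expect_identical(unname(staged), mono,
                     label = sprintf("rep %d (%s)", rep, ov))
  }
})

test_that("evaluating stage 3 before stage 2 yields the same assignments", {
  sc <- make_scenario("random", seed = 5, out_dir = tempfile())
  rules <- read_rules(sc$paths$rules)
  eng <- build_engine(sc$features, rules, sc$axis_lengths)
  aln <- read_sam(sc$paths$sam[["lib1"]], "tiny-collapse")$alignments
  for (i in seq_len(min(nrow(aln), 150))) {
    a <- lapply(aln, `[[`, i)
    hits <- query_index(eng$index, a$ref, a$start, a$end)
    if (!length(hits)) next
    cands <- eng$candidates[hits, , drop = FALSE]
    ab <- cands[stage2_match(a, cands, rules), , drop = FALSE]
    ab <- ab[stage3_match(a, ab, rules), , drop = FALSE]
    ba <- cands[stage3_match(a, cands, rules), , drop = FALSE]
    ba <- ba[stage2_match(a, ba, rules), , drop = FALSE]
    expect_identical(resolve_hierarchy(ab)$cand_id,
                     resolve_hierarchy(ba)$cand_id)
  }
})
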