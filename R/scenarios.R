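# Individual scenario builders. Each returns genome, axis lengths,
# feature table, structured rule spec and per-library read books; file
# writing and ground-truth computation happen in make_scenario().

.scenario_mirna_isomir <- function() {
  axis <- c(chrI = 400L)
  genome <- as.list(.rand_genome(axis))
  features <- .feature_table(
    c("mir-1", "mir-2"), "mirbase", "miRNA", "chrI",
    c(100L, 200L), c(122L, 222L), c("+", "-"))
  rule_spec <- list(
    .rule_spec("miRNA", 1, "anchor5", 0, 4, strand = "S", lengths = 16:28,
               field = "Type", value = "miRNA"),
    .rule_spec("isomiR_minus1", 1, "anchor5", -1, 4, strand = "S",
               lengths = 16:28, field = "Type", value = "miRNA"),
    .rule_spec("isomiR_plus1", 1, "anchor5", 1, 4, strand = "S",
               lengths = 16:28, field = "Type", value = "miRNA"),
    .rule_spec("miRNA_other", 9, "partial", strand = "S", lengths = 16:28,
               field = "Type", value = "miRNA"))
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    exts <- if (lib == "lib1") c(0L, 2L, 4L) else c(1L, 3L)
    for (o in c(-1L, 0L, 1L)) for (e in exts) {
      # plus-strand miRNA: 5' end at 100+o, 3' extension e
      .add_read(book, "chrI", 100L + o, 122L + e, "+", n = sample(1:5, 1))
      # minus-strand miRNA: 5' end at 221-o, 3' extension e past 200
      .add_read(book, "chrI", 200L - e, 222L - o, "-", n = sample(1:5, 1))
    }
    .add_read(book, "chrI", 103L, 125L, "+", n = 2L)   # 5' off by 3: catch-all
    .add_read(book, "chrI", 100L, 122L, "-", n = 3L)   # antisense: unassigned
    .add_read(book, "chrI", 300L, 322L, "+", n = 1L)   # off-feature: unassigned
    .add_read(book, NA, NA, NA, n = 2L, unmapped = TRUE)
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}

.scenario_rrna_vs_sirna <- function() {
  axis <- c(chrI = 600L)
  genome <- as.list(.rand_genome(axis))
  features <- .feature_table("rrn-1", "rfam", "rRNA", "chrI", 50L, 350L, "+")
  rule_spec <- list(
    .rule_spec("rRNA", 1, "partial", strand = "S",
               field = "Type", value = "rRNA"),
    .rule_spec("siRNA", 7, "partial", strand = "*",
               field = "Type", value = "rRNA"))
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    sense <- if (lib == "lib1")
      list(c(60L, 82L), c(100L, 130L), c(150L, 171L), c(220L, 244L),
           c(300L, 326L))
    else list(c(70L, 95L), c(140L, 162L), c(250L, 272L))
    anti <- if (lib == "lib1")
      list(c(80L, 102L), c(200L, 222L), c(260L, 282L))
    else list(c(90L, 112L), c(310L, 332L))
    for (iv in sense)
      .add_read(book, "chrI", iv[1], iv[2], "+", n = sample(1:6, 1))
    for (iv in anti)
      .add_read(book, "chrI", iv[1], iv[2], "-", n = sample(1:6, 1))
    .add_read(book, "chrI", 400L, 430L, "+", n = 2L)   # off-feature
    .add_read(book, NA, NA, NA, n = 1L, unmapped = TRUE)
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}

.scenario_g22_g26 <- function() {
  axis <- c(chrI = 600L)
  genome <- as.list(.rand_genome(axis))
  features <- .feature_table("gene-1", "wormbase", "gene", "chrI",
                             100L, 400L, "+")
  rule_spec <- list(
    .rule_spec("22G", 1, "nested", strand = "A", nt5 = "G", lengths = 22L,
               field = "Type", value = "gene"),
    .rule_spec("26G", 1, "nested", strand = "A", nt5 = "G", lengths = 26L,
               field = "Type", value = "gene"))
  g22_starts <- c(120L, 160L, 200L, 240L)
  g26_starts <- c(130L, 260L, 300L)
  for (s in g22_starts)
    genome <- .force_nt5(genome, "chrI", s, s + 22L, "-", "G")
  for (s in g26_starts)
    genome <- .force_nt5(genome, "chrI", s, s + 26L, "-", "G")
  genome <- .force_nt5(genome, "chrI", 180L, 202L, "+", "G")  # sense decoy
  genome <- .force_nt5(genome, "chrI", 340L, 362L, "-", "A")  # 5'A decoy
  genome <- .force_nt5(genome, "chrI", 210L, 234L, "-", "G")  # 24 nt decoy
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    s22 <- if (lib == "lib1") g22_starts else g22_starts[c(1L, 3L)]
    s26 <- if (lib == "lib1") g26_starts else g26_starts[c(2L, 3L)]
    for (s in s22) .add_read(book, "chrI", s, s + 22L, "-", n = sample(1:8, 1))
    for (s in s26) .add_read(book, "chrI", s, s + 26L, "-", n = sample(1:8, 1))
    .add_read(book, "chrI", 180L, 202L, "+", n = 3L)  # sense 5'G 22 nt
    .add_read(book, "chrI", 340L, 362L, "-", n = 2L)  # antisense 5'A 22 nt
    .add_read(book, "chrI", 210L, 234L, "-", n = 4L)  # antisense 5'G 24 nt
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}

.scenario_promoter <- function() {
  axis <- c(chrI = 2600L)
  genome <- as.list(.rand_genome(axis))
  features <- .feature_table(
    c("gene-1", "gene-2"), "refseq", "gene", "chrI",
    c(1100L, 1600L), c(1400L, 1900L), c("+", "-"))
  rule_spec <- list(
    .rule_spec("gene_body", 1, "nested", 0, 0, strand = "*",
               field = "Type", value = "gene"),
    .rule_spec("promoter_sRNA", 2, "nested", -1000, 0, strand = "*",
               field = "Type", value = "gene"))
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    body <- list(c(1150L, 1172L), c(1300L, 1326L), c(1700L, 1722L))
    upstream <- if (lib == "lib1")
      list(c(200L, 222L), c(600L, 624L), c(1050L, 1072L),  # gene-1 5' side
           c(2000L, 2022L), c(2400L, 2426L), c(2550L, 2572L))  # gene-2
    else list(c(450L, 474L), c(980L, 1002L), c(2100L, 2124L))
    for (iv in body)
      .add_read(book, "chrI", iv[1], iv[2], sample(c("+", "-"), 1),
                n = sample(1:4, 1))
    for (iv in upstream)
      .add_read(book, "chrI", iv[1], iv[2], sample(c("+", "-"), 1),
                n = sample(1:4, 1))
    .add_read(book, "chrI", 1090L, 1112L, "+", n = 2L)  # straddles gene-1 start
    .add_read(book, "chrI", 20L, 42L, "+", n = 1L)      # beyond both windows
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}

.scenario_multimapper <- function() {
  axis <- c(chrI = 700L)
  genome <- as.list(.rand_genome(axis))
  # three copies of the same 30 nt segment; only two are annotated
  seg <- substr(genome$chrI, 101L, 130L)
  for (at in c(301L, 501L)) substr(genome$chrI, at, at + 29L) <- seg
  features <- .feature_table(c("locus-1", "locus-2"), "custom", "locus",
                             "chrI", c(90L, 290L), c(140L, 340L),
                             c("+", "+"))
  rule_spec <- list(
    .rule_spec("sRNA", 1, "partial", strand = "*",
               field = "Type", value = "locus"))
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    n1 <- if (lib == "lib1") 4L else 6L
    .add_read(book, "chrI", NA, NA, "+", n = n1,
              loci = list(c(100L, 122L), c(300L, 322L)))
    .add_read(book, "chrI", NA, NA, "+", n = 2L,
              loci = list(c(105L, 127L), c(505L, 527L)))
    .add_read(book, "chrI", 310L, 332L, "+", n = 6L)
    .add_read(book, "chrI", NA, NA, "+", n = 3L,
              loci = list(c(100L, 124L), c(300L, 324L), c(500L, 524L)))
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}

.scenario_gffless <- function() {
  axis <- c(`mir-52` = 60L, `mir-53` = 58L, `let-7` = 70L)
  genome <- as.list(.rand_genome(axis))
  # features mirror what features_from_sam_header() derives from @SQ lines
  features <- .feature_table(names(axis), ".", "reference", names(axis),
                             0L, as.integer(axis), "+",
                             attributes = rep(list(list()), length(axis)))
  rule_spec <- list(
    .rule_spec("miRNA", 1, "nested", strand = "S", lengths = 16:30),
    .rule_spec("antisense_frag", 2, "partial", strand = "A"))
  libs <- list()
  for (lib in c("lib1", "lib2")) {
    book <- .read_book()
    ivs <- list(c("mir-52", 0L, 22L), c("mir-52", 1L, 23L),
                c("mir-52", 10L, 32L), c("mir-53", 5L, 27L),
                c("mir-53", 20L, 42L), c("let-7", 0L, 26L),
                c("let-7", 30L, 52L))
    if (lib == "lib2") ivs <- ivs[c(1L, 3L, 4L, 6L)]
    for (iv in ivs)
      .add_read(book, iv[1], as.integer(iv[2]), as.integer(iv[3]), "+",
                n = sample(1:10, 1))
    .add_read(book, "mir-52", 8L, 30L, "-", n = 2L)   # antisense fragment
    .add_read(book, "let-7", 0L, 35L, "+", n = 1L)    # too long: unassigned
    libs[[lib]] <- .book_to_lib(book, genome)
  }
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = TRUE, libraries = libs)
}

.scenario_random <- function(n_reads, n_features, n_rules) {
  axis <- c(chrI = 5000L, chrII = 3000L)
  genome <- as.list(.rand_genome(axis))
  refs <- sample(names(axis), n_features, replace = TRUE)
  width <- sample(60:300, n_features, replace = TRUE)
  fstart <- vapply(seq_len(n_features), function(i)
    sample.int(axis[[refs[i]]] - width[i], 1L) - 1L, integer(1))
  features <- .feature_table(
    sprintf("feat%03d", seq_len(n_features)),
    sample(c("src1", "src2"), n_features, replace = TRUE),
    sample(c("gene", "miRNA", "rRNA"), n_features, replace = TRUE),
    refs, fstart, fstart + width,
    sample(c("+", "-", "."), n_features, replace = TRUE,
           prob = c(0.45, 0.45, 0.1)))

  filt_pool <- list(c(NA, NA), c("Type", "gene"), c("Type", "miRNA"),
                    c("Type", "rRNA"), c("Source", "src1"))
  ov_pool <- list(list("partial", 0L, 0L), list("nested", 0L, 0L),
                  list("nested", -50L, 10L), list("anchor5", 0L, 4L),
                  list("anchor5", -1L, 4L), list("anchor3", -4L, 0L),
                  list("exact", 0L, 0L))
  len_pool <- list(NULL, 20:24, 22L, 26L, 18:30)
  nt_pool <- list(NULL, "G", c("A", "G"))
  mm_pool <- list(NULL, c(0L, 0L), c(0L, 1L))
  rule_spec <- lapply(seq_len(n_rules), function(j) {
    fv <- filt_pool[[sample.int(length(filt_pool), 1L)]]
    ov <- ov_pool[[sample.int(length(ov_pool), 1L)]]
    .rule_spec(sprintf("class%d", j), sample(1:3, 1L), ov[[1]], ov[[2]],
               ov[[3]], strand = sample(c("S", "A", "*"), 1L),
               nt5 = nt_pool[[sample.int(3L, 1L)]],
               lengths = len_pool[[sample.int(5L, 1L)]],
               mm = mm_pool[[sample.int(3L, 1L)]],
               field = fv[1], value = fv[2])
  })

  books <- list(lib1 = .read_book(), lib2 = .read_book())
  for (book in books) {
    for (i in seq_len(n_reads)) {
      len <- sample(18:28, 1L)
      strand <- sample(c("+", "-"), 1L)
      if (stats::runif(1) < 0.75) {
        f <- sample.int(n_features, 1L)
        ref <- features$ref[f]
        place <- sample(c("fiveprime", "inside", "exact"), 1L,
                        prob = c(0.35, 0.5, 0.15))
        if (place == "fiveprime") {
          off <- sample(-1:1, 1L)
          anchor <- if (features$strand[f] == "-")
            features$end[f] - 1L - off else features$start[f] + off
          start <- if (strand == "+") anchor else anchor + 1L - len
        } else if (place == "exact" &&
                   features$end[f] - features$start[f] <= 35L) {
          start <- features$start[f]
          len <- features$end[f] - features$start[f]
        } else {
          start <- sample(seq(features$start[f] - 20L,
                              features$end[f] + 20L - len), 1L)
        }
      } else {
        ref <- sample(names(axis), 1L)
        start <- sample.int(axis[[ref]] - len, 1L) - 1L
      }
      L <- axis[[ref]]
      start <- max(0L, min(as.integer(start), L - len))
      n <- sample(1:5, 1L)
      nm <- if (stats::runif(1) < 0.1) 1L else 0L
      if (stats::runif(1) < 0.1) {
        # multi-mapper: duplicate the segment on the other reference
        ref2 <- setdiff(names(axis), ref)[1]
        start2 <- sample.int(axis[[ref2]] - len, 1L) - 1L
        seg <- substr(genome[[ref]], start + 1L, start + len)
        substr(genome[[ref2]], start2 + 1L, start2 + len) <- seg
        .add_read(book, ref, NA, NA, strand, n = n, nm = nm,
                  loci = list(c(start, start + len)))
        book$alns[[length(book$alns)]]$ref <- ref
        book$alns[[length(book$alns) + 1L]] <- data.frame(
          seq_idx = length(book$seqs), ref = ref2, start = start2,
          end = start2 + len, strand = strand, nm = nm,
          stringsAsFactors = FALSE)
      } else {
        .add_read(book, ref, start, start + len, strand, n = n, nm = nm)
      }
    }
    for (u in 1:3) .add_read(book, NA, NA, NA, n = sample(1:3, 1L),
                             unmapped = TRUE)
  }
  libs <- lapply(books, .book_to_lib, genome = genome)
  list(genome = genome, axis_lengths = axis, features = features,
       rule_spec = rule_spec, gffless = FALSE, libraries = libs)
}
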