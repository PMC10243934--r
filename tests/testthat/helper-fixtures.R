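# In-code fixture builders shared across test files. All inputs are
# generated at test time; nothing is read from stored data files.

sam_line <- function(qname, flag, ref, pos1, seq, nh = NULL, nm = NULL) {
  tags <- c(if (!is.null(nh)) sprintf("NH:i:%d", nh),
            if (!is.null(nm)) sprintf("NM:i:%d", nm))
  paste(c(qname, flag, ref, pos1, 255, paste0(nchar(seq), "M"), "*", 0, 0,
          seq, strrep("I", nchar(seq)), tags), collapse = "\t")
}

sam_unmapped_line <- function(qname, seq = "ACGTACGTACGT") {
  paste(c(qname, 4, "*", 0, 0, "*", "*", 0, 0, seq,
          strrep("I", nchar(seq))), collapse = "\t")
}

write_test_sam <- function(records, refs = c(chrI = 400L),
                           path = tempfile(fileext = ".sam"),
                           header = TRUE) {
  lines <- character(0)
  if (header)
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  writeLines(c(lines, records), path)
  path
}

write_test_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# rules CSV from compact row descriptions
rules_header <- paste("Select for...,with value...,Classify as...,Hierarchy,",
                      "Strand,5' nt,Length,Overlap,Mismatches", sep = "")
rule_line <- function(select = "Any", value = "Any", classify, hierarchy = 1,
                      strand = "Any", nt5 = "Any", len = "Any",
                      overlap = "Partial", mm = "Any") {
  paste(sapply(c(select, value, classify, hierarchy, strand, nt5, len,
                 overlap, mm), function(x) sprintf('"%s"', x)),
        collapse = ",")
}
write_test_rules <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(rules_header, rows), path)
  path
}

# minimal feature table without going through a GFF file
feature_tbl <- function(feature_id, ref, start, end, strand,
                        type = "gene", source = ".", attributes = NULL) {
  out <- data.frame(feature_id = feature_id, source = source, type = type,
                    ref = ref, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  out$attributes <- if (is.null(attributes))
    lapply(feature_id, function(id) list(ID = id)) else attributes
  class(out) <- c("feature_table", class(out))
  out
}

aln_row <- function(start, end, strand = "+", nt5 = "A", mismatches = 0L,
                    seq_count = 1L, n_alignments = 1L, ref = "chrI",
                    read_id = "r1") {
  list(read_id = read_id, seq_count = seq_count, ref = ref,
       start = as.integer(start), end = as.integer(end), strand = strand,
       five_prime_nt = nt5, length = as.integer(end - start),
       mismatches = as.integer(mismatches),
       n_alignments = as.integer(n_alignments))
}

# 6-decimal fixed formatting used by the output writer
fmt6 <- function(x) sprintf("%.6f", x)

# engine counts table vs oracle counts table, byte-for-byte after
# formatting, with identical row sets
expect_counts_match_oracle <- function(engine_counts, oracle_counts, libs) {
  key_e <- paste(engine_counts$feature_id, engine_counts$classifier)
  key_o <- paste(oracle_counts$feature_id, oracle_counts$classifier)
  expect_setequal(key_e, key_o)
  o <- oracle_counts[match(key_e, key_o), , drop = FALSE]
  for (lib in libs) {
    expect_identical(fmt6(engine_counts[[lib]]), fmt6(o[[lib]]),
                     label = paste("library", lib))
  }
}

run_scenario <- function(name, seed = 1L, config_override = list()) {
  sc <- make_scenario(name, seed = seed, out_dir = tempfile("sc"))
  cfg <- read_config(sc$paths$config)
  for (k in names(config_override)) cfg[[k]] <- config_override[[k]]
  list(scenario = sc, result = run_count(cfg))
}
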