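# Deterministic synthetic-data generator. Each scenario builds a small
# genome, an annotation, a rule table and >= 2 SAM libraries (collapsed and
# expanded variants) with known ground truth, exercising one counting
# recipe: miRNA/isomiR anchored selection, structural-RNA filtering by
# hierarchy, 22G/26G class separation, promoter-window capture,
# multi-mapping (n/m)/k sharing, GFF-less direct-to-sequence counting, or
# a fully randomized mix. The ground truth comes from brute_force_assign(),
# an exhaustive per-alignment evaluator that shares no code with the
# staged engine or the interval index.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.rand_genome <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

.feature_table <- function(feature_id, source, type, ref, start, end, strand,
                           attributes = NULL) {
  out <- data.frame(feature_id = feature_id, source = source, type = type,
                    ref = ref, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  out$attributes <- if (is.null(attributes))
    lapply(feature_id, function(id) list(ID = id)) else attributes
  class(out) <- c("feature_table", class(out))
  out
}

# structured rule spec: same shape as read_rules() output; the CSV on disk
# is rendered FROM this, and the brute-force oracle consumes it directly
.rule_spec <- function(classifier, hierarchy, mode = "partial",
                       shift5 = 0L, shift3 = 0L, strand = "*", nt5 = NULL,
                       lengths = NULL, mm = NULL, field = NA_character_,
                       value = NA_character_) {
  list(field = field, value = value, classifier = classifier,
       hierarchy = as.integer(hierarchy), strand = strand, nt5 = nt5,
       lengths = lengths, mode = mode, shift5 = as.integer(shift5),
       shift3 = as.integer(shift3), mm = mm)
}

.fmt_intset <- function(v) {
  if (is.null(v)) return("Any")
  v <- sort(unique(v))
  runs <- split(v, cumsum(c(1L, diff(v) != 1L)))
  paste(vapply(runs, function(r)
    if (length(r) == 1L) as.character(r) else paste0(r[1], "-", r[length(r)]),
    character(1)), collapse = ",")
}

.render_rules_csv <- function(rule_spec, path) {
  rows <- lapply(rule_spec, function(r) {
    overlap <- switch(r$mode,
      partial = "Partial", exact = "Exact",
      nested = sprintf("Nested, %d, %d", r$shift5, r$shift3),
      anchor5 = sprintf("5' anchored, %d, %d", r$shift5, r$shift3),
      anchor3 = sprintf("3' anchored, %d, %d", r$shift5, r$shift3))
    data.frame(
      `Select for...` = if (is.na(r$field)) "Any" else r$field,
      `with value...` = if (is.na(r$value)) "Any" else r$value,
      `Classify as...` = r$classifier,
      Hierarchy = r$hierarchy,
      Strand = switch(r$strand, S = "Sense", A = "Antisense", "Any"),
      `5' nt` = if (is.null(r$nt5)) "Any" else paste(r$nt5, collapse = ","),
      Length = .fmt_intset(r$lengths),
      Overlap = overlap,
      Mismatches = if (is.null(r$mm)) "Any" else
        if (r$mm[1] == r$mm[2]) as.character(r$mm[1]) else
          paste0(r$mm[1], "-", r$mm[2]),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

# alignment-level read book-keeping during scenario construction
.read_book <- function() {
  env <- new.env(parent = emptyenv())
  env$seqs <- list()    # per sequence: n, unmapped
  env$alns <- list()    # per alignment: seq_idx, ref, start, end, strand, nm
  env
}

.add_read <- function(book, ref, start, end, strand = "+", n = 1L, nm = 0L,
                      loci = NULL, unmapped = FALSE) {
  idx <- length(book$seqs) + 1L
  book$seqs[[idx]] <- list(n = as.integer(n), unmapped = unmapped)
  if (!unmapped) {
    ivs <- if (is.null(loci)) list(c(start, end)) else loci
    for (iv in ivs) {
      book$alns[[length(book$alns) + 1L]] <- data.frame(
        seq_idx = idx, ref = ref, start = as.integer(iv[1]),
        end = as.integer(iv[2]), strand = strand, nm = as.integer(nm),
        stringsAsFactors = FALSE)
    }
  }
  idx
}

.book_to_lib <- function(book, genome) {
  n_seq <- length(book$seqs)
  seqs <- data.frame(
    seq_idx = seq_len(n_seq),
    n = vapply(book$seqs, `[[`, integer(1), "n"),
    unmapped = vapply(book$seqs, `[[`, logical(1), "unmapped"))
  alns <- if (length(book$alns)) do.call(rbind, book$alns) else
    data.frame(seq_idx = integer(0), ref = character(0), start = integer(0),
               end = integer(0), strand = character(0), nm = integer(0))
  alns$seq <- vapply(seq_len(nrow(alns)), function(i) {
    s <- substr(genome[[alns$ref[i]]], alns$start[i] + 1L, alns$end[i])
    if (alns$nm[i] > 0L) {
      # burn the declared mismatches into the stored sequence, away from
      # both ends so the 5' nt is untouched
      for (p in seq_len(alns$nm[i]) + 5L) {
        orig <- substr(s, p, p)
        sub <- setdiff(c("A", "C", "G", "T"), orig)[1]
        substr(s, p, p) <- sub
      }
    }
    s
  }, character(1))
  list(seqs = seqs, alignments = alns)
}

# genome editing helpers: force the base at a position (0-based) so a
# planned read gets the intended 5' nt
.force_nt5 <- function(genome, ref, start, end, strand, nt) {
  g <- genome[[ref]]
  if (strand == "+") {
    substr(g, start + 1L, start + 1L) <- nt
  } else {
    substr(g, end, end) <- .complement(nt)
  }
  genome[[ref]] <- g
  genome
}

.write_scenario_sam <- function(path, axis_lengths, lib, style) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(axis_lengths),
                     as.integer(axis_lengths)))
  seqs <- lib$seqs; alns <- lib$alignments
  m_of <- table(factor(alns$seq_idx, levels = seqs$seq_idx))
  rec <- function(qname, a) {
    flag <- if (a$strand == "-") 16L else 0L
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d\tNM:i:%d",
            qname, flag, a$ref, a$start + 1L, a$end - a$start, a$seq,
            strrep("I", a$end - a$start), as.integer(m_of[[a$seq_idx]]),
            a$nm)
  }
  unmapped_rec <- function(qname, len = 22L) {
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", qname,
            strrep("A", len), strrep("I", len))
  }
  for (i in seqs$seq_idx) {
    n <- seqs$n[i]
    qnames <- if (style == "collapsed") sprintf("seq%d_x%d", i, n)
              else sprintf("r%d.%d", i, seq_len(n))
    rows <- which(alns$seq_idx == i)
    for (q in qnames) {
      if (seqs$unmapped[i]) {
        lines <- c(lines, unmapped_rec(q))
      } else {
        for (j in rows) lines <- c(lines, rec(q, alns[j, , drop = FALSE]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic counting scenario
#'
#' Builds a complete, self-contained input set on disk: genome FASTA,
#' GFF3 annotation (except for the GFF-less scenario), rules CSV, sample
#' sheet, run configuration, two libraries as collapsed-read SAM files
#' (tiny-collapse style identifiers) plus an expanded one-record-per-read
#' twin of each, and a ground-truth TSV (`read_id`, `feature`,
#' `classifier`, `expected_weight`) computed by [brute_force_assign()].
#' The same seed always yields byte-identical files.
#'
#' Scenarios: `mirna_isomir` (5'-anchored rules with offsets -1/0/+1 and
#' 4 nt of 3' slack, on both feature strands), `rrna_vs_sirna`
#' (hierarchy-1 sense structural-RNA rule over a permissive antisense
#' rule), `g22_g26` (antisense 5'G reads split into 22 nt and 26 nt
#' classes), `promoter` (gene-body rule at hierarchy 1 plus a -1000 nt
#' shifted nested window at hierarchy 2), `multimapper` ((n/m)/k sharing
#' with an unannotated decoy locus), `gffless` (alignments directly to
#' reference hairpins), and `random` (randomized features, rules and reads
#' for property testing).
#'
#' @param name scenario name (see above).
#' @param seed integer seed; every random choice derives from it.
#' @param out_dir directory to write into (created; files go to
#'   `out_dir/<name>/`).
#' @param n_reads,n_features,n_rules sizes for the `random` scenario.
#' @return invisibly, the scenario object: a list with `genome`,
#'   `axis_lengths`, `features`, `rule_spec`, `gffless`, `libraries`,
#'   `paths` and `ground_truth`.
#' @export
make_scenario <- function(name = c("mirna_isomir", "rrna_vs_sirna",
                                   "g22_g26", "promoter", "multimapper",
                                   "gffless", "random"),
                          seed = 1L, out_dir = tempfile("scenario"),
                          n_reads = 200L, n_features = 20L, n_rules = 6L) {
  name <- match.arg(name)
  sc <- .with_seed(seed, switch(name,
    mirna_isomir = .scenario_mirna_isomir(),
    rrna_vs_sirna = .scenario_rrna_vs_sirna(),
    g22_g26 = .scenario_g22_g26(),
    promoter = .scenario_promoter(),
    multimapper = .scenario_multimapper(),
    gffless = .scenario_gffless(),
    random = .scenario_random(n_reads, n_features, n_rules)))
  sc$name <- name
  sc$seed <- seed
  .write_scenario(sc, file.path(out_dir, name))
}

.write_scenario <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(dir = dir)
  dna <- Biostrings::DNAStringSet(unlist(sc$genome))
  names(dna) <- names(sc$genome)
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(dna, paths$genome)
  if (!sc$gffless) {
    paths$gff <- file.path(dir, "features.gff3")
    write_gff(sc$features, paths$gff)
  }
  paths$rules <- file.path(dir, "rules.csv")
  .render_rules_csv(sc$rule_spec, paths$rules)
  libs <- names(sc$libraries)
  paths$sam <- character(0); paths$sam_expanded <- character(0)
  for (lib in libs) {
    p <- file.path(dir, paste0(lib, ".sam"))
    pe <- file.path(dir, paste0(lib, ".expanded.sam"))
    .write_scenario_sam(p, sc$axis_lengths, sc$libraries[[lib]], "collapsed")
    .write_scenario_sam(pe, sc$axis_lengths, sc$libraries[[lib]], "expanded")
    paths$sam[lib] <- p; paths$sam_expanded[lib] <- pe
  }
  paths$samples <- file.path(dir, "samples.csv")
  utils::write.csv(data.frame(file = basename(paths$sam), name = libs,
                              stringsAsFactors = FALSE),
                   paths$samples, row.names = FALSE, quote = TRUE)
  paths$config <- file.path(dir, "config.yml")
  cfg <- list(samples = "samples.csv", rules = "rules.csv",
              out_dir = "runs", collapsed_format = "tiny-collapse")
  if (!sc$gffless) cfg$gff <- "features.gff3"
  yaml::write_yaml(cfg, paths$config)
  sc$paths <- paths
  oracle <- brute_force_assign(sc)
  sc$ground_truth <- oracle$ground_truth
  paths$ground_truth <- file.path(dir, "ground_truth.tsv")
  utils::write.table(sc$ground_truth, paths$ground_truth, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sc$paths <- paths
  invisible(sc)
}
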