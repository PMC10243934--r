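# Per-library counting: route alignments through the interval index and
# the three-stage engine, apply (n/m)/k sharing, and accumulate counts,
# class totals, stats and 5' nt x length distributions.

#' Assemble the selection engine for a run
#'
#' @param features a `feature_table`.
#' @param rules a `selection_rules` object.
#' @param axis_lengths named integer vector of reference lengths (from the
#'   SAM header).
#' @param gffless bypass Stage 1 attribute filters (every feature pairs
#'   with every rule).
#' @return list with `candidates`, `index`, `rules`, `features`.
#' @export
build_engine <- function(features, rules, axis_lengths, gffless = FALSE) {
  candidates <- stage1_select(features, rules, gffless = gffless)
  index <- build_index(candidates, axis_lengths)
  list(candidates = candidates, index = index, rules = rules,
       features = features)
}

#' Assign one alignment to features
#'
#' Runs the alignment through the interval index and Stages 2-3, resolves
#' hierarchy, and computes each retained (feature, rule) pair's share of
#' the sequence's reads. A sequence with `n` read counts and `m` genomic
#' alignments contributes `(n/m)/k` reads per feature, where `k` is the
#' number of features passing selection at the locus; within a feature the
#' share is split evenly over its `r` passing minimum-hierarchy rules.
#' `m` and `k` are each optional: with `normalize_by_alignments = FALSE`
#' the full `n` is used at every locus, and with
#' `normalize_by_features = FALSE` every retained feature receives the full
#' `n/m`.
#'
#' @param aln one alignment row (list with `start`, `end`, `strand`,
#'   `five_prime_nt`, `length`, `mismatches`, `seq_count`, `n_alignments`,
#'   `ref`).
#' @param engine from [build_engine()].
#' @param normalize_by_alignments divide by `m`.
#' @param normalize_by_features divide by `k`.
#' @return data.frame with columns `feature_id`, `classifier`, `rule_idx`,
#'   `cand_id`, `weight`; zero rows when the alignment is unassigned at
#'   this locus.
#' @export
assign_alignment <- function(aln, engine, normalize_by_alignments = TRUE,
                             normalize_by_features = TRUE) {
  hits <- query_index(engine$index, aln$ref, aln$start, aln$end)
  empty <- data.frame(feature_id = character(0), classifier = character(0),
                      rule_idx = integer(0), cand_id = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  cands <- engine$candidates[hits, , drop = FALSE]
  s2 <- stage2_match(aln, cands, engine$rules)
  cands <- cands[s2, , drop = FALSE]
  if (!nrow(cands)) return(empty)
  s3 <- stage3_match(aln, cands, engine$rules)
  passing <- cands[s3, , drop = FALSE]
  if (!nrow(passing)) return(empty)
  res <- resolve_hierarchy(passing)
  m_eff <- if (normalize_by_alignments) aln$n_alignments else 1L
  k_eff <- if (normalize_by_features) res$k else 1L
  data.frame(feature_id = res$feature_id, classifier = res$classifier,
             rule_idx = res$rule_idx, cand_id = res$cand_id,
             weight = (aln$seq_count / m_eff) / (k_eff * res$r),
             stringsAsFactors = FALSE)
}

#' Count one library
#'
#' Streams the SAM file, assigns every mapped alignment, and accumulates
#' per-candidate weights, library statistics and the 5' nt x length
#' distribution. The distribution tallies raw read counts (`n`, not
#' normalized weights) once per sequence, restricted to sequences with at
#' least one assigned alignment unless `all_mapped_distributions` is set.
#' Unassigned mass is tracked in read-equivalents (`n/m` per unassigned
#' alignment), so `assigned + unassigned = mapped` holds exactly.
#'
#' @param sam_path path to the library's SAM file.
#' @param engine from [build_engine()].
#' @param config a `run_config` (or list with the same flags).
#' @return list with `counts` (numeric vector over candidate ids), `stats`
#'   (list), `nt_len` (data.frame `nt`, `length`, `count`), and `trace`
#'   (data.frame or NULL).
#' @export
count_library <- function(sam_path, engine, config = as_config(
                            list(samples = sam_path, rules = sam_path))) {
  rs <- read_sam(sam_path, config$collapsed_format)
  aln <- rs$alignments
  ncand <- nrow(engine$candidates)
  acc <- numeric(ncand)
  unassigned <- 0
  assigned_ids <- character(0)
  trace <- if (isTRUE(config$trace)) vector("list", nrow(aln)) else NULL
  for (i in seq_len(nrow(aln))) {
    a <- lapply(aln, `[[`, i)
    res <- assign_alignment(a, engine,
                            normalize_by_alignments = config$normalize_by_alignments,
                            normalize_by_features = config$normalize_by_features)
    if (nrow(res)) {
      acc[res$cand_id] <- acc[res$cand_id] + res$weight
      assigned_ids <- c(assigned_ids, a$read_id)
    } else {
      unassigned <- unassigned + a$seq_count / a$n_alignments
    }
    if (!is.null(trace)) trace[[i]] <- .trace_alignment(a, engine, res)
  }
  assigned_ids <- unique(assigned_ids)
  # per-sequence attributes for the distribution table (first record wins;
  # records of one sequence share length and 5' nt by construction)
  first <- !duplicated(aln$read_id)
  per_seq <- aln[first, c("read_id", "seq_count", "five_prime_nt", "length")]
  if (!isTRUE(config$all_mapped_distributions))
    per_seq <- per_seq[per_seq$read_id %in% assigned_ids, , drop = FALSE]
  nt_len <- if (nrow(per_seq)) {
    stats::aggregate(seq_count ~ five_prime_nt + length, data = per_seq,
                     FUN = sum)
  } else {
    data.frame(five_prime_nt = character(0), length = integer(0),
               seq_count = integer(0))
  }
  names(nt_len) <- c("nt", "length", "count")
  nt_len <- nt_len[order(nt_len$nt, nt_len$length), , drop = FALSE]
  rownames(nt_len) <- NULL
  stats <- list(
    total_sequences = rs$totals$total_sequences,
    total_reads = rs$totals$total_reads,
    mapped_sequences = rs$totals$mapped_sequences,
    mapped_reads = rs$totals$mapped_reads,
    assigned_reads = rs$totals$mapped_reads - unassigned,
    unassigned_mapped_reads = unassigned)
  list(counts = acc, stats = stats, nt_len = nt_len,
       trace = if (is.null(trace)) NULL else do.call(rbind, trace))
}

.trace_alignment <- function(a, engine, res) {
  hits <- query_index(engine$index, a$ref, a$start, a$end)
  if (!length(hits)) return(NULL)
  cands <- engine$candidates[hits, , drop = FALSE]
  s2 <- stage2_match(a, cands, engine$rules)
  s3 <- rep(FALSE, nrow(cands))
  s3[s2] <- stage3_match(a, cands[s2, , drop = FALSE], engine$rules)
  stage <- ifelse(!s2, "stage2", ifelse(!s3, "stage3", "hierarchy"))
  stage[cands$cand_id %in% res$cand_id] <- "assigned"
  data.frame(read_id = a$read_id, feature = cands$feature_id,
             rule = cands$rule_idx, stage = stage, stringsAsFactors = FALSE)
}

#' Library-level normalization
#'
#' @param column numeric vector of counts.
#' @param stats library stats from [count_library()].
#' @param mode `"none"`, `"rpm"` (reads per million mapped reads:
#'   `value * 1e6 / mapped_reads`, mapped reads counted once per sequence)
#'   or `"custom"` (multiply by a user factor, e.g. from spike-ins).
#' @param factor custom normalization factor (required for
#'   `mode = "custom"`).
#' @return the normalized vector.
#' @export
normalize_library <- function(column, stats, mode = c("none", "rpm", "custom"),
                              factor = NA_real_) {
  mode <- match.arg(mode)
  switch(mode,
    none = column,
    rpm = {
      if (!is.numeric(stats$mapped_reads) || stats$mapped_reads <= 0)
        stop("rpm normalization requires mapped_reads > 0")
      column * 1e6 / stats$mapped_reads
    },
    custom = {
      if (is.na(factor)) stop("custom normalization requires a norm_factor")
      column * factor
    })
}

.fmt_counts <- function(x) sprintf("%.6f", x)

#' Write all output tables for a completed run
#'
#' Writes `feature_counts.csv` (one row per (feature, classifier) pair),
#' `rule_totals.csv`, `class_totals.csv`, `summary_stats.csv` and one
#' `nt_len_<library>.csv` per library (5' nt x read length matrix of raw
#' assigned-read counts). Fractional counts are printed with fixed
#' 6-decimal precision.
#'
#' @param counts numeric matrix, rows = (feature, classifier) pairs
#'   (rownames unused), columns = libraries; with attributes `feature_id`
#'   and `classifier` vectors (see [run_count()]), or a data.frame with
#'   `feature_id` and `classifier` columns followed by library columns.
#' @param rule_totals data.frame `rule`, `classifier` + library columns.
#' @param class_totals data.frame `classifier` + library columns.
#' @param stats data.frame of summary statistics (stat x library).
#' @param nt_len_tables named list (library -> data.frame `nt`, `length`,
#'   `count`).
#' @param out_dir existing, writable output directory.
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(counts, rule_totals, class_totals, stats,
                          nt_len_tables, out_dir) {
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    written <<- c(written, p)
  }
  num_cols <- function(df) {
    for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- .fmt_counts(df[[j]])
    df
  }
  wr(num_cols(counts), "feature_counts.csv")
  wr(num_cols(rule_totals), "rule_totals.csv")
  wr(num_cols(class_totals), "class_totals.csv")
  wr(stats, "summary_stats.csv")
  for (lib in names(nt_len_tables)) {
    tab <- nt_len_tables[[lib]]
    lens <- if (nrow(tab)) sort(unique(tab$length)) else integer(0)
    mat <- matrix(0L, nrow = 5L, ncol = length(lens),
                  dimnames = list(c("A", "C", "G", "T", "N"),
                                  as.character(lens)))
    for (i in seq_len(nrow(tab)))
      mat[tab$nt[i], as.character(tab$length[i])] <- tab$count[i]
    df <- data.frame(nt = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    wr(df, paste0("nt_len_", lib, ".csv"))
  }
  invisible(written)
}

#' Run the full counting workflow
#'
#' Loads features (from the configured GFF, or from the SAM header of the
#' first library in GFF-less mode), assembles the candidate index once,
#' counts every library in the sample sheet, applies library-level
#' normalization (rpm when configured, otherwise a per-library custom
#' factor when present in the sample sheet), and writes all outputs into a
#' fresh timestamped directory under `out_dir` together with a copy of the
#' effective configuration (`config.effective.yml`) and a run log.
#'
#' @param config a `run_config`, a plain list of configuration values, or a
#'   path to a YAML configuration file.
#' @return invisibly, a list with `out_dir`, the assembled `counts`
#'   data.frame, `rule_totals`, `class_totals`, `stats`, `nt_len` tables
#'   and the `engine`.
#' @export
run_count <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- as_config(config)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  sheet <- read_sample_sheet(config$samples)
  missing <- sheet$file[!file.exists(sheet$file)]
  if (length(missing)) stop("SAM file(s) not found: ",
                            paste(missing, collapse = ", "))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, 2L) != 0L)
    stop("output directory is not writable: ", config$out_dir)
  run_dir <- .fresh_run_dir(config$out_dir)

  rules <- read_rules(config$rules)
  axis_lengths <- .sam_header_targets(sheet$file[1])
  gffless <- is.null(config[["gff"]])
  features <- if (gffless) {
    note("GFF-less mode: features taken from SAM header of ", sheet$file[1])
    features_from_sam_header(sheet$file[1])
  } else {
    read_gff(config[["gff"]], id_attr = config$gff_id_attr)
  }
  engine <- withCallingHandlers(
    build_engine(features, rules, axis_lengths, gffless = gffless),
    warning = function(w) { note("warning: ", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  if (length(engine$index$notes)) note(engine$index$notes)
  if (nrow(engine$candidates) == 0L)
    note("Stage 1 selected no (feature, rule) candidates")

  libs <- sheet$name
  per_lib <- vector("list", length(libs)); names(per_lib) <- libs
  for (i in seq_along(libs)) {
    per_lib[[i]] <- withCallingHandlers(
      count_library(sheet$file[i], engine, config),
      warning = function(w) { note("warning [", libs[i], "]: ",
                                   conditionMessage(w))
                              invokeRestart("muffleWarning") })
  }

  # normalization mode per library
  modes <- if (config$rpm) rep("rpm", nrow(sheet)) else
    ifelse(!is.na(sheet$norm_factor), "custom", "none")
  norm <- function(v, i) normalize_library(v, per_lib[[i]]$stats, modes[i],
                                           sheet$norm_factor[i])

  cands <- engine$candidates
  row_key <- paste(cands$feature_id, cands$classifier, sep = "\r")
  rows <- !duplicated(row_key)
  counts <- data.frame(feature_id = cands$feature_id[rows],
                       classifier = cands$classifier[rows],
                       stringsAsFactors = FALSE)
  rule_totals <- data.frame(
    rule = seq_along(rules),
    classifier = vapply(rules, `[[`, character(1), "classifier"),
    stringsAsFactors = FALSE)
  class_totals <- data.frame(
    classifier = unique(rule_totals$classifier), stringsAsFactors = FALSE)
  for (i in seq_along(libs)) {
    acc <- norm(per_lib[[i]]$counts, i)
    counts[[libs[i]]] <- as.numeric(
      tapply(acc, factor(match(row_key, row_key[rows]),
                         levels = seq_len(sum(rows))), sum, default = 0))
    rule_totals[[libs[i]]] <- as.numeric(
      tapply(acc, factor(cands$rule_idx, levels = seq_along(rules)), sum,
             default = 0))
    class_totals[[libs[i]]] <- as.numeric(
      tapply(acc, factor(cands$classifier,
                         levels = class_totals$classifier), sum,
             default = 0))
  }

  stat_names <- c("total_sequences", "total_reads", "mapped_sequences",
                  "mapped_reads", "assigned_reads",
                  "unassigned_mapped_reads")
  stats <- data.frame(stat = c(stat_names, "normalization",
                               "norm_factor"), stringsAsFactors = FALSE)
  for (i in seq_along(libs)) {
    s <- per_lib[[i]]$stats
    stats[[libs[i]]] <- c(
      vapply(stat_names, function(k) .fmt_counts(s[[k]]), character(1)),
      modes[i],
      if (modes[i] == "custom") .fmt_counts(sheet$norm_factor[i]) else "")
  }

  nt_len <- lapply(per_lib, `[[`, "nt_len")
  write_outputs(counts, rule_totals, class_totals, stats, nt_len, run_dir)
  yaml::write_yaml(.config_as_list(config), file.path(run_dir,
                                                      "config.effective.yml"))
  for (i in seq_along(libs)) {
    tr <- per_lib[[i]]$trace
    if (!is.null(tr))
      utils::write.table(tr, file.path(run_dir, paste0("trace_", libs[i],
                                                       ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(c(sprintf("run completed: %d librar%s, %d feature(s), %d rule(s)",
                       length(libs), if (length(libs) == 1) "y" else "ies",
                       nrow(features), length(rules)),
               log_lines),
             file.path(run_dir, "run.log"))
  invisible(list(out_dir = run_dir, counts = counts,
                 rule_totals = rule_totals, class_totals = class_totals,
                 stats = stats, nt_len = nt_len, engine = engine,
                 per_lib = per_lib))
}

.config_as_list <- function(cfg) {
  x <- unclass(cfg)
  x[!vapply(x, is.null, logical(1))]
}

.fresh_run_dir <- function(out_dir) {
  stamp <- format(Sys.time(), "%Y-%m-%d_%H-%M-%S")
  d <- file.path(out_dir, paste0("run_", stamp))
  k <- 1L
  while (dir.exists(d)) {
    k <- k + 1L
    d <- file.path(out_dir, paste0("run_", stamp, "-", k))
  }
  dir.create(d, recursive = TRUE)
  d
}
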