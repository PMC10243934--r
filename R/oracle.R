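# Brute-force reference assigner. Evaluates every (alignment, feature,
# rule) triple with a single monolithic predicate — no interval index, no
# staging — and applies minimum-hierarchy resolution and (n/m)/k sharing
# directly. It is deliberately quadratic and shares no code with the
# engine; the engine is tested against it.

# monolithic predicate: attribute filter + position + mismatches + read
# attributes, evaluated in one pass from first principles
.bf_pass <- function(ref, start, end, strand, nm, seq, f, rule, L,
                     gffless) {
  if (!gffless && !is.na(rule$field) && !is.na(rule$value)) {
    fl <- tolower(rule$field)
    ok <- if (fl == "source") identical(f$source, rule$value)
          else if (fl == "type") identical(f$type, rule$value)
          else rule$value %in% f$attributes[[rule$field]]
    if (!ok) return(FALSE)
  }
  if (!identical(ref, f$ref)) return(FALSE)
  len <- end - start
  read5 <- if (strand == "+") start else end - 1L
  read3 <- if (strand == "+") end - 1L else start
  plus <- f$strand != "-"
  s5 <- rule$shift5; s3 <- rule$shift3
  ws <- if (plus) f$start + s5 else f$start - s3
  we <- if (plus) f$end + s3 else f$end - s5
  ws <- max(0L, ws); we <- min(L, we)
  pos_ok <- switch(rule$mode,
    partial = start < f$end && end > f$start,
    nested = start >= ws && end <= we,
    exact = start == f$start && end == f$end,
    anchor5 = {
      a <- if (plus) f$start + s5 else f$end - 1L - s5
      t_ok <- if (plus) read3 <= f$end - 1L + s3 else read3 >= f$start - s3
      read5 == a && t_ok
    },
    anchor3 = {
      a <- if (plus) f$end - 1L + s3 else f$start - s3
      h_ok <- if (plus) read5 >= f$start + s5 else read5 <= f$end - 1L - s5
      read3 == a && h_ok
    })
  if (!pos_ok) return(FALSE)
  if (!is.null(rule$mm) && (nm < rule$mm[1] || nm > rule$mm[2]))
    return(FALSE)
  if (!is.null(rule$lengths) && !(len %in% rule$lengths)) return(FALSE)
  nt5 <- if (strand == "+") substr(seq, 1L, 1L)
         else .complement(substr(seq, len, len))
  if (!is.null(rule$nt5) && !(toupper(nt5) %in% rule$nt5)) return(FALSE)
  if (rule$strand == "*") return(TRUE)
  if (f$strand == ".") return(FALSE)
  if (rule$strand == "S") strand == f$strand else strand != f$strand
}

#' Brute-force reference assignment for a scenario
#'
#' Computes expected counts tables for every library of a synthetic
#' scenario by exhaustive per-alignment, per-feature, per-rule predicate
#' evaluation, with no interval index and no staged filtering. Serves as
#' the independent oracle the counting engine is validated against.
#'
#' @param scenario a scenario object from [make_scenario()].
#' @param normalize_by_alignments,normalize_by_features the optional `m`
#'   and `k` factors of the `(n/m)/k` share.
#' @return list with `counts` (data.frame `feature_id`, `classifier` +
#'   one column per library), `rule_totals`, `class_totals`, `stats`
#'   (per-library list: `mapped_reads`, `assigned_reads`,
#'   `unassigned_mapped_reads`) and `ground_truth` (data.frame `library`,
#'   `read_id`, `feature`, `classifier`, `expected_weight`, computed with
#'   both normalization factors on).
#' @export
brute_force_assign <- function(scenario, normalize_by_alignments = TRUE,
                               normalize_by_features = TRUE) {
  features <- scenario$features
  rules <- scenario$rule_spec
  axis <- scenario$axis_lengths
  gffless <- isTRUE(scenario$gffless)

  # (feature, rule) pairs surviving the attribute filter
  pairs <- list()
  for (j in seq_along(rules)) {
    for (i in seq_len(nrow(features))) {
      f <- c(as.list(features[i, c("feature_id", "source", "type", "ref",
                                   "start", "end", "strand")]),
             list(attributes = features$attributes[[i]]))
      keep <- gffless || is.na(rules[[j]]$field) || is.na(rules[[j]]$value)
      if (!keep) {
        fl <- tolower(rules[[j]]$field)
        keep <- if (fl == "source") identical(f$source, rules[[j]]$value)
                else if (fl == "type") identical(f$type, rules[[j]]$value)
                else rules[[j]]$value %in% f$attributes[[rules[[j]]$field]]
      }
      if (keep) pairs[[length(pairs) + 1L]] <-
          list(fi = i, rj = j, feature_id = f$feature_id,
               classifier = rules[[j]]$classifier)
    }
  }
  pair_df <- data.frame(
    fi = vapply(pairs, `[[`, integer(1), "fi"),
    rj = vapply(pairs, `[[`, integer(1), "rj"),
    feature_id = vapply(pairs, `[[`, character(1), "feature_id"),
    classifier = vapply(pairs, `[[`, character(1), "classifier"),
    stringsAsFactors = FALSE)

  libs <- names(scenario$libraries)
  pair_counts <- matrix(0, nrow = nrow(pair_df), ncol = length(libs),
                        dimnames = list(NULL, libs))
  # hoist per-pair feature/rule structs out of the alignment loop
  feat_structs <- lapply(seq_len(nrow(features)), function(i)
    c(as.list(features[i, c("feature_id", "source", "type", "ref",
                            "start", "end", "strand")]),
      list(attributes = features$attributes[[i]])))
  pair_f <- feat_structs[pair_df$fi]
  pair_r <- rules[pair_df$rj]
  pair_h <- vapply(pair_r, `[[`, integer(1), "hierarchy")
  np <- nrow(pair_df)
  stats <- list()
  gt <- list()
  for (lib in libs) {
    book <- scenario$libraries[[lib]]
    alns <- as.list(book$alignments)
    aln_of <- split(seq_along(alns$seq_idx), alns$seq_idx)
    unassigned <- 0
    mapped <- 0
    for (si in book$seqs$seq_idx) {
      if (book$seqs$unmapped[si]) next
      rows <- aln_of[[as.character(si)]]
      m <- length(rows)
      n <- book$seqs$n[si]
      mapped <- mapped + n
      read_id <- sprintf("seq%d_x%d", si, n)
      seq_assigned <- list()
      seq_total <- 0
      for (r in rows) {
        a <- list(ref = alns$ref[r], start = alns$start[r],
                  end = alns$end[r], strand = alns$strand[r],
                  nm = alns$nm[r], seq = alns$seq[r])
        pass <- logical(np)
        for (p in seq_len(np)) {
          pass[p] <- .bf_pass(a$ref, a$start, a$end, a$strand, a$nm, a$seq,
                              pair_f[[p]], pair_r[[p]],
                              axis[[a$ref]], gffless)
        }
        if (!any(pass)) {
          unassigned <- unassigned + n / m
          next
        }
        hmin <- min(pair_h[pass])
        kept <- which(pass & pair_h == hmin)
        k <- length(unique(pair_df$feature_id[kept]))
        r_of <- table(pair_df$feature_id[kept])
        m_eff <- if (normalize_by_alignments) m else 1L
        k_eff <- if (normalize_by_features) k else 1L
        for (p in kept) {
          w <- (n / m_eff) / (k_eff * as.integer(r_of[[pair_df$feature_id[p]]]))
          pair_counts[p, lib] <- pair_counts[p, lib] + w
          # ground truth always records the fully normalized share
          w_gt <- (n / m) / (k * as.integer(r_of[[pair_df$feature_id[p]]]))
          key <- paste(pair_df$feature_id[p], pair_df$classifier[p],
                       sep = "\r")
          seq_assigned[[key]] <- (seq_assigned[[key]] %||% 0) + w_gt
          seq_total <- seq_total + w_gt
        }
      }
      if (length(seq_assigned)) {
        for (key in names(seq_assigned)) {
          fc <- strsplit(key, "\r", fixed = TRUE)[[1]]
          gt[[length(gt) + 1L]] <- data.frame(
            library = lib, read_id = read_id, feature = fc[1],
            classifier = fc[2], expected_weight = seq_assigned[[key]],
            stringsAsFactors = FALSE)
        }
      }
      if (seq_total < n - 1e-9 || !length(seq_assigned)) {
        gt[[length(gt) + 1L]] <- data.frame(
          library = lib, read_id = read_id, feature = "*",
          classifier = "unassigned", expected_weight = n - seq_total,
          stringsAsFactors = FALSE)
      }
    }
    stats[[lib]] <- list(mapped_reads = mapped,
                         assigned_reads = mapped - unassigned,
                         unassigned_mapped_reads = unassigned)
  }

  key <- paste(pair_df$feature_id, pair_df$classifier, sep = "\r")
  first <- !duplicated(key)
  counts <- data.frame(feature_id = pair_df$feature_id[first],
                       classifier = pair_df$classifier[first],
                       stringsAsFactors = FALSE)
  rule_totals <- data.frame(
    rule = seq_along(rules),
    classifier = vapply(rules, `[[`, character(1), "classifier"),
    stringsAsFactors = FALSE)
  class_totals <- data.frame(classifier = unique(rule_totals$classifier),
                             stringsAsFactors = FALSE)
  for (lib in libs) {
    counts[[lib]] <- as.numeric(tapply(
      pair_counts[, lib], factor(match(key, key[first]),
                                 levels = seq_len(sum(first))),
      sum, default = 0))
    rule_totals[[lib]] <- as.numeric(tapply(
      pair_counts[, lib], factor(pair_df$rj, levels = seq_along(rules)),
      sum, default = 0))
    class_totals[[lib]] <- as.numeric(tapply(
      pair_counts[, lib], factor(pair_df$classifier,
                                 levels = class_totals$classifier),
      sum, default = 0))
  }
  list(counts = counts, rule_totals = rule_totals,
       class_totals = class_totals, stats = stats,
       ground_truth = do.call(rbind, gt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
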