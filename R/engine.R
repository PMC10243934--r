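# Three-stage selection engine.
#
# Stage 1 pairs features with rules by GFF attribute filters and
# precomputes each pair's positional match window. Stage 2 tests an
# alignment's positional overlap and mismatch count against a candidate.
# Stage 3 tests the read's own attributes (5' nt, length, strand relative
# to the feature). Hierarchy resolution keeps only minimum-hierarchy
# passers and determines the (n/m)/k share.

# Orientation convention for shifts: negative = toward the feature's 5'
# side (upstream), positive = toward its 3' side, in the FEATURE's
# orientation. For a '-'-strand feature this reverses genomic direction:
# shift5 moves the right genomic boundary rightward and shift3 moves the
# left genomic boundary leftward. Features with strand '.' are treated as
# '+' for window geometry.

.window_for <- function(fstart, fend, strand, shift5, shift3) {
  plus <- strand != "-"
  ws <- ifelse(plus, fstart + shift5, fstart - shift3)
  we <- ifelse(plus, fend + shift3, fend - shift5)
  cbind(ws, we)
}

.stage1_pass <- function(features, rule) {
  if (is.na(rule$field) || is.na(rule$value))
    return(rep(TRUE, nrow(features)))
  fld <- tolower(rule$field)
  if (fld == "source") return(features$source == rule$value)
  if (fld == "type") return(features$type == rule$value)
  vapply(features$attributes,
         function(a) rule$value %in% a[[rule$field]], logical(1))
}

#' Stage 1: pair features with rules and precompute match windows
#'
#' Creates one candidate per (feature, rule) pair whose feature satisfies
#' the rule's attribute filter (all features pair with all rules in
#' GFF-less mode, where Stage 1 is bypassed). Each candidate carries the
#' rule-shifted match window used by the interval index and by Stage 2.
#'
#' @param features a `feature_table` ([read_gff()] or
#'   [features_from_sam_header()]).
#' @param rules a `selection_rules` object ([read_rules()]).
#' @param gffless if `TRUE`, skip attribute filtering entirely.
#' @return data.frame of candidates: `cand_id`, `feature_id`, `classifier`,
#'   `rule_idx`, `hierarchy`, `ref`, `fstart`, `fend`, `fstrand`, `mode`,
#'   `shift5`, `shift3`, `wstart`, `wend`.
#' @export
stage1_select <- function(features, rules, gffless = FALSE) {
  out <- vector("list", length(rules))
  for (j in seq_along(rules)) {
    rule <- rules[[j]]
    pass <- if (gffless) rep(TRUE, nrow(features)) else .stage1_pass(features, rule)
    idx <- which(pass)
    if (!length(idx)) next
    w <- .window_for(features$start[idx], features$end[idx],
                     features$strand[idx], rule$shift5, rule$shift3)
    out[[j]] <- data.frame(
      feature_id = features$feature_id[idx],
      classifier = rule$classifier,
      rule_idx = j, hierarchy = rule$hierarchy,
      ref = features$ref[idx],
      fstart = features$start[idx], fend = features$end[idx],
      fstrand = features$strand[idx],
      mode = rule$mode, shift5 = rule$shift5, shift3 = rule$shift3,
      wstart = w[, 1], wend = w[, 2],
      stringsAsFactors = FALSE)
  }
  cands <- do.call(rbind, out)
  if (is.null(cands))
    cands <- data.frame(feature_id = character(0), classifier = character(0),
                        rule_idx = integer(0), hierarchy = integer(0),
                        ref = character(0), fstart = integer(0),
                        fend = integer(0), fstrand = character(0),
                        mode = character(0), shift5 = integer(0),
                        shift3 = integer(0), wstart = integer(0),
                        wend = integer(0), stringsAsFactors = FALSE)
  cands <- cands[order(cands$rule_idx, cands$ref, cands$fstart,
                       cands$fend, cands$feature_id), , drop = FALSE]
  cands$cand_id <- seq_len(nrow(cands))
  rownames(cands) <- NULL
  cands
}

#' Stage 2: positional-overlap and mismatch test
#'
#' Vectorized over candidate rows for a single alignment. Mode semantics
#' (all coordinates 0-based half-open, anchors compared as the coordinate
#' of the terminal included base):
#' * `partial`: at least 1 nt intersection with the feature interval;
#' * `nested`: alignment interval contained in the shifted window;
#' * `exact`: alignment interval equals the unshifted feature interval;
#' * `anchor5`: the read's 5' end equals the feature's 5' end shifted by
#'   `shift5` in feature orientation, and the read's 3' end extends at most
#'   `shift3` nt past the feature's 3' end (negative `shift3` = must stop
#'   short);
#' * `anchor3`: mirror image.
#'
#' @param aln one alignment (list or single data.frame row with `start`,
#'   `end`, `strand`, `mismatches`).
#' @param cands candidate rows (subset of [stage1_select()] output).
#' @param rules the `selection_rules` object.
#' @return logical vector, one per candidate row.
#' @export
stage2_match <- function(aln, cands, rules) {
  as <- aln$start; ae <- aln$end
  read5 <- if (aln$strand == "+") as else ae - 1L
  read3 <- if (aln$strand == "+") ae - 1L else as
  plus <- cands$fstrand != "-"
  pos <- logical(nrow(cands))

  m <- cands$mode == "partial"
  pos[m] <- as < cands$fend[m] & ae > cands$fstart[m]
  m <- cands$mode == "nested"
  pos[m] <- as >= cands$wstart[m] & ae <= cands$wend[m]
  m <- cands$mode == "exact"
  pos[m] <- as == cands$fstart[m] & ae == cands$fend[m]
  m <- cands$mode == "anchor5"
  if (any(m)) {
    anchor <- ifelse(plus[m], cands$fstart[m] + cands$shift5[m],
                     cands$fend[m] - 1L - cands$shift5[m])
    tail_ok <- ifelse(plus[m],
                      read3 <= cands$fend[m] - 1L + cands$shift3[m],
                      read3 >= cands$fstart[m] - cands$shift3[m])
    pos[m] <- read5 == anchor & tail_ok
  }
  m <- cands$mode == "anchor3"
  if (any(m)) {
    anchor <- ifelse(plus[m], cands$fend[m] - 1L + cands$shift3[m],
                     cands$fstart[m] - cands$shift3[m])
    head_ok <- ifelse(plus[m],
                      read5 >= cands$fstart[m] + cands$shift5[m],
                      read5 <= cands$fend[m] - 1L - cands$shift5[m])
    pos[m] <- read3 == anchor & head_ok
  }

  mm_ok <- vapply(cands$rule_idx, function(j) {
    mm <- rules[[j]]$mm
    is.null(mm) || (aln$mismatches >= mm[1] && aln$mismatches <= mm[2])
  }, logical(1))
  pos & mm_ok
}

#' Stage 3: read-attribute test
#'
#' Checks the read's length, 5' nucleotide and strand relative to the
#' feature. The ambiguity code `N` never satisfies a concrete nucleotide
#' selector; features with undefined strand (`.`) satisfy only rules whose
#' strand requirement is `Any`.
#'
#' @inheritParams stage2_match
#' @return logical vector, one per candidate row.
#' @export
stage3_match <- function(aln, cands, rules) {
  vapply(seq_len(nrow(cands)), function(i) {
    rule <- rules[[cands$rule_idx[i]]]
    if (!is.null(rule$lengths) && !(aln$length %in% rule$lengths))
      return(FALSE)
    if (!is.null(rule$nt5) && !(aln$five_prime_nt %in% rule$nt5))
      return(FALSE)
    fs <- cands$fstrand[i]
    if (rule$strand == "*") return(TRUE)
    if (fs == ".") return(FALSE)
    if (rule$strand == "S") aln$strand == fs else aln$strand != fs
  }, logical(1))
}

#' Resolve hierarchy among passing candidates at one locus
#'
#' Keeps only candidates whose rule hierarchy equals the minimum over all
#' passers. `k` is the number of distinct features retained; a feature
#' passing several minimum-hierarchy rules has its share split evenly
#' across those rules (`r` per feature), so feature-level totals do not
#' depend on how rules subdivide a class.
#'
#' @param passing data.frame with columns `feature_id`, `rule_idx`,
#'   `hierarchy` (and any others, carried through).
#' @return the retained rows with added columns `k` (distinct features) and
#'   `r` (rules per feature among the retained rows).
#' @export
resolve_hierarchy <- function(passing) {
  if (nrow(passing) == 0L) {
    passing$k <- integer(0); passing$r <- integer(0)
    return(passing)
  }
  hmin <- min(passing$hierarchy)
  kept <- passing[passing$hierarchy == hmin, , drop = FALSE]
  kept$k <- length(unique(kept$feature_id))
  tab <- table(kept$feature_id)
  kept$r <- as.integer(tab[kept$feature_id])
  kept
}
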