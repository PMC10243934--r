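# SAM ingestion. Files are converted to coordinate-sorted BAM in a session
# temp directory via Rsamtools and scanned from there; conversions are
# cached per path for the lifetime of the session.

.sam_cache <- new.env(parent = emptyenv())

.sam_to_bam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  key <- normalizePath(path)
  hit <- .sam_cache[[key]]
  if (!is.null(hit) && file.exists(hit$bam) &&
      identical(hit$mtime, file.mtime(path)))
    return(hit$bam)
  dest <- tempfile(fileext = "")
  bam <- tryCatch(
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE),
    error = function(e) stop("failed to read SAM file '", path,
                             "' (missing or invalid header?): ",
                             conditionMessage(e)))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (!length(hdr$targets))
    stop("SAM file '", path, "' has no @SQ header lines")
  .sam_cache[[key]] <- list(bam = bam, mtime = file.mtime(path))
  bam
}

.sam_header_targets <- function(path) {
  bam <- .sam_to_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  tg <- hdr$targets
  if (is.null(tg)) integer(0) else tg
}

.complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

# seq_count extraction from collapsed read identifiers.
# tiny-collapse style: "<prefix>_count=<int>" or "seq<idx>_x<int>";
# FASTX style: "<id>-<int>".
.collapsed_patterns <- list(
  `tiny-collapse` = c("_count=([0-9]+)$", "^seq[0-9]+_x([0-9]+)$"),
  fastx = c("-([0-9]+)$"))

.match_count <- function(ids, patterns) {
  out <- rep(NA_integer_, length(ids))
  for (p in patterns) {
    m <- regmatches(ids, regexec(p, ids))
    v <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_,
                integer(1))
    out[is.na(out)] <- v[is.na(out)]
  }
  out
}

.parse_seq_counts <- function(ids, collapsed_format, path) {
  if (collapsed_format == "none" || !length(ids))
    return(rep(1L, length(ids)))
  if (collapsed_format == "auto") {
    probe <- unique(ids)[seq_len(min(100L, length(unique(ids))))]
    for (fmt in names(.collapsed_patterns)) {
      if (!anyNA(.match_count(probe, .collapsed_patterns[[fmt]])))
        return(.parse_seq_counts(ids, fmt, path))
    }
    warning("read identifiers in '", path,
            "' match no known collapsed format; treating counts as 1")
    return(rep(1L, length(ids)))
  }
  counts <- .match_count(ids, .collapsed_patterns[[collapsed_format]])
  if (anyNA(counts)) {
    bad <- ids[which(is.na(counts))[1]]
    stop("read ID '", bad, "' in '", path,
         "' does not match collapsed format '", collapsed_format, "'")
  }
  counts
}

#' Read a SAM file into an alignment table
#'
#' Each mapped record becomes one row with a strand-aware 0-based half-open
#' genomic interval and read attributes used by the selection engine.
#' Alignments are assumed ungapped and end-to-end (Bowtie v1 style), so the
#' aligned length equals the stored sequence length. The 5' nucleotide of a
#' minus-strand alignment is the complement of the last base of the stored
#' (reference-orientation) sequence.
#'
#' Per-sequence read counts (`n`) are extracted from collapsed read
#' identifiers when `collapsed_format` is not `"none"`; `"auto"` probes the
#' first 100 distinct identifiers against the tiny-collapse and FASTX
#' conventions and falls back to 1 with a warning if neither matches
#' consistently. The number of genomic alignments per sequence (`m`) comes
#' from the `NH` tag when present, otherwise from grouping records by read
#' identifier in a pre-pass. Mismatch counts come from the `NM` tag; a
#' missing tag yields 0 with a one-time warning per file.
#'
#' Unmapped records (FLAG 0x4) contribute to library totals but are not
#' emitted as alignments.
#'
#' @param path path to a SAM file (header required).
#' @param collapsed_format one of `"auto"`, `"tiny-collapse"`, `"fastx"`,
#'   `"none"`.
#' @return list with `alignments` (data.frame: `read_id`, `seq_count`,
#'   `ref`, `start`, `end`, `strand`, `five_prime_nt`, `length`,
#'   `mismatches`, `n_alignments`), sorted by coordinate then read id, and
#'   `totals` (list: `total_sequences`, `total_reads`, `mapped_reads`,
#'   `mapped_sequences`).
#' @export
read_sam <- function(path,
                     collapsed_format = c("auto", "tiny-collapse",
                                          "fastx", "none")) {
  collapsed_format <- match.arg(collapsed_format)
  bam <- .sam_to_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq"),
    tag = c("NH", "NM"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  qname <- res$qname
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  all_ids <- unique(qname)
  id_counts <- .parse_seq_counts(all_ids, collapsed_format, path)
  names(id_counts) <- all_ids

  mapped_ids <- unique(qname[!unmapped])
  totals <- list(
    total_sequences = length(all_ids),
    total_reads = sum(id_counts),
    mapped_sequences = length(mapped_ids),
    mapped_reads = sum(id_counts[mapped_ids]))

  keep <- !unmapped
  if (!any(keep)) {
    aln <- data.frame(read_id = character(0), seq_count = integer(0),
                      ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      five_prime_nt = character(0), length = integer(0),
                      mismatches = integer(0), n_alignments = integer(0),
                      stringsAsFactors = FALSE)
    return(list(alignments = aln, totals = totals))
  }
  qn <- qname[keep]
  seqs <- as.character(res$seq[keep])
  strand <- ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+")
  qw <- res$qwidth[keep]
  start <- res$pos[keep] - 1L
  nm <- res$tag$NM[keep]
  if (is.null(nm)) nm <- rep(NA_integer_, sum(keep))
  if (anyNA(nm)) {
    warning("NM tag missing for some records in '", path,
            "'; assuming 0 mismatches")
    nm[is.na(nm)] <- 0L
  }
  nh <- res$tag$NH[keep]
  if (is.null(nh) || anyNA(nh)) {
    tab <- table(qn)
    nh <- as.integer(tab[qn])
  }
  last <- substr(seqs, qw, qw)
  nt5 <- ifelse(strand == "+", substr(seqs, 1L, 1L), .complement(last))
  aln <- data.frame(
    read_id = qn,
    seq_count = as.integer(id_counts[qn]),
    ref = as.character(res$rname[keep]),
    start = start, end = start + qw, strand = strand,
    five_prime_nt = toupper(nt5), length = as.integer(qw),
    mismatches = as.integer(nm), n_alignments = as.integer(nh),
    stringsAsFactors = FALSE)
  ord <- order(aln$ref, aln$start, aln$end, aln$strand, aln$read_id)
  aln <- aln[ord, , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln, totals = totals)
}
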