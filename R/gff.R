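#' Read a GFF3 annotation into a feature table
#'
#' Parses a GFF3 file (via rtracklayer) and converts coordinates from GFF
#' 1-based closed to the 0-based half-open convention used everywhere inside
#' the engine. All column-9 attribute keys are retained as a key -> values
#' map (multi-valued attributes split on commas per the GFF3 grammar).
#'
#' Feature identifiers are taken from the `ID` attribute, falling back to
#' `id_attr` when `ID` is absent, and finally to
#' `<ref>:<start>-<end>:<strand>`.
#'
#' @param path path to a GFF3 file.
#' @param id_attr attribute key used as feature id when `ID` is missing.
#' @return data.frame of class `feature_table` with columns `feature_id`,
#'   `source`, `type`, `ref`, `start` (0-based), `end` (exclusive),
#'   `strand` (`+`/`-`/`.`) and list-column `attributes`.
#' @export
read_gff <- function(path, id_attr = "sequence_name") {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  .validate_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  reserved <- c("source", "type", "score", "phase")
  attr_cols <- setdiff(names(mc), reserved)
  n <- length(gr)
  attributes <- vector("list", n)
  for (i in seq_len(n)) {
    a <- list()
    for (k in attr_cols) {
      v <- mc[[k]][i]
      v <- as.character(if (methods::is(v, "List")) unlist(v) else v)
      v <- v[!is.na(v)]
      if (length(v)) a[[k]] <- v
    }
    attributes[[i]] <- a
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  ref <- as.character(GenomicRanges::seqnames(gr))
  feature_id <- vapply(seq_len(n), function(i) {
    a <- attributes[[i]]
    if (!is.null(a[["ID"]])) return(a[["ID"]][1])
    if (!is.null(a[[id_attr]])) return(a[[id_attr]][1])
    sprintf("%s:%d-%d:%s", ref[i], start0[i], end0[i], strand[i])
  }, character(1))
  out <- data.frame(
    feature_id = feature_id,
    source = as.character(mc$source),
    type = as.character(mc$type),
    ref = ref, start = start0, end = end0, strand = strand,
    stringsAsFactors = FALSE)
  out$attributes <- attributes
  if (any(out$end <= out$start)) stop("GFF feature with end <= start")
  if (any(!nzchar(out$feature_id))) stop("empty feature id in GFF")
  class(out) <- c("feature_table", class(out))
  out
}

# light structural pre-scan so malformed lines are reported with a number;
# full attribute parsing is rtracklayer's job
.validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l) || startsWith(l, "#")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("GFF line %d: expected >= 8 tab-separated columns", ln))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("GFF line %d: non-numeric coordinates", ln))
    if (e < s)
      stop(sprintf("GFF line %d: end (%d) < start (%d)", ln, e, s))
  }
  invisible(TRUE)
}

#' Write a feature table back to GFF3
#'
#' Inverse of [read_gff()] up to attribute ordering: coordinates are
#' converted back to GFF 1-based closed.
#'
#' @param features a `feature_table`.
#' @param path output path.
#' @export
write_gff <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$ref,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand == ".", "*", features$strand))
  mc <- S4Vectors::DataFrame(
    source = features$source, type = features$type,
    score = NA_real_, phase = NA_integer_)
  keys <- unique(unlist(lapply(features$attributes, names)))
  for (k in keys) {
    mc[[k]] <- IRanges::CharacterList(lapply(features$attributes, function(a) {
      if (is.null(a[[k]])) character(0) else a[[k]]
    }))
  }
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Derive one feature per reference sequence from a SAM header
#'
#' GFF-less mode: when no annotation is supplied, each `@SQ` reference
#' sequence is treated as a single plus-strand feature spanning its full
#' length, and attribute-based feature retrieval is bypassed (every feature
#' pairs with every rule). Used for alignments made directly to small RNA
#' or transcript sequences rather than to a genome.
#'
#' @param sam_path path to a SAM file with `@SQ` header lines (`SN`, `LN`).
#' @return a `feature_table` with one row per reference sequence.
#' @export
features_from_sam_header <- function(sam_path) {
  targets <- .sam_header_targets(sam_path)
  if (!length(targets)) stop("SAM header has no @SQ lines: ", sam_path)
  out <- data.frame(
    feature_id = names(targets),
    source = ".", type = "reference",
    ref = names(targets), start = 0L, end = as.integer(targets),
    strand = "+", stringsAsFactors = FALSE)
  out$attributes <- rep(list(list()), nrow(out))
  class(out) <- c("feature_table", class(out))
  out
}
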