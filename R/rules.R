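#' Read a selection-rule table
#'
#' Each CSV row defines one selection rule with three groups of criteria:
#' feature-attribute filters applied when features are loaded from a GFF
#' ("Select for..." / "with value..."), a positional-overlap and mismatch
#' selector applied per alignment locus ("Overlap", "Mismatches"), and
#' read-attribute filters ("5' nt", "Length", "Strand"). "Hierarchy" is a
#' positive integer: among all rules a read satisfies at a locus, only the
#' minimum-hierarchy ones receive counts. "Classify as..." labels the
#' output rows for feature-rule pairs.
#'
#' The Overlap column accepts `Partial`, `Exact`, `Nested[, shift5, shift3]`,
#' `5' anchored[, shift5, shift3]` and `3' anchored[, shift5, shift3]`.
#' Shifts are signed nt offsets expressed in the feature's orientation:
#' negative values move toward the feature's 5' side (upstream), positive
#' toward its 3' side. `Partial` and `Exact` do not admit nonzero shifts.
#' The literal value `Any` (case-insensitive, or an empty cell) is a
#' wildcard in the attribute-filter, 5' nt, Length, Strand and Mismatches
#' columns.
#'
#' @param path path to the rules CSV. Expected header:
#'   `Select for...,with value...,Classify as...,Hierarchy,Strand,5' nt,Length,Overlap,Mismatches`
#' @return an object of class `selection_rules`: a list with one parsed
#'   rule per CSV row, in file order.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("Select for...", "with value...", "Classify as...",
                "Hierarchy", "Strand", "5' nt", "Length", "Overlap",
                "Mismatches")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("rules CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("at least one rule required")
  rules <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rules[[i]] <- .parse_rule_row(df[i, , drop = FALSE], i)
  }
  class(rules) <- "selection_rules"
  rules
}

.is_wild <- function(x) {
  x <- trimws(x)
  is.na(x) || x == "" || tolower(x) == "any"
}

.rule_err <- function(row, msg) stop(sprintf("rules CSV row %d: %s", row, msg))

.parse_rule_row <- function(r, i) {
  hier <- suppressWarnings(as.integer(trimws(r[["Hierarchy"]])))
  if (is.na(hier) || hier < 1L) .rule_err(i, "Hierarchy must be a positive integer")
  ov <- .parse_overlap(r[["Overlap"]], i)
  field_raw <- trimws(r[["Select for..."]])
  value_raw <- trimws(r[["with value..."]])
  field <- if (.is_wild(field_raw)) NA_character_ else field_raw
  value <- if (.is_wild(value_raw)) NA_character_ else value_raw
  list(
    index = i,
    field = field,                 # NA = wildcard; "Source"/"Type"/attribute key
    value = value,                 # NA = wildcard
    classifier = trimws(r[["Classify as..."]]),
    hierarchy = hier,
    strand = .parse_rule_strand(r[["Strand"]], i),
    nt5 = .parse_nt5(r[["5' nt"]], i),
    lengths = .parse_lengths(r[["Length"]], i),
    mode = ov$mode, shift5 = ov$shift5, shift3 = ov$shift3,
    mm = .parse_mismatches(r[["Mismatches"]], i)
  )
}

.parse_overlap <- function(s, i) {
  if (.is_wild(s)) return(list(mode = "partial", shift5 = 0L, shift3 = 0L))
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  kw <- tolower(parts[1])
  mode <- switch(kw,
    "partial" = "partial", "nested" = "nested", "exact" = "exact",
    "5' anchored" = "anchor5", "5' anchor" = "anchor5",
    "3' anchored" = "anchor3", "3' anchor" = "anchor3",
    .rule_err(i, paste0("unknown overlap keyword '", parts[1], "'")))
  shifts <- c(0L, 0L)
  if (length(parts) > 3L) .rule_err(i, "too many overlap fields")
  if (length(parts) >= 2L) {
    sv <- suppressWarnings(as.integer(parts[-1]))
    if (anyNA(sv)) .rule_err(i, "overlap shifts must be integers")
    shifts[seq_along(sv)] <- sv
  }
  if (mode %in% c("partial", "exact") && any(shifts != 0L))
    .rule_err(i, paste0(parts[1], " overlap does not accept nonzero shifts"))
  list(mode = mode, shift5 = shifts[1], shift3 = shifts[2])
}

.parse_rule_strand <- function(s, i) {
  if (.is_wild(s)) return("*")
  switch(tolower(trimws(s)),
         "sense" = "S", "antisense" = "A",
         .rule_err(i, paste0("Strand must be Sense, Antisense or Any, got '",
                             s, "'")))
}

.parse_nt5 <- function(s, i) {
  if (.is_wild(s)) return(NULL)
  nts <- toupper(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  bad <- setdiff(nts, c("A", "C", "G", "T"))
  if (length(bad))
    .rule_err(i, paste0("5' nt selector must list A/C/G/T, got '",
                        paste(bad, collapse = ","), "'"))
  unique(nts)
}

.parse_int_ranges <- function(s, what, i, min_allowed) {
  items <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  out <- integer(0)
  for (it in items) {
    m <- regmatches(it, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", it))[[1]]
    if (length(m) == 3L) {
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (hi < lo) .rule_err(i, paste0("empty ", what, " range '", it, "'"))
      out <- c(out, lo:hi)
    } else {
      v <- suppressWarnings(as.integer(it))
      if (is.na(v)) .rule_err(i, paste0("malformed ", what, " value '", it, "'"))
      out <- c(out, v)
    }
  }
  if (any(out < min_allowed))
    .rule_err(i, paste0(what, " values must be >= ", min_allowed))
  sort(unique(out))
}

.parse_lengths <- function(s, i) {
  if (.is_wild(s)) return(NULL)
  v <- .parse_int_ranges(s, "Length", i, 1L)
  if (!length(v)) .rule_err(i, "Length set is empty")
  v
}

.parse_mismatches <- function(s, i) {
  if (.is_wild(s)) return(NULL)
  v <- .parse_int_ranges(s, "Mismatches", i, 0L)
  c(min(v), max(v))
}
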