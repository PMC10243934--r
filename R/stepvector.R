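#' Piecewise-constant genomic interval index
#'
#' A step vector partitions a reference axis `[0, L)` into consecutive,
#' non-overlapping steps, each carrying the set of candidate identifiers
#' whose match window covers every position in the step. Queries return the
#' union of step sets overlapped by the query interval, i.e. exactly the
#' candidates whose window intersects the query in at least one position.
#' Adjacent steps with identical sets are always merged, so the structure is
#' a canonical normal form independent of insertion order.
#'
#' @param starts,ends integer vectors of candidate window coordinates,
#'   0-based half-open, already clamped to `[0, L)`.
#' @param ids integer candidate identifiers, parallel to `starts`.
#' @param L axis length in nt.
#' @return An object of class `step_vector` with elements `breaks` (step
#'   boundaries, length `n_steps + 1`, first 0 and last `L`) and `sets`
#'   (list of sorted integer vectors, one per step).
#' @keywords internal
step_vector <- function(starts, ends, ids, L) {
  stopifnot(length(starts) == length(ends), length(ids) == length(starts))
  if (L <= 0L) stop("axis length must be positive")
  keep <- ends > starts
  starts <- as.integer(starts[keep]); ends <- as.integer(ends[keep])
  ids <- as.integer(ids[keep])
  breaks <- sort(unique(c(0L, L, starts, ends)))
  n_steps <- length(breaks) - 1L
  sets <- rep(list(integer(0)), n_steps)
  if (length(ids)) {
    j1 <- match(starts, breaks)
    j2 <- match(ends, breaks) - 1L
    step_of <- sequence(j2 - j1 + 1L, from = j1)
    id_rep <- rep(ids, j2 - j1 + 1L)
    got <- split(id_rep, step_of)
    idx <- as.integer(names(got))
    sets[idx] <- lapply(got, function(v) sort(unique(v)))
  }
  sv <- list(breaks = breaks, sets = sets, L = as.integer(L))
  class(sv) <- "step_vector"
  .sv_canonicalize(sv)
}

# merge adjacent steps carrying identical sets (canonical form)
.sv_canonicalize <- function(sv) {
  n <- length(sv$sets)
  if (n <= 1L) return(sv)
  same <- vapply(seq_len(n - 1L),
                 function(j) identical(sv$sets[[j]], sv$sets[[j + 1L]]),
                 logical(1))
  if (!any(same)) return(sv)
  keep <- c(TRUE, !same)  # keep first step of each run
  sv$sets <- sv$sets[keep]
  sv$breaks <- c(sv$breaks[c(keep, FALSE)], sv$L)
  sv
}

#' Query a step vector for candidates overlapping an interval
#'
#' @param sv a `step_vector`.
#' @param start,end 0-based half-open query interval. Out-of-axis queries
#'   are clamped with a warning (reads may slightly overhang contig ends).
#' @return sorted integer vector of candidate ids whose window intersects
#'   `[start, end)` in at least one position.
#' @keywords internal
sv_query <- function(sv, start, end) {
  if (end <= start) stop("query interval must be non-empty")
  if (start < 0L || end > sv$L) {
    warning(sprintf("query [%d,%d) clamped to axis [0,%d)", start, end, sv$L))
    start <- max(start, 0L); end <- min(end, sv$L)
    if (end <= start) return(integer(0))
  }
  j1 <- findInterval(start, sv$breaks)
  j2 <- findInterval(end - 1L, sv$breaks)
  sort(unique(unlist(sv$sets[j1:j2], use.names = FALSE)))
}

#' Build per-reference step vectors from candidate match windows
#'
#' Windows are clamped to their reference axis; a clamp past position 0 or
#' beyond the contig end (e.g. a -1000 promoter shift near a contig edge)
#' is recorded as a note. Candidates whose window is empty after clamping
#' are dropped.
#'
#' @param candidates a candidate table as produced by [stage1_select()],
#'   with columns `ref`, `wstart`, `wend` and one row per candidate id.
#' @param axis_lengths named integer vector, reference name -> length.
#' @return An object of class `feature_index`: a named list of
#'   `step_vector`s plus the axis lengths.
#' @export
build_index <- function(candidates, axis_lengths) {
  unknown <- setdiff(unique(candidates$ref), names(axis_lengths))
  if (length(unknown))
    stop("unknown reference name(s) in candidates: ",
         paste(unknown, collapse = ", "))
  notes <- character(0)
  svs <- list()
  for (ref in names(axis_lengths)) {
    L <- as.integer(axis_lengths[[ref]])
    sel <- which(candidates$ref == ref)
    ws <- pmax(candidates$wstart[sel], 0L)
    we <- pmin(candidates$wend[sel], L)
    clamped <- sel[candidates$wstart[sel] < 0L | candidates$wend[sel] > L]
    if (length(clamped))
      notes <- c(notes, sprintf(
        "%d candidate window(s) on %s clamped to [0,%d)", length(clamped), ref, L))
    svs[[ref]] <- step_vector(ws, we, sel, L)
  }
  idx <- list(vectors = svs, axis_lengths = axis_lengths, notes = notes)
  class(idx) <- "feature_index"
  idx
}

#' Query a feature index
#'
#' @param index a `feature_index` from [build_index()].
#' @param ref reference sequence name.
#' @param start,end 0-based half-open interval.
#' @return integer vector of candidate row ids.
#' @export
query_index <- function(index, ref, start, end) {
  sv <- index$vectors[[ref]]
  if (is.null(sv)) return(integer(0))
  sv_query(sv, start, end)
}

#' Dump a feature index as a step table
#'
#' Debug view: one row per step with its candidate ids comma-joined.
#'
#' @param index a `feature_index`.
#' @return data.frame with columns `ref`, `start`, `end`, `candidate_ids`.
#' @export
index_dump <- function(index) {
  out <- lapply(names(index$vectors), function(ref) {
    sv <- index$vectors[[ref]]
    n <- length(sv$sets)
    data.frame(
      ref = ref,
      start = sv$breaks[seq_len(n)],
      end = sv$breaks[seq_len(n) + 1L],
      candidate_ids = vapply(sv$sets, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
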