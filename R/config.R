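#' Read a run configuration file
#'
#' YAML keys: `samples` (sample sheet CSV, required), `rules` (rules CSV,
#' required), `gff` (optional; when absent the run is GFF-less and features
#' come from the SAM header), `out_dir` (default `"."`),
#' `normalize_by_alignments` (default `TRUE`), `normalize_by_features`
#' (default `TRUE`), `rpm` (default `FALSE`), `collapsed_format` (default
#' `"auto"`), `all_mapped_distributions` (default `FALSE`), `trace`
#' (default `FALSE`), `gff_id_attr` (default `"sequence_name"`). Relative
#' paths are resolved against the configuration file's directory.
#'
#' @param path path to a YAML configuration file.
#' @return a validated named list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  as_config(raw, base_dir = base)
}

#' Build a run configuration from a list
#'
#' @param x named list of configuration values (see [read_config()]).
#' @param base_dir directory against which relative paths are resolved.
#' @return a validated `run_config`.
#' @export
as_config <- function(x, base_dir = ".") {
  defaults <- list(
    samples = NULL, rules = NULL, gff = NULL, out_dir = ".",
    normalize_by_alignments = TRUE, normalize_by_features = TRUE,
    rpm = FALSE, collapsed_format = "auto",
    all_mapped_distributions = FALSE, trace = FALSE,
    gff_id_attr = "sequence_name")
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x[!vapply(x, is.null, logical(1))])
  if (is.null(cfg$samples)) stop("config requires 'samples'")
  if (is.null(cfg$rules)) stop("config requires 'rules'")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|~)", p)) p <- file.path(base_dir, p)
    p
  }
  cfg$samples <- resolve(cfg$samples)
  cfg$rules <- resolve(cfg$rules)
  cfg[["gff"]] <- resolve(cfg[["gff"]])
  cfg$out_dir <- resolve(cfg$out_dir)
  for (k in c("samples", "rules", "gff")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured ", k, " file not found: ", cfg[[k]])
  }
  cfg$collapsed_format <- match.arg(cfg$collapsed_format,
                                    c("auto", "tiny-collapse", "fastx", "none"))
  for (k in c("normalize_by_alignments", "normalize_by_features", "rpm",
              "all_mapped_distributions", "trace")) {
    if (!is.logical(cfg[[k]]) || length(cfg[[k]]) != 1L || is.na(cfg[[k]]))
      stop("config key '", k, "' must be TRUE or FALSE")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a sample sheet
#'
#' CSV with columns `file` (SAM path), `name` (unique display name) and
#' optionally `norm_factor` (positive custom normalization factor, applied
#' when `rpm` is off).
#'
#' @param path path to the sample sheet CSV.
#' @param base_dir directory against which relative SAM paths are resolved.
#' @return data.frame with columns `file`, `name`, `norm_factor`
#'   (`NA` when absent).
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("file", "name") %in% names(df)))
    stop("sample sheet must have columns 'file' and 'name'")
  if (nrow(df) == 0) stop("sample sheet is empty")
  if (anyDuplicated(df$name))
    stop("sample sheet display names must be unique")
  if (is.null(df$norm_factor)) df$norm_factor <- NA_real_
  df$norm_factor <- as.numeric(df$norm_factor)
  if (any(!is.na(df$norm_factor) & df$norm_factor <= 0))
    stop("norm_factor values must be > 0")
  rel <- !grepl("^(/|~)", df$file)
  df$file[rel] <- file.path(base_dir, df$file[rel])
  df[, c("file", "name", "norm_factor")]
}
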