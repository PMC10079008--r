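#' Pipeline run configuration
#'
#' Collects the knobs shared by the command-line entry points: the global
#' seed, the recruitment scoring scheme, assembly thresholds and the
#' tissue-to-immune map. Every stochastic operation receives an explicit
#' seed derived from `seed`.
#'
#' @param seed integer global seed (default 42)
#' @param scheme a [scoring_scheme()]
#' @param min_overlap,max_mismatch_rate greedy assembly thresholds
#' @param max_rounds maximum iterative-rescue rounds
#' @param min_stretch_len minimum G/C stretch length
#' @param min_cds_length minimum CDS length profiled in gene-set statistics
#' @param immune_map named logical vector: tissue -> immune flag
#' @return a `run_config` list
#' @export
run_config <- function(seed = 42L, scheme = scoring_scheme(),
                       min_overlap = 30L, max_mismatch_rate = 0.02,
                       max_rounds = 5L, min_stretch_len = 3L,
                       min_cds_length = 300L, immune_map = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- list(seed = as.integer(seed), scheme = scheme,
              min_overlap = as.integer(min_overlap),
              max_mismatch_rate = max_mismatch_rate,
              max_rounds = as.integer(max_rounds),
              min_stretch_len = as.integer(min_stretch_len),
              min_cds_length = as.integer(min_cds_length),
              immune_map = immune_map)
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Numeric-looking values
#' are coerced; `true`/`false` become logical. Keys with a `tissue.` prefix
#' populate the tissue-to-immune map. Unknown keys are an error so typos
#' cannot silently fall back to defaults.
#'
#' @param path configuration file
#' @param overrides named list applied after the file (flag overrides)
#' @return a [run_config()]
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  parse_val <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  parsed <- setNames(lapply(vals, parse_val), keys)
  for (k in names(overrides)) parsed[[k]] <- overrides[[k]]

  tis <- grepl("^tissue\\.", names(parsed))
  immune <- NULL
  if (any(tis)) {
    immune <- vapply(parsed[tis], isTRUE, logical(1))
    names(immune) <- sub("^tissue\\.", "", names(parsed)[tis])
    parsed <- parsed[!tis]
  }
  scheme_keys <- c("match", "mismatch", "gap_open", "gap_extend", "lambda",
                   "K", "bit_threshold", "word_size")
  cfg_keys <- c("seed", "min_overlap", "max_mismatch_rate", "max_rounds",
                "min_stretch_len", "min_cds_length")
  unknown <- setdiff(names(parsed), c(scheme_keys, cfg_keys))
  if (length(unknown)) stop("unknown config key: ", unknown[1L])
  scheme <- do.call(scoring_scheme, parsed[intersect(names(parsed),
                                                     scheme_keys)])
  args <- parsed[intersect(names(parsed), cfg_keys)]
  args$scheme <- scheme
  args$immune_map <- immune
  do.call(run_config, args)
}
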