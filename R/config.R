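#' Pipeline configuration
#'
#' Bundles every tunable parameter of the driver-module pipeline with its
#' published default. All thresholds are inclusive ("at least" / "at most").
#'
#' @param fold_threshold Minimum linear fold change for a cell-line DEG call
#'   (default 2: "at least 2-fold").
#' @param R_pct Percentage of lung tumors with a discordant call needed to
#'   drop a DEG candidate (default 20).
#' @param alpha_normal One-sided tail probability per direction for the
#'   normal-reference z threshold (default 0.05, i.e. z = 1.645).
#' @param m Minimum tumors in a transcriptomic module block (default 50).
#' @param n Minimum genes in a transcriptomic module block (default 8).
#' @param r Quasi-biclique density fraction: every gene must touch at least
#'   a fraction `r` of the block's tumors and every tumor a fraction `r` of
#'   its genes (default 0.75).
#' @param t A tumor outside the block joins `T_nor` when at most `t * |G|`
#'   module genes are dysregulated in the module direction (default 0.5).
#' @param candidate_p Per-gene hypergeometric enrichment cutoff for driver
#'   candidates (default 0.01).
#' @param S Genetic-algorithm population size (default 20).
#' @param k Driver-module size (default 6).
#' @param r_me Minimum mutual-exclusivity ratio for a feasible solution
#'   (default 0.8).
#' @param generations Number of GA generations (default 6000).
#' @param seed Integer RNG seed, or `NULL` to leave the RNG untouched.
#' @param log2_input If `TRUE`, expression files are treated as log2 values
#'   and exponentiated on load.
#' @param barcode_trim Number of leading characters kept from TCGA-style
#'   sample barcodes when joining tables (default 15); `NULL` disables
#'   truncation.
#' @param silent_classes MAF `Variant_Classification` values treated as
#'   non-events (default exactly `"Silent"`).
#'
#' @return A `pipeline_config` object (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$m
pipeline_config <- function(fold_threshold = 2,
                            R_pct = 20,
                            alpha_normal = 0.05,
                            m = 50,
                            n = 8,
                            r = 0.75,
                            t = 0.5,
                            candidate_p = 0.01,
                            S = 20,
                            k = 6,
                            r_me = 0.8,
                            generations = 6000,
                            seed = NULL,
                            log2_input = FALSE,
                            barcode_trim = 15,
                            silent_classes = "Silent") {
  cfg <- list(
    fold_threshold = fold_threshold, R_pct = R_pct,
    alpha_normal = alpha_normal, m = m, n = n, r = r, t = t,
    candidate_p = candidate_p, S = S, k = k, r_me = r_me,
    generations = generations, seed = seed, log2_input = log2_input,
    barcode_trim = barcode_trim, silent_classes = silent_classes
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$fold_threshold > 1,
    cfg$R_pct > 0, cfg$R_pct <= 100,
    cfg$alpha_normal > 0, cfg$alpha_normal < 0.5,
    cfg$m >= 1, cfg$n >= 1,
    cfg$r > 0, cfg$r <= 1,
    cfg$t > 0, cfg$t < 1,
    cfg$candidate_p > 0, cfg$candidate_p <= 1,
    cfg$S >= 3,
    cfg$k >= 2,
    cfg$r_me > 0, cfg$r_me <= 1,
    cfg$generations >= 0
  )
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Only keys present in the file override the defaults, so a config file can
#' be sparse. `write_config()` then `read_config()` round-trips.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(val)) "NULL" else paste(val, collapse = ", ")))
  }
  invisible(x)
}

# timestamped stage logging to stderr; silenced via options(metadriver.quiet = TRUE)
md_log <- function(fmt, ...) {
  if (isTRUE(getOption("metadriver.quiet", FALSE))) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}
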