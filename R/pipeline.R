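#' Run the full driver-module pipeline
#'
#' Executes the four stages end to end: (1) `deg` — call DEGs along the
#' cell-line lineage and refine them against the lung cohorts; (2) `modules`
#' — call BRCA dysregulation and mine one transcriptomic module per TF and
#' direction; (3) `sga` — build the binary alteration matrix from the MAF and
#' copy-number table; (4) `ga` — for every module, filter driver candidates
#' by per-gene enrichment and run the genetic algorithm. Any stage error
#' aborts with a diagnostic naming the stage. Stage outputs are pure
#' functions of (inputs, config, seed); with `cache_dir` set they are cached
#' by content hash and reused.
#'
#' @param paths Named list of input paths as produced by
#'   [simulate_scenario()]: `cellline`, `comparisons`, `lung_tumors`,
#'   `lung_normals` (parallel vectors), `brca_tumors`, `brca_normals`,
#'   `gmt`, `maf`, `gistic`.
#' @param config A [pipeline_config()].
#' @param cache_dir Optional directory for stage caches.
#' @param report_path Optional JSON path; when set the report is also written
#'   via [write_report()].
#' @return A `pipeline_report`: `modules` tibble (one row per transcriptomic
#'   module with its driver solution), `degs`, the preprocessed `sga` matrix,
#'   `config`, `seed`, `timings`, and the per-module GA `fits`.
#' @export
run_pipeline <- function(paths, config = pipeline_config(), cache_dir = NULL,
                         report_path = NULL) {
  validate_config(config)
  timings <- list()
  run_stage <- function(stage, key_files, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      if (!is.null(cache_dir)) {
        key_files <- unlist(key_files)
        missing_f <- key_files[!file.exists(key_files)]
        if (length(missing_f) > 0) {
          stop("missing input file(s): ", paste(missing_f, collapse = ", "),
               call. = FALSE)
        }
        key <- rlang::hash(list(stage, unname(tools::md5sum(key_files)),
                                unclass(config)))
        cache_file <- file.path(cache_dir, paste0(stage, "-", key, ".rds"))
        if (file.exists(cache_file)) {
          md_log("stage %s: cache hit", stage)
          readRDS(cache_file)
        } else {
          out <- fun()
          dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(out, cache_file)
          out
        }
      } else {
        fun()
      }
    }, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    md_log("stage %s done in %.1fs", stage, timings[[stage]])
    res
  }

  degs <- run_stage("deg", paths[c("cellline", "comparisons", "lung_tumors",
                                   "lung_normals")], function() {
    expr <- read_expression(paths$cellline, "CELL_LINE",
                            log2_input = config$log2_input)
    comparisons <- readr::read_tsv(paths$comparisons,
                                   col_types = "cc", progress = FALSE)
    degs <- call_cellline_degs(expr, comparisons,
                               fold_threshold = config$fold_threshold)
    lung_dys <- purrr::map2(paths$lung_tumors, paths$lung_normals,
                            function(tp, np) {
      ref <- fit_normal_reference(read_expression(np, "NORMAL",
                                                  config$log2_input))
      call_dysregulation(read_expression(tp, "TUMOR", config$log2_input),
                         ref, alpha_normal = config$alpha_normal)
    })
    refine_degs(degs, lung_dys, R_pct = config$R_pct)
  })

  modules_out <- run_stage("modules", paths[c("brca_tumors", "brca_normals",
                                              "gmt")], function() {
    ref <- fit_normal_reference(read_expression(paths$brca_normals, "NORMAL",
                                                config$log2_input))
    dysreg <- call_dysregulation(
      read_expression(paths$brca_tumors, "TUMOR", config$log2_input),
      ref, alpha_normal = config$alpha_normal
    )
    tf_targets <- read_gmt(paths$gmt)
    list(dysreg = dysreg,
         modules = discover_modules(degs, tf_targets, dysreg, config))
  })
  dysreg <- modules_out$dysreg
  modules <- modules_out$modules

  sga <- run_stage("sga", paths[c("maf", "gistic", "brca_tumors",
                                  "brca_normals")], function() {
    mutations <- read_maf(paths$maf, barcode_trim = config$barcode_trim)
    cna <- read_gistic(paths$gistic, barcode_trim = config$barcode_trim)
    preprocess_sga(mutations, cna, dysreg,
                   silent_classes = config$silent_classes)
  })

  fits <- vector("list", nrow(modules))
  sol_cols <- tibble::tibble(
    driver_genes = rep(list(character(0)), nrow(modules)),
    me_ratio = NA_real_, enrichment_p = NA_real_, weight = NA_real_
  )[seq_len(nrow(modules)), ]
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(modules))) {
    candidates <- tryCatch(
      filter_candidates(sga, modules$t_abn[[i]], modules$t_nor[[i]],
                        candidate_p = config$candidate_p),
      error = function(e) stop("stage 'ga' failed: ", conditionMessage(e),
                               call. = FALSE)
    )
    if (nrow(candidates) < config$k) {
      warning(sprintf("module %d (%s/%s): only %d candidate gene(s) at p <= %g; skipping GA",
                      i, modules$tf[i], modules$direction[i],
                      nrow(candidates), config$candidate_p), call. = FALSE)
      next
    }
    cfg_i <- config
    # per-module seed: independent yet reproducible from config$seed
    if (!is.null(config$seed)) {
      cfg_i$seed <- (as.integer(config$seed) %% 1000003L) * 2011L + 7919L * i
    }
    fit <- evolve(candidates, sga, modules$t_abn[[i]], modules$t_nor[[i]],
                  config = cfg_i)
    fits[[i]] <- fit
    sol_cols$driver_genes[[i]] <- fit$best$genes
    sol_cols$me_ratio[i] <- fit$best$me_ratio
    sol_cols$enrichment_p[i] <- fit$best$enrichment_p
    sol_cols$weight[i] <- fit$best$weight
  }
  timings$ga <- proc.time()[["elapsed"]] - t0
  md_log("stage ga done in %.1fs", timings$ga)

  report <- structure(list(
    modules = dplyr::bind_cols(modules, sol_cols),
    degs = degs,
    sga = sga,
    config = unclass(config),
    seed = config$seed,
    timings = tibble::tibble(stage = names(timings),
                             seconds = unlist(timings)),
    fits = fits
  ), class = "pipeline_report")
  if (!is.null(report_path)) {
    write_report(report[c("modules", "config", "seed")], report_path)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d DEGs, %d transcriptomic module(s)\n",
              nrow(x$degs), nrow(x$modules)))
  if (nrow(x$modules) > 0) {
    for (i in seq_len(nrow(x$modules))) {
      cat(sprintf("  %s/%s: %d genes, |T_abn|=%d, |T_nor|=%d; driver [%s] me=%.3f p=%.3g\n",
                  x$modules$tf[i], x$modules$direction[i],
                  x$modules$n_genes[i], x$modules$n_abn[i], x$modules$n_nor[i],
                  paste(x$modules$driver_genes[[i]], collapse = ","),
                  x$modules$me_ratio[i], x$modules$enrichment_p[i]))
    }
  }
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(
    n_degs = nrow(x$degs),
    n_modules = nrow(x$modules),
    best_enrichment_p = if (nrow(x$modules) > 0) min(x$modules$weight, na.rm = TRUE) else NA_real_,
    seed = x$seed %||% NA_integer_
  )
}
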