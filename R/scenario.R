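#' Default synthetic study conditions
#'
#' The parameter set every end-to-end test and the acceptance script run
#' under: a 300-gene universe; a 3-step cell-line lineage planting 60 up- and
#' 60 down-regulated genes at fold 2.5; LUSC/LUAD-like lung cohorts (100
#' tumors, 50 normals each) with 5 planted lung-discordant up-genes; a
#' BRCA-like cohort of 200 tumors (50 normals) carrying one planted 10-gene
#' UP module over 120 module-abnormal tumors at within-block density 0.9 and
#' background dysregulation 0.05; and a planted exclusive 6-gene driver
#' covering 85% of the abnormal tumors at background SGA rate 0.03, 30%
#' silent background mutations and 30% of planted events as copy-number.
#'
#' @return Named list of generator parameters.
#' @export
default_scenario <- function() {
  list(
    n_genes = 300, depth = 3, frac_up = 0.2, frac_down = 0.2,
    fold_effect = 2.5, noise_sd = 0.1,
    n_lung_tumors = 100, n_lung_normals = 50, n_discordant = 5,
    lung_discordant_frac = 0.3,
    n_tumors = 200, n_normals = 50, module_genes = 10, n_abn = 120,
    within_density = 0.9, background_dysreg = 0.05,
    n_decoy_targets = 10, n_decoy_tfs = 2,
    k = 6, coverage = 0.85, background_sga = 0.03,
    silent_fraction = 0.3, cna_fraction = 0.3
  )
}

#' Generate one fully consistent synthetic study
#'
#' Couples the three generators so every planted structure survives the
#' pipeline stages it should: the planted transcriptomic-module genes are a
#' subset of the planted cell-line up-DEGs; a few planted up-genes are made
#' lung-discordant (down-regulated in >= R% of each lung cohort) so the
#' refinement filter has something to remove; and the planted driver's
#' copy-number events are written into the BRCA tumor expression so the
#' CNA-expression concordance check keeps them. The driver's `T_nor` ground
#' truth is the complement of the planted `T_abn`.
#'
#' @param params Scenario parameters, see [default_scenario()].
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return List with elements `cellline` (expr + comparisons), `lung` (list
#'   of two cohorts, each with tumor/normal matrices), `brca` (tumor/normal
#'   matrices + `tf_targets`), `sga` (mutations, cna), and `truth`.
#' @export
generate_scenario <- function(params = default_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(default_scenario(), params)
  genes <- sprintf("g%04d", seq_len(p$n_genes))

  # planted DEG sets; the module and discordant genes are carved out of "up"
  n_up <- round(p$frac_up * p$n_genes)
  n_down <- round(p$frac_down * p$n_genes)
  planted <- sample_vec(genes, n_up + n_down)
  up <- planted[seq_len(n_up)]
  down <- planted[n_up + seq_len(n_down)]
  module <- sample_vec(up, p$module_genes)
  discordant <- sample_vec(setdiff(up, module), p$n_discordant)

  cellline <- generate_cellline_series(
    n_genes = p$n_genes, depth = p$depth, fold_effect = p$fold_effect,
    noise_sd = p$noise_sd, genes = genes,
    planted_up = up, planted_down = down
  )

  # lung cohorts: discordant genes planted DOWN in a fraction of tumors
  lung <- lapply(c("LUSC", "LUAD"), function(cohort) {
    generate_tumor_cohort(
      n_genes = p$n_genes, n_tumors = p$n_lung_tumors,
      n_normals = p$n_lung_normals, direction = "DOWN",
      n_abn = round(p$lung_discordant_frac * p$n_lung_tumors),
      within_density = 1.0, background_rate = p$background_dysreg,
      genes = genes, module_gene_ids = discordant,
      n_decoy_tfs = 0
    )
  })
  names(lung) <- c("LUSC", "LUAD")

  brca <- generate_tumor_cohort(
    n_genes = p$n_genes, n_tumors = p$n_tumors, n_normals = p$n_normals,
    n_abn = p$n_abn, direction = "UP",
    within_density = p$within_density, background_rate = p$background_dysreg,
    n_decoy_targets = p$n_decoy_targets, n_decoy_tfs = p$n_decoy_tfs,
    genes = genes, module_gene_ids = module
  )
  t_abn <- brca$truth$t_abn
  t_nor <- setdiff(colnames(brca$tumors), t_abn)

  sga <- generate_sga(
    genes = genes, t_abn = t_abn, t_nor = t_nor, k = p$k,
    coverage = p$coverage, background_rate = p$background_sga,
    silent_fraction = p$silent_fraction, cna_fraction = p$cna_fraction,
    driver_genes = sample_vec(setdiff(genes, module), p$k),
    direction = "UP"
  )

  # make planted CNA events expression-concordant in the BRCA matrix
  if (any(sga$truth$is_cna)) {
    amp <- sga$truth$assignment[sga$truth$is_cna, ]
    vals <- unclass(brca$tumors)
    idx <- cbind(match(amp$gene, rownames(vals)), match(amp$tumor, colnames(vals)))
    mu <- brca$truth$mu[amp$gene]
    delta <- brca$truth$delta[amp$gene]
    vals[idx] <- mu + 4 * delta
    brca$tumors <- expression_matrix(vals, "TUMOR")
  }

  list(
    cellline = cellline,
    lung = lung,
    brca = brca,
    sga = sga,
    truth = list(
      up = sort(up), down = sort(down),
      discordant = sort(discordant),
      module = sort(module), t_abn = sort(t_abn), t_nor = sort(t_nor),
      tf = brca$truth$tf, direction = "UP",
      driver = sga$truth$driver, covered = sga$truth$covered,
      params = p, seed = seed
    )
  )
}

#' Write a synthetic scenario to disk in the pipeline's input formats
#'
#' Emits every file [run_pipeline()] consumes — expression TSVs, a
#' comparisons TSV, a GMT of TF targets, a MAF of mutations, a GISTIC-style
#' thresholded copy-number table — plus `truth.json` with the planted ground
#' truth and `config.yaml` with the pipeline configuration.
#'
#' @param dir Output directory (created if needed).
#' @param params Scenario parameters, see [default_scenario()].
#' @param seed Integer seed.
#' @param config A [pipeline_config()] written alongside the data.
#' @return Invisibly, the named list of file paths (the `paths` argument of
#'   [run_pipeline()]).
#' @export
simulate_scenario <- function(dir, params = default_scenario(), seed = 1,
                              config = pipeline_config(seed = seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_scenario(params, seed = seed)
  f <- function(...) file.path(dir, paste0(...))

  write_expression(sc$cellline$expr, f("cellline.tsv"))
  readr::write_tsv(sc$cellline$comparisons, f("comparisons.tsv"), progress = FALSE)
  for (cohort in names(sc$lung)) {
    write_expression(sc$lung[[cohort]]$tumors, f(tolower(cohort), "_tumors.tsv"))
    write_expression(sc$lung[[cohort]]$normals, f(tolower(cohort), "_normals.tsv"))
  }
  write_expression(sc$brca$tumors, f("brca_tumors.tsv"))
  write_expression(sc$brca$normals, f("brca_normals.tsv"))
  write_gmt(sc$brca$tf_targets, f("tf_targets.gmt"))

  maf <- tibble::tibble(
    Hugo_Symbol = sc$sga$mutations$gene,
    Tumor_Sample_Barcode = sc$sga$mutations$tumor,
    Variant_Classification = sc$sga$mutations$variant_classification
  )
  readr::write_tsv(maf, f("mutations.maf"), progress = FALSE)

  tumors <- c(sc$truth$t_abn, sc$truth$t_nor)
  cn <- matrix(0L, nrow(sc$brca$tumors), length(tumors),
               dimnames = list(rownames(sc$brca$tumors), sort(tumors)))
  if (nrow(sc$sga$cna) > 0) {
    cn[cbind(match(sc$sga$cna$gene, rownames(cn)),
             match(sc$sga$cna$tumor, colnames(cn)))] <- sc$sga$cna$call
  }
  readr::write_tsv(tibble::as_tibble(cn, rownames = "gene"), f("cna_calls.tsv"),
                   progress = FALSE)

  truth <- sc$truth
  truth$params <- NULL
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE, digits = NA)
  write_config(config, f("config.yaml"))

  paths <- list(
    cellline = f("cellline.tsv"),
    comparisons = f("comparisons.tsv"),
    lung_tumors = c(f("lusc_tumors.tsv"), f("luad_tumors.tsv")),
    lung_normals = c(f("lusc_normals.tsv"), f("luad_normals.tsv")),
    brca_tumors = f("brca_tumors.tsv"),
    brca_normals = f("brca_normals.tsv"),
    gmt = f("tf_targets.gmt"),
    maf = f("mutations.maf"),
    gistic = f("cna_calls.tsv"),
    config = f("config.yaml"),
    truth = f("truth.json")
  )
  invisible(paths)
}
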