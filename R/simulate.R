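#' Simulate a metastatic cell-line lineage expression series
#'
#' Emulates a parental line and a chain of increasingly metastatic
#' derivatives. The parent profile is log-normal; each child inherits its
#' parent's profile, multiplies the planted up-regulated genes by
#' `fold_effect`, divides the planted down-regulated genes by it, and adds
#' multiplicative log-normal noise of scale `noise_sd` to every gene.
#'
#' @param n_genes Number of genes.
#' @param depth Lineage depth (number of child generations).
#' @param frac_up,frac_down Fractions of genes planted as up-/down-regulated.
#' @param fold_effect Planted fold change (>= the fold threshold you intend to
#'   test with).
#' @param noise_sd Standard deviation of the log-normal noise on log2 scale.
#' @param genes Optional gene symbols (default `g0001`...).
#' @param planted_up,planted_down Optional explicit planted gene sets,
#'   overriding the sampled ones (used to keep scenario pieces consistent).
#' @return List with `expr` ([expression_matrix()]), `comparisons` tibble
#'   (child, parent), and `truth` (list with `up`, `down` planted gene sets).
#' @export
generate_cellline_series <- function(n_genes = 300, depth = 3,
                                     frac_up = 0.2, frac_down = 0.2,
                                     fold_effect = 2.5, noise_sd = 0.1,
                                     genes = NULL, planted_up = NULL,
                                     planted_down = NULL) {
  stopifnot(n_genes >= 10, depth >= 1, frac_up + frac_down < 1,
            fold_effect >= 1, noise_sd >= 0)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  if (is.null(planted_up) && is.null(planted_down)) {
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    planted <- sample_vec(genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- planted[n_up + seq_len(n_down)]
  } else {
    up <- planted_up %||% character(0)
    down <- planted_down %||% character(0)
    stopifnot(all(c(up, down) %in% genes),
              length(intersect(up, down)) == 0)
  }

  base <- 2^stats::rnorm(n_genes, mean = 7, sd = 1)
  names(base) <- genes
  samples <- c("parental", sprintf("LM%d", seq_len(depth) - 1L))
  mat <- matrix(0, n_genes, depth + 1L, dimnames = list(genes, samples))
  mat[, 1] <- base
  effect <- rep(1, n_genes); names(effect) <- genes
  effect[up] <- fold_effect
  effect[down] <- 1 / fold_effect
  for (d in seq_len(depth)) {
    noise <- 2^stats::rnorm(n_genes, 0, noise_sd)
    # the planted effect is applied once, at the first derivation
    mat[, d + 1L] <- mat[, d] * (if (d == 1) effect else 1) * noise
  }
  comparisons <- tibble::tibble(child = samples[-1],
                                parent = samples[-length(samples)])
  list(
    expr = expression_matrix(mat, "CELL_LINE"),
    comparisons = comparisons,
    truth = list(up = sort(up), down = sort(down))
  )
}

#' Simulate a tumor cohort with one planted transcriptomic module
#'
#' Normals are drawn per gene from a fixed normal distribution (mean from a
#' gene-specific log-normal baseline, constant coefficient of variation). A
#' designated set of module-abnormal tumors shifts each planted module gene
#' by at least 3 reference standard deviations (in the module direction) with
#' probability `within_density`; every other gene-tumor pair is shifted, in a
#' random direction, at the `background_rate`. The TF map assigns the planted
#' genes plus decoys to one TF and adds unrelated decoy TFs.
#'
#' @param n_genes,n_tumors,n_normals Cohort dimensions.
#' @param module_genes Number of planted module genes.
#' @param n_abn Number of designated module-abnormal tumors.
#' @param direction Planted direction, `"UP"` or `"DOWN"`.
#' @param within_density Probability a module gene is shifted in a designated
#'   tumor.
#' @param background_rate Probability of a background shift elsewhere.
#' @param n_decoy_targets Extra (non-module) genes attached to the planted
#'   TF's target set.
#' @param n_decoy_tfs Unrelated TFs with random target sets.
#' @param genes Optional gene symbols.
#' @param module_gene_ids Optional explicit module genes (overrides
#'   `module_genes`); `character(0)` plants no module.
#' @return List with `tumors` and `normals` ([expression_matrix()]),
#'   `tf_targets`, and `truth` (tf, direction, module genes, `t_abn` ids,
#'   baseline `mu`/`delta`).
#' @export
generate_tumor_cohort <- function(n_genes = 300, n_tumors = 200,
                                  n_normals = 20, module_genes = 10,
                                  n_abn = 120, direction = "UP",
                                  within_density = 0.9,
                                  background_rate = 0.05,
                                  n_decoy_targets = 10, n_decoy_tfs = 2,
                                  genes = NULL, module_gene_ids = NULL) {
  stopifnot(module_genes <= n_genes, n_abn <= n_tumors, n_normals >= 3,
            within_density > 0, within_density <= 1,
            background_rate >= 0, background_rate < 1,
            direction %in% c("UP", "DOWN"))
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n_genes))
  mu <- 2^stats::rnorm(n_genes, mean = 7, sd = 1)
  delta <- 0.1 * mu  # constant coefficient of variation
  names(mu) <- names(delta) <- genes

  normals <- matrix(stats::rnorm(n_genes * n_normals, mu, delta),
                    n_genes, n_normals,
                    dimnames = list(genes, sprintf("N%03d", seq_len(n_normals))))
  tumors <- matrix(stats::rnorm(n_genes * n_tumors, mu, delta),
                   n_genes, n_tumors,
                   dimnames = list(genes, sprintf("T%03d", seq_len(n_tumors))))

  if (is.null(module_gene_ids)) {
    module <- sample_vec(genes, module_genes)
  } else {
    stopifnot(all(module_gene_ids %in% genes))
    module <- module_gene_ids
  }
  t_abn <- sample_vec(colnames(tumors), n_abn)
  sign_dir <- if (direction == "UP") 1 else -1
  shift <- function(x, g, s) pmax(x + s * (3.5 + stats::rexp(length(x), 2)) * delta[g], 0)

  # planted module block
  for (g in module) {
    hit <- t_abn[stats::runif(n_abn) < within_density]
    tumors[g, hit] <- shift(tumors[g, hit], g, sign_dir)
  }
  # background dysregulation everywhere else
  bg <- matrix(stats::runif(n_genes * n_tumors) < background_rate,
               n_genes, n_tumors, dimnames = dimnames(tumors))
  bg[module, t_abn] <- FALSE
  idx <- which(bg, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    sgn <- sample(c(-1, 1), nrow(idx), replace = TRUE)
    g_idx <- rownames(tumors)[idx[, 1]]
    tumors[idx] <- shift(tumors[idx], g_idx, sgn)
  }

  decoys <- sample_vec(setdiff(genes, module), n_decoy_targets)
  tf_targets <- list(TF_planted = sort(c(module, decoys)))
  for (i in seq_len(n_decoy_tfs)) {
    tf_targets[[sprintf("TF_decoy%d", i)]] <-
      sort(sample_vec(setdiff(genes, module),
                      max(length(module) + n_decoy_targets, 5)))
  }
  list(
    tumors = expression_matrix(tumors, "TUMOR"),
    normals = expression_matrix(normals, "NORMAL"),
    tf_targets = tf_targets,
    truth = list(tf = "TF_planted", direction = direction,
                 module = sort(module), t_abn = sort(t_abn),
                 mu = mu, delta = delta)
  )
}

#' Simulate somatic alterations with a planted exclusive driver module
#'
#' A `coverage` fraction of `T_abn` tumors is partitioned among the `k`
#' planted driver genes so that each covered tumor receives exactly one
#' planted event (planted ME ratio 1.0 at background 0). A `cna_fraction` of
#' planted events is emitted as ±2 copy-number calls (the rest as missense
#' mutations); planted copy-number events come with a concordant
#' dysregulation call so they survive preprocessing. Background events are
#' placed uniformly over all genes and tumors at `background_rate`, with a
#' `silent_fraction` of background mutation records classified `Silent`.
#'
#' @param genes Gene universe (character).
#' @param t_abn,t_nor Tumor id vectors.
#' @param k Planted driver size.
#' @param coverage Fraction of `T_abn` covered by planted events.
#' @param background_rate Per gene-tumor probability of a background event.
#' @param silent_fraction Fraction of background mutations that are silent.
#' @param cna_fraction Fraction of planted events emitted as copy-number.
#' @param driver_genes Optional explicit driver genes (default: sampled).
#' @param direction Direction of the planted copy-number concordance
#'   (`"UP"` emits amplifications, `"DOWN"` deletions).
#' @return List with `mutations` tibble, `cna` tibble, `dysreg`
#'   ([dysreg_matrix()] giving the concordance calls for every CNA), and
#'   `truth` (driver genes, covered tumors, per-event assignments).
#' @export
generate_sga <- function(genes, t_abn, t_nor, k = 6, coverage = 0.85,
                         background_rate = 0.03, silent_fraction = 0.3,
                         cna_fraction = 0.3, driver_genes = NULL,
                         direction = "UP") {
  stopifnot(coverage > 0, coverage <= 1, k >= 2, length(genes) >= k,
            background_rate >= 0, background_rate < 1)
  tumors <- c(t_abn, t_nor)
  if (is.null(driver_genes)) driver_genes <- sample_vec(genes, k)
  stopifnot(length(driver_genes) == k, all(driver_genes %in% genes))

  covered <- sample_vec(t_abn, round(coverage * length(t_abn)))
  assignment <- tibble::tibble(
    gene = driver_genes[1 + (seq_along(covered) - 1L) %% k],
    tumor = covered
  )
  is_cna <- stats::runif(nrow(assignment)) < cna_fraction

  bg <- which(matrix(stats::runif(length(genes) * length(tumors)) < background_rate,
                     length(genes), length(tumors)), arr.ind = TRUE)
  bg_mut <- tibble::tibble(gene = genes[bg[, 1]], tumor = tumors[bg[, 2]])
  # drop background collisions with planted events so exclusivity holds there
  bg_mut <- dplyr::anti_join(bg_mut, assignment, by = c("gene", "tumor"))
  silent <- stats::runif(nrow(bg_mut)) < silent_fraction

  mutations <- dplyr::bind_rows(
    tibble::tibble(gene = assignment$gene[!is_cna],
                   tumor = assignment$tumor[!is_cna],
                   variant_classification = "Missense_Mutation"),
    tibble::tibble(gene = bg_mut$gene, tumor = bg_mut$tumor,
                   variant_classification = c("Missense_Mutation",
                                              "Silent")[silent + 1L])
  )
  call_val <- if (direction == "UP") 2L else -2L
  cna <- tibble::tibble(gene = assignment$gene[is_cna],
                        tumor = assignment$tumor[is_cna],
                        call = call_val)
  # concordant dysregulation for every CNA (gene UP for amp, DOWN for del)
  dy <- matrix(0L, length(genes), length(tumors),
               dimnames = list(genes, tumors))
  if (nrow(cna) > 0) {
    dy[cbind(match(cna$gene, genes), match(cna$tumor, tumors))] <-
      if (direction == "UP") 1L else -1L
  }
  list(
    mutations = mutations,
    cna = cna,
    dysreg = dysreg_matrix(dy),
    truth = list(driver = sort(driver_genes), covered = sort(covered),
                 assignment = assignment, is_cna = is_cna)
  )
}
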