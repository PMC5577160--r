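#' Expression matrix container
#'
#' A genes-by-samples numeric matrix on the linear scale, with one role per
#' sample (`CELL_LINE`, `TUMOR` or `NORMAL`). Values must be finite and
#' non-negative; gene and sample identifiers must be unique.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param role Either a single role recycled to all samples or one role per
#'   sample.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, role) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(values))) stop("expression values must be finite", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative on the linear scale", call. = FALSE)
  role <- match_roles(role, ncol(values))
  structure(values, role = role, class = c("expression_matrix", "matrix", "array"))
}

expr_roles <- c("CELL_LINE", "TUMOR", "NORMAL")

match_roles <- function(role, n_samples) {
  role <- as.character(role)
  if (length(role) == 1) role <- rep(role, n_samples)
  if (length(role) != n_samples) {
    stop("need one sample role or one role per sample", call. = FALSE)
  }
  bad <- setdiff(unique(role), expr_roles)
  if (length(bad) > 0) {
    stop("unknown sample role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  role
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(table(attr(x, "role"))),
                            table(attr(x, "role"))), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    role = rep(attr(x, "role"), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Read an expression matrix from TSV
#'
#' The file has gene symbols in the first column and one column per sample.
#' Duplicate gene rows are collapsed by their mean. Any non-numeric cell is a
#' parse error that names the offending gene and sample.
#'
#' @param path TSV file path.
#' @param role Sample role(s) to attach (`CELL_LINE`, `TUMOR` or `NORMAL`).
#' @param log2_input If `TRUE`, values are interpreted as log2 and
#'   exponentiated to the linear scale on load.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, role, log2_input = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("expression file '", path, "' is empty or has no sample columns", call. = FALSE)
  }
  genes <- raw[[1]]
  if (anyNA(genes) || any(genes == "")) {
    stop("expression file '", path, "': empty gene symbol at data line ",
         which(is.na(genes) | genes == "")[1], call. = FALSE)
  }
  samples <- names(raw)[-1]
  vals <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "expression file '%s': non-numeric value '%s' for gene '%s', sample '%s' (data line %d)",
      path, raw[[bad[2] + 1]][bad[1]], genes[bad[1]], samples[bad[2]], bad[1]
    ), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes
  if (log2_input) vals <- 2^vals
  expression_matrix(vals, role)
}

#' Write an expression matrix as TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(unclass(expr), rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read somatic mutation calls from a MAF-style file
#'
#' Requires the `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns; everything else is ignored. Barcodes are
#' truncated to the sample-level identifier (first `barcode_trim` characters)
#' so mutation, copy-number and expression tables join on the same ids.
#' Silent-variant filtering happens downstream in [preprocess_sga()].
#'
#' @param path MAF TSV path.
#' @param barcode_trim Leading characters to keep from each barcode; `NULL`
#'   keeps barcodes verbatim.
#' @return A tibble with columns `gene`, `tumor`, `variant_classification`.
#' @export
read_maf <- function(path, barcode_trim = 15) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE, show_col_types = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("MAF file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene = raw$Hugo_Symbol,
    tumor = trim_barcode(raw$Tumor_Sample_Barcode, barcode_trim),
    variant_classification = raw$Variant_Classification
  )
  if (any(is.na(out$variant_classification) | out$variant_classification == "")) {
    stop("MAF file '", path, "': empty Variant_Classification at data line ",
         which(is.na(out$variant_classification) | out$variant_classification == "")[1],
         call. = FALSE)
  }
  out
}

trim_barcode <- function(x, barcode_trim) {
  if (is.null(barcode_trim)) return(x)
  ifelse(nchar(x) > barcode_trim, substr(x, 1, barcode_trim), x)
}

#' Read GISTIC-style thresholded copy-number calls
#'
#' Expects a gene-by-sample integer table (first column gene symbol) with
#' values in −2..2; anything outside that range is an error. Returns the
#' calls in long form.
#'
#' @param path TSV path.
#' @param barcode_trim As in [read_maf()].
#' @return A tibble with columns `gene`, `tumor`, `call` (integer in −2..2).
#' @export
read_gistic <- function(path, barcode_trim = 15) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("copy-number file '", path, "' is empty or has no sample columns", call. = FALSE)
  }
  genes <- raw[[1]]
  vals <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < -2) || any(vals > 2)) {
    bad <- which(is.na(vals) | vals != round(vals) | vals < -2 | vals > 2,
                 arr.ind = TRUE)[1, ]
    stop(sprintf(
      "copy-number file '%s': invalid call '%s' for gene '%s' (must be integer in -2..2)",
      path, raw[[bad[2] + 1]][bad[1]], genes[bad[1]]
    ), call. = FALSE)
  }
  samples <- trim_barcode(names(raw)[-1], barcode_trim)
  tibble::tibble(
    gene = rep(genes, times = ncol(vals)),
    tumor = rep(samples, each = nrow(vals)),
    call = as.integer(vals)
  )
}

#' Read transcription-factor target sets from GMT
#'
#' Standard GMT: one set per line, tab-separated as name, description,
#' members. Empty target sets are rejected.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (TF -> target gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file '", path, "' is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop("GMT file '", path, "': line ", short[1],
         " has no target genes", call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (any(lengths(sets) == 0)) {
    stop("GMT file '", path, "': empty target set for ",
         names(sets)[lengths(sets) == 0][1], call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("GMT file '", path, "': duplicate set names", call. = FALSE)
  sets
}

#' Write transcription-factor target sets as GMT
#'
#' @param tf_targets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(tf_targets, path) {
  lines <- vapply(names(tf_targets), function(nm) {
    paste(c(nm, nm, tf_targets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and re-read the pipeline report
#'
#' The report pairs each transcriptomic module with its driver solution. It
#' is written twice: a JSON file carrying the full nested structure and a
#' flat TSV summary next to it (same path with extension `.tsv`).
#'
#' @param report A `pipeline_report` as returned by [run_pipeline()], or any
#'   list with a `modules` tibble in the same shape.
#' @param path Output JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the report list with `modules` restored as a tibble.
#' @export
write_report <- function(report, path) {
  out <- report
  out$modules <- lapply(seq_len(nrow(report$modules)), function(i) {
    row <- as.list(report$modules[i, ])
    lapply(row, function(v) if (is.list(v)) v[[1]] else v)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flat <- dplyr::mutate(
    report$modules,
    genes = vapply(.data$genes, paste, character(1), collapse = ","),
    driver_genes = vapply(.data$driver_genes, paste, character(1), collapse = ",")
  )
  flat <- dplyr::select(flat, -dplyr::any_of(c("t_abn", "t_nor")))
  readr::write_tsv(flat, sub("\\.json$", ".tsv", path), progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  mods <- rep$modules
  cols <- names(mods[[1]])
  tb <- tibble::as_tibble(lapply(stats::setNames(cols, cols), function(cn) {
    vals <- lapply(mods, function(m) m[[cn]])
    if (all(lengths(vals) == 1) && !is.list(vals[[1]])) unlist(vals) else vals
  }))
  rep$modules <- tb
  rep
}
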