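#' Call differentially expressed genes along a cell-line lineage
#'
#' A gene is up-regulated if its child/parent linear fold change is at least
#' `fold_threshold` in any of the supplied parent-to-child comparisons, and
#' down-regulated if parent/child reaches the threshold. Per-comparison calls
#' are unioned across all comparisons, then genes called in both directions
#' anywhere along the lineage are dropped, so the returned directions are
#' disjoint. Expression values are floored at `pseudocount` before the ratio
#' is taken, which guards zero denominators while leaving ratios of ordinary
#' values untouched (an exact 2-fold change stays on the inclusive boundary).
#'
#' @param expr Cell-line [expression_matrix()] (all roles `CELL_LINE`).
#' @param comparisons Data frame with columns `child` and `parent`, one row
#'   per lineage step; both must be sample ids of `expr`.
#' @param fold_threshold Minimum fold change, > 1; the comparison is
#'   inclusive ("at least").
#' @param pseudocount Floor applied to numerator and denominator of every
#'   ratio.
#' @return A tibble with columns `gene` and `direction` (`"UP"`/`"DOWN"`).
#' @export
call_cellline_degs <- function(expr, comparisons, fold_threshold = 2,
                               pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"), fold_threshold > 1)
  comparisons <- tibble::as_tibble(comparisons)
  stopifnot(all(c("child", "parent") %in% names(comparisons)))
  ids <- unique(c(comparisons$child, comparisons$parent))
  missing_ids <- setdiff(ids, colnames(expr))
  if (length(missing_ids) > 0) {
    stop("comparison sample(s) absent from expression matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (any(comparisons$child == comparisons$parent)) {
    stop("a comparison has child == parent", call. = FALSE)
  }
  roles <- attr(expr, "role")[match(ids, colnames(expr))]
  if (any(roles != "CELL_LINE")) {
    stop("all comparison samples must have role CELL_LINE", call. = FALSE)
  }
  up <- character(0); down <- character(0)
  for (i in seq_len(nrow(comparisons))) {
    child <- pmax(expr[, comparisons$child[i]], pseudocount)
    parent <- pmax(expr[, comparisons$parent[i]], pseudocount)
    ratio <- child / parent
    up <- union(up, rownames(expr)[ratio >= fold_threshold])
    down <- union(down, rownames(expr)[1 / ratio >= fold_threshold])
  }
  conflicted <- intersect(up, down)
  tibble::tibble(
    gene = c(setdiff(up, conflicted), setdiff(down, conflicted)),
    direction = rep(c("UP", "DOWN"),
                    c(length(up) - length(conflicted),
                      length(down) - length(conflicted)))
  )
}

#' Fit the per-gene normal reference
#'
#' Mean and standard deviation of each gene's expression over the normal
#' controls of a cohort; the standard deviation uses the unbiased (n − 1)
#' denominator. At least three normals are required.
#'
#' @param expr_normals [expression_matrix()] with all roles `NORMAL`.
#' @return A tibble with columns `gene`, `mu`, `delta`.
#' @export
fit_normal_reference <- function(expr_normals) {
  stopifnot(inherits(expr_normals, "expression_matrix"))
  if (ncol(expr_normals) < 3) {
    stop("need at least 3 normal samples to fit a reference", call. = FALSE)
  }
  if (any(attr(expr_normals, "role") != "NORMAL")) {
    stop("all samples must have role NORMAL", call. = FALSE)
  }
  x <- unclass(expr_normals)
  tibble::tibble(
    gene = rownames(x),
    mu = unname(rowMeans(x)),
    delta = unname(apply(x, 1, stats::sd))
  )
}

dysreg_codes <- c(DOWN = -1L, NEUTRAL = 0L, UP = 1L)

#' Dysregulation matrix container
#'
#' Integer genes-by-tumors matrix with calls coded `UP` = 1, `NEUTRAL` = 0,
#' `DOWN` = −1 (ternary by construction, so a gene is never both).
#'
#' @param calls Integer matrix in {−1, 0, 1} with gene rownames and tumor
#'   colnames.
#' @return A `dysreg_matrix` object.
#' @export
dysreg_matrix <- function(calls) {
  stopifnot(is.matrix(calls), all(calls %in% c(-1L, 0L, 1L)),
            !is.null(rownames(calls)), !is.null(colnames(calls)))
  storage.mode(calls) <- "integer"
  structure(calls, class = c("dysreg_matrix", "matrix", "array"))
}

#' @export
print.dysreg_matrix <- function(x, ...) {
  cat(sprintf("<dysreg_matrix> %d genes x %d tumors (UP %d, DOWN %d calls)\n",
              nrow(x), ncol(x), sum(x == 1L), sum(x == -1L)))
  invisible(x)
}

#' @export
tidy.dysreg_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    tumor = rep(colnames(x), each = nrow(x)),
    call = names(dysreg_codes)[match(as.vector(unclass(x)), dysreg_codes)]
  )
}

#' Call per-tumor dysregulation against a normal reference
#'
#' A gene is `UP` in a tumor when its z-score against the normal reference
#' reaches the one-sided normal quantile `z(1 - alpha_normal)` (1.645 at the
#' default 0.05), `DOWN` when it reaches the mirrored lower quantile, and
#' `NEUTRAL` otherwise. Genes with zero reference spread are `NEUTRAL` unless
#' `strict_zero_delta = TRUE`, in which case any departure from the mean is
#' called by its sign.
#'
#' @param expr_tumors [expression_matrix()] with all roles `TUMOR`.
#' @param ref Normal reference tibble from [fit_normal_reference()].
#' @param alpha_normal One-sided tail probability per direction.
#' @param strict_zero_delta Call zero-variance genes by sign of `x - mu`.
#' @return A [dysreg_matrix()] over the tumor cohort.
#' @export
call_dysregulation <- function(expr_tumors, ref, alpha_normal = 0.05,
                               strict_zero_delta = FALSE) {
  stopifnot(inherits(expr_tumors, "expression_matrix"))
  missing_ref <- setdiff(rownames(expr_tumors), ref$gene)
  if (length(missing_ref) > 0) {
    stop("gene(s) missing from the normal reference: ",
         paste(utils::head(missing_ref, 5), collapse = ", "),
         if (length(missing_ref) > 5) ", ...", call. = FALSE)
  }
  idx <- match(rownames(expr_tumors), ref$gene)
  mu <- ref$mu[idx]
  delta <- ref$delta[idx]
  zcut <- stats::qnorm(1 - alpha_normal)
  x <- unclass(expr_tumors)
  dev <- x - mu
  calls <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  ok <- delta > 0
  z <- dev[ok, , drop = FALSE] / delta[ok]
  calls[ok, ][z >= zcut] <- 1L
  calls[ok, ][z <= -zcut] <- -1L
  if (strict_zero_delta && any(!ok)) {
    calls[!ok, ][dev[!ok, , drop = FALSE] > 0] <- 1L
    calls[!ok, ][dev[!ok, , drop = FALSE] < 0] <- -1L
  }
  dysreg_matrix(calls)
}

#' Refine DEG candidates against lung-tumor cohorts
#'
#' Drops an up-regulated candidate if it is called `DOWN` in at least
#' `R_pct`% of the tumors of any supplied lung cohort (and symmetrically for
#' down-regulated candidates called `UP`). Genes absent from a cohort count
#' as 0% discordant there. Pure filter: the output is a subset of the input.
#'
#' @param degs DEG tibble from [call_cellline_degs()].
#' @param lung_dysreg A single [dysreg_matrix()] or a list of them (one per
#'   lung cohort).
#' @param R_pct Discordance percentage threshold (inclusive).
#' @return A DEG tibble of the retained genes.
#' @export
refine_degs <- function(degs, lung_dysreg, R_pct = 20) {
  if (inherits(lung_dysreg, "dysreg_matrix")) lung_dysreg <- list(lung_dysreg)
  stopifnot(length(lung_dysreg) > 0, R_pct > 0)
  for (dm in lung_dysreg) {
    if (!inherits(dm, "dysreg_matrix") || ncol(dm) == 0) {
      stop("each lung cohort must be a non-empty dysreg_matrix", call. = FALSE)
    }
  }
  discordant_frac <- function(genes, dm, bad_call) {
    frac <- numeric(length(genes))
    present <- genes %in% rownames(dm)
    if (any(present)) {
      sub <- unclass(dm)[genes[present], , drop = FALSE]
      frac[present] <- rowMeans(sub == bad_call)
    }
    frac
  }
  keep <- vapply(seq_len(nrow(degs)), function(i) {
    bad_call <- if (degs$direction[i] == "UP") -1L else 1L
    !any(vapply(lung_dysreg, function(dm) {
      discordant_frac(degs$gene[i], dm, bad_call) >= R_pct / 100
    }, logical(1)))
  }, logical(1))
  degs[keep, ]
}
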