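#' Build the gene-by-tumor bipartite graph for one TF and direction
#'
#' Gene nodes are the DEG candidates of the given direction that are targets
#' of the TF; tumor nodes are the cohort tumors; an edge joins a gene to a
#' tumor when the gene is dysregulated in that tumor in the module direction.
#'
#' @param degs DEG tibble (`gene`, `direction`).
#' @param tf_targets Named list of TF target sets as from [read_gmt()].
#' @param tf A name of `tf_targets`.
#' @param direction `"UP"` or `"DOWN"`.
#' @param dysreg [dysreg_matrix()] over the tumor cohort.
#' @return A `bipartite_graph`: list with `genes`, `tumors` and a logical
#'   `adj` incidence matrix (genes x tumors). The gene side may be empty.
#' @export
build_bipartite <- function(degs, tf_targets, tf, direction, dysreg) {
  stopifnot(direction %in% c("UP", "DOWN"), inherits(dysreg, "dysreg_matrix"))
  if (!tf %in% names(tf_targets)) {
    stop("unknown TF id: ", tf, call. = FALSE)
  }
  genes <- sort(intersect(
    intersect(degs$gene[degs$direction == direction], tf_targets[[tf]]),
    rownames(dysreg)
  ))
  adj <- unclass(dysreg)[genes, , drop = FALSE] == dysreg_codes[[direction]]
  structure(
    list(genes = genes, tumors = colnames(dysreg), adj = adj,
         tf = tf, direction = direction),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %s/%s: %d genes x %d tumors, %d edges\n",
              x$tf, x$direction, length(x$genes), length(x$tumors), sum(x$adj)))
  invisible(x)
}

block_feasible <- function(adj, n, m, r) {
  nrow(adj) >= n && ncol(adj) >= m &&
    all(rowSums(adj) >= r * ncol(adj)) &&
    all(colSums(adj) >= r * nrow(adj))
}

#' Mine a dense quasi-biclique from a bipartite graph
#'
#' Searches for a block of at least `n` genes and `m` tumors in which every
#' gene touches at least `r` of the block's tumors and every tumor touches at
#' least `r` of the block's genes. The search is a deterministic peeling
#' heuristic: starting from the full graph, the node (gene or tumor) with the
#' smallest edge fraction to the opposite side is deleted until both density
#' constraints hold or a size bound is crossed; deleted nodes are then
#' greedily re-admitted while feasibility is preserved. Ties are broken by
#' side (genes first) then lexicographically by node id.
#'
#' @param graph A `bipartite_graph` from [build_bipartite()].
#' @param n,m,r Minimum genes, minimum tumors, density fraction in (0, 1].
#' @return A list with `genes`, `tumors` and `achieved_density` (the minimum
#'   per-node edge fraction in the block), or `NULL` when no feasible block
#'   is found.
#' @export
find_dense_submatrix <- function(graph, n = 8, m = 50, r = 0.75) {
  stopifnot(n >= 1, m >= 1, r > 0, r <= 1)
  adj <- graph$adj
  if (nrow(adj) < n || ncol(adj) < m) return(NULL)
  g_in <- rep(TRUE, nrow(adj)); names(g_in) <- graph$genes
  t_in <- rep(TRUE, ncol(adj)); names(t_in) <- graph$tumors
  deleted <- character(0)   # node keys in deletion order
  repeat {
    sub <- adj[g_in, t_in, drop = FALSE]
    if (block_feasible(sub, 1, 1, r)) break
    if (sum(g_in) <= n && sum(t_in) <= m) break  # cannot peel further
    rf <- rowSums(sub) / ncol(sub)
    cf <- colSums(sub) / nrow(sub)
    # candidate for deletion: smallest fraction; genes before tumors, then id
    frac <- c(rf, cf)
    side <- rep(c(0L, 1L), c(length(rf), length(cf)))
    ids <- c(rownames(sub), colnames(sub))
    ord <- order(frac, side, ids)
    pick <- 1L
    # respect size bounds: skip a side already at its minimum
    while (pick <= length(ord)) {
      j <- ord[pick]
      if (side[j] == 0L && sum(g_in) > n) break
      if (side[j] == 1L && sum(t_in) > m) break
      pick <- pick + 1L
    }
    if (pick > length(ord)) break
    j <- ord[pick]
    if (side[j] == 0L) g_in[ids[j]] <- FALSE else t_in[ids[j]] <- FALSE
    deleted <- c(deleted, paste0(if (side[j] == 0L) "g:" else "t:", ids[j]))
  }
  # greedy re-admission of deleted nodes that keep the block feasible
  if (length(deleted) > 0) {
    repeat {
      added <- FALSE
      for (key in deleted) {
        typ <- substr(key, 1, 2); id <- substring(key, 3)
        if (typ == "g:" && !g_in[id]) {
          g_try <- g_in; g_try[id] <- TRUE
          if (block_feasible(adj[g_try, t_in, drop = FALSE], 1, 1, r)) {
            g_in <- g_try; added <- TRUE
          }
        } else if (typ == "t:" && !t_in[id]) {
          t_try <- t_in; t_try[id] <- TRUE
          if (block_feasible(adj[g_in, t_try, drop = FALSE], 1, 1, r)) {
            t_in <- t_try; added <- TRUE
          }
        }
      }
      if (!added) break
    }
  }
  sub <- adj[g_in, t_in, drop = FALSE]
  if (!block_feasible(sub, n, m, r)) return(NULL)
  list(
    genes = rownames(sub),
    tumors = colnames(sub),
    achieved_density = min(min(rowSums(sub) / ncol(sub)),
                           min(colSums(sub) / nrow(sub)))
  )
}

#' Partition the cohort into module-abnormal and module-normal tumors
#'
#' `T_abn` is the tumor side of the mined block. Every other tumor with at
#' most `t * |G|` module genes dysregulated in the module direction joins
#' `T_nor` (inclusive bound); tumors exceeding that bound but outside the
#' block belong to neither set.
#'
#' @param block List with `genes` and `tumors` from [find_dense_submatrix()].
#' @param dysreg [dysreg_matrix()] over the cohort.
#' @param direction `"UP"` or `"DOWN"`.
#' @param t Fraction of module genes tolerated in a normal-like tumor.
#' @return List with character vectors `t_abn` and `t_nor`.
#' @export
derive_partition <- function(block, dysreg, direction, t = 0.5) {
  stopifnot(length(block$genes) > 0, direction %in% c("UP", "DOWN"))
  code <- dysreg_codes[[direction]]
  counts <- colSums(unclass(dysreg)[block$genes, , drop = FALSE] == code)
  others <- setdiff(colnames(dysreg), block$tumors)
  list(
    t_abn = block$tumors,
    t_nor = others[counts[others] <= t * length(block$genes)]
  )
}

#' Discover transcriptomic modules across all TFs and directions
#'
#' For every TF and each direction with DEG candidates, builds the bipartite
#' graph, mines a quasi-biclique and derives the tumor partition. Modules
#' whose gene sets overlap at Jaccard >= 0.8 are deduplicated, keeping the one
#' with the larger `T_abn`; the result is sorted by `|T_abn|` descending.
#'
#' @param degs DEG tibble.
#' @param tf_targets Named list of TF target sets.
#' @param dysreg [dysreg_matrix()] over the tumor cohort.
#' @param config A [pipeline_config()] supplying `n`, `m`, `r`, `t`.
#' @return A tibble with columns `tf`, `direction`, list-columns `genes`,
#'   `t_abn`, `t_nor`, and counts `n_genes`, `n_abn`, `n_nor`,
#'   `achieved_density`.
#' @export
discover_modules <- function(degs, tf_targets, dysreg, config = pipeline_config()) {
  rows <- list()
  for (tf in names(tf_targets)) {
    for (direction in c("UP", "DOWN")) {
      if (!any(degs$direction == direction)) next
      graph <- build_bipartite(degs, tf_targets, tf, direction, dysreg)
      if (length(graph$genes) == 0) next
      block <- find_dense_submatrix(graph, n = config$n, m = config$m, r = config$r)
      if (is.null(block)) next
      part <- derive_partition(block, dysreg, direction, t = config$t)
      rows[[length(rows) + 1]] <- tibble::tibble(
        tf = tf, direction = direction,
        genes = list(block$genes),
        t_abn = list(part$t_abn), t_nor = list(part$t_nor),
        n_genes = length(block$genes),
        n_abn = length(part$t_abn), n_nor = length(part$t_nor),
        achieved_density = block$achieved_density
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      tf = character(0), direction = character(0),
      genes = list(), t_abn = list(), t_nor = list(),
      n_genes = integer(0), n_abn = integer(0), n_nor = integer(0),
      achieved_density = numeric(0)
    ))
  }
  mods <- dplyr::arrange(dplyr::bind_rows(rows),
                         dplyr::desc(.data$n_abn), .data$tf, .data$direction)
  # dedup near-identical gene sets, keeping the larger T_abn (list is sorted)
  keep <- rep(TRUE, nrow(mods))
  for (i in seq_len(nrow(mods))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      a <- mods$genes[[i]]; b <- mods$genes[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= 0.8) { keep[i] <- FALSE; break }
    }
  }
  mods[keep, ]
}
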