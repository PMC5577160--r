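#' Mutual-exclusivity ratio of a gene set
#'
#' The number of `T_abn` tumors covered by at least one alteration event of
#' the set, divided by the set's total event count in `T_abn` (one event per
#' altered gene-tumor pair). 1.0 means perfectly exclusive: no tumor is hit
#' by two genes of the set. Undefined (error) when the set has no events in
#' `T_abn`; [solution_weight()] maps that case to weight 1.
#'
#' @param genes Non-empty character vector.
#' @param sga An `sga_matrix`.
#' @param t_abn Tumor ids of the module-abnormal set.
#' @return A fraction in (0, 1].
#' @export
me_ratio <- function(genes, sga, t_abn) {
  stopifnot(length(genes) > 0)
  ev <- sga$events[intersect(genes, rownames(sga$events)),
                   intersect(t_abn, colnames(sga$events)), drop = FALSE]
  n_events <- sum(ev)
  if (n_events == 0) {
    stop("gene set has no SGA events in T_abn; ME ratio undefined", call. = FALSE)
  }
  sum(colSums(ev) > 0) / n_events
}

#' Weight of a candidate driver solution
#'
#' Lower is better. The weight is 1 (worst) when the solution is invalid:
#' fewer than `k` genes, no events in `T_abn`, or a mutual-exclusivity ratio
#' below `r_me`. Otherwise the weight is the module-level SGA enrichment
#' p-value of the gene set.
#'
#' @inheritParams me_ratio
#' @param t_nor Control tumor ids.
#' @param k Required solution size.
#' @param r_me Minimum feasible ME ratio.
#' @return A weight in (0, 1].
#' @export
solution_weight <- function(genes, sga, t_abn, t_nor, k = 6, r_me = 0.8) {
  if (length(unique(genes)) < k) return(1)
  ratio <- tryCatch(me_ratio(genes, sga, t_abn), error = function(e) NA_real_)
  if (is.na(ratio) || ratio < r_me) return(1)
  module_enrichment(genes, sga, t_abn, t_nor)
}

# --- internal fast evaluation context ------------------------------------
# Precomputes per-candidate event vectors so the GA inner loop is a handful
# of vector ops; weights are memoized per sorted gene-index key.
ga_context <- function(candidates, sga, t_abn, t_nor, k, r_me) {
  pool <- candidates$gene
  ev <- sga$events
  abn <- intersect(t_abn, colnames(ev))
  all_t <- c(intersect(t_abn, colnames(ev)), intersect(t_nor, colnames(ev)))
  cov_abn <- matrix(FALSE, length(pool), length(abn),
                    dimnames = list(pool, abn))
  cov_all <- matrix(FALSE, length(pool), length(all_t),
                    dimnames = list(pool, all_t))
  present <- pool %in% rownames(ev)
  cov_abn[present, ] <- ev[pool[present], abn, drop = FALSE]
  cov_all[present, ] <- ev[pool[present], all_t, drop = FALSE]
  list(
    pool = pool, p_gene = candidates$p,
    cov_abn = cov_abn, cov_all = cov_all,
    is_abn = colnames(cov_all) %in% t_abn,
    K = length(t_abn), N = length(t_abn) + length(t_nor),
    k = k, r_me = r_me, cache = new.env(parent = emptyenv())
  )
}

ga_weight <- function(idx, ctx) {
  key <- paste(sort.int(idx), collapse = ",")
  w <- ctx$cache[[key]]
  if (!is.null(w)) return(w)
  w <- 1
  if (length(idx) >= ctx$k) {
    ev <- ctx$cov_abn[idx, , drop = FALSE]
    n_events <- sum(ev)
    if (n_events > 0) {
      ratio <- sum(colSums(ev) > 0) / n_events
      if (ratio >= ctx$r_me) {
        cov <- colSums(ctx$cov_all[idx, , drop = FALSE]) > 0
        x <- sum(cov & ctx$is_abn)
        w <- hypergeom_tail(x, sum(cov), ctx$K, ctx$N)
      }
    }
  }
  ctx$cache[[key]] <- w
  w
}

#' Greedy seeding of one GA solution
#'
#' Builds a solution gene by gene in ascending order of per-gene enrichment
#' p, skipping any gene whose addition would drop the running ME ratio below
#' `r_me`. Before construction, each gene already used by earlier seeds is
#' independently masked out with probability 0.5, so successive seeds explore
#' different regions of the pool. If the greedy pass stalls below `k` genes,
#' the solution is padded with random eligible genes; if even padding cannot
#' reach `k`, the undersized solution is returned (it scores weight 1).
#'
#' @param candidates Candidate tibble from [filter_candidates()].
#' @param sga An `sga_matrix`.
#' @param t_abn Module-abnormal tumor ids.
#' @param k Solution size.
#' @param r_me Minimum feasible ME ratio.
#' @param used Character vector of genes used by previous seeds.
#' @return Character vector of up to `k` distinct genes.
#' @export
greedy_seed <- function(candidates, sga, t_abn, k = 6, r_me = 0.8,
                        used = character(0)) {
  stopifnot(nrow(candidates) >= k)
  ctx <- ga_context(candidates, sga, t_abn, character(0), k, r_me)
  idx <- greedy_seed_idx(ctx, match(unique(used), ctx$pool))
  ctx$pool[idx]
}

greedy_seed_idx <- function(ctx, used_idx) {
  n_pool <- length(ctx$pool)
  masked <- rep(FALSE, n_pool)
  used_idx <- used_idx[!is.na(used_idx)]
  if (length(used_idx) > 0) {
    masked[used_idx] <- stats::runif(length(used_idx)) < 0.5
  }
  order_p <- order(ctx$p_gene, ctx$pool)
  sol <- integer(0)
  covered <- rep(FALSE, ncol(ctx$cov_abn))
  n_events <- 0L
  for (j in order_p) {
    if (length(sol) >= ctx$k) break
    if (masked[j]) next
    ev_j <- ctx$cov_abn[j, ]
    new_events <- n_events + sum(ev_j)
    if (new_events == 0) next
    new_ratio <- sum(covered | ev_j) / new_events
    if (new_ratio < ctx$r_me) next
    sol <- c(sol, j)
    covered <- covered | ev_j
    n_events <- new_events
  }
  if (length(sol) < ctx$k) {
    eligible <- setdiff(which(!masked), sol)
    if (length(eligible) > 0) {
      extra <- sample_vec(eligible, min(ctx$k - length(sol), length(eligible)))
      sol <- c(sol, extra)
    }
  }
  if (length(sol) < ctx$k) {  # last resort: ignore masking to reach size k
    eligible <- setdiff(seq_len(n_pool), sol)
    sol <- c(sol, sample_vec(eligible, min(ctx$k - length(sol), length(eligible))))
  }
  sol
}

# sample() without its length-1 surprise
sample_vec <- function(x, size) x[sample.int(length(x), size)]

#' Single-point crossover and mutation of two parent solutions
#'
#' Exchanges the suffixes of the two parents at a uniform cut position in
#' 1..k−1, repairs any duplicate genes by substituting uniform draws from the
#' pool, then mutates exactly two positions of the first child and one of the
#' second with pool genes not present in the child before or during mutation
#' (so exactly 2 and 1 genes change). Children always hold `k` distinct
#' genes.
#'
#' @param parent_a,parent_b Character vectors of `k` genes.
#' @param pool Candidate gene pool.
#' @return List of two character vectors (`child_a`, `child_b`).
#' @export
crossover_mutate <- function(parent_a, parent_b, pool) {
  k <- length(parent_a)
  stopifnot(length(parent_b) == k, k >= 2)
  if (length(pool) < k + 2) stop("candidate pool too small to repair children", call. = FALSE)
  ia <- match(parent_a, pool); ib <- match(parent_b, pool)
  stopifnot(!anyNA(ia), !anyNA(ib))
  kids <- crossover_mutate_idx(ia, ib, length(pool))
  list(child_a = pool[kids[[1]]], child_b = pool[kids[[2]]])
}

crossover_mutate_idx <- function(ia, ib, n_pool) {
  k <- length(ia)
  cut <- sample.int(k - 1L, 1L)
  ca <- c(ia[seq_len(cut)], ib[(cut + 1L):k])
  cb <- c(ib[seq_len(cut)], ia[(cut + 1L):k])
  repair <- function(ch) {
    while (anyDuplicated(ch)) {
      dup <- which(duplicated(ch))[1]
      ch[dup] <- sample.int(n_pool, 1L)
    }
    ch
  }
  mutate_n <- function(ch, n_mut) {
    pos <- sample_vec(seq_len(k), min(n_mut, k))
    banned <- ch  # never reintroduce a pre-mutation gene: n_mut genes change
    for (p in pos) {
      repl <- sample_vec(setdiff(seq_len(n_pool), union(banned, ch)), 1L)
      ch[p] <- repl
    }
    ch
  }
  list(mutate_n(repair(ca), 2L), mutate_n(repair(cb), 1L))
}

#' Genetic-algorithm search for a driver module
#'
#' Searches the filtered candidate genes for the size-`k` set with the lowest
#' weight (the module-level enrichment p-value among feasible, mutually
#' exclusive solutions). The first generation holds `round(2S/3)` greedy
#' seeds and the rest random `k`-sets; each generation mates every unordered
#' pair of current solutions via [crossover_mutate()] and keeps the `S`
#' lowest-weight solutions among parents and children (ties broken by the
#' sorted gene list), so the best weight never increases. Fully reproducible
#' from `config$seed`.
#'
#' @param candidates Candidate tibble from [filter_candidates()]; at least
#'   `k` rows.
#' @param sga An `sga_matrix`.
#' @param t_abn,t_nor Tumor id vectors.
#' @param config A [pipeline_config()] supplying `S`, `k`, `r_me`,
#'   `generations` and `seed`.
#' @return A `driver_fit` object: `best` (genes, me_ratio, enrichment_p,
#'   weight), `history` (per-generation best weight, length
#'   `generations + 1`), `population` tibble, plus the settings used.
#' @export
evolve <- function(candidates, sga, t_abn, t_nor, config = pipeline_config()) {
  stopifnot(nrow(candidates) >= config$k)
  if (!is.null(config$seed)) set.seed(config$seed)
  ctx <- ga_context(candidates, sga, t_abn, t_nor, config$k, config$r_me)
  n_pool <- length(ctx$pool)
  S <- config$S; k <- config$k
  n_greedy <- round(2 * S / 3)

  pop <- vector("list", S)
  used <- integer(0)
  for (i in seq_len(n_greedy)) {
    sol <- greedy_seed_idx(ctx, used)
    pop[[i]] <- sol
    used <- union(used, sol)
  }
  for (i in seq(n_greedy + 1L, S)) {
    pop[[i]] <- sample_vec(seq_len(n_pool), min(k, n_pool))
  }
  weights <- vapply(pop, ga_weight, numeric(1), ctx = ctx)
  history <- numeric(config$generations + 1L)
  history[1] <- min(weights)

  pairs <- utils::combn(S, 2)
  for (gen in seq_len(config$generations)) {
    children <- vector("list", 2L * ncol(pairs))
    for (pi in seq_len(ncol(pairs))) {
      a <- pop[[pairs[1, pi]]]; b <- pop[[pairs[2, pi]]]
      if (length(a) == k && length(b) == k && n_pool >= k + 2) {
        kids <- crossover_mutate_idx(a, b, n_pool)
      } else {
        kids <- list(a, b)  # undersized parents pass through unchanged
      }
      children[[2 * pi - 1L]] <- kids[[1]]
      children[[2 * pi]] <- kids[[2]]
    }
    all_sol <- c(pop, children)
    all_w <- c(weights, vapply(children, ga_weight, numeric(1), ctx = ctx))
    keys <- vapply(all_sol, function(s) paste(sort.int(s), collapse = ","),
                   character(1))
    ord <- order(all_w, keys)[seq_len(S)]
    pop <- all_sol[ord]
    weights <- all_w[ord]
    history[gen + 1L] <- weights[1]
  }

  best_idx <- pop[[1]]
  best_genes <- ctx$pool[best_idx]
  best_ratio <- tryCatch(me_ratio(best_genes, sga, t_abn),
                         error = function(e) NA_real_)
  structure(list(
    best = list(
      genes = best_genes,
      me_ratio = best_ratio,
      enrichment_p = module_enrichment(best_genes, sga, t_abn, t_nor),
      weight = weights[1]
    ),
    history = history,
    population = tibble::tibble(
      rank = seq_len(S),
      genes = lapply(pop, function(s) ctx$pool[s]),
      weight = weights
    ),
    S = S, k = k, r_me = config$r_me,
    generations = config$generations, seed = config$seed
  ), class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("<driver_fit> best weight %.4g after %d generations\n",
              x$best$weight, x$generations))
  cat("  genes:", paste(x$best$genes, collapse = ", "), "\n")
  cat(sprintf("  ME ratio %.3f, enrichment p %.4g\n",
              x$best$me_ratio, x$best$enrichment_p))
  invisible(x)
}

#' @export
tidy.driver_fit <- function(x, ...) {
  dplyr::mutate(x$population,
                genes = vapply(.data$genes, paste, character(1), collapse = ","))
}

#' @export
glance.driver_fit <- function(x, ...) {
  tibble::tibble(
    best_weight = x$best$weight,
    me_ratio = x$best$me_ratio,
    enrichment_p = x$best$enrichment_p,
    k = x$k, S = x$S, generations = x$generations,
    converged_at = which.min(x$history) - 1L
  )
}

#' @export
autoplot.driver_fit <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$history) - 1L,
                       best_weight = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$best_weight)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best weight (enrichment p)",
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}
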