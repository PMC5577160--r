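#' Build the binary somatic-alteration matrix
#'
#' Collapses mutation and copy-number evidence into a gene-by-tumor binary
#' indicator of at least one valid alteration event, keeping per-cell
#' provenance (`MUT`, `AMP`, `DEL`). Invalid events are removed here: silent
#' mutations are excluded, a high-level amplification (call >= +2) counts only
#' when the gene is expression-UP in that tumor, a high-level deletion
#' (call <= −2) only when the gene is DOWN, and low-level calls (±1, 0) never
#' produce events.
#'
#' @param mutations Tibble of mutation records (`gene`, `tumor`,
#'   `variant_classification`) as from [read_maf()].
#' @param cna Tibble of copy-number calls (`gene`, `tumor`, `call`) as from
#'   [read_gistic()], or `NULL` for mutation-only data.
#' @param dysreg [dysreg_matrix()] used for the CNA-expression concordance
#'   check; must cover every tumor appearing in `cna`.
#' @param silent_classes Variant classifications treated as non-events.
#' @return An `sga_matrix`: logical `events` matrix plus logical provenance
#'   matrices `mut`, `amp`, `del` of the same shape.
#' @export
preprocess_sga <- function(mutations, cna = NULL, dysreg = NULL,
                           silent_classes = "Silent") {
  mutations <- tibble::as_tibble(mutations)
  if (!is.null(cna) && nrow(cna) > 0) {
    if (is.null(dysreg)) {
      stop("copy-number calls require a dysregulation matrix for the concordance check",
           call. = FALSE)
    }
    missing_t <- setdiff(unique(cna$tumor), colnames(dysreg))
    if (length(missing_t) > 0) {
      stop("tumor(s) in copy-number data absent from dysregulation matrix: ",
           paste(utils::head(missing_t, 5), collapse = ", "), call. = FALSE)
    }
  }
  genes <- sort(unique(c(mutations$gene, if (!is.null(cna)) cna$gene)))
  tumors <- sort(unique(c(mutations$tumor, if (!is.null(cna)) cna$tumor)))
  shape <- list(genes, tumors)
  mut <- matrix(FALSE, length(genes), length(tumors), dimnames = shape)
  amp <- mut; del <- mut
  keep <- !(mutations$variant_classification %in% silent_classes)
  if (any(keep)) {
    mut[cbind(match(mutations$gene[keep], genes),
              match(mutations$tumor[keep], tumors))] <- TRUE
  }
  if (!is.null(cna) && nrow(cna) > 0) {
    dy <- unclass(dysreg)
    in_dysreg <- cna$gene %in% rownames(dy)
    state <- rep(0L, nrow(cna))
    state[in_dysreg] <- dy[cbind(match(cna$gene[in_dysreg], rownames(dy)),
                                 match(cna$tumor[in_dysreg], colnames(dy)))]
    amp_keep <- cna$call >= 2L & state == 1L
    del_keep <- cna$call <= -2L & state == -1L
    if (any(amp_keep)) {
      amp[cbind(match(cna$gene[amp_keep], genes),
                match(cna$tumor[amp_keep], tumors))] <- TRUE
    }
    if (any(del_keep)) {
      del[cbind(match(cna$gene[del_keep], genes),
                match(cna$tumor[del_keep], tumors))] <- TRUE
    }
  }
  structure(list(events = mut | amp | del, mut = mut, amp = amp, del = del),
            class = "sga_matrix")
}

#' @export
print.sga_matrix <- function(x, ...) {
  cat(sprintf("<sga_matrix> %d genes x %d tumors; %d events (MUT %d, AMP %d, DEL %d)\n",
              nrow(x$events), ncol(x$events), sum(x$events),
              sum(x$mut), sum(x$amp), sum(x$del)))
  invisible(x)
}

#' @export
tidy.sga_matrix <- function(x, ...) {
  idx <- which(x$events, arr.ind = TRUE)
  tibble::tibble(
    gene = rownames(x$events)[idx[, 1]],
    tumor = colnames(x$events)[idx[, 2]],
    mut = x$mut[idx], amp = x$amp[idx], del = x$del[idx]
  )
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, draws)`: the probability that at
#' least `x` of `draws` draws without replacement from a population of `N`
#' containing `K` successes are successes. While every binomial coefficient
#' fits in double precision the tail is summed from exact `choose()` terms;
#' beyond that it switches to log-space summation (log-sum-exp), so it stays
#' accurate to full double precision across the population sizes a tumor
#' cohort reaches.
#'
#' @param x Observed success count (vectorised).
#' @param draws Number of draws.
#' @param K Successes in the population.
#' @param N Population size.
#' @return `P(X >= x)`, a probability in (0, 1].
#' @export
hypergeom_tail <- function(x, draws, K, N) {
  stopifnot(length(draws) == 1, length(K) == 1, length(N) == 1,
            N >= 0, K >= 0, K <= N, draws >= 0, draws <= N,
            all(x >= 0), all(x <= draws))
  exact <- lchoose(N, draws) < 700  # all terms representable as doubles
  vapply(x, function(xi) {
    lo <- max(xi, draws - (N - K))  # support lower bound
    hi <- min(draws, K)
    if (lo > hi) return(if (xi <= max(0, draws - (N - K))) 1 else 0)
    i <- lo:hi
    if (exact) {
      return(min(1, sum(choose(K, i) * choose(N - K, draws - i)) / choose(N, draws)))
    }
    lg <- lchoose(K, i) + lchoose(N - K, draws - i) - lchoose(N, draws)
    mx <- max(lg)
    min(1, exp(mx + log(sum(exp(lg - mx)))))
  }, numeric(1))
}

#' Per-gene SGA enrichment in the module-abnormal tumors
#'
#' For each gene, tests whether its alteration events concentrate in `T_abn`
#' using the hypergeometric upper tail with `T_nor` as the control
#' background: the population is `T_abn` with `T_nor` (tumors in neither
#' partition are ignored), successes are the `T_abn` tumors, and the draws
#' are the event-bearing tumors of that population. Genes passing the cutoff
#' are returned sorted by p, ties broken by gene symbol.
#'
#' @param sga An `sga_matrix` from [preprocess_sga()].
#' @param t_abn,t_nor Disjoint, non-empty character vectors of tumor ids.
#' @param candidate_p Inclusive p-value cutoff (default 0.01).
#' @return A tibble with columns `gene`, `x_abn`, `draws`, `K`, `N`, `p`.
#' @export
filter_candidates <- function(sga, t_abn, t_nor, candidate_p = 0.01) {
  stopifnot(inherits(sga, "sga_matrix"))
  if (length(t_abn) == 0 || length(t_nor) == 0) {
    stop("T_abn and T_nor must both be non-empty", call. = FALSE)
  }
  if (length(intersect(t_abn, t_nor)) > 0) {
    stop("T_abn and T_nor must be disjoint", call. = FALSE)
  }
  ev <- sga$events
  abn <- intersect(t_abn, colnames(ev))
  nor <- intersect(t_nor, colnames(ev))
  K <- length(t_abn)
  N <- length(t_abn) + length(t_nor)
  x_abn <- rowSums(ev[, abn, drop = FALSE])
  draws <- x_abn + rowSums(ev[, nor, drop = FALSE])
  p <- vapply(seq_along(x_abn), function(i) {
    hypergeom_tail(x_abn[i], draws[i], K, N)
  }, numeric(1))
  out <- tibble::tibble(
    gene = rownames(ev), x_abn = as.integer(x_abn),
    draws = as.integer(draws), K = K, N = N, p = p
  )
  out <- out[out$p <= candidate_p, ]
  dplyr::arrange(out, .data$p, .data$gene)
}

#' Module-level SGA enrichment
#'
#' The coverage set is every tumor of `T_abn` with `T_nor` holding at least
#' one event in any module gene; the enrichment p-value is the hypergeometric
#' upper tail of the covered `T_abn` count given the coverage size, `|T_abn|`
#' successes and the `T_abn` + `T_nor` population.
#'
#' @param genes Non-empty character vector of module genes.
#' @param sga An `sga_matrix`.
#' @param t_abn,t_nor Tumor id vectors.
#' @return A probability in (0, 1].
#' @export
module_enrichment <- function(genes, sga, t_abn, t_nor) {
  stopifnot(length(genes) > 0)
  ev <- sga$events
  genes_in <- intersect(genes, rownames(ev))
  K <- length(t_abn)
  N <- length(t_abn) + length(t_nor)
  if (length(genes_in) == 0) return(1)
  covered <- function(tumors) {
    tu <- intersect(tumors, colnames(ev))
    if (length(tu) == 0) return(0L)
    sum(colSums(ev[genes_in, tu, drop = FALSE]) > 0)
  }
  x <- covered(t_abn)
  draws <- x + covered(t_nor)
  hypergeom_tail(x, draws, K, N)
}

#' Null distribution of module enrichment from random gene sets
#'
#' Draws `reps` uniform k-gene sets from the gene universe of the SGA matrix
#' (or a supplied universe) and computes each set's module-level enrichment
#' p-value, for comparison against discovered driver modules.
#'
#' @param sga An `sga_matrix`.
#' @param t_abn,t_nor Tumor id vectors.
#' @param k Genes per random set.
#' @param reps Number of random sets.
#' @param universe Candidate gene universe (default: all SGA genes).
#' @return A tibble with columns `rep` and `p`.
#' @export
random_baseline <- function(sga, t_abn, t_nor, k, reps = 100,
                            universe = rownames(sga$events)) {
  stopifnot(reps >= 1)
  if (length(universe) < k) {
    stop("candidate universe smaller than k", call. = FALSE)
  }
  p <- vapply(seq_len(reps), function(i) {
    module_enrichment(sample(universe, k), sga, t_abn, t_nor)
  }, numeric(1))
  tibble::tibble(rep = seq_len(reps), p = p)
}

#' Compare a driver module's enrichment with the random baseline
#'
#' @param baseline Tibble from [random_baseline()].
#' @param module_p Enrichment p-value(s) of discovered driver module(s).
#' @return A ggplot: the baseline distribution of −log10 p with the module
#'   value(s) marked.
#' @export
plot_baseline <- function(baseline, module_p) {
  ggplot2::ggplot(baseline, ggplot2::aes(x = -log10(.data$p))) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = -log10(module_p),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "enrichment p"),
                  y = "random gene sets",
                  title = "Driver-module enrichment vs random selection") +
    ggplot2::theme_minimal()
}
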