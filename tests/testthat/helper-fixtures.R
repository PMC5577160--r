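# Small fixture builders used across test files.

make_expr <- function(values, role) {
  expression_matrix(values, role)
}

# dysreg_matrix from a character matrix of UP/DOWN/NEUTRAL
make_dysreg <- function(calls_chr) {
  codes <- c(DOWN = -1L, NEUTRAL = 0L, UP = 1L)
  m <- matrix(codes[calls_chr], nrow(calls_chr), ncol(calls_chr),
              dimnames = dimnames(calls_chr))
  dysreg_matrix(m)
}

# sga_matrix built through the public API from a logical gene x tumor matrix
# (every event a missense mutation)
sga_from_matrix <- function(events) {
  idx <- which(events, arr.ind = TRUE)
  mutations <- tibble::tibble(
    gene = rownames(events)[idx[, 1]],
    tumor = colnames(events)[idx[, 2]],
    variant_classification = "Missense_Mutation"
  )
  # anchor rows/columns so empty genes and tumors are preserved
  anchors <- tibble::tibble(
    gene = rep(rownames(events), each = 1),
    tumor = colnames(events)[1],
    variant_classification = "Silent"
  )
  anchors2 <- tibble::tibble(
    gene = rownames(events)[1],
    tumor = colnames(events),
    variant_classification = "Silent"
  )
  preprocess_sga(dplyr::bind_rows(mutations, anchors, anchors2))
}

# random bipartite graph with an optional planted dense block
random_bipartite <- function(n_genes, n_tumors, planted_genes = 0,
                             planted_tumors = 0, within = 0.9, background = 0.05) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  tumors <- sprintf("T%02d", seq_len(n_tumors))
  adj <- matrix(stats::runif(n_genes * n_tumors) < background,
                n_genes, n_tumors, dimnames = list(genes, tumors))
  pg <- genes[seq_len(planted_genes)]
  pt <- tumors[seq_len(planted_tumors)]
  if (planted_genes > 0 && planted_tumors > 0) {
    adj[pg, pt] <- matrix(stats::runif(planted_genes * planted_tumors) < within,
                          planted_genes, planted_tumors)
  }
  calls <- matrix(0L, n_genes, n_tumors, dimnames = list(genes, tumors))
  calls[adj] <- 1L
  list(adj = adj, dysreg = dysreg_matrix(calls),
       planted_genes = pg, planted_tumors = pt)
}

as_graph <- function(adj, tf = "TF1", direction = "UP") {
  structure(list(genes = rownames(adj), tumors = colnames(adj),
                 adj = adj, tf = tf, direction = direction),
            class = "bipartite_graph")
}
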