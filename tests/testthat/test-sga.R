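test_that("preprocessing drops silent mutations and discordant CNAs", {
  mutations <- tibble::tibble(
    gene = c("A", "A", "B"),
    tumor = c("t1", "t2", "t1"),
    variant_classification = c("Missense_Mutation", "Silent", "Nonsense_Mutation")
  )
  cna <- tibble::tibble(
    gene = c("C", "C", "D", "D"),
    tumor = c("t1", "t2", "t1", "t2"),
    call = c(2L, 2L, -2L, -1L)
  )
  calls <- matrix("NEUTRAL", 4, 2, dimnames = list(c("A", "B", "C", "D"), c("t1", "t2")))
  calls["C", "t1"] <- "UP"     # concordant amplification
  calls["D", "t1"] <- "DOWN"   # concordant deletion
  calls["D", "t2"] <- "DOWN"   # concordant but call is only -1
  sga <- preprocess_sga(mutations, cna, make_dysreg(calls))

  expect_true(sga$mut["A", "t1"])
  expect_false(sga$events["A", "t2"])            # silent excluded
  expect_true(sga$amp["C", "t1"])
  expect_false(sga$events["C", "t2"])            # +2 but NEUTRAL
  expect_true(sga$del["D", "t1"])
  expect_false(sga$events["D", "t2"])            # -1 never an event
  expect_equal(sga$events, sga$mut | sga$amp | sga$del)

  expect_error(
    preprocess_sga(mutations, tibble::tibble(gene = "C", tumor = "t9", call = 2L),
                   make_dysreg(calls)),
    "t9"
  )
})

test_that("hypergeometric tail reproduces hand-computed values exactly", {
  expect_equal(hypergeom_tail(3, 3, 6, 10), 1 / 6)        # C(6,3)/C(10,3)
  expect_equal(hypergeom_tail(4, 5, 6, 10), 66 / 252)     # [C(6,4)C(4,1)+C(6,5)]/C(10,5)
  expect_equal(hypergeom_tail(0, 3, 6, 10), 1)
  expect_equal(hypergeom_tail(6, 10, 6, 10), 1)           # whole population drawn
  expect_error(hypergeom_tail(4, 3, 6, 10))
  expect_error(hypergeom_tail(1, 11, 6, 10))
})

test_that("hypergeometric tail matches enumeration and phyper oracles", {
  for (N in c(6, 9)) {
    for (K in 0:N) for (draws in 0:N) for (x in 0:draws) {
      expect_equal(hypergeom_tail(x, draws, K, N),
                   oracle_hyper_enum(x, draws, K, N), tolerance = 1e-12)
    }
  }
  set.seed(1)
  for (i in 1:200) {
    N <- sample(2:2000, 1); K <- sample(0:N, 1); draws <- sample(0:N, 1)
    x <- sample(0:draws, 1)
    mine <- hypergeom_tail(x, draws, K, N)
    ref <- stats::phyper(x - 1, K, N - K, draws, lower.tail = FALSE)
    if (ref > 0) expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("candidate filtering matches the worked enrichment examples", {
  # gene altered in 3 tumors, all in T_abn; |T_abn| = 6, |T_nor| = 4
  events <- matrix(FALSE, 2, 10,
                   dimnames = list(c("g1", "g2"), sprintf("t%d", 1:10)))
  events["g1", c("t1", "t2", "t3")] <- TRUE
  sga <- sga_from_matrix(events)
  t_abn <- sprintf("t%d", 1:6); t_nor <- sprintf("t%d", 7:10)

  all_genes <- filter_candidates(sga, t_abn, t_nor, candidate_p = 1)
  expect_equal(all_genes$p[all_genes$gene == "g1"], 1 / 6)
  expect_equal(all_genes$p[all_genes$gene == "g2"], 1)  # zero events

  kept <- filter_candidates(sga, t_abn, t_nor, candidate_p = 0.01)
  expect_equal(nrow(kept), 0L)  # both excluded at 0.01

  expect_error(filter_candidates(sga, character(0), t_nor), "non-empty")
  expect_error(filter_candidates(sga, t_abn, t_abn[1]), "disjoint")
})

test_that("a strongly enriched planted gene passes the 0.01 filter", {
  # deterministic 120/80 partition: altered in 40% of T_abn, 1% of T_nor
  t_abn <- sprintf("a%03d", 1:120); t_nor <- sprintf("n%03d", 1:80)
  events <- matrix(FALSE, 2, 200, dimnames = list(c("drv", "bg"), c(t_abn, t_nor)))
  events["drv", t_abn[1:48]] <- TRUE
  events["drv", t_nor[1]] <- TRUE
  events["bg", c(t_abn[1:3], t_nor[1:2])] <- TRUE
  sga <- sga_from_matrix(events)
  kept <- filter_candidates(sga, t_abn, t_nor, candidate_p = 0.01)
  expect_equal(kept$gene, "drv")
  expect_lt(kept$p, 1e-10)

  # idempotent: re-filtering the kept universe changes nothing
  expect_equal(filter_candidates(sga, t_abn, t_nor, 0.01), kept)
})

test_that("module enrichment follows the coverage definition", {
  t_abn <- sprintf("t%d", 1:6); t_nor <- sprintf("t%d", 7:10)
  # 4 covered tumors in T_abn, 1 in T_nor -> P(X >= 4; N=10, K=6, draws=5)
  events <- matrix(FALSE, 6, 10, dimnames = list(sprintf("g%d", 1:6), c(t_abn, t_nor)))
  for (i in 1:4) events[i, t_abn[i]] <- TRUE
  events[5, t_nor[1]] <- TRUE
  sga <- sga_from_matrix(events)
  expect_equal(module_enrichment(rownames(events), sga, t_abn, t_nor), 66 / 252)

  # full coverage of T_abn, none of T_nor: the smallest achievable tail
  events2 <- matrix(FALSE, 1, 10, dimnames = list("g", c(t_abn, t_nor)))
  events2["g", t_abn] <- TRUE
  sga2 <- sga_from_matrix(events2)
  expect_equal(module_enrichment("g", sga2, t_abn, t_nor),
               1 / choose(10, 6))
  # no coverage at all
  expect_equal(module_enrichment("g2", sga2, t_abn, t_nor), 1)
})

test_that("enrichment p is monotone in event placement", {
  set.seed(8)
  t_abn <- sprintf("a%02d", 1:30); t_nor <- sprintf("n%02d", 1:20)
  for (i in 1:50) {
    events <- matrix(stats::runif(50) < 0.2, 1, 50,
                     dimnames = list("g", c(t_abn, t_nor)))
    sga <- sga_from_matrix(events)
    p0 <- filter_candidates(sga, t_abn, t_nor, 1)$p[1]
    free_abn <- t_abn[!events[1, t_abn]]
    if (length(free_abn) > 0) {
      ev2 <- events; ev2[1, free_abn[1]] <- TRUE
      p_more_abn <- filter_candidates(sga_from_matrix(ev2), t_abn, t_nor, 1)$p[1]
      expect_lte(p_more_abn, p0)
    }
    free_nor <- t_nor[!events[1, t_nor]]
    if (length(free_nor) > 0) {
      ev3 <- events; ev3[1, free_nor[1]] <- TRUE
      p_more_nor <- filter_candidates(sga_from_matrix(ev3), t_abn, t_nor, 1)$p[1]
      expect_gte(p_more_nor, p0)
    }
  }
})

test_that("random baseline is deterministic under a seed and validates k", {
  events <- matrix(stats::runif(200) < 0.3, 10, 20,
                   dimnames = list(sprintf("g%d", 1:10), sprintf("t%d", 1:20)))
  sga <- sga_from_matrix(events)
  t_abn <- sprintf("t%d", 1:12); t_nor <- sprintf("t%d", 13:20)
  set.seed(99); b1 <- random_baseline(sga, t_abn, t_nor, k = 3, reps = 20)
  set.seed(99); b2 <- random_baseline(sga, t_abn, t_nor, k = 3, reps = 20)
  expect_identical(b1, b2)
  expect_error(random_baseline(sga, t_abn, t_nor, k = 11), "smaller than k")

  # k = whole universe is a single deterministic value
  one <- random_baseline(sga, t_abn, t_nor, k = 10, reps = 1)
  expect_equal(one$p, module_enrichment(rownames(events), sga, t_abn, t_nor))
})

test_that("a planted exclusive driver beats nearly all random gene sets", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:100)
  t_abn <- sprintf("a%03d", 1:60); t_nor <- sprintf("n%03d", 1:40)
  sim <- generate_sga(genes, t_abn, t_nor, k = 6, coverage = 0.9,
                      background_rate = 0.02, silent_fraction = 0,
                      cna_fraction = 0)
  sga <- preprocess_sga(sim$mutations)
  p_planted <- module_enrichment(sim$truth$driver, sga, t_abn, t_nor)
  base <- random_baseline(sga, t_abn, t_nor, k = 6, reps = 100)
  expect_gte(mean(base$p >= p_planted), 0.95)
})
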