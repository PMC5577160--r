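cellline_fixture <- function(values) {
  make_expr(values, "CELL_LINE")
}

test_that("fold-change calls respect the inclusive threshold and union rule", {
  vals <- matrix(c(10, 10, 10, 10,   # parent
                   25, 20, 19, 4),   # child
                 nrow = 4, dimnames = list(c("up1", "bnd", "mid", "dn1"),
                                           c("P", "C")))
  expr <- cellline_fixture(vals)
  degs <- call_cellline_degs(expr, tibble::tibble(child = "C", parent = "P"))
  expect_setequal(degs$gene[degs$direction == "UP"], c("up1", "bnd"))  # 2.5 and exactly 2
  expect_setequal(degs$gene[degs$direction == "DOWN"], "dn1")          # 10/4 = 2.5
  expect_false("mid" %in% degs$gene)                                   # 1.9-fold
})

test_that("genes up in one comparison and down in another are removed", {
  vals <- matrix(c(10, 10,
                   25, 25,    # C1: conflict up 2.5x, stay up
                   10, 60),   # C2: conflict down (25->10), stay up (25->60)
                 nrow = 2, dimnames = list(c("conflict", "stay"),
                                           c("P", "C1", "C2")))
  expr <- cellline_fixture(vals)
  comps <- tibble::tibble(child = c("C1", "C2"), parent = c("P", "C1"))
  degs <- call_cellline_degs(expr, comps)
  expect_false("conflict" %in% degs$gene)
  expect_equal(degs$gene[degs$direction == "UP"], "stay")
  expect_equal(length(intersect(degs$gene[degs$direction == "UP"],
                                degs$gene[degs$direction == "DOWN"])), 0)
})

test_that("zero expression never causes a division error", {
  vals <- matrix(c(0, 5, 5, 0), nrow = 2,
                 dimnames = list(c("zeroP", "zeroC"), c("P", "C")))
  expr <- cellline_fixture(vals)
  degs <- call_cellline_degs(expr, tibble::tibble(child = "C", parent = "P"))
  expect_true("zeroP" %in% degs$gene[degs$direction == "UP"])   # 5/1 floor
  expect_true("zeroC" %in% degs$gene[degs$direction == "DOWN"])
})

test_that("comparisons are validated", {
  vals <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("P", "C")))
  expr <- make_expr(vals * 1.0, c("CELL_LINE", "TUMOR"))
  expect_error(
    call_cellline_degs(expr, tibble::tibble(child = "C", parent = "P")),
    "CELL_LINE"
  )
  expr2 <- cellline_fixture(matrix(1:4 * 1.0, 2, dimnames = list(c("A", "B"), c("P", "C"))))
  expect_error(
    call_cellline_degs(expr2, tibble::tibble(child = "P", parent = "P")),
    "child == parent"
  )
  expect_error(
    call_cellline_degs(expr2, tibble::tibble(child = "X", parent = "P")),
    "absent"
  )
})

test_that("normal reference gives mean and unbiased sd", {
  vals <- matrix(c(8, 10, 12, 5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("N1", "N2", "N3")))
  ref <- fit_normal_reference(make_expr(vals, "NORMAL"))
  expect_equal(ref$mu, c(10, 5))
  expect_equal(ref$delta, c(2, 0))

  expect_error(fit_normal_reference(make_expr(vals[, 1:2], "NORMAL")), "at least 3")
  expect_error(fit_normal_reference(make_expr(vals, "TUMOR")), "NORMAL")
})

test_that("dysregulation calls follow the one-sided z threshold", {
  ref <- tibble::tibble(gene = "A", mu = 10, delta = 2)
  vals <- matrix(c(14, 10, 6.5), 1, dimnames = list("A", c("T1", "T2", "T3")))
  dys <- call_dysregulation(make_expr(vals, "TUMOR"), ref)
  expect_equal(as.vector(unclass(dys)), c(1L, 0L, -1L))  # z = 2, 0, -1.75 at cut 1.645

  # missing reference entry errors naming the gene
  vals2 <- rbind(vals, Z = c(1, 1, 1))
  expect_error(call_dysregulation(make_expr(vals2, "TUMOR"), ref), "Z")
})

test_that("zero-variance genes are NEUTRAL unless strict calling is enabled", {
  ref <- tibble::tibble(gene = "A", mu = 5, delta = 0)
  vals <- matrix(c(5, 7), 1, dimnames = list("A", c("T1", "T2")))
  expr <- make_expr(vals, "TUMOR")
  expect_equal(as.vector(unclass(call_dysregulation(expr, ref))), c(0L, 0L))
  expect_equal(as.vector(unclass(call_dysregulation(expr, ref, strict_zero_delta = TRUE))),
               c(0L, 1L))
})

test_that("dysregulation is monotone in the tumor value", {
  ref <- tibble::tibble(gene = "A", mu = 100, delta = 10)
  xs <- seq(50, 150, by = 1)
  calls <- vapply(xs, function(x) {
    m <- matrix(x, 1, 1, dimnames = list("A", "T1"))
    unclass(call_dysregulation(make_expr(m, "TUMOR"), ref))[1, 1]
  }, integer(1))
  expect_true(all(diff(calls) >= 0))
})

test_that("lung refinement removes discordant genes at the inclusive R% bound", {
  degs <- tibble::tibble(gene = c("u25", "u10", "d20", "u0"),
                         direction = c("UP", "UP", "DOWN", "UP"))
  # 20 tumors; u25 DOWN in 5 (25%), u10 DOWN in 2 (10%), d20 UP in exactly 4 (20%)
  calls <- matrix("NEUTRAL", 4, 20,
                  dimnames = list(c("u25", "u10", "d20", "u0"), sprintf("T%02d", 1:20)))
  calls["u25", 1:5] <- "DOWN"
  calls["u10", 1:2] <- "DOWN"
  calls["d20", 1:4] <- "UP"
  lusc <- make_dysreg(calls)
  out <- refine_degs(degs, lusc, R_pct = 20)
  expect_setequal(out$gene, c("u10", "u0"))

  # second cohort at 15% discordance keeps u10 (neither cohort reaches 20%)
  calls2 <- calls; calls2[, ] <- "NEUTRAL"; calls2["u10", 1:3] <- "DOWN"
  out2 <- refine_degs(degs[degs$gene == "u10", ], list(lusc, make_dysreg(calls2)))
  expect_equal(out2$gene, "u10")

  # pure filter: output is always a subset of the input
  expect_true(all(out$gene %in% degs$gene))
  # genes absent from the cohort are 0% discordant
  extra <- tibble::tibble(gene = "absent", direction = "UP")
  expect_equal(refine_degs(extra, lusc)$gene, "absent")
  expect_error(refine_degs(degs, list()), "non-empty|length")
})

test_that("DEG sets stay disjoint through the full deg stage", {
  set.seed(11)
  sim <- generate_cellline_series(n_genes = 100, noise_sd = 0.3)
  degs <- call_cellline_degs(sim$expr, sim$comparisons)
  expect_equal(anyDuplicated(degs$gene), 0L)
})
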