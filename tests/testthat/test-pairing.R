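test_that("a lone nucleus below its cell is paired to it", {
  inst <- toy_instance(cbind(10, 10), cbind(8, 10, 10))
  p <- pair_nuclei_to_cells(inst$cells, inst$nuclei, max_dist = 15)
  expect_equal(p$pairs, c("1" = 1L))
  expect_lt(p$cost, 2)
})

test_that("matching is globally optimal where greedy fails", {
  # greedy picks (c1,n1) cost 1 then is forced into total 11; optimum is 6
  M <- rbind(c(1, 2, 100),
             c(2, 6, 5),
             c(100, 5, 2))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  totals <- vapply(perms, function(p) sum(M[cbind(1:3, p)]), numeric(1))
  expect_equal(min(totals), 6)    # brute force over all 3! permutations
  asg <- epiquant:::hungarian_lsap(M)
  expect_equal(sum(M[cbind(1:3, asg)]), 6)
})

test_that("empty inputs give an empty pairing with zero cost", {
  inst <- toy_instance(cbind(10, 10), cbind(8, 40, 40))
  empty_n <- nuclei_labels(array(0L, inst$cells$grid$shape), inst$cells$grid)
  p <- pair_nuclei_to_cells(inst$cells, empty_n, max_dist = 5)
  expect_length(p$pairs, 0)
  expect_equal(p$cost, 0)
})

test_that("total cost matches the exhaustive optimum on random instances", {
  # property over random geometric instances with <= 7 cells and nuclei
  set.seed(11)
  for (rep in 1:25) {
    ncell <- sample(1:7, 1); nnuc <- sample(1:7, 1)
    cy <- sample(seq(4, 60, by = 8), ncell)
    cx <- sample(seq(4, 60, by = 8), ncell)
    inst <- toy_instance(cbind(cy, cx),
                         cbind(sample(2:25, nnuc, TRUE),
                               sample(2:60, nnuc, TRUE),
                               sample(2:60, nnuc, TRUE)))
    max_dist <- runif(1, 5, 30)
    p <- pair_nuclei_to_cells(inst$cells, inst$nuclei, max_dist = max_dist)
    cost <- pairing_cost_matrix(inst$cells, inst$nuclei)
    bf <- brute_force_matching(cost, cost <= max_dist)
    expect_equal(length(p$pairs), bf$cardinality)
    expect_equal(p$cost, bf$cost, tolerance = 1e-9)
    # no pair violates max_dist; injective both ways
    expect_true(all(cost[cbind(match(as.integer(names(p$pairs)),
                                     cell_labels(inst$cells)),
                               match(p$pairs, inst$nuclei$props$label))]
                    <= max_dist))
    expect_false(anyDuplicated(p$pairs) > 0)
  }
})

test_that("pairing is stable under simultaneous relabeling", {
  b <- get_bundle("small")
  p1 <- pair_nuclei_to_cells(b$truth$cells, b$truth$nuclei, max_dist = 15)
  # shift all labels by 10 on both sides
  lab2 <- b$truth$cells$labels2d
  lab2[lab2 > 0] <- lab2[lab2 > 0] + 10L
  cz <- b$truth$cells$cell_z
  names(cz) <- as.integer(names(cz)) + 10L
  cells2 <- apical_cell_map(lab2, cz, b$truth$cells$grid)
  nl2 <- b$truth$nuclei$labels3d
  nl2[nl2 > 0] <- nl2[nl2 > 0] + 10L
  nuclei2 <- nuclei_labels(nl2, b$truth$nuclei$grid)
  p2 <- pair_nuclei_to_cells(cells2, nuclei2, max_dist = 15)
  expect_equal(unname(p2$pairs), unname(p1$pairs) + 10L)
  expect_equal(p2$cost, p1$cost, tolerance = 1e-9)
})

test_that("simulated nuclei pair to their generating cells", {
  b <- get_bundle("default")
  p <- pair_nuclei_to_cells(b$truth$cells, b$truth$nuclei, max_dist = 15)
  agree <- mean(as.integer(names(p$pairs)) == p$pairs)
  expect_gte(agree, 0.95)
})
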