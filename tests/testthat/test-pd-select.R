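test_that("rooted PD matches hand-computed path unions", {
  expect_equal(pd_of(star3(), "leaf1"), 1)
  expect_equal(pd_of(star3(), c("leaf1", "leaf2", "leaf3")), 6)
  expect_equal(pd_of(caterpillar(), c("A", "C")), 8) # 1 + 3 + 4
  expect_equal(pd_of(caterpillar(), character()), 0)
  expect_error(pd_of(caterpillar(), "Z"), class = "sagdiv_invalid_input")
})

test_that("brute force handles the unconstrained and zero-budget corners", {
  tr <- star3()
  costs <- c(leaf1 = 1, leaf2 = 1, leaf3 = Inf)
  all_in <- solve_bruteforce(selection_problem(tr, costs, budget = Inf, cap = 3))
  expect_identical(all_in$chosen, c("leaf1", "leaf2")) # Inf cost never chosen
  expect_equal(all_in$pd, 3)

  none <- solve_bruteforce(selection_problem(tr, c(leaf1 = 2, leaf2 = 2),
                                             budget = 0, cap = 2))
  expect_identical(none$chosen, character())
  expect_equal(none$pd, 0)
})

test_that("exact solver agrees with brute force, and results re-validate", {
  for (s in 1:30) {
    inst <- random_instance(s)
    rb <- solve_bruteforce(inst$problem)
    re <- solve_exact(inst$problem)
    expect_equal(re$pd, rb$pd, tolerance = 1e-9)
    expect_identical(re$chosen, rb$chosen) # shared lexicographic tie-break
    validate_selection(inst$problem, rb)
    validate_selection(inst$problem, re)
  }
})

test_that("cardinality-only problems are solved optimally at scale", {
  cfg <- sim_config(seed = 41, n_leaves = 60)
  tr <- sim_tree(cfg)
  cand <- tr$tip.label[1:40]
  costs <- setNames(rep(1, 40), cand)
  prob <- selection_problem(tr, costs, budget = Inf, cap = 15)
  res <- solve_exact(prob)
  expect_true(res$optimal)
  expect_identical(length(res$chosen), 15L)
  # cross-check against brute force on a reduced version of the same tree
  small <- selection_problem(tr, costs[1:12], budget = Inf, cap = 5)
  expect_equal(solve_exact(small)$pd, solve_bruteforce(small)$pd,
               tolerance = 1e-9)
})

test_that("the IP formulation has the expected shape and corner optimum", {
  inst <- random_instance(3, n_leaves = 8)
  ip <- build_ip(inst$problem)
  expect_identical(ip$n_x, length(inst$problem$costs))
  expect_identical(ip$n_y, nrow(inst$tree$edge))
  # y_e <= sum x constraints (one per edge) + budget + cap
  expect_identical(length(ip$constraints), ip$n_y + 2L)

  tr <- caterpillar()
  one <- selection_problem(tr, c(A = 1), budget = 10, cap = 1, anchored = FALSE)
  res <- solve_exact(one)
  expect_equal(res$pd, pd_of(tr, "A"))
  expect_error(build_ip(selection_problem(tr, c(A = Inf), cap = 1)),
               class = "sagdiv_invalid_input")
})

test_that("the LP relaxation bounds the integer optimum from above", {
  for (s in 1:20) {
    inst <- random_instance(s, n_leaves = 10)
    lp <- ip_lp_bound(build_ip(inst$problem))
    expect_gte(lp, solve_exact(inst$problem)$objective - 1e-6)
  }
})

test_that("greedy equals the optimum when nothing binds and beats one sweep", {
  tr <- star3()
  costs <- c(leaf1 = 1, leaf2 = 1, leaf3 = 1)
  g <- solve_greedy(selection_problem(tr, costs, budget = Inf, cap = 3))
  expect_identical(g$chosen, c("leaf1", "leaf2", "leaf3"))
  expect_equal(g$pd, 6)

  # adversarial: one expensive high-PD leaf vs two cheap low-PD leaves;
  # the density sweep alone picks the cheap pair, the gain sweep the big leaf
  adv <- ape::read.tree(text = "(big:10,(s1:1,s2:1):0.1);")
  prob <- selection_problem(adv, c(big = 10, s1 = 1, s2 = 1),
                            budget = 10, cap = 3, anchored = FALSE)
  g2 <- solve_greedy(prob)
  expect_equal(g2$pd, solve_bruteforce(prob)$pd, tolerance = 1e-9)
})

test_that("PD is monotone and submodular on random probes", {
  tr <- sim_tree(sim_config(seed = 51, n_leaves = 20))
  idx_tips <- tr$tip.label
  withr::with_seed(99, {
    for (i in 1:50) {
      s_small <- sample(idx_tips, sample(0:10, 1))
      extra <- sample(setdiff(idx_tips, s_small), 2)
      s_big <- c(s_small, extra[1])
      # monotone
      expect_lte(pd_of(tr, s_small), pd_of(tr, s_big) + 1e-12)
      # submodular: marginal gain of extra[2] shrinks as the base grows
      gain_small <- pd_of(tr, c(s_small, extra[2])) - pd_of(tr, s_small)
      gain_big <- pd_of(tr, c(s_big, extra[2])) - pd_of(tr, s_big)
      expect_lte(gain_big, gain_small + 1e-12)
    }
  })
})

test_that("duplicate placements on one edge add only their pendant length", {
  tr <- sim_tree(sim_config(seed = 61, n_leaves = 8))
  pl <- tibble::tibble(
    sag_id = c("s1", "s2"), edge_ref = c(4L, 4L),
    distal_position = c(0.5, 0.5), pendant_length = c(0.2, 0.3)
  )
  gr <- graft_placements(tr, pl)
  both <- pd_of(gr$tree, c("s1", "s2"))
  first <- pd_of(gr$tree, "s1")
  expect_equal(both - first, 0.3, tolerance = 1e-9)
})

test_that("anchored problems score candidates by marginal gain", {
  tr <- caterpillar()
  # A, B are reference leaves; C is the candidate
  anchored <- selection_problem(tr, c(C = 1), budget = Inf, cap = 1,
                                anchored = TRUE)
  res <- solve_exact(anchored)
  expect_identical(res$chosen, "C")
  expect_equal(res$objective, pd_of(tr, c("A", "B", "C")))
  expect_equal(res$pd, pd_of(tr, "C"))
})
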