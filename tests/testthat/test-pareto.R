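# the three-variant worked example: "a" dominates "b", "c" has the top
# primary activity, and the non-dominated set is {a, c}
fig1a_points <- function() {
  objective_points(rbind(a = c(1.0, 3.0), b = c(0.5, 2.0), c = c(2.0, 1.0)),
                   ids = c("a", "b", "c"), scale = "log")
}

test_that("dominance is strict in every objective", {
  p <- rbind(a = c(1.0, 3.0), b = c(0.5, 2.0), c = c(2.0, 1.0))
  expect_true(dominates(p["a", ], p["b", ]))
  expect_false(dominates(p["c", ], p["a", ]))
  expect_false(dominates(p["a", ], p["a", ]))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "dimension mismatch")
  # weak mode: equal-in-one, better-in-other dominates
  expect_true(dominates(c(1, 2), c(1, 1), strict = FALSE))
  expect_false(dominates(c(1, 2), c(1, 1)))
})

test_that("the three-variant front is {a, c}", {
  fr <- pareto_front(fig1a_points())
  expect_setequal(fr$ids, c("a", "c"))
})

test_that("tied points coexist on the front under strict dominance", {
  pts <- objective_points(rbind(c(1, 1), c(1, 1), c(1, 1)), scale = "log")
  fr <- pareto_front(pts)
  expect_equal(nrow(fr$coords), 3L)
})

test_that("sweep front extraction matches the all-pairs oracle", {
  set.seed(123)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    n <- sample(c(10, 50, 200, 500), 1)
    coords <- matrix(rnorm(n * k), n, k)
    if (rep %% 5 == 0) coords <- round(coords)  # force ties
    fr <- pareto_front(coords)
    expect_equal(sort(attr(fr, "index")), which(oracle_front(coords)),
                 info = paste("instance", rep))
  }
})

test_that("front extraction is idempotent and respects dominance edits", {
  set.seed(5)
  pts <- objective_points(matrix(rnorm(60), 30, 2), scale = "log")
  fr <- pareto_front(pts)
  expect_equal(pareto_front(fr)$coords, fr$coords)
  # adding a dominated point never changes the front
  low <- apply(pts$coords, 2, min) - 1
  pts2 <- objective_points(rbind(pts$coords, low), scale = "log")
  expect_equal(unname(pareto_front(pts2)$coords), unname(fr$coords))
  # a point dominating everything becomes the sole member
  high <- apply(pts$coords, 2, max) + 1
  pts3 <- objective_points(rbind(pts$coords, high), scale = "log")
  expect_equal(nrow(pareto_front(pts3)$coords), 1L)
})

test_that("optimistic prediction recovers the true front from noiseless
           reconstructions", {
  set.seed(3)
  spec <- landscape_spec(8, p_main = matrix(runif(16, -0.5, 0.5), ncol = 2),
                         noise_sd = 0)
  gen <- generate_activity_table(spec, n_random = 40, seed = 4)
  ens <- bootstrap_reconstruct(gen$table, B = 3, seed = 6,
                               include_pairs = FALSE)
  cand <- optimistic_pareto(ens)
  truth_front <- pareto_front(objective_points(
    gen$truth$activities, ids = rownames(gen$truth$genotypes),
    scale = "log"))
  expect_setequal(as.character(cand), unname(truth_front$ids))
  # B = 1: candidates are exactly that replica's front genotypes
  ens1 <- bootstrap_reconstruct(gen$table, B = 1, seed = 6,
                                include_pairs = FALSE)
  fr1 <- pareto_front(objective_points(ens1$predictions[[1]],
                                       ids = rownames(ens1$genotypes),
                                       scale = "log"))
  expect_setequal(optimistic_pareto(ens1), unique(fr1$ids))
})

test_that("screening rounds request only unmeasured candidates and merge", {
  sc <- paper_scale_scenario(seed = 12)
  measured <- sc$table
  # all candidates already measured: empty request
  expect_equal(nrow(screening_round(measured, measured$genotype[1:5])), 0L)
  cand <- setdiff(rownames(enumerate_library(10)), measured$genotype)[1:11]
  req <- screening_round(measured, c(cand, measured$genotype[1]))
  expect_equal(req$genotype, cand)
  expect_true(all(is.na(req$primary)))
  # 29 measured + 11 new = 40
  new_tab <- activity_table(cand, cbind(rnorm(11), rnorm(11)))
  merged <- merge_screening_results(measured, new_tab)
  expect_equal(nrow(merged), 40L)
  expect_equal(anyDuplicated(merged$genotype), 0L)
})

test_that("measured-set front is non-decreasing across screening rounds", {
  for (s in 1:5) {
    sc <- paper_scale_scenario(seed = 100 + s)
    truth <- sc$truth
    ens <- bootstrap_reconstruct(sc$table, B = 5, seed = 200 + s)
    cand <- optimistic_pareto(ens)
    req <- screening_round(sc$table, cand)
    # oracle screen: measure the requested variants on the true landscape
    idx <- truth$index[req$genotype]
    merged <- merge_screening_results(
      sc$table, activity_table(req$genotype,
                               truth$activities[idx, , drop = FALSE]))
    obj <- table_objectives(sc$table)
    f1 <- pareto_front(objective_points(
      as.matrix(as.data.frame(sc$table)[obj]), ids = sc$table$genotype,
      scale = "log"))
    f2 <- pareto_front(objective_points(
      as.matrix(as.data.frame(merged)[obj]), ids = merged$genotype,
      scale = "log"))
    # every round-1 front point is dominated by or equal to some round-2
    # front point
    ok <- apply(f1$coords, 1, function(p)
      any(apply(f2$coords, 1, function(q) all(q >= p))))
    expect_true(all(ok), info = paste("seed", s))
  }
})

test_that("trade-off line fitting is exact on degenerate fronts", {
  two <- objective_points(rbind(c(0, 1), c(1, 0)), scale = "linear")
  ln <- fit_tradeoff_line(two)
  expect_equal(ln$slope, -1)
  expect_equal(ln$intercept, 1)
  expect_equal(ln$rss, 0)
  # collinear front: zero residual
  col3 <- objective_points(cbind(c(0, 1, 2), c(5, 4, 3)), scale = "linear")
  expect_equal(fit_tradeoff_line(col3)$rss, 0, tolerance = 1e-12)
  expect_error(fit_tradeoff_line(objective_points(rbind(c(1, 1)),
                                                  scale = "linear")),
               "at least 2")
  # log-scale points are refused: the line is defined on linear activities
  expect_error(fit_tradeoff_line(fig1a_points()), "linear")
  expect_warning(
    fit_tradeoff_line(objective_points(rbind(c(1, 0), c(1, 2)),
                                       scale = "linear")),
    "degeneracy")
})

test_that("triangle statistic gives the closed-form null probability", {
  none <- objective_points(matrix(numeric(0), 0, 2), scale = "linear")
  expect_equal(triangle_statistic(none)$null_probability, 1)
  set.seed(1)
  # 40 points strictly inside the triangle below the max-connecting line
  w <- matrix(runif(120), 40, 3)
  x <- w / rowSums(w)
  pts <- objective_points(x[, 1:2], scale = "linear")
  ideal <- list(slope = -1, intercept = 1)  # the line x + y = 1
  tri <- triangle_statistic(pts, line = ideal)
  expect_equal(tri$ndp, 40L)
  expect_equal(tri$count_below, 40L)
  expect_equal(tri$null_probability, 0.5^40)
  expect_equal(tri$null_probability, 9.09e-13, tolerance = 1e-3)
})
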