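# The constrained bivariate rational-function family, its libraries and
# parameter counting.

test_that("normalization maps [0, v_max) onto [0, inf)", {
  expect_equal(normalize_cpp(0, 2), 0)
  expect_equal(normalize_cpp(1, 2, r = 1), 1)
  expect_equal(normalize_cpp(1.5, 2, r = 1), 3)
  expect_equal(normalize_cpp(1, 2, r = 2.5), 1)
  v <- seq(0, 1.9, by = 0.1)
  expect_true(all(diff(normalize_cpp(v, 2, 0.7)) > 0))
  expect_error(normalize_cpp(2, 2), "cap")
  expect_error(normalize_cpp(0.5, 2, r = 11), "\\(0, 10\\]")
})

test_that("eval_rational honours the variant structure", {
  # variant 9 is constant
  expect_equal(eval_rational(9, list(p4 = 0.4), c(0, 1, 7), c(2, 0, 5)),
               rep(0.4, 3))
  # variant 8 direct arithmetic: (p1 XY + p4)/(q1 XY + 1)
  expect_equal(eval_rational(8, list(p1 = 2, p4 = 1, q1 = 1), 1, 1), 1.5)
  # origin value is p4 for every variant
  set.seed(1)
  for (id in 1:15) {
    p <- random_variant_params(id)
    expect_identical(eval_rational(id, p, 0, 0), p$p4)
  }
  expect_error(eval_rational(3, list(p1 = 1, q1 = 1), 1, 1), "p4")
  expect_error(eval_rational(8, list(p1 = -1, p4 = 1, q1 = 1), 1, 1), "> 0")
})

test_that("constrained first-degree form equals the unconstrained parent", {
  # eliminating p2, p3 via p2 = p4 q2, p3 = p4 q3 reproduces the general
  # first-degree rational function
  eval_parent <- function(p, X, Y) {
    (p$p1 * X * Y + p$p4 * p$q2 * X + p$p4 * p$q3 * Y + p$p4) /
      (p$q1 * X * Y + p$q2 * X + p$q3 * Y + 1)
  }
  set.seed(7)
  for (i in 1:50) {
    p <- random_variant_params(1)
    X <- 10^runif(5, -3, 3); Y <- 10^runif(5, -3, 3)
    expect_equal(eval_rational(1, p, X, Y), eval_parent(p, X, Y),
                 tolerance = 1e-12)
  }
})

test_that("first-degree variants are monotone; second-degree need not be", {
  set.seed(11)
  grid <- 10^seq(-2, 2, length.out = 41)
  for (i in 1:50) {
    id <- sample(1:8, 1)
    p <- random_variant_params(id)
    fx <- eval_rational(id, p, grid, 1.3)
    fy <- eval_rational(id, p, 0.7, grid)
    expect_true(all(diff(fx) >= -1e-12 * max(abs(fx))) ||
                  all(diff(fx) <= 1e-12 * max(abs(fx))))
    expect_true(all(diff(fy) >= -1e-12 * max(abs(fy))) ||
                  all(diff(fy) <= 1e-12 * max(abs(fy))))
  }
  # the second-degree family admits interior extrema: the lubricant
  # bulk-density parameters are a witness (non-monotone in X at fixed Y)
  p13 <- list(p1 = 14.21, p4 = 0.17, q1 = 51.58, q5 = 0.17)
  fx <- eval_rational(13, p13, grid, 1)
  expect_true(any(diff(fx) > 0) && any(diff(fx) < 0))
})

test_that("limit values follow the constrained-family structure", {
  set.seed(5)
  for (id in 1:15) {
    p <- random_variant_params(id)
    lim <- limit_values(id, p)
    expect_identical(unname(lim["f00"]), p$p4)
    expect_identical(unname(lim["f0inf"]), p$p4)
    expect_identical(unname(lim["finf0"]), p$p4)
    if (rational_variant(id)$family == "first") {
      expect_equal(unname(lim["finfinf"]), p$p1 / p$q1)
    }
    # numerical check of the single-variable infinities
    expect_equal(eval_rational(id, p, 1e6, 0), p$p4, tolerance = 1e-5)
    expect_equal(eval_rational(id, p, 0, 1e6), p$p4, tolerance = 1e-5)
  }
})

test_that("pair and triple libraries enumerate the allowed combinations", {
  pl <- pair_library()
  expect_equal(nrow(pl), 43L)
  expect_true(any(pl[, 1] == 9 & pl[, 2] == 9))
  expect_true(any(pl[, 1] == 9 & pl[, 2] == 15))
  expect_true(any(pl[, 1] == 3 & pl[, 2] == 3))
  expect_false(any(pl[, 1] == 1 & pl[, 2] == 2))
  expect_false(is.unsorted(pl[, 1]))

  e16 <- eq16_pair_library()
  expect_equal(nrow(e16), 25L)
  expect_true(all(e16 <= 9))
  expect_true(any(e16[, 1] == 9 & e16[, 2] == 5))

  trip <- compaction_triple_library()
  expect_equal(nrow(trip), 41L)
  printed <- rbind(c(9, 3, 3), c(3, 9, 3), c(1, 9, 1), c(9, 5, 5),
                   c(9, 1, 1), c(6, 9, 6), c(8, 9, 8), c(9, 9, 9),
                   c(9, 8, 8), c(8, 9, 9))
  for (k in seq_len(nrow(printed))) {
    expect_true(any(trip[, 1] == printed[k, 1] & trip[, 2] == printed[k, 2] &
                      trip[, 3] == printed[k, 3]))
  }
  # one of a, 1/b is always constant
  expect_true(all(trip[, 1] == 9 | trip[, 2] == 9))
})

test_that("parameter counting reproduces the library table", {
  expect_identical(vapply(1:15, param_count, integer(1)),
                   c(7L, 5L, 6L, 4L, 6L, 4L, 5L, 3L, 1L,
                     7L, 5L, 6L, 4L, 6L, 4L))
})

test_that("parameter counting reproduces the ranked-model Np columns", {
  bulk <- function(i) model_combination("bulk_density", c(phi = i))
  expect_equal(vapply(c(13, 11, 8, 12, 4, 7, 5, 3, 1),
                      function(i) param_count(bulk(i)), integer(1)),
               c(4L, 5L, 3L, 6L, 4L, 5L, 6L, 6L, 7L))

  wt <- function(...) param_count(model_combination("weight", ...))
  expect_equal(wt(weight_form = "eq21"), 2L)
  expect_equal(wt(weight_form = "eq23"), 5L)
  expect_equal(wt(weight_form = "eq23", zeroed = "xi1"), 4L)
  expect_equal(wt(weight_form = "eq23", zeroed = "xi5"), 4L)
  expect_equal(wt(weight_form = "eq23", zeroed = c("xi1", "xi5")), 3L)

  comp <- function(a, b, r) {
    param_count(model_combination("compaction", c(a = a, inv_b = b, rho_c = r)))
  }
  expect_equal(mapply(comp, c(9, 3, 1, 9, 9, 6, 8, 9, 9, 8),
                      c(3, 9, 9, 5, 1, 9, 9, 9, 8, 9),
                      c(3, 3, 1, 5, 1, 6, 8, 9, 8, 9)),
               c(11, 11, 13, 11, 13, 9, 7, 3, 7, 5))

  rec <- function(e, r) {
    param_count(model_combination("elastic_recovery",
                                  c(eps0 = e, rho_c_eps = r)))
  }
  expect_equal(mapply(rec, c(5, 6, 7, 2, 9, 9, 8, 4),
                      c(5, 9, 9, 9, 8, 9, 9, 9)),
               c(11, 6, 7, 7, 5, 3, 5, 6))

  ten <- function(s, r) {
    param_count(model_combination("tensile_strength",
                                  c(sigma0 = s, rho_c_sigma = r)))
  }
  expect_equal(mapply(ten, c(3, 1, 7, 5, 3, 9, 9, 8),
                      c(3, 1, 7, 5, 9, 5, 7, 8)),
               c(10, 12, 8, 10, 7, 7, 6, 6))
})

test_that("model combinations are validated", {
  expect_error(model_combination("compaction", c(a = 3, inv_b = 3, rho_c = 3)),
               "constant")
  expect_error(model_combination("tensile_strength", c(sigma0 = 3)),
               "rho_c_sigma")
  expect_error(model_combination("bulk_density", c(phi = 16)), "1..15")
})

test_that("the libraries serialize to JSON for audit", {
  path <- tempfile(fileext = ".json")
  write_library_json(path)
  obj <- jsonlite::read_json(path)
  expect_length(obj$variants, 15L)
  expect_length(obj$pair_library, 43L)
  expect_length(obj$compaction_triple_library, 41L)
})
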