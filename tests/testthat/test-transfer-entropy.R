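test_that("shannon entropy matches closed forms and rejects bad input", {
  expect_identical(shannon_entropy(c(0.5, 0.5)), 1)
  expect_identical(shannon_entropy(c(1, 0, 0)), 0)
  expect_identical(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(c(0.5, 0.4)), "normalized")
  expect_error(shannon_entropy(c(-0.5, 1.5)), "normalized")
})

test_that("renyi entropy matches closed forms and converges to Shannon", {
  for (q in c(0.1, 0.5, 2, 7)) {
    expect_equal(renyi_entropy(rep(1 / 8, 8), q), 3, tolerance = 1e-12)
  }
  expect_equal(renyi_entropy(c(0.5, 0.5), 2), 1, tolerance = 1e-12)
  expect_equal(renyi_entropy(c(0.75, 0.25), 2), -log2(0.625), tolerance = 1e-12)
  withr::with_seed(4, {
    p <- runif(6)
    p <- p / sum(p)
  })
  expect_lt(abs(renyi_entropy(p, 0.999) - shannon_entropy(p)), 1e-3)
  expect_error(renyi_entropy(c(0.5, 0.5), -1), "q must be")
  expect_error(renyi_entropy(c(0.5, 0.5), 1), "Shannon limit")
})

test_that("quantile discretization puts 5/90/5 percent in the tail bins", {
  s <- discretize(1:100)
  expect_identical(as.integer(table(s$symbols)), c(5L, 90L, 5L))
  expect_identical(s$alphabet_size, 3L)
})

test_that("discretization is invariant under monotone transforms", {
  withr::with_seed(11, x <- rnorm(300))
  ref <- discretize(x)$symbols
  expect_identical(discretize(exp(x))$symbols, ref)
  expect_identical(discretize(x^3)$symbols, ref)
  expect_identical(discretize(5 * x - 2)$symbols, ref)
})

test_that("degenerate and missing-valued series are handled", {
  expect_error(discretize(rep(1, 50)), "fewer distinct values")
  expect_error(discretize(c(rep(1, 48), 2, 3)), "too concentrated|fewer bins")
  expect_error(discretize(rnorm(10)), "at least 20")
  # NAs split contiguity blocks
  withr::with_seed(2, x <- rnorm(60))
  x[30] <- NA
  s <- discretize(x)
  expect_length(s$symbols, 59)
  expect_identical(length(unique(s$blocks)), 2L)
  expect_identical(which(diff(s$blocks) != 0), 29L)
})

test_that("self transfer entropy is exactly zero", {
  withr::with_seed(8, x <- sample(0:2, 500, replace = TRUE))
  expect_identical(shannon_te(x, x)$value, 0)
  expect_identical(suppressWarnings(renyi_te(x, x, q = 0.5))$value, 0)
})

test_that("binary copy process carries exactly one bit", {
  # Y_{t+1} = X_t with X iid fair coin and Y_t independent of X_t:
  # exact joint over (y+, yh, xh) is uniform on consistent combinations
  joint <- array(0, dim = c(2, 2, 2))
  for (yh in 0:1) for (xh in 0:1) joint[xh + 1, yh + 1, xh + 1] <- 0.25
  expect_identical(te_from_joint(joint), 1)
  expect_equal(te_from_joint(joint, "renyi", q = 0.5), 1, tolerance = 1e-12)
})

test_that("empirical STE/RTE agree with brute-force enumeration", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      x <- sample(0:2, 30, replace = TRUE)
      y <- sample(0:2, 30, replace = TRUE)
      expect_equal(suppressWarnings(shannon_te(x, y))$value,
        oracle_ste(x, y),
        tolerance = 1e-12
      )
      expect_equal(suppressWarnings(renyi_te(x, y, q = 0.5))$value,
        oracle_rte(x, y, q = 0.5),
        tolerance = 1e-12
      )
    }
  })
})

test_that("higher Markov orders match the enumeration oracle", {
  withr::with_seed(33, {
    x <- sample(0:1, 400, replace = TRUE)
    y <- sample(0:1, 400, replace = TRUE)
  })
  expect_equal(shannon_te(x, y, m = 2, n = 1)$value, oracle_ste(x, y, m = 2, n = 1),
    tolerance = 1e-12
  )
  expect_equal(shannon_te(x, y, m = 1, n = 2)$value, oracle_ste(x, y, m = 1, n = 2),
    tolerance = 1e-12
  )
  expect_equal(
    suppressWarnings(renyi_te(x, y, q = 0.1, m = 2, n = 2))$value,
    oracle_rte(x, y, q = 0.1, m = 2, n = 2),
    tolerance = 1e-12
  )
})

test_that("STE equals its conditional-entropy decomposition", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- sample(0:2, 120, replace = TRUE)
      y <- sample(0:2, 120, replace = TRUE)
      expect_equal(suppressWarnings(shannon_te(x, y))$value,
        oracle_ste_decomposition(x, y),
        tolerance = 1e-12
      )
    }
  })
})

test_that("STE and RTE are invariant under symbol relabeling", {
  withr::with_seed(14, {
    x <- sample(0:2, 300, replace = TRUE)
    y <- sample(0:2, 300, replace = TRUE)
  })
  perm <- c(2L, 0L, 1L)
  expect_equal(shannon_te(perm[x + 1], perm[y + 1])$value,
    shannon_te(x, y)$value,
    tolerance = 1e-12
  )
  expect_equal(renyi_te(perm[x + 1], perm[y + 1], q = 0.1)$value,
    renyi_te(x, y, q = 0.1)$value,
    tolerance = 1e-12
  )
})

test_that("plug-in STE is non-negative on arbitrary inputs", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      a <- sample(2:4, 1)
      x <- sample(0:(a - 1), 100, replace = TRUE)
      y <- sample(0:(a - 1), 100, replace = TRUE)
      expect_gte(suppressWarnings(shannon_te(x, y))$value, 0)
    }
  })
})

test_that("RTE approaches STE as q approaches 1, and negatives are preserved", {
  withr::with_seed(6, {
    x <- sample(0:2, 600, replace = TRUE)
    y <- sample(0:2, 600, replace = TRUE)
  })
  ste <- shannon_te(x, y)$value
  gaps <- vapply(
    c(0.9, 0.99, 0.999),
    function(q) abs(renyi_te(x, y, q = q)$value - ste), numeric(1)
  )
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
  # a skewed random pair at q = 2 has negative RTE; it must come through
  withr::with_seed(87, {
    xa <- sample(0:2, 80, replace = TRUE, prob = c(.6, .3, .1))
    ya <- sample(0:2, 80, replace = TRUE, prob = c(.7, .2, .1))
  })
  v <- suppressWarnings(renyi_te(xa, ya, q = 2))$value
  expect_lt(v, 0)
  expect_equal(v, oracle_rte(xa, ya, q = 2), tolerance = 1e-12)
})

test_that("transitions never span contiguity-block boundaries", {
  # two blocks glued together must give the same counts as analyzing the
  # blocks separately and pooling
  withr::with_seed(12, {
    x1 <- sample(0:1, 50, replace = TRUE)
    y1 <- sample(0:1, 50, replace = TRUE)
    x2 <- sample(0:1, 50, replace = TRUE)
    y2 <- sample(0:1, 50, replace = TRUE)
  })
  blocks <- rep(1:2, each = 50)
  sx <- symbolic_series(c(x1, x2), 2L, blocks)
  sy <- symbolic_series(c(y1, y2), 2L, blocks)
  glued <- shannon_te(sx, sy)
  expect_identical(glued$n_transitions, 98L)
  pooled_counts <- unclass(soundflow:::joint_counts(sx, sy))
  sep <- soundflow:::joint_counts(x1, y1) + soundflow:::joint_counts(x2, y2)
  expect_identical(as.vector(pooled_counts), as.vector(sep))
})

test_that("small transition counts trigger a bias warning", {
  x <- sample(0:2, 21, replace = TRUE)
  expect_warning(shannon_te(x, rev(x)), "biased")
})

test_that("shuffle null calibrates coupled versus independent pairs", {
  pair <- gen_coupled_pair(coupling_spec(n_steps = 2000, seed = 42))
  sx <- discretize(pair$x)
  sy <- discretize(pair$y)
  coupled <- shuffle_null(sx, sy, reps = 99, seed = 7)
  expect_gt(coupled$percentile, 0.99)
  indep <- gen_coupled_pair(coupling_spec(
    n_steps = 2000,
    coupling_strength = 0, seed = 42
  ))
  null_case <- shuffle_null(discretize(indep$x), discretize(indep$y),
    reps = 99, seed = 7
  )
  expect_lt(
    abs(null_case$observed - null_case$null_mean),
    4 * null_case$null_sd
  )
  expect_error(shuffle_null(sx, sy, reps = 0), ">= 19")
})

test_that("te_matrix covers all ordered pairs and is generally asymmetric", {
  sm <- urban_park_sites()
  spec <- soundscape_spec(sm,
    protocol = "continuous",
    start = as.POSIXct("2015-05-25 06:30:00", tz = "UTC"), seed = 2
  )
  im <- gen_index_series(spec)
  tem <- te_matrix(im, "H")
  expect_identical(nrow(tem), 16L * 15L)
  m <- te_to_matrix(tem)
  expect_identical(unname(diag(m)), rep(0, 16))
  expect_gt(max(abs(m - t(m))), 0)
  # permuting input row order leaves the result unchanged
  withr::with_seed(3, im_shuffled <- im[sample(nrow(im)), ])
  tem2 <- te_matrix(im_shuffled, "H")
  expect_equal(
    dplyr::arrange(tem, from_site, to_site),
    dplyr::arrange(tem2, from_site, to_site)
  )
})
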