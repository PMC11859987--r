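rand_te_tbl <- function(n_sites, seed = 1, period = "all", dyadic = FALSE) {
  withr::with_seed(seed, {
    ids <- as.character(seq_len(n_sites))
    pairs <- tidyr::expand_grid(from_site = ids, to_site = ids)
    pairs <- pairs[pairs$from_site != pairs$to_site, ]
    te <- if (dyadic) {
      sample(0:4096, nrow(pairs), replace = TRUE) / 1024
    } else {
      runif(nrow(pairs))
    }
    tibble::tibble(
      pairs,
      estimator = "shannon", q = NA_real_, m = 1L, n = 1L,
      period = period, te_bits = te, n_transitions = 1000L
    )
  })
}

grid_sites <- function(n_sites) {
  k <- ceiling(sqrt(n_sites))
  g <- tidyr::expand_grid(gy = seq_len(k) - 1, gx = seq_len(k) - 1)[seq_len(n_sites), ]
  site_map(data.frame(
    site_id = as.character(seq_len(n_sites)),
    x = g$gx * 100, y = g$gy * 100
  ))
}

test_that("day periods are assigned by half-open local-time intervals", {
  stamps <- as.POSIXct(
    c(
      "2022-04-13 05:00:00", "2022-04-13 07:59:59", "2022-04-13 08:00:00",
      "2022-04-13 17:59:59", "2022-04-13 18:00:00", "2022-04-13 02:30:00",
      "2022-04-13 04:59:59", "2022-04-13 00:00:00"
    ),
    tz = "UTC"
  )
  expect_identical(
    split_periods(stamps),
    c("dawn", "dawn", "day", "day", "night", "night", "night", "night")
  )
  hourly <- as.POSIXct("2022-04-13 00:00:00", tz = "UTC") + 3600 * (0:23)
  expect_identical(
    as.integer(table(factor(split_periods(hourly), c("dawn", "day", "night")))),
    c(3L, 10L, 11L)
  )
})

test_that("the TE difference orients arrows and drops exact ties", {
  d1 <- dtem(0.3, 0.1)
  expect_equal(d1$dtem, 0.2, tolerance = 1e-15)
  expect_identical(d1$direction, "forward")
  d2 <- dtem(0.1, 0.3)
  expect_equal(d2$dtem, 0.2, tolerance = 1e-15)
  expect_identical(d2$direction, "reverse")
  expect_identical(dtem(0.2, 0.2)$direction, "tie")
})

test_that("percentile thresholds interpolate linearly", {
  expect_equal(percentile_threshold(1:100, 95), 95.05, tolerance = 1e-12)
  expect_identical(percentile_threshold(1:100, 0), 1)
  expect_identical(percentile_threshold(rep(2, 50), 95), 2)
  expect_error(percentile_threshold(1, 95), "at least 2")
})

test_that("networks keep exactly the arrows above the cutoff", {
  te_tbl <- rand_te_tbl(16, seed = 5)
  sm <- grid_sites(16)
  nw <- build_network(te_tbl, sm, percentile = 95)
  # recount with an explicit loop
  m <- te_to_matrix(te_tbl)
  d_or <- c()
  for (i in 1:15) {
    for (j in (i + 1):16) {
      d_or <- c(d_or, abs(m[i, j] - m[j, i]))
    }
  }
  cutoff <- quantile(d_or, 0.95, names = FALSE)
  expect_equal(nw$threshold_value, cutoff, tolerance = 1e-12)
  expect_identical(nw$n_bar, sum(d_or > cutoff))
  expect_identical(nw$n_bar, 6L) # 5% of 120 oriented pairs
  # every edge strictly above threshold and oriented toward the larger TE
  expect_true(all(nw$edges$dtem > nw$threshold_value))
  expect_true(all(nw$edges$te_forward > nw$edges$te_reverse))
  expect_true(all(nw$edges$d_i > 0))
})

test_that("thresholds are scale-equivariant and monotone in p", {
  te_tbl <- rand_te_tbl(10, seed = 6)
  sm <- grid_sites(10)
  nw95 <- build_network(te_tbl, sm, percentile = 95)
  doubled <- te_tbl
  doubled$te_bits <- doubled$te_bits * 2
  nw95_doubled <- build_network(doubled, sm, percentile = 95)
  key <- function(nw) paste(nw$edges$source, nw$edges$target)
  expect_identical(key(nw95_doubled), key(nw95))
  nw75 <- build_network(te_tbl, sm, percentile = 75)
  expect_true(all(key(nw95) %in% key(nw75)))
  nw0 <- build_network(te_tbl, sm, percentile = 0)
  expect_identical(nw0$n_bar, 45L) # all non-tie oriented pairs
})

test_that("networks demand complete coordinates and one configuration", {
  te_tbl <- rand_te_tbl(4, seed = 2)
  small <- site_map(data.frame(site_id = c("1", "2"), x = 0:1, y = 0:1))
  expect_error(build_network(te_tbl, small, 95), "missing coordinates")
  mixed <- dplyr::bind_rows(
    rand_te_tbl(4, seed = 2, period = "dawn"),
    rand_te_tbl(4, seed = 3, period = "night")
  )
  expect_error(build_network(mixed, grid_sites(4), 95), "mixes")
})

test_that("emission and reception balance exactly", {
  # symmetric matrix: everyone neutral
  sym <- rand_te_tbl(6, seed = 7)
  m <- te_to_matrix(sym)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  sym$te_bits <- m[cbind(sym$from_site, sym$to_site)]
  prof_sym <- emission_reception(sym)
  expect_true(all(prof_sym$classification == "neutral"))
  expect_identical(sum(prof_sym$net), 0)
  # two-site worked example
  two <- tibble::tibble(
    from_site = c("A", "B"), to_site = c("B", "A"),
    estimator = "shannon", q = NA_real_, m = 1L, n = 1L, period = "all",
    te_bits = c(0.4, 0.1), n_transitions = 100L
  )
  prof <- emission_reception(two)
  expect_equal(prof$net, c(0.3, -0.3), tolerance = 1e-15)
  expect_identical(prof$classification, c("hot", "cold"))
  # conservation on random matrices, exact zero
  for (s in 1:25) {
    prof_r <- emission_reception(rand_te_tbl(12, seed = s, dyadic = TRUE))
    expect_identical(sum(prof_r$net), 0)
  }
})

test_that("arrow densities count by source site and reject empty groups", {
  te_tbl <- rand_te_tbl(10, seed = 9)
  sm <- grid_sites(10)
  sm$group <- rep(c("internal", "external"), each = 5)
  nw <- build_network(te_tbl, sm, percentile = 50)
  ad <- arrow_density(nw)
  for (g in ad$group) {
    members <- sm$site_id[sm$group == g]
    expect_identical(
      ad$density[ad$group == g],
      sum(nw$edges$source %in% members) / length(members)
    )
  }
  expect_equal(sum(ad$n_arrows), nw$n_bar)
  # all arrows sourced in one 5-site group gives density n/5
  solo <- arrow_density(nw, groups = list(all = sm$site_id))
  expect_equal(solo$density, nw$n_bar / 10)
  expect_error(arrow_density(nw, groups = list(bad = character())), "empty")
  # no arrows -> all densities zero
  nw_empty <- build_network(te_tbl, sm, cutoff = 10)
  expect_true(all(arrow_density(nw_empty)$density == 0))
})

test_that("the normalized distance index follows its defining arithmetic", {
  sm <- site_map(data.frame(
    site_id = c("a", "b", "c", "d"),
    x = c(0, 50, 0, 100), y = c(0, 0, 10, 10)
  ))
  edges_tbl <- tibble::tibble(
    from_site = c("a", "c", "b", "d", "a", "d"),
    to_site = c("b", "d", "a", "c", "d", "a"),
    estimator = "shannon", q = NA_real_, m = 1L, n = 1L, period = "all",
    te_bits = c(0.9, 0.8, 0.1, 0.2, 0, 0), n_transitions = 100L
  )
  nw <- build_network(edges_tbl, sm, percentile = 0)
  # arrows a->b (50 m) and c->d (100 m): d_max = 100, d_n = 0.75
  expect_identical(nw$n_bar, 2L)
  expect_equal(sort(nw$edges$d_i), c(50, 100), tolerance = 1e-12)
  expect_equal(ndi(nw), 0.75, tolerance = 1e-12)
  expect_equal(nw$d_n, 0.75, tolerance = 1e-12)
  # single arrow or equal lengths give exactly 1
  single <- build_network(edges_tbl[c(1, 3), ], sm, cutoff = 0.5)
  expect_identical(single$n_bar, 1L)
  expect_identical(ndi(single), 1)
  # normalizing over all site pairs instead uses the map diagonal
  expect_equal(ndi(nw, d_max = "pairs"), mean(c(50, 100) / sqrt(100^2 + 10^2)),
    tolerance = 1e-12
  )
  empty <- build_network(edges_tbl, sm, cutoff = 10)
  expect_warning(dn <- ndi(empty), "no arrows")
  expect_true(is.na(dn))
  expect_s3_class(autoplot(nw), "ggplot")
  expect_identical(tidy(nw), nw$edges)
  expect_identical(glance(nw)$n_bar, 2L)
})

test_that("dawn connectivity dominates and interior sites source the arrows", {
  sm <- river_park_sites()
  wins <- 0L
  seeds <- 1:8
  for (s in seeds) {
    im <- gen_index_series(soundscape_spec(sm, days = 7, seed = 300 + s))
    tes <- lapply(
      c("dawn", "night"),
      function(p) te_matrix(im, "BI", period = p)
    )
    pool <- unlist(lapply(tes, function(tb) {
      m <- te_to_matrix(tb)
      up <- upper.tri(m)
      abs(m[up] - t(m)[up])
    }))
    cutoff <- percentile_threshold(pool, 75)
    nets <- lapply(tes, function(tb) build_network(tb, sm, cutoff = cutoff))
    dens <- vapply(nets, function(nw) nw$n_bar / attr(sm, "n_eff"), numeric(1))
    ad <- arrow_density(nets[[1]])
    dn <- vapply(nets, function(nw) ifelse(is.na(nw$d_n), 0, nw$d_n), numeric(1))
    ok <- dens[1] > dens[2] &&
      ad$density[ad$group == "internal"] > ad$density[ad$group == "external"] &&
      dn[1] >= dn[2]
    wins <- wins + ok
  }
  expect_gt(wins, length(seeds) / 2)
})
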