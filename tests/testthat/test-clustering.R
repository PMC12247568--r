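test_that("separable planted window sets are recovered exactly", {
  dat <- make_window_data(noise = 0, n_windows = 200, seed = 10)
  fit <- fit_states(dat$x, k = 4, n_init = 10, seed = 1)
  expect_true(all(fit$centroids %in% c(0, 1)))
  perm <- align_labels(fit, list(centroids = dat$centroids))
  expect_equal(fit$centroids[order(perm), ], dat$centroids)
  expect_equal(matched_accuracy(fit$labels, dat$labels, fit$centroids,
                                dat$centroids), 1)
  expect_equal(fit$inertia, 0)
})

test_that("k = 1 reduces to the mean edge-occupancy vector", {
  dat <- make_window_data(noise = 0.1, n_windows = 100, seed = 11)
  fit <- fit_states(dat$x, k = 1, n_init = 3, seed = 1)
  expect_equal(drop(fit$centroids), colMeans(dat$x), tolerance = 1e-12)
})

test_that("noisy planted windows cluster with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  dat <- make_window_data(noise = 0.1, n_windows = 600, seed = 12)
  fit <- fit_states(dat$x, k = 4, n_init = 10, seed = 2)
  ari <- mclust::adjustedRandIndex(fit$labels, dat$labels)
  expect_gte(ari, 0.9)
  expect_gte(matched_accuracy(fit$labels, dat$labels, fit$centroids,
                              dat$centroids), 0.9)
})

test_that("fits are seed-reproducible and best-of-restarts beats one restart", {
  dat <- make_window_data(noise = 0.15, n_windows = 300, seed = 13)
  a <- fit_states(dat$x, 4, n_init = 10, seed = 5)
  b <- fit_states(dat$x, 4, n_init = 10, seed = 5)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$labels, b$labels)
  singles <- sapply(1:5, function(s)
    fit_states(dat$x, 4, n_init = 1, seed = s)$inertia)
  expect_lte(a$inertia, min(singles) + 1e-9)
  expect_error(fit_states(dat$x[1:3, ], 4), class = "ps_insufficient_data")
})

test_that("group clustering pools subject centroids and respects symmetry", {
  dat <- make_window_data(noise = 0, n_windows = 100, seed = 14)
  base <- fit_states(dat$x, 4, n_init = 5, seed = 1)
  # identical subjects reproduce the shared centroids up to permutation
  grp <- fit_states_group(list(base, base, base), seed = 2)
  perm <- align_labels(grp, base)
  expect_equal(grp$centroids[order(perm), ], base$centroids,
               tolerance = 1e-9)

  # a subject with permuted state labels leaves the group result unchanged
  shuffled <- base
  shuffled$centroids <- base$centroids[c(3, 1, 4, 2), ]
  grp2 <- fit_states_group(list(base, shuffled, base), seed = 2)
  perm2 <- align_labels(grp2, grp)
  expect_equal(grp2$centroids[order(perm2), ], grp$centroids,
               tolerance = 1e-9)

  # synthetic subjects around common planted states recover them
  set.seed(15)
  subjects <- lapply(1:24, function(i) {
    m <- base
    m$centroids <- pmin(pmax(base$centroids +
                               matrix(rnorm(length(base$centroids), sd = 0.05),
                                      nrow = 4), 0), 1)
    m
  })
  grp3 <- fit_states_group(subjects, seed = 3)
  perm3 <- align_labels(grp3, base)
  cosines <- sapply(1:4, function(i) {
    a <- grp3$centroids[i, ]; b <- base$centroids[perm3[i], ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_true(all(cosines > 0.95))

  wrong <- base
  wrong$centroids <- wrong$centroids[, 1:10]
  expect_error(fit_states_group(list(base, wrong)),
               class = "ps_incompatible_models")
})

test_that("assignment picks the nearest centroid with low-index ties", {
  cents <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  model <- structure(list(centroids = cents, k = 2L), class = "state_model")
  expect_equal(assign_states(rbind(c(1, 0, 0, 0)), model)$labels, 1L)
  expect_equal(assign_states(rbind(c(0, 0, 0, 1)), model)$labels, 2L)
  # exactly equidistant window goes to the lowest state index
  expect_equal(assign_states(rbind(c(0.5, 0, 0, 0.5)), model)$labels, 1L)
  expect_error(assign_states(rbind(c(1, 0)), model),
               class = "ps_incompatible_models")
})

test_that("elbow selection finds well-separated planted state counts", {
  dat <- make_window_data(k = 4, noise = 0.1, n_windows = 500, seed = 16)
  eb <- elbow_select_k(dat$x, k_grid = 2:10, n_init = 5, seed = 1)
  expect_equal(eb$k_star, 4L)
  expect_true(all(diff(eb$inertia) < 1e-6)) # non-increasing in k

  dat3 <- make_window_data(k = 3, noise = 0.1, n_windows = 500, seed = 17)
  expect_equal(elbow_select_k(dat3$x, k_grid = 2:10, n_init = 5,
                              seed = 1)$k_star, 3L)

  # a single repeated pattern has zero inertia at k = 1 and a flat curve
  flat <- matrix(rep(c(1, 0, 1, 0), 50), 50, 4, byrow = TRUE)
  expect_warning(ebf <- elbow_select_k(flat, k_grid = 1L, n_init = 2,
                                       seed = 1),
                 "flat")
  expect_equal(ebf$k_star, 1L)
  expect_equal(ebf$inertia[1], 0)
})

test_that("label alignment recovers permutations, including under jitter", {
  dat <- make_window_data(noise = 0, n_windows = 100, seed = 18)
  ref <- list(centroids = dat$centroids)
  expect_equal(align_labels(ref, ref), 1:4)
  swapped <- list(centroids = dat$centroids[c(2, 1, 4, 3), ])
  expect_equal(align_labels(swapped, ref), c(2, 1, 4, 3))
  set.seed(19)
  jit <- list(centroids = dat$centroids[c(3, 4, 2, 1), ] +
                matrix(rnorm(4 * ncol(dat$centroids), sd = 0.05), 4))
  expect_equal(align_labels(jit, ref), c(3, 4, 2, 1))
})

test_that("canonical ordering puts concentrated states first, diffuse last", {
  cents <- rbind(diffuse = rep(0.05, 200),
                 strong = c(rep(0.9, 20), rep(0, 180)),
                 mid = c(rep(0.5, 20), rep(0, 180)))
  model <- structure(list(centroids = unname(cents), k = 3L),
                     class = "state_model")
  expect_equal(canonical_state_order(model), c(2L, 3L, 1L))
})
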