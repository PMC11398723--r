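test_that("eta-squared matches its definition and symmetries", {
  expect_equal(eta_squared(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(eta_squared(c(1, 2, 3), c(3, 2, 1)), 0)   # numerator 4 / 4
  a <- rnorm(30); b <- rnorm(30)
  set.seed(10)
  perm <- sample(30)
  expect_equal(eta_squared(a, b), eta_squared(b, a))
  expect_equal(eta_squared(a, b), eta_squared(a[perm], b[perm]))
  # bounded in [0, 1] on arbitrary profiles
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(12, sd = runif(1, 0.1, 5))
    e <- eta_squared(x, y)
    expect_gte(e, 0); expect_lte(e, 1)
  }
  expect_error(eta_squared(rep(1, 5), rep(1, 5)), "constant")
  expect_error(eta_squared(1:3, 1:4), "length")
})

test_that("similarity matrices are symmetric, unit-diagonal, group-averaged", {
  set.seed(6)
  mats <- lapply(1:3, function(i) {
    rsfc_from_mefc(matrix(rnorm(12 * 10), 12, 10), df = 10,
                   subject_id = paste0("s", i))
  })
  sub <- c(2, 5, 9)
  s1 <- similarity_matrix(mats[[1]], sub)
  expect_equal(diag(s1$eta2), rep(1, 3))
  expect_equal(s1$eta2, t(s1$eta2))
  expect_true(all(s1$eta2 >= 0 & s1$eta2 <= 1))
  # single parcel: 1 x 1 matrix [[1]]
  expect_equal(similarity_matrix(mats[[1]], 5)$eta2, matrix(1, 1, 1))
  # identical rows give off-diagonal 1
  m <- mats[[1]]
  m$z[5, ] <- m$z[2, ]; m$z[, 5] <- m$z[, 2]
  m$z[5, 5] <- 0; m$z[2, 5] <- m$z[5, 2] <- 0
  s_dup <- similarity_matrix(m, c(2, 5))
  expect_gt(s_dup$eta2[1, 2], 0.95)
  # group = mean of per-subject matrices
  grp <- similarity_matrix(mats, sub)
  per <- lapply(mats, similarity_matrix, subset_parcels = sub)
  expect_equal(grp$eta2,
               (per[[1]]$eta2 + per[[2]]$eta2 + per[[3]]$eta2) / 3)
  expect_identical(grp$subject_id, "group")
  expect_error(similarity_matrix(mats[[1]], c(2, 99)), "missing")
  expect_error(similarity_matrix(mats[[1]], integer(0)), "empty")
})

test_that("Ward merges match brute-force ESS on small planted clouds", {
  set.seed(11)
  X <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
             matrix(rnorm(10, 4, 0.2), 5, 2))
  sol <- ward_cluster(X)
  expect_true(all(diff(sol$merges$height) >= -1e-10))
  labs <- cut_dendrogram(sol, 2)
  expect_equal(compare_partitions(labs, rep(1:2, each = 5)), 1)
  # k=2 cut attains the enumerated minimal ESS
  oracle <- min_ess_bipartition(X)
  ess_of <- function(lab) {
    sum(sapply(unique(lab), function(cl) {
      sum(scale(X[lab == cl, , drop = FALSE], scale = FALSE)^2)
    }))
  }
  expect_equal(ess_of(labs), oracle$ess, tolerance = 1e-10)
  # total merge heights equal the ESS of the single cluster
  expect_equal(sum(sol$merges$height), ess_of(rep(1, 10)), tolerance = 1e-10)
  Xna <- X; Xna[1, 1] <- NA
  expect_error(ward_cluster(Xna), "NaN")
})

test_that("dendrogram cuts expose the height-gap diagnostic", {
  set.seed(12)
  # three near-equidistant clouds, so the k = 3 cut has the dominant gap
  X <- rbind(cbind(rnorm(6, 0, 0.3), rnorm(6, 0, 0.3)),
             cbind(rnorm(6, 10, 0.3), rnorm(6, 0, 0.3)),
             cbind(rnorm(6, 5, 0.3), rnorm(6, 8.66, 0.3)))
  sol <- ward_cluster(X)
  expect_equal(cut_dendrogram(sol, 1), rep(1L, 18), ignore_attr = TRUE)
  expect_equal(sort(cut_dendrogram(sol, 18)), 1:18, ignore_attr = TRUE)
  labs <- cut_dendrogram(sol, 3)
  gaps <- attr(labs, "height_gaps")
  expect_equal(gaps$k[which.max(gaps$gap)], 3)
  expect_equal(compare_partitions(labs, rep(1:3, each = 6)), 1)
  expect_error(cut_dendrogram(sol, 0), "k must be")
  expect_error(cut_dendrogram(sol, 19), "k must be")
})

test_that("cluster mean maps average member rows per subject", {
  set.seed(13)
  mats <- lapply(1:3, function(i) {
    rsfc_from_mefc(matrix(rnorm(10 * 8), 10, 8), df = 8,
                   subject_id = paste0("s", i))
  })
  sub <- c(1, 4, 7, 9)
  labs <- c(1, 1, 2, 2)
  maps <- cluster_mean_maps(mats, labs, sub)
  expect_named(maps, c("cluster1", "cluster2"))
  expect_equal(dim(maps$cluster1), c(3, 10))
  expect_equal(maps$cluster1[2, ],
               colMeans(mats[[2]]$z[c(1, 4), ]))
  # single-member cluster is that parcel's own row
  single <- cluster_mean_maps(mats, c(1, 2, 3, 3), sub)
  expect_equal(single$cluster2[1, ], mats[[1]]$z[4, ])
  # member order has no effect
  maps_perm <- cluster_mean_maps(mats, labs[c(2, 1, 4, 3)],
                                 sub[c(2, 1, 4, 3)])
  expect_equal(maps_perm$cluster1, maps$cluster1)
  expect_error(cluster_mean_maps(mats, labs, sub[-1]), "cover")
})
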