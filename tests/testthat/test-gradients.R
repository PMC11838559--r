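test_that("top-fraction thresholding keeps the k largest entries per row", {
  set.seed(8)
  m <- matrix(runif(25), 5, 5)
  thr <- threshold_top_fraction(m, 0.5)
  k <- ceiling(0.5 * 4)
  for (i in 1:5) {
    off <- setdiff(1:5, i)
    kept <- off[thr[i, off] != 0]
    expect_length(kept, k)
    # sort-based oracle: the k largest off-diagonal values
    expect_setequal(m[i, kept], sort(m[i, off], decreasing = TRUE)[1:k])
    expect_equal(thr[i, i], m[i, i])
  }
  # fraction 1 keeps everything
  expect_equal(threshold_top_fraction(m, 1), m)
  # ties break toward the lower column index
  mt <- matrix(0, 3, 3); mt[1, 2] <- mt[1, 3] <- 0.5
  thr_t <- threshold_top_fraction(mt, 0.4)  # k = 1
  expect_equal(thr_t[1, 2], 0.5)
  expect_equal(thr_t[1, 3], 0)
  expect_error(threshold_top_fraction(matrix(1, 2, 3)), "square")
  # a 360-parcel matrix retains ceil(0.10 * 359) = 36 per row
  m360 <- matrix(rnorm(360^2), 360, 360)
  t360 <- threshold_top_fraction(m360, 0.10)
  row_counts <- rowSums(t360 != 0) - 1L  # minus the diagonal
  expect_true(all(row_counts == 36L))
})

test_that("normalized-angle affinity matches the cosine/arccos formula", {
  set.seed(9)
  m <- matrix(rnorm(16), 4, 4)
  a <- normalized_angle_affinity(m)
  for (i in 1:4) for (j in 1:4) {
    cs <- sum(m[i, ] * m[j, ]) / sqrt(sum(m[i, ]^2) * sum(m[j, ]^2))
    expect_equal(a[i, j], 1 - acos(min(max(cs, -1), 1)) / pi, tolerance = 1e-12)
  }
  expect_true(all(a >= 0 & a <= 1))
  # identical rows -> 1, orthogonal -> 0.5, antipodal -> 0
  m2 <- rbind(c(1, 0), c(1, 0), c(0, 2), c(-3, 0))
  a2 <- normalized_angle_affinity(m2)
  expect_equal(a2[1, 2], 1)
  expect_equal(a2[1, 3], 0.5)
  expect_equal(a2[1, 4], 0, tolerance = 1e-12)
  expect_error(normalized_angle_affinity(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("diffusion embedding matches a dense eigen oracle on small graphs", {
  set.seed(10)
  n <- 12
  a <- abs(matrix(rnorm(n^2), n, n)); a <- (a + t(a)) / 2; diag(a) <- 1
  g <- diffusion_map_embed(a, n_components = 3, alpha = 0.5)
  # oracle: explicitly build the random-walk operator and eigendecompose it
  # with the general (non-symmetric) solver; directions must agree up to sign
  d <- rowSums(a)
  w <- a / outer(d^0.5, d^0.5)
  p <- w / rowSums(w)
  ep <- eigen(p)
  ord <- order(Re(ep$values), decreasing = TRUE)
  lam <- Re(ep$values[ord]); vec <- Re(ep$vectors[, ord])
  unit <- function(v) v / sqrt(sum(v^2))
  for (j in 1:3) {
    o <- unit(vec[, j + 1])
    got <- unit(g$coordinates[, j])
    expect_equal(abs(sum(o * got)), 1, tolerance = 1e-8)
    expect_equal(g$eigenvalues[j], lam[j + 1], tolerance = 1e-10)
  }
  # sign convention: each gradient's largest-magnitude loading is positive
  for (j in 1:3) {
    expect_gt(g$coordinates[which.max(abs(g$coordinates[, j])), j], 0)
  }
  expect_true(all(diff(g$variance_explained) <= 1e-12))
  expect_true(all(g$variance_explained > 0 & g$variance_explained <= 1))
})

test_that("embedding separates weakly coupled blocks and is permutation-equivariant", {
  blk <- matrix(0.05, 10, 10)
  blk[1:5, 1:5] <- 0.9
  blk[6:10, 6:10] <- 0.9
  diag(blk) <- 1
  g <- diffusion_map_embed(blk, n_components = 2)
  s1 <- sign(g$coordinates[1:5, 1])
  s2 <- sign(g$coordinates[6:10, 1])
  expect_true(all(s1 == s1[1]))
  expect_true(all(s2 == s2[1]))
  expect_true(s1[1] != s2[1])

  set.seed(11)
  n <- 9
  a <- abs(matrix(rnorm(n^2), n, n)); a <- (a + t(a)) / 2; diag(a) <- 1
  perm <- sample(n)
  g1 <- diffusion_map_embed(a, 3)
  g2 <- diffusion_map_embed(a[perm, perm], 3)
  expect_equal(g2$coordinates, g1$coordinates[perm, ], tolerance = 1e-8)

  disc <- diag(4); disc[1, 2] <- disc[2, 1] <- 1
  expect_error(diffusion_map_embed(disc), "disconnected")
})

test_that("group template equals the embedding of the mean affinity", {
  set.seed(12)
  mk <- function() {
    a <- abs(matrix(rnorm(64), 8, 8)); a <- (a + t(a)) / 2; diag(a) <- 1
    a
  }
  a1 <- mk()
  t1 <- build_group_template(list(a1))
  expect_equal(t1$coordinates, diffusion_map_embed(a1)$coordinates)
  # identical subjects: template equals the common embedding
  t2 <- build_group_template(list(a1, a1, a1))
  expect_equal(t2$coordinates, diffusion_map_embed(a1)$coordinates)
  expect_lte(sum(t2$variance_explained), 1)
  expect_error(build_group_template(list(a1, mk()[1:7, 1:7])), "shapes")
})

test_that("Procrustes alignment recovers a known rotation and is isometric", {
  set.seed(13)
  coords <- matrix(rnorm(60), 20, 3)
  template <- structure(list(coordinates = coords, template_id = "t"),
                        class = "wmo_gradients")
  subject <- structure(list(coordinates = coords, template_id = NA),
                       class = "wmo_gradients")
  al0 <- align_to_template(subject, template)
  expect_lt(al0$residual, 1e-10)
  expect_equal(al0$rotation, diag(3), tolerance = 1e-10)

  rot <- random_orthogonal(99)
  subject2 <- structure(list(coordinates = coords %*% rot), class = "wmo_gradients")
  al <- align_to_template(subject2, template)
  expect_lt(al$residual, 1e-10)
  expect_equal(al$coordinates, coords, tolerance = 1e-10)
  # isometry: inter-parcel distances unchanged
  expect_equal(as.matrix(dist(al$coordinates)), as.matrix(dist(subject2$coordinates)),
               tolerance = 1e-10)

  degenerate <- structure(list(coordinates = matrix(0, 20, 3)), class = "wmo_gradients")
  expect_error(align_to_template(degenerate, template), "rank deficient")
})

test_that("variance floor flags low-variance solutions", {
  g <- structure(list(variance_explained = c(0.3, 0.2, 0.1)), class = "wmo_gradients")
  expect_true(check_variance_floor(g, 0.5)$valid)
  expect_false(check_variance_floor(g, 0.7)$valid)
})

test_that("Procrustes solution agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(14)
  target <- matrix(rnorm(45), 15, 3)
  subject <- target %*% random_orthogonal(5) + matrix(rnorm(45, sd = 0.05), 15, 3)
  al <- align_to_template(structure(list(coordinates = subject), class = "wmo_gradients"),
                          structure(list(coordinates = target, template_id = "t"),
                                    class = "wmo_gradients"))
  vp <- vegan::procrustes(target, subject, scale = FALSE, symmetric = FALSE)
  # vegan translates to centroids as well; compare the rotations
  expect_equal(abs(det(al$rotation)), 1, tolerance = 1e-10)
  expect_equal(al$rotation %*% t(vp$rotation), diag(3), tolerance = 0.05)
})
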