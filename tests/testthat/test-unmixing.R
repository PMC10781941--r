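test_that("estimate_alpha recovers a known ratio on disjoint structure", {
  # two spatially disjoint blocks; target carries 0.3 of the source
  f1 <- matrix(0, 64, 64); f1[8:20, 8:20] <- 800
  f2 <- matrix(0, 64, 64); f2[40:56, 40:56] <- 1000
  mixed <- f1 + 0.3 * f2
  cur <- estimate_alpha(mixed, f2)
  expect_s3_class(cur, "mi_curve")
  expect_equal(cur$argmin_alpha, 0.3, tolerance = 0.011)
  # statistically independent channels: no mixing detected
  st <- phantom_pair(81)
  expect_lte(estimate_alpha(st[[1]], st[[2]])$argmin_alpha, 0.02)
  # fully colocalized channels without mixing: overcorrection reproduced
  co <- phantom_pair(82, rho = 1)
  expect_gt(estimate_alpha(co[[1]], co[[2]])$argmin_alpha, 0)
})

test_that("estimate_alpha validates its inputs", {
  x <- rand_img(91)
  expect_error(estimate_alpha(x, matrix(1, 64, 64)), "constant")
  expect_error(estimate_alpha(x, x, grid = numeric(0)), "empty")
  expect_error(estimate_alpha(x, x, grid = c(0.3, 0.2)), "increasing")
})

test_that("unmix_pair inverts the forward model on disjoint phantoms", {
  truth <- phantom_pair(101)
  alpha <- matrix(c(0, 0.6, 0.2, 0), 2, 2)
  mixed <- apply_mixing(truth, alpha)
  est <- mixing_estimate(alpha)
  rec <- unmix_pair(mixed, est)
  # single-step subtraction recovers (1 - a12*a21) * F exactly, up to
  # clamping of sub-noise negatives
  shrink <- 1 - alpha[1, 2] * alpha[2, 1]
  for (i in 1:2)
    expect_lt(max(abs(rec[[i]] - shrink * truth[[i]])) /
              max(truth[[i]]), 0.02)
  # identity and absent-channel edge cases
  id <- unmix_pair(mixed, mixing_estimate(matrix(0, 2, 2)))
  expect_equal(as.list(id), as.list(mixed))
  z <- image_stack(list(truth[[1]], matrix(0, 256, 256)))
  out <- unmix_pair(z, mixing_estimate(matrix(c(0, 0.4, 0.7, 0), 2, 2)))
  expect_equal(out[[1]], truth[[1]])
})

test_that("build_p_matrix follows the update-matrix structure", {
  expect_equal(build_p_matrix(mixing_estimate(matrix(0, 3, 3))), diag(3))
  est <- mixing_estimate(matrix(c(0, 0.6, 0.2, 0), 2, 2), gamma = 1)
  expect_equal(build_p_matrix(est),
               matrix(c(1, -0.6, -0.2, 1), 2, 2))
  set.seed(7)
  a <- matrix(runif(9, 0, 0.5), 3, 3); diag(a) <- 0
  p <- build_p_matrix(mixing_estimate(a, gamma = 0.4))
  for (i in 1:3) for (j in 1:3)
    expect_equal(p[i, j], if (i == j) 1 else -0.4 * a[i, j])
})

test_that("demix_stack is a no-op at gamma zero and reduces to unmix_pair", {
  st <- phantom_pair(111, a12 = 0.2, a21 = 0.6)
  off <- demix_stack(st, demix_config(gamma = 0, max_iters = 3))
  expect_equal(as.list(off$stack), as.list(st))
  # n = 2, gamma = 1, one iteration == estimate both ratios + unmix_pair
  res <- demix_stack(st, demix_config(gamma = 1, max_iters = 1))
  a12 <- estimate_alpha(st[[1]], st[[2]])$argmin_alpha
  a21 <- estimate_alpha(st[[2]], st[[1]])$argmin_alpha
  byhand <- unmix_pair(st, mixing_estimate(matrix(c(0, a21, a12, 0), 2, 2)))
  expect_equal(as.list(res$stack), as.list(byhand))
  expect_equal(res$estimate$alpha, matrix(c(0, a21, a12, 0), 2, 2))
})

test_that("demix_stack leaves an already-unmixed stack alone", {
  st <- phantom_pair(121)
  res <- demix_stack(st)
  expect_true(res$converged)
  expect_lte(max(res$estimate$alpha), 0.02)
  for (i in 1:2)
    expect_lt(max(abs(res$stack[[i]] - st[[i]])) / max(st[[i]]), 0.03)
})

test_that("three-channel demixing matches a hand-rolled matrix-product oracle", {
  # lighter field: three channels of fully exclusive cells must all pack
  sp <- phantom_spec(n_channels = 3, n_cells = 40, seed = 131)
  truth <- generate_ground_truth(sp)
  alpha <- matrix(c(0, 0.3, 0.1,
                    0.2, 0, 0.15,
                    0.05, 0.25, 0), 3, 3, byrow = TRUE)
  diag(alpha) <- 0
  mixed <- apply_mixing(truth, alpha)
  cfg <- demix_config(gamma = 0.5, max_iters = 4)
  res <- demix_stack(mixed, cfg)
  # replay the iterations from the recorded history
  X <- as.list(mixed)
  hist <- res$history
  for (k in seq_len(res$estimate$iterations_run)) {
    A <- matrix(0, 3, 3)
    rows <- hist[hist$iteration == k, ]
    for (r in seq_len(nrow(rows)))
      A[rows$i[r], rows$j[r]] <- rows$alpha[r]
    P <- diag(3) - 0.5 * A
    X <- lapply(1:3, function(i)
      pmax(P[i, 1] * X[[1]] + P[i, 2] * X[[2]] + P[i, 3] * X[[3]], 0))
  }
  for (i in 1:3)
    expect_equal(res$stack[[i]], X[[i]], tolerance = 1e-9)
  # recovered channels approximate the truth
  for (i in 1:3)
    expect_lt(sqrt(mean((res$stack[[i]] - truth[[i]])^2)) /
              sqrt(mean(truth[[i]]^2)), 0.15)
  # all outputs non-negative
  expect_true(all(vapply(as.list(res$stack), min, 0) >= 0))
})

test_that("whole-image estimation recovers ratios across the tested range", {
  for (a in c(0.1, 0.3, 0.6)) {
    st <- phantom_pair(140 + round(100 * a), a12 = a, a21 = a)
    expect_equal(estimate_alpha(st[[1]], st[[2]])$argmin_alpha, a,
                 tolerance = 0.05)
    expect_equal(estimate_alpha(st[[2]], st[[1]])$argmin_alpha, a,
                 tolerance = 0.05)
  }
})
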