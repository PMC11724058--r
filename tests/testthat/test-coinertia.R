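make_tables <- function(n = 6, p = 8, q = 10, seed = 1) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p,
                  dimnames = list(paste0("g", 1:n), paste0("mi", 1:p))),
       Y = matrix(rnorm(n * q), n, q,
                  dimnames = list(paste0("g", 1:n), paste0("mr", 1:q))))
}

test_that("fitting a table against itself gives RV 1 and matched scores", {
  tt <- make_tables(q = 8, seed = 2)
  X <- tt$X
  Y <- X; colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  fit <- coinertia_fit(X, Y, k = 2)
  expect_equal(fit$rv, 1, tolerance = 1e-12)
  # same table twice: both row projections coincide up to axis sign
  agree <- abs(abs(colSums(fit$row_scores_X * fit$row_scores_Y)) -
                 sqrt(colSums(fit$row_scores_X^2) *
                        colSums(fit$row_scores_Y^2)))
  expect_lt(max(agree), 1e-8)
})

test_that("eigenvalues match an independent eigendecomposition oracle", {
  tt <- make_tables(seed = 3)
  fit <- coinertia_fit(tt$X, tt$Y, k = 2)
  want <- oracle_coinertia_eig(tt$X, tt$Y)
  expect_equal(fit$eigenvalues[seq_along(want)], want, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  tt <- make_tables()
  expect_error(coinertia_fit(tt$X[1, , drop = FALSE], tt$Y[1, , drop = FALSE]),
               "at least 2 groups")
  expect_error(coinertia_fit(tt$X, tt$Y[c(2, 1, 3:6), ]), "aligned")
  Yc <- tt$Y; Yc[] <- 3
  expect_error(rv_coefficient(tt$X, Yc), "constant")
})

test_that("RV matches the brute-force trace formula on toy tables", {
  set.seed(9)
  X <- matrix(rnorm(8), 4, 2)
  Y <- matrix(rnorm(8), 4, 2)
  expect_equal(rv_coefficient(X, Y), oracle_rv(X, Y), tolerance = 1e-12)
})

test_that("RV is in [0,1] and invariant to column permutation and scaling", {
  set.seed(13)
  for (trial in 1:30) {
    n <- sample(3:8, 1)
    X <- matrix(rnorm(n * sample(2:12, 1)), n)
    Y <- matrix(rnorm(n * sample(2:12, 1)), n)
    rv <- rv_coefficient(X, Y)
    expect_gte(rv, 0); expect_lte(rv, 1)
    expect_equal(rv_coefficient(X[, sample(ncol(X))], Y), rv)
    expect_equal(rv_coefficient(X * 7.3, Y), rv)
  }
})

test_that("eigenvalue total equals the squared norm of the centered cross-product", {
  set.seed(17)
  for (trial in 1:20) {
    tt <- make_tables(n = sample(3:8, 1), p = sample(3:15, 1),
                      q = sample(3:15, 1), seed = trial + 100)
    fit <- coinertia_fit(tt$X, tt$Y, k = 2)
    Xc <- sweep(tt$X, 2, colMeans(tt$X))
    Yc <- sweep(tt$Y, 2, colMeans(tt$Y))
    expect_equal(sum(fit$eigenvalues), sum((t(Xc) %*% Yc)^2),
                 tolerance = 1e-8)
  }
})

test_that("quadrants follow the sign convention with zero as positive", {
  sc <- rbind(a = c(0.3, 0.7), b = c(-1, 2), c = c(-1, -1), d = c(0, -1))
  expect_equal(unname(quadrant_assign(sc)), c("Q1", "Q2", "Q3", "Q4"))
  expect_error(quadrant_assign(cbind(1:3)), "2 axes")
})

test_that("quadrants can be renamed after group centroids", {
  cent <- rbind(K562 = c(2, 2), A549 = c(-2, 2),
                HeLa = c(-2, -2), HEK293T = c(2, -2))
  sc <- rbind(p1 = c(1, 1), p2 = c(-0.5, -3))
  out <- quadrant_assign(sc, relabel_centroids = cent)
  expect_equal(unname(out), c("K562", "HeLa"))
  bad <- cent; bad["A549", ] <- c(3, 3)
  expect_error(quadrant_assign(sc, relabel_centroids = bad), "distinct")
})

test_that("target overlays count per quadrant and tally missing targets", {
  tt <- make_tables(seed = 21)
  fit <- coinertia_fit(tt$X, tt$Y, k = 2)
  # place two real targets plus one absent from the fitted matrix
  tm <- consensus_targets(list(
    data.frame(mirna = "mi1", gene = c("mr1", "mr2", "ghost")),
    data.frame(mirna = "mi1", gene = c("mr1", "mr2", "ghost"))),
    min_algorithms = 2)
  ov <- target_overlay(fit, tm, "mi1")
  expect_equal(sum(ov$counts), 2)
  expect_equal(ov$missing, 1)
  expect_equal(names(ov$counts), c("Q1", "Q2", "Q3", "Q4"))
  want <- quadrant_assign(fit$col_loadings_Y[c("mr1", "mr2"), 1:2])
  expect_equal(ov$quadrant, want)
  expect_error(target_overlay(fit, tm, "nope"), "not in target map")
})

test_that("consensus keeps pairs supported by enough algorithms", {
  preds <- list(
    data.frame(mirna = "m1", gene = c("a", "b")),
    data.frame(mirna = "m1", gene = c("a", "b")),
    data.frame(mirna = "m1", gene = "a"),
    data.frame(mirna = c("m1", "m2"), gene = c("c", "d")))
  tm <- consensus_targets(preds, min_algorithms = 3)
  expect_equal(tm$table$gene, "a")
  expect_equal(tm$table$support, 3L)
  expect_equal(tm$map, list(m1 = "a"))
  empty <- consensus_targets(list(), min_algorithms = 3)
  expect_equal(nrow(empty$table), 0)
})
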