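test_that("NIPALS PLS reproduces exact relationships", {
  set.seed(1)
  # orthonormal centered X, Y equal to one column: one component explains
  # all Y variance (the first weight vector aligns exactly with it)
  X <- qr.Q(qr(scale(matrix(rnorm(40 * 6), 40, 6), scale = FALSE)))
  colnames(X) <- letters[1:6]
  m <- fit_pls(X, X[, 1], n_components = 1, scaling = "none")
  expect_equal(sum(m$explained_y_variance), 1, tolerance = 1e-9)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, letters[1:6]))
  m <- fit_pls(X, X[, 1], n_components = 1)

  # orthonormal X: first-component weights proportional to X'y
  Xo <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5))) * sqrt(49)
  colnames(Xo) <- letters[1:5]
  y <- rnorm(50)
  mo <- fit_pls(Xo, y, n_components = 1, scaling = "none")
  w_expect <- crossprod(scale(Xo, scale = FALSE), y - mean(y))[, 1]
  w_expect <- w_expect / sqrt(sum(w_expect^2))
  expect_equal(abs(sum(mo$x_weights[, 1] * w_expect)), 1, tolerance = 1e-8)

  # row permutation leaves the model identical up to row order
  perm <- sample(40)
  m2 <- fit_pls(X[perm, ], X[perm, 1], n_components = 1)
  expect_equal(m2$x_weights, m$x_weights, tolerance = 1e-9)
  expect_equal(m2$x_scores[order(perm), 1], m$x_scores[, 1], tolerance = 1e-9)
})

test_that("one-component PLS matches the SVD direction of X'Y", {
  set.seed(6)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, letters[1:8]))
  Y <- cbind(rnorm(60), rnorm(60))
  m <- fit_pls(X, Y, n_components = 1)
  Xs <- m$X_scaled
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(crossprod(Xs, Yc))
  expect_equal(abs(sum(m$x_weights[, 1] * sv$u[, 1])), 1, tolerance = 1e-6)
})

test_that("constant X columns are dropped with a warning", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  expect_warning(m <- fit_pls(X, rnorm(20), 1), "constant")
  expect_equal(rownames(m$x_weights), "a")
})

test_that("VIP satisfies its algebraic identity and special cases", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 7), 30, 7, dimnames = list(NULL, letters[1:7]))
    Y <- cbind(X[, 1] + rnorm(30, 0, 0.5), rnorm(30))
    m <- fit_pls(X, Y, n_components = 3)
    v <- vip(m)
    expect_equal(sum(v^2), nrow(m$x_weights), tolerance = 1e-8)
    expect_true(all(v >= 0))
  }
  # 1 component, two equally weighted variables -> both VIP = 1
  m1 <- list(x_weights = matrix(c(1, -1) / sqrt(2), 2, 1,
                                dimnames = list(c("a", "b"), NULL)),
             explained_y_variance = 0.7, n_components = 1)
  class(m1) <- "pls_model"
  expect_equal(unname(vip(m1)), c(1, 1))
})

test_that("p(corr) behaves like a score-variable correlation", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, letters[1:5]))
  y <- X[, 1] + rnorm(200, 0, 0.2)
  m <- fit_pls(X, y, n_components = 1)
  pc <- p_corr(m, 1)
  # a column equal to the scores correlates at 1 (up to sign)
  X2 <- cbind(X, sc = m$x_scores[, 1])
  m2 <- fit_pls(X2, y, n_components = 1)
  pc2 <- p_corr(m2, 1)
  expect_gt(abs(pc2["sc"]), 0.99)
  # independent noise columns stay below |0.2| most of the time
  expect_true(mean(abs(pc[2:5]) < 0.2) >= 0.75)
})

test_that("Q2Y cross-validation and permutation test are sane", {
  set.seed(4)
  X <- matrix(rnorm(70 * 10), 70, 10, dimnames = list(NULL, letters[1:10]))
  y <- 2 * X[, 1] - X[, 2] + rnorm(70, 0, 0.1)
  v <- validate_pls(X, y, n_components = 2, folds = 7, n_permutations = 30,
                    seed = 1)
  expect_gt(v$q2y, 0.9)
  expect_lte(v$permutation_p, 1)
  expect_gte(v$permutation_p, 1 / 31)
  # Q2Y <= R2Y on the same data
  m <- fit_pls(X, y, n_components = 2)
  expect_lte(v$q2y, sum(m$explained_y_variance))
  # independent Y: the permutation p is roughly uniform, so its average
  # over null repeats sits well away from significance
  p0 <- vapply(1:3, function(r) {
    validate_pls(X, rnorm(70), n_components = 2, folds = 7,
                 n_permutations = 40, seed = r)$permutation_p
  }, 1)
  expect_gt(mean(p0), 0.2)
})

test_that("the discriminant selection rule is a pure conjunction", {
  out <- select_discriminant(
    vips = c(fl = 1.63, a = 0.99, b = 1.5, c = 1.2),
    p_corrs = c(fl = 0.52, a = 0.9, b = 0.1, c = -0.4),
    wmw_ps = c(fl = 0.0001, a = 0.001, b = 0.001, c = 0.2))
  expect_true(out$selected[out$metabolite_id == "fl"])
  expect_false(out$selected[out$metabolite_id == "a"])  # VIP fails
  expect_false(out$selected[out$metabolite_id == "b"])  # p_corr fails
  expect_false(out$selected[out$metabolite_id == "c"])  # p fails
  expect_equal(out$metabolite_id[1], "fl")  # sorted by VIP
  expect_warning(
    out2 <- select_discriminant(c(x = 1.5, y = NA), c(x = 0.5, y = 0.5),
                                c(x = 0.01, y = 0.01)),
    "missing")
  expect_equal(out2$metabolite_id, "x")
})

test_that("bile-acid ratios follow their definitions", {
  panel <- c(CA = 2, CDCA = 1, LCA = 1, DCA = 0,
             TCA = 1, TCDCA = 1, TDCA = 1, GCA = 1, TLCA = 1, GCDCA = 1,
             GDCA = 1, GLCA = 1)
  r <- bile_acid_ratios(panel)
  expect_equal(r$ba_cba, 4 / 7)
  expect_equal(r$ca_cca, 2 / 2)
  expect_equal(r$cdca_ccdca, 1 / 2)
  expect_equal(r$lca_clca, 1 / 2)

  # all unconjugated zero -> ratios 0; conjugated zero -> undefined (NA)
  zero_un <- panel; zero_un[c("CA", "CDCA", "LCA", "DCA")] <- 0
  expect_true(all(bile_acid_ratios(zero_un) == 0))
  zero_conj <- panel
  zero_conj[c("TCA", "TCDCA", "TDCA", "GCA", "TLCA", "GCDCA", "GDCA",
              "GLCA")] <- 0
  expect_true(all(is.na(bile_acid_ratios(zero_conj))))
})

test_that("baseline-shift tests detect a planted shift at one visit", {
  set.seed(7)
  meta <- data.frame(
    sample_id = sprintf("s%03d", 1:160),
    infant_id = sprintf("i%03d", 1:160),
    visit = rep(c("V0", "V1", "V3", "V6"), each = 40),
    age = rep(c(30, 60, 120, 365), each = 40),
    arm = "control")
  vals <- stats::setNames(rnorm(160, 10), meta$sample_id)
  vals[meta$visit == "V1"] <- vals[meta$visit == "V1"] - 5
  p <- baseline_shift_tests(vals, meta, "control")
  expect_lt(p["V1"], 0.001)
  expect_equal(unname(which.min(p)), 1L)

  const <- stats::setNames(rep(1, 160), meta$sample_id)
  expect_true(all(baseline_shift_tests(const, meta, "control") == 1))
})

test_that("PLS agrees with an independent implementation on scores", {
  skip_if_not_installed("mixOmics")
  set.seed(10)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, letters[1:8]))
  y <- X[, 1] - X[, 3] + rnorm(50, 0, 0.3)
  m <- fit_pls(X, y, n_components = 2)
  ref <- mixOmics::pls(X, y, ncomp = 2, scale = TRUE, mode = "regression")
  for (a in 1:2) {
    expect_gt(abs(stats::cor(m$x_scores[, a], ref$variates$X[, a])), 0.999)
  }
})
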