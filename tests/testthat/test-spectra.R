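test_that("Newton polynomials count closed walks", {
  ico <- dodeca_dual()
  expect_equal(newton_polynomial(ico, 0), 12)
  expect_equal(newton_polynomial(ico, 2), 2 * 30)      # twice the edges
  # closed 3-walks by explicit triple enumeration (independent oracle)
  a <- embedding_adjacency(ico$embedding)
  walks3 <- 0
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    walks3 <- walks3 + a[i, j] * a[j, k] * a[k, i]
  expect_equal(newton_polynomial(ico, 3), walks3)
  expect_equal(walks3, 6 * 20)                         # 6 x triangles
  # shifted matrix: trace of (A + (beta/alpha) D)^k via explicit powers
  p <- character_params(0.5, 0.25)
  M <- a + 0.5 * diag(rowSums(a))
  expect_equal(newton_polynomial(ico, 4, p), sum(diag(M %*% M %*% M %*% M)))
})

test_that("the character matches the icosahedron closed-form spectrum", {
  # adjacency eigenvalues: 5, sqrt(5) (x3), -sqrt(5) (x3), -1 (x5);
  # adding (beta/alpha) D shifts all by 5 beta/alpha
  for (p in list(character_params(0.5, 0.25), character_params(1, 0.5))) {
    sh <- 5 * p$beta / p$alpha
    lam <- c(5, rep(sqrt(5), 3), rep(-sqrt(5), 3), rep(-1, 5)) + sh
    expect_equal(graph_character(dodeca_dual(), p), sum(exp(p$alpha * lam)),
                 tolerance = 1e-12)
  }
})

test_that("character equals the trace of the matrix exponential", {
  skip_if_not_installed("Matrix")
  for (td in list(dodeca_dual(), isomer_by_index(30, 2, as = "dual"),
                  goldberg(1, 1, as = "dual"))) {
    a <- embedding_adjacency(td$embedding)
    M <- 0.5 * a + 0.25 * diag(rowSums(a))
    tr <- sum(diag(as.matrix(Matrix::expm(M))))
    expect_equal(graph_character(td), tr, tolerance = 1e-9)
  }
})

test_that("the character tends to the vertex count as parameters vanish", {
  p0 <- character_params(1e-8, 1e-8)
  for (td in list(dodeca_dual(), isomer_by_index(36, 7, as = "dual")))
    expect_equal(graph_character(td, p0), td$m, tolerance = 1e-6)
})

test_that("the character is a graph invariant", {
  td <- isomer_by_index(32, 4, as = "dual")
  ref <- graph_character(td)
  for (s in 1:3)
    expect_equal(graph_character(relabel_dual(td, s)), ref, tolerance = 1e-12)
})

test_that("normalized characters anchor the extremal structures at 0 and 1", {
  expect_equal(normalized_character(goldberg(1, 1, as = "dual"), 60), 0)
  expect_equal(normalized_character(nanotube_5_0(60, as = "dual"), 60), 1)
  expect_error(normalized_character(dodeca_dual(), 44), "does not admit")
})

test_that("histograms honour the bin count with support in [0, 1]", {
  h <- character_histogram(60, bins = 250)
  expect_length(h$counts, 250L)
  expect_equal(sum(h$counts), 1812L)
  expect_true(all(h$normalized >= 0 - 1e-12 & h$normalized <= 1 + 1e-12))
  h6 <- character_histogram(60, graph_choice = "hex", bins = 100)
  expect_length(h6$counts, 100L)
  expect_true(all(h6$normalized >= -1e-9 & h6$normalized <= 1 + 1e-9))
})

test_that("characters separate all isomers up to n = 30", {
  col <- conjecture3_check(30)
  expect_equal(nrow(col), 0L)
  # relabelling is never reported as a collision (same value to numerical
  # precision, far inside the collision tolerance)
  td <- isomer_by_index(30, 1, as = "dual")
  expect_equal(graph_character(td), graph_character(relabel_dual(td, 1)),
               tolerance = 1e-13)
})

test_that("zeta values match closed forms with bounded remainders", {
  expect_equal(riemann_zeta(2), pi^2 / 6, tolerance = 1e-12)
  expect_equal(round(riemann_zeta(9), 8), 1.00200839)
  # K-stability: the Euler-Maclaurin tail makes K = 50 and K = 400 agree
  for (s in c(1.5, 3, 9))
    expect_equal(riemann_zeta(s, K = 50L), riemann_zeta(s, K = 400L),
                 tolerance = 1e-11)
  skip_if_not_installed("pracma")
  for (s in c(2, 4, 9))
    expect_equal(riemann_zeta(s), pracma::zeta(s), tolerance = 1e-9)
  expect_error(riemann_zeta(1), "s > 1")
})
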