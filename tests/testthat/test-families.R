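test_that("t-triangles have the documented census", {
  t0 <- t_triangle(0)
  expect_equal(t0$embedding$n_vertices, 1L)

  t2 <- t_triangle(2)
  deg <- embedding_degrees(t2$embedding)
  expect_equal(t2$embedding$n_vertices, 6L)
  expect_equal(sum(deg == 2L), 3L)
  expect_equal(sum(deg == 4L), 3L)
  expect_equal(sum(lengths(trace_faces(t2$embedding)) == 3L), 4L)  # t^2 inner

  t4 <- t_triangle(4)
  expect_equal(t4$embedding$n_vertices, 15L)
  deg4 <- embedding_degrees(t4$embedding)
  expect_equal(sum(deg4 == 2L), 3L)
  expect_equal(sum(deg4 == 4L), 9L)          # 3(t-1)
  expect_equal(sum(deg4 == 6L), 3L)
  expect_equal(sum(lengths(trace_faces(t4$embedding)) == 3L), 16L)
})

test_that("truncation deletes corner rows and marks open edges", {
  expect_equal(truncated_triangle(3, 0, 0, 0)$embedding$n_vertices,
               t_triangle(3)$embedding$n_vertices)
  tr <- truncated_triangle(4, 1, 0, 0)
  expect_equal(tr$embedding$n_vertices, 14L)   # corner vertex removed
  expect_equal(nrow(tr$open_edges), 1L)
  # deep truncations used by the glued family: r rows remove r(r+1)/2
  for (t in 2:4) {
    tc <- truncated_triangle(2 * t, t - 1, t - 1, t - 1)
    expect_equal(tc$embedding$n_vertices,
                 (2 * t + 1) * (t + 1) - 3 * t * (t - 1) / 2)
    expect_equal(nrow(tc$open_edges), 3L * (t - 1L))
  }
  expect_error(truncated_triangle(3, 2, 1, 0), "truncation")
  expect_error(truncated_triangle(2, 0, 0, 1), "r1 >= r2")
})

test_that("the glued family has the stated counts and no gSW path", {
  for (t in 2:4) {
    td <- construction2(t)
    expect_equal(2L * (td$m - 2L), 4L * (t^2 + 6L * t + 7L))
    expect_false(has_gsw_path(td))
    expect_identical(pentagon_partition(td), rep(3L, 4L))
  }
  # hexagonal subgraph census at t = 2: 36 vertices, four hexagonal holes,
  # 13 triangles contributed by each of the four glued patches
  s6 <- subgraph6(construction2(2))
  expect_equal(s6$n_vertices, 36L)
  fs <- lengths(fullerite:::.trace_rotation(s6$rotation))
  expect_equal(sum(fs == 6L), 4L)
  expect_equal(sum(fs == 3L), 4L * 13L)
  expect_equal(sum(fs == 3L) / 4L, 2^2 + 6 * 2 - 3)
})

test_that("boundary-preserving growth yields an isomer for every n >= 36", {
  expect_true(same_dual_graph(construction3(36, as = "dual"),
                              isomer_by_index(36, 1, as = "dual")))
  for (n in c(38, 44, 70, 100)) {
    f <- construction3(n)
    expect_s3_class(f, "fullerene")
    expect_equal(f$n, n)
  }
  expect_error(construction3(34), "n >= 36")
  expect_error(construction3(37), "even")
})

test_that("(5,0)-nanotubes scale by five-vertex belts", {
  expect_true(same_dual_graph(nanotube_5_0(20, as = "dual"), dodeca_dual()))
  for (n in c(30, 60, 90)) {
    td <- nanotube_5_0(n, as = "dual")
    expect_equal(td$m, n / 2 + 2)
    # belt count: all degree-6 vertices sit in (n - 20)/10 belts of five
    expect_equal(sum(embedding_degrees(td$embedding) == 6L), (n - 20L) / 2L)
  }
  expect_error(nanotube_5_0(24), "10r")
})

test_that("Goldberg subdivision hits n = 20((p+q)^2 - pq) and is IPR", {
  expect_true(same_dual_graph(goldberg(1, 0, as = "dual"), dodeca_dual()))
  cases <- list(c(1, 1, 60), c(2, 0, 80), c(2, 1, 140))
  for (cs in cases) {
    td <- goldberg(cs[[1]], cs[[2]], as = "dual")
    expect_equal(2L * (td$m - 2L), cs[[3]])
    expect_true(is_ipr(td))
  }
  expect_error(goldberg(0, 0), "p >= 1")
  expect_error(goldberg(1, 2), "p >= q")
})

test_that("the prism dual seed has bipyramid structure", {
  b5 <- bipyramid_seed(5)
  expect_equal(sort(embedding_degrees(b5$embedding)), c(3L, 3L, 4L, 4L, 4L))
  b12 <- bipyramid_seed(12)
  deg <- embedding_degrees(b12$embedding)
  expect_equal(sort(unique(deg)), c(4L, 10L))
  expect_equal(sum(deg == 10L), 2L)            # two apices of degree m - 2
  expect_equal(embedding_edges(b12$embedding), 3L * 12L - 6L)
  expect_length(trace_faces(b12$embedding), 2L * 12L - 4L)
  expect_error(bipyramid_seed(4), "m >= 5")
})
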