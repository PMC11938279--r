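test_that("fullerene invariants hold for generated isomers", {
  for (n in c(20, 24, 30, 36)) {
    codes <- enumerate_isomers(n)
    for (j in seq_len(min(3L, nrow(codes)))) {
      f <- windup(spiral_code(n, codes[j, ]))
      expect_equal(embedding_edges(f$embedding), 3L * n / 2L)
      fs <- lengths(trace_faces(f$embedding))
      expect_equal(sum(fs == 5L), 12L)
      expect_equal(sum(fs == 6L), n / 2L - 10L)
    }
  }
})

test_that("pentagonal and hexagonal subgraphs partition the dual vertex set", {
  t20 <- dodeca_dual()
  s5 <- subgraph5(t20); s6 <- subgraph6(t20)
  expect_equal(s5$n_vertices, 12L)
  expect_equal(s6$n_vertices, 0L)
  expect_equal(sum(lengths(s5$rotation)) / 2, 30)   # icosahedron edge count

  t60 <- goldberg(1, 1, as = "dual")
  expect_equal(subgraph6(t60)$n_vertices, 20L)      # n/2 - 10
  expect_equal(sum(lengths(subgraph5(t60)$rotation)), 0L)  # IPR: no edges

  for (n in c(26, 34, 40)) {
    td <- isomer_by_index(n, 1, as = "dual")
    expect_equal(subgraph6(td)$n_vertices, n / 2L - 10L)
    expect_equal(subgraph5(td)$n_vertices + subgraph6(td)$n_vertices, td$m)
  }
})

test_that("pentagon partitions are partitions of 12 with documented values", {
  expect_identical(pentagon_partition(dodeca_dual()), rep(12L, 1L))
  expect_identical(pentagon_partition(goldberg(1, 1, as = "dual")), rep(1L, 12L))
  expect_identical(pentagon_partition(construction2(2)), rep(3L, 4L))
  for (n in c(28, 32, 36)) {
    codes <- enumerate_isomers(n)
    for (j in seq_len(nrow(codes))) {
      pp <- pentagon_partition(windup(spiral_code(n, codes[j, ]), as = "dual"))
      expect_equal(sum(pp), 12L)
      expect_true(all(diff(pp) <= 0L))
    }
  }
})

test_that("isolated-pentagon detection matches exhaustive small-n scans", {
  expect_false(is_ipr(dodeca_dual()))
  expect_true(is_ipr(goldberg(1, 1, as = "dual")))
  for (n in seq(24, 40, by = 2)) {
    codes <- enumerate_isomers(n)
    for (j in seq_len(nrow(codes)))
      expect_false(is_ipr(windup(spiral_code(n, codes[j, ]), as = "dual")))
  }
})

test_that("integer partition counts match the enumeration oracle", {
  expect_equal(count_integer_partitions(1), 1L)
  expect_equal(count_integer_partitions(12), 77L)
  for (k in 2:9)
    expect_equal(count_integer_partitions(k), length(partitions_oracle(k)))
})
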