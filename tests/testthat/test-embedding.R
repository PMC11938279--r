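test_that("face tracing recovers the face sets of reference polyhedra", {
  tri <- planar_embedding(list(c(2L, 3L), c(3L, 1L), c(1L, 2L)))
  expect_length(trace_faces(tri), 2L)
  expect_true(all(lengths(trace_faces(tri)) == 3L))

  dode <- windup(spiral_code(20, 1:12))
  fs <- trace_faces(dode$embedding)
  expect_length(fs, 12L)
  expect_true(all(lengths(fs) == 5L))

  ico <- planar_embedding(icosa_rotation_handmade())
  fi <- trace_faces(ico)
  expect_length(fi, 20L)
  expect_true(all(lengths(fi) == 3L))
})

test_that("every directed edge lies on exactly one traced face", {
  ico <- planar_embedding(icosa_rotation_handmade())
  fs <- trace_faces(ico)
  darts <- unlist(lapply(fs, function(w) {
    l <- length(w)
    paste(w, w[c(2:l, 1L)], sep = ".")
  }))
  expect_equal(length(darts), 2L * embedding_edges(ico))
  expect_false(anyDuplicated(darts) > 0)
})

test_that("embedding validation rejects broken rotation systems", {
  expect_error(planar_embedding(list(c(2L, 2L), c(1L, 1L))), "parallel")
  expect_error(planar_embedding(list(c(1L, 2L), c(1L))), "loop")
  expect_error(planar_embedding(list(2L, 1L, integer(0))), "connected")
  # K5-like non-planar rotation data fails the Euler check
  rot_k5 <- lapply(1:5, function(v) setdiff(1:5, v))
  expect_error(planar_embedding(rot_k5), "planar")
})

test_that("dualization is an involution and maps counts correctly", {
  f20 <- windup(spiral_code(20, 1:12))
  t20 <- dualize(f20)
  expect_s3_class(t20, "dual_triangulation")
  expect_equal(t20$m, 12L)
  back <- dualize_inverse(t20)
  expect_equal(back$n, 20L)
  expect_identical(unwind_canonical(back)$positions, 1:12)

  f60 <- goldberg(1, 1)
  t60 <- dualize(f60)
  expect_equal(t60$m, 32L)
  deg <- embedding_degrees(t60$embedding)
  expect_equal(sum(deg == 5L), 12L)
  expect_equal(sum(deg == 6L), 20L)
})

test_that("dual round-trip is the identity up to isomorphism on sampled isomers", {
  for (n in c(24, 28, 32, 36, 40)) {
    codes <- enumerate_isomers(n)
    take <- unique(round(seq(1, nrow(codes), length.out = 5)))
    for (j in take) {
      f <- windup(spiral_code(n, codes[j, ]))
      rt <- dualize_inverse(dualize(f))
      expect_identical(unwind_canonical(rt)$positions, codes[j, ])
    }
  }
})

test_that("triangulation embedding reconstruction matches a known embedding", {
  ico <- planar_embedding(icosa_rotation_handmade())
  adj <- embedding_adjacency(ico)
  rec <- triangulation_embedding(adj)
  expect_equal(embedding_adjacency(rec), adj)
  expect_true(all(lengths(trace_faces(rec)) == 3L))
})
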