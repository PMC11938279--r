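test_that("facet-vertex classification matches known hexagonal subgraphs", {
  # an isolated t-triangle has no multi-facet vertices
  t3 <- t_triangle(3)
  cls <- classify_facet_vertices(list(n_vertices = t3$embedding$n_vertices,
                                      rotation = t3$embedding$rotation))
  expect_true(all(cls$label == "none"))

  # T6 of the gSW-free C56 isomer: six 2-facet vertices (the pinches that
  # open into the four 2-triangles)
  c56 <- isomer_by_index(56, 622, as = "dual")
  cls56 <- classify_facet_vertices(subgraph6(c56))
  expect_equal(sum(cls56$label == "two_facet"), 6L)
  expect_equal(sum(cls56$label == "three_facet"), 0L)

  # T6 of the isolated-pentagon C60 is the dodecahedral hexagon-adjacency
  # graph: every face is a pentagonal hole, every vertex a 3-facet vertex
  cls60 <- classify_facet_vertices(subgraph6(goldberg(1, 1, as = "dual")))
  expect_equal(nrow(cls60), 20L)
  expect_true(all(cls60$label == "three_facet"))
})

test_that("cut-partitions reproduce the documented decompositions", {
  label_of <- function(cp) sort(vapply(cp$classification, function(cl) {
    if (cl$type == "t_triangle") paste0("t", cl[["t"]])
    else if (cl$type == "truncated") paste0("t", cl[["t"]], "r",
                                            paste(cl$truncation, collapse = ""))
    else "other"
  }, character(1)))

  cp56 <- cut_partition(subgraph6(isomer_by_index(56, 622, as = "dual")))
  expect_identical(label_of(cp56), rep("t2", 4L))

  cp80 <- cut_partition(subgraph6(goldberg(2, 0, as = "dual")))
  expect_identical(label_of(cp80), rep("t1", 20L))

  cp92 <- cut_partition(subgraph6(construction2(2)))
  expect_identical(label_of(cp92), rep("t4r111", 4L))

  cp20 <- cut_partition(subgraph6(dodeca_dual()))
  expect_length(cp20$components, 0L)
})

test_that("vertex conservation: output count = input + splits", {
  for (td in list(isomer_by_index(56, 622, as = "dual"),
                  goldberg(2, 0, as = "dual"),
                  construction2(2),
                  isomer_by_index(40, 17, as = "dual"))) {
    cp <- cut_partition(subgraph6(td))
    expect_equal(cp$n_vertices_out, cp$n_vertices_in + cp$n_split_vertices)
    expect_equal(sum(lengths(cp$components)), cp$n_vertices_out)
  }
})

test_that("cut-partition components never contain multi-facet or degree-5 vertices", {
  for (n in c(36, 40)) {
    codes <- enumerate_isomers(n)
    for (j in unique(round(seq(1, nrow(codes), length.out = 6)))) {
      cp <- cut_partition(subgraph6(windup(spiral_code(n, codes[j, ]), as = "dual")))
      for (comp in cp$components) {
        expect_true(all(lengths(comp) != 5L))
        inc <- fullerite:::.facet_incidence(comp)
        occ <- vapply(seq_along(comp), function(v)
          sum(inc$sizes[inc$corner_faces[[v]]] > 3L), integer(1))
        expect_true(all(occ <= 1L))
      }
    }
  }
})

test_that("component recognition inverts the patch generators", {
  expect_identical(recognize_component(t_triangle(0))$type, "t_triangle")
  r2 <- recognize_component(t_triangle(2))
  expect_identical(r2$type, "t_triangle"); expect_equal(r2[["t"]], 2L)
  # a relabelled truncated triangle is still recognized
  tr <- truncated_triangle(4, 1, 0, 0)
  rot <- tr$embedding$rotation
  set.seed(3)
  perm <- sample.int(length(rot))
  rot2 <- vector("list", length(rot))
  for (v in seq_along(rot)) rot2[[perm[[v]]]] <- perm[rot[[v]]]
  rr <- recognize_component(rot2)
  expect_identical(rr$type, "truncated")
  expect_equal(rr[["t"]], 4L)
  expect_equal(rr$truncation, c(1L, 0L, 0L))
  # a path graph is not a triangle patch
  expect_identical(recognize_component(list(2L, c(1L, 3L), 2L))$type, "other")
})

test_that("the partition-vs-gSW predicate only fails on trivial small-triangle cases", {
  sc <- conjecture2_scan(36)
  expect_equal(nrow(sc), 35L)
  bad <- sc[!sc$agree, ]
  # disagreements: gSW-capable isomers whose hexagonal subgraph already
  # falls apart into 0-/1-triangles; no gSW-free isomer is mis-classified
  expect_true(all(bad$has_gsw_path))
  expect_true(all(bad$all_triangles))
  gsw_free <- sc[!sc$has_gsw_path, ]
  expect_true(all(gsw_free$agree))
})
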