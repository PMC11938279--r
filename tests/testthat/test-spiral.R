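test_that("windup decodes the dodecahedron and rejects impossible codes", {
  f <- windup(spiral_code(20, 1:12))
  expect_s3_class(f, "fullerene")
  expect_equal(f$n, 20L)
  # twelve leading pentagons at n = 60 oversaturate the spiral early
  r <- windup(spiral_code(60, 1:12))
  expect_true(is_spiral_rejection(r))
  expect_error(spiral_code(20, c(1:11, 11)), "increasing")
  expect_error(spiral_code(20, 1:11), "12")
})

test_that("windup/unwind round-trips on every enumerated code up to n = 36", {
  for (n in seq(20, 36, by = 2)) {
    codes <- enumerate_isomers(n)
    for (j in seq_len(nrow(codes))) {
      f <- windup(spiral_code(n, codes[j, ]), as = "dual")
      expect_false(is_spiral_rejection(f))
      expect_identical(unwind_canonical(f)$positions, codes[j, ])
    }
  }
})

test_that("the canonical code is invariant under relabelling", {
  td <- isomer_by_index(28, 2, as = "dual")
  ref <- unwind_canonical(td)$positions
  for (s in 1:3)
    expect_identical(unwind_canonical(relabel_dual(td, s))$positions, ref)
})

test_that("enumeration matches the naive subset-scan oracle for n <= 26", {
  for (n in c(20, 24, 26)) {
    got <- enumerate_isomers(n)
    attributes(got) <- attributes(got)["dim"]
    expect_identical(got, unname(enumerate_oracle(n)))
  }
  expect_equal(nrow(enumerate_isomers(22)), 0L)
})

test_that("enumeration reproduces the known isomer counts", {
  known <- c(`20` = 1, `24` = 1, `26` = 1, `28` = 2, `30` = 3, `32` = 6,
             `34` = 6, `36` = 15, `38` = 17, `40` = 40)
  for (n in names(known))
    expect_equal(iso_count(as.integer(n)), unname(known[[n]]))
})

test_that("isomer_by_index retrieves documented isomers", {
  expect_identical(unwind_canonical(isomer_by_index(20, 1))$positions, 1:12)
  expect_error(isomer_by_index(28, 3), "fewer")
})

test_that("pentagon-vector ranking is a lexicographic bijection", {
  expect_identical(unrank_pentagon_vector(1, 60), 1:12)
  expect_identical(unrank_pentagon_vector(choose(60, 12), 60), 49:60)
  set.seed(5)
  for (i in 1:300) {
    N <- sample.int(1e7, 1)
    expect_equal(rank_pentagon_vector(unrank_pentagon_vector(N, 40), 40), N)
  }
})

test_that("rejection sampling returns valid fullerenes uniformly", {
  res <- sample_rejection(20, rng_seed = 1)
  expect_identical(res$codes[1, ], 1:12)
  res28 <- sample_rejection(28, rng_seed = 3, n_accept = 600)
  expect_equal(nrow(res28$codes), 600L)
  counts <- table(apply(res28$codes, 1, paste, collapse = " "))
  expect_length(counts, 2L)
  # every accepted code is canonical
  for (k in seq_len(2L)) {
    pos <- as.integer(strsplit(names(counts)[[k]], " ")[[1]])
    f <- windup(spiral_code(28, pos), as = "dual")
    expect_identical(unwind_canonical(f)$positions, pos)
  }
  # reproducibility
  res28b <- sample_rejection(28, rng_seed = 3, n_accept = 600)
  expect_identical(res28$codes, res28b$codes)
  expect_equal(res28$trials, res28b$trials)
})

test_that("the length-n dialect lowers the acceptance rate but not the law", {
  res <- sample_rejection(24, rng_seed = 9, n_accept = 20, dialect = "n")
  expect_equal(nrow(res$codes), 20L)
  # only one isomer exists at n = 24
  expect_equal(nrow(unique(res$codes)), 1L)
  expect_gt(res$trials, 20)
})
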