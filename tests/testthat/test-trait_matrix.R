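test_that("trait table CSV round-trips, preserving order and questionable codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",t1,t2", "g1,1,0", "g2,?,1"), path)
  tt <- read_trait_table(path)
  expect_equal(tt$group_labels, c("g1", "g2"))
  expect_equal(tt$trait_labels, c("t1", "t2"))
  expect_identical(tt$cells[1, ], c(t1 = 1L, t2 = 0L))
  expect_true(is.na(tt$cells["g2", "t1"]))
  expect_equal(sum(is.na(tt$cells)), 1)

  big <- random_trait_table(9, 82, q_prob = 0.02, seed = 11)
  out <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(big, out)
  back <- read_trait_table(out)
  expect_identical(back$cells, big$cells)
  expect_identical(back$group_labels, big$group_labels)
})

test_that("malformed trait tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",t1,t2", "g1,1,x"), path)
  expect_error(read_trait_table(path), "unmappable cell value 'x'")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(",t1,t2", empty)
  expect_error(read_trait_table(empty), "no data rows")

  expect_error(
    trait_table(matrix(0L, 2, 2), group_labels = c("a", "a"),
                trait_labels = c("t1", "t2")),
    "duplicate group labels")
  expect_error(
    trait_table(matrix(2L, 1, 1), "g", "t"), "invalid cell value")
})

test_that("jaccard_counts implements the two questionable-code policies", {
  cnt <- jaccard_counts(c(1L, 1L, 0L, 1L), c(1L, 0L, 0L, 1L))
  expect_equal(unclass(cnt)[c("a", "b", "c", "d", "n_deleted")],
               list(a = 2L, b = 1L, c = 0L, d = 1L, n_deleted = 0L))

  del <- jaccard_counts(c(1L, NA, 0L), c(1L, 1L, 1L), "pairwise_delete")
  expect_equal(unclass(del)[c("a", "b", "c", "d", "n_deleted")],
               list(a = 1L, b = 0L, c = 1L, d = 0L, n_deleted = 1L))

  rec <- jaccard_counts(c(1L, NA, 0L), c(1L, 1L, 1L), "recode_present")
  expect_equal(unclass(rec)[c("a", "b", "c", "d", "n_deleted")],
               list(a = 2L, b = 0L, c = 1L, d = 0L, n_deleted = 0L))

  expect_error(jaccard_counts(1L, c(1L, 0L)), "length")
})

test_that("jaccard counts always partition the trait set", {
  for (seed in 1:10) {
    tt <- random_trait_table(2, 40, q_prob = 0.1, seed = seed)
    cnt <- jaccard_counts(tt$cells[1, ], tt$cells[2, ])
    expect_equal(cnt$a + cnt$b + cnt$c + cnt$d + cnt$n_deleted, 40)
    expect_true(all(unlist(cnt) >= 0))
  }
})

test_that("jaccard_matrix handles identity, disjoint and formula cases", {
  tt <- trait_table(rbind(c(1L, 1L, 0L, 0L),
                          c(1L, 1L, 0L, 0L),   # identical to row 1
                          c(0L, 0L, 1L, 1L)),  # disjoint from rows 1-2
                    c("a", "b", "c"), paste0("t", 1:4))
  D <- jaccard_matrix(tt, polarity = "distance")
  expect_equal(D$values["a", "b"], 0)
  expect_equal(D$values["a", "c"], 1)
  expect_equal(diag(D$values), c(a = 0, b = 0, c = 0))

  # a=2, b=1, c=1 -> S = 0.5
  tt2 <- trait_table(rbind(c(1L, 1L, 1L, 0L),
                           c(1L, 1L, 0L, 1L)), c("x", "y"), paste0("t", 1:4))
  S <- jaccard_matrix(tt2, polarity = "similarity")
  expect_equal(S$values["x", "y"], 0.5)
  expect_equal(jaccard_matrix(tt2)$values["x", "y"], 0.5)
  expect_equal(diag(S$values), c(x = 1, y = 1))
})

test_that("jaccard_matrix errors when a pair has no scorable presences", {
  tt <- trait_table(rbind(c(0L, 0L), c(0L, 0L)), c("a", "b"), c("t1", "t2"))
  expect_error(jaccard_matrix(tt), "pair \\(a, b\\): no scorable presences")
})

test_that("jaccard matrix matches a brute-force per-pair oracle", {
  for (seed in c(3, 17)) {
    tt <- random_trait_table(9, 82, q_prob = 0.02, seed = seed)
    D <- jaccard_matrix(tt, polarity = "distance")
    for (i in 1:8) {
      for (j in (i + 1):9) {
        expect_equal(D$values[i, j],
                     brute_jaccard_distance(tt$cells[i, ], tt$cells[j, ]),
                     tolerance = 1e-12)
      }
    }
    R <- jaccard_matrix(tt, missing_policy = "recode_present")
    expect_equal(R$values[2, 7],
                 brute_jaccard_distance(tt$cells[2, ], tt$cells[7, ],
                                        recode = TRUE))
  }
})

test_that("jaccard similarity ignores joint absences and respects structure", {
  tt <- random_trait_table(6, 30, q_prob = 0, seed = 5)
  S <- jaccard_matrix(tt, polarity = "similarity")
  # augmenting with columns absent everywhere changes nothing
  aug <- trait_table(cbind(tt$cells, matrix(0L, 6, 10)),
                     tt$group_labels, paste0("t", 1:40))
  expect_equal(jaccard_matrix(aug, polarity = "similarity")$values, S$values)

  # without questionable cells the two policies agree exactly
  expect_equal(jaccard_matrix(tt, "pairwise_delete")$values,
               jaccard_matrix(tt, "recode_present")$values)

  # distances live in [0,1], are symmetric, vanish only on identical rows
  D <- jaccard_matrix(tt)
  expect_true(all(D$values >= 0 & D$values <= 1))
  expect_equal(D$values, t(D$values))

  # reordering groups commutes with matrix construction
  ord <- c(4, 2, 6, 1, 3, 5)
  ttr <- trait_table(tt$cells[ord, ], tt$group_labels[ord], tt$trait_labels)
  expect_equal(jaccard_matrix(ttr)$values, D$values[ord, ord])
})

test_that("offdiag_vector uses row-major upper-triangle order", {
  m <- pairwise_matrix(rbind(c(0, 1, 2), c(1, 0, 3), c(2, 3, 0)),
                       c("a", "b", "c"), polarity = "distance")
  v <- offdiag_vector(m)
  expect_equal(unname(v), c(1, 2, 3))
  expect_equal(names(v), c("a|b", "a|c", "b|c"))

  m9 <- random_distance_matrix(9, seed = 2)
  expect_length(offdiag_vector(m9), 36)

  # same values + same label order => same vector, regardless of provenance
  m2 <- pairwise_matrix(m9$values, m9$labels, polarity = "distance")
  expect_identical(offdiag_vector(m2), offdiag_vector(m9))
})

test_that("polarity conversion is an involution with the right diagonal", {
  D <- random_distance_matrix(5, seed = 9)
  S <- convert_polarity(D, "similarity")
  expect_equal(S$values[2, 4], 1 - D$values[2, 4])
  expect_equal(diag(S$values), rep(1, 5), ignore_attr = TRUE)
  back <- convert_polarity(S, "distance")
  expect_equal(back$values, D$values)
})

test_that("pairwise matrix CSV round-trips with its polarity sidecar", {
  m <- random_distance_matrix(6, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_matrix(m, path)
  back <- read_pairwise_matrix(path)
  expect_equal(back$values, m$values)
  expect_equal(back$polarity, "distance")
  expect_equal(back$labels, m$labels)
  # explicit polarity wins over absence of a sidecar
  plain <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(m$values), plain)
  expect_error(read_pairwise_matrix(plain), "polarity")
  expect_equal(read_pairwise_matrix(plain, "similarity")$polarity,
               "similarity")
})

test_that("pairwise_matrix validates shape, symmetry and finiteness", {
  expect_error(pairwise_matrix(matrix(1, 2, 3)), "square")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pairwise_matrix(bad, c("a", "b")), "not symmetric")
  inf <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(pairwise_matrix(inf, c("a", "b")), "finite")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(pairwise_matrix(neg, c("a", "b"), "distance"), "negative")
  expect_silent(pairwise_matrix(neg, c("a", "b"), "similarity"))
})
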