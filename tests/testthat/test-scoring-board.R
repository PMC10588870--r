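test_that("leaves snap up to the smallest containing board square", {
  b <- board_spec()
  a <- assign_cluster(L = 10, W = 20, b)         # 3.94 in, 7.87 in
  expect_equal(a$L_cell, 4.5)
  expect_equal(a$W_cell, 8.5)
  expect_identical(a$key, "4.5x8.5")
  # a value exactly on a grid line belongs to that line's cell
  onln <- assign_cluster(3.5 * 2.54, 3.5 * 2.54, b)
  expect_equal(c(onln$L_cell, onln$W_cell), c(3.5, 3.5))
  # below the smallest square maps to it
  expect_equal(assign_cluster(2, 2, b)$L_cell, 3.5)
  # beyond the largest square is a flagged overflow cell
  ov <- assign_cluster(50, 10, b)                 # 19.7 in
  expect_true(ov$overflow)
  expect_match(ov$key, ">15.5")
  expect_error(assign_cluster(-1, 5, b), "positive")
})

test_that("clustering partitions the plant's leaves", {
  rec <- make_records(L = c(10, 10, 10, 18, 25, 30),
                      W = c(20, 20, 20, 22, 31, 33))
  cl <- group_leaves(rec)
  expect_s3_class(cl, "leaf_clusters")
  expect_identical(sum(cl$LN), nrow(rec))
  expect_identical(sort(unname(unlist(cl$member_ids))), sort(rec$leaf_id))
  # identical leaves share one cluster
  expect_identical(cl$LN[cl$key == "4.5x8.5"], 3L)
  # distinct cells give distinct clusters
  keys <- assign_cluster(rec$L, rec$W, board_spec())$key
  expect_identical(nrow(cl), length(unique(keys)))
  expect_error(group_leaves(rec[0, ]), "no leaves")
  expect_error(group_leaves(rbind(rec, make_records(5, 5, plant_id = "p2"))),
               "single plant")
})

test_that("a field-sized population occupies at least as many cells as its representatives", {
  pop <- generate_population(209, l_range = c(10.47, 29.26),
                             w_range = c(13.08, 40.58), seed = 41)
  cl <- group_leaves(pop, board_spec(max_cell = 23.5))
  expect_gte(nrow(cl), 13)  # 13 representatives imply >= 13 occupied cells
})

test_that("representative sampling is seeded, clipped and averaged", {
  rec <- make_records(L = rep(10, 10), W = rep(20, 10), LA = 1:10 * 10)
  cl <- group_leaves(rec)
  expect_identical(nrow(cl), 1L)
  # k clipped to cluster size
  one <- select_representatives(group_leaves(rec[1, ]), k = 2, seed = 1)
  expect_identical(one$rep_ids[[1]], rec$leaf_id[1])
  # identical selection under a fixed seed
  s1 <- select_representatives(cl, k = 2, seed = 42)
  s2 <- select_representatives(cl, k = 2, seed = 42)
  expect_identical(s1$rep_ids, s2$rep_ids)
  # representative area is the mean over the representatives
  cl2 <- group_leaves(rec[1:2, ])
  cl2 <- select_representatives(cl2, k = 2, seed = 1)
  cl2 <- set_representative_area(cl2, rec[1:2, ])
  expect_equal(cl2$la_rep, 15)
})

test_that("per-plant totals follow the cluster sum", {
  rec <- make_records(L = c(10, 30), W = c(20, 33), LA = c(100, 10))
  cl <- group_leaves(rec)
  cl$la_rep <- c(100, 10)[match(cl$key, assign_cluster(rec$L, rec$W,
                                                       board_spec())$key)]
  cl$LN <- c(10L, 2L)[match(cl$key, assign_cluster(rec$L, rec$W,
                                                   board_spec())$key)]
  tot <- total_leaf_area(cl)
  expect_equal(tot$total_la_cm2, 100 * 10 + 10 * 2)
  expect_equal(tot$total_la_m2, tot$total_la_cm2 / 1e4)
  cl$la_rep[1] <- NA
  expect_error(total_leaf_area(cl), "la_rep")
})

test_that("the cluster total is the exact sum in the singleton limit", {
  pop <- generate_population(40, noise_sd = 0.1, seed = 17)
  # k larger than any cluster: every member is a representative, so
  # la_rep * LN telescopes to the exact per-leaf sum
  est <- estimate_total_la(pop, board = board_spec(max_cell = 23.5),
                           mode = "photo", k = 1000, seed = 1)
  expect_equal(est$total_la_cm2, sum(pop$LA), tolerance = 1e-12)
})

test_that("totals are monotone in representative area and leaf count", {
  rec <- make_records(L = c(10, 18), W = c(20, 25), LA = c(50, 120))
  cl <- group_leaves(rec)
  cl <- set_representative_area(select_representatives(cl, 2, seed = 1), rec)
  base <- total_leaf_area(cl)$total_la_cm2
  up <- cl; up$la_rep[1] <- up$la_rep[1] + 5
  expect_gt(total_leaf_area(up)$total_la_cm2, base)
  up2 <- cl; up2$LN[2] <- up2$LN[2] + 1L
  expect_gt(total_leaf_area(up2)$total_la_cm2, base)
})

test_that("board refinement never worsens the cell-based hybrid total", {
  mdl <- builtin_model("model4")
  for (s in 1:5) {
    pop <- generate_population(60, noise_sd = 0, seed = 300 + s)
    exact <- sum(pop$LA)
    errs <- vapply(c(1, 0.5, 0.25), function(st) {
      b <- board_spec(min_cell = 3.5, max_cell = 23.5, step = st)
      abs(estimate_total_la(pop, board = b, mode = "hybrid", model = mdl,
                            hybrid_from = "cells", seed = 1)$total_la_cm2 -
            exact)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-9))
  }
})
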