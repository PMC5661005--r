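seg_create <- columnet:::seg_create
seg_all_perms <- columnet:::seg_all_perms

test_that("a full-sampling basal segment predicts through 40% location noise but not 50%", {
  il <- input_layer()  # full-size geometry, theta_basal = 6
  loc <- random_sdr(2400, 10, rng_stream(2))
  seg_create(il$basal, cell = 17L, bits = loc$active, perm0 = 0.6)

  il_predict(il, loc)
  expect_identical(il$predicted, 17L)

  r <- rng_stream(9)
  il_predict(il, sdr_corrupt(loc, 0.4, r))  # 6 surviving bits >= 6
  expect_identical(il$predicted, 17L)
  il_predict(il, sdr_corrupt(loc, 0.5, r))  # 5 surviving bits < 6
  expect_length(il$predicted, 0)

  # no segments anywhere else -> nothing predicted for a fresh location
  il_predict(il, random_sdr(2400, 10, r))
  expect_length(il$predicted, 0)
  expect_error(il_predict(il, sdr(10, 1)), "size")
})

test_that("predictive state matches a brute-force segment re-scan", {
  il <- input_layer(n_in = 5, m = 4, s_in = 2, n_ext = 60,
                    theta_basal = 3, theta_basal_apical = 2)
  r <- rng_stream(4)
  # random segments with mixed permanences over a tiny cell population
  for (i in 1:30) {
    cell <- with_rng(r, sample.int(20, 1))
    bits <- with_rng(r, sample.int(60, 6))
    seg_create(il$basal, cell, bits, 0.1)
    il$basal$perm[[il$basal$n_seg]] <-
      with_rng(r, runif(6))  # not index-consistent yet
  }
  # rebuild the store from its own snapshot so the index matches the perms
  il$basal <- columnet:::seg_store_from_list(
    columnet:::seg_store_to_list(il$basal))
  for (trial in 1:25) {
    loc <- random_sdr(60, 8, r)
    il_predict(il, loc)
    expect_setequal(
      il$predicted,
      brute_active_cells(il$basal, loc$active, il$theta_basal))
  }
})

test_that("winner minicolumns activate predicted cells, burst when surprised", {
  il <- input_layer(n_in = 6, m = 4, s_in = 3, n_ext = 60, theta_basal = 3)
  loc <- sdr(60, 1:6)
  # minicolumn 1 (cells 1:4): one predicted cell; minicolumn 2: none
  seg_create(il$basal, 2L, 1:6, 0.6)
  il_predict(il, loc)
  il_activate(il, c(1L, 2L))
  expect_identical(sort(il$active), c(2L, 5L, 6L, 7L, 8L))
  expect_identical(il$burst_cols, 2L)
})

test_that("apical support lowers the basal threshold and wins activation ties", {
  il <- input_layer(n_in = 4, m = 4, s_in = 2, n_ext = 60, n_out = 50,
                    theta_basal = 4, theta_basal_apical = 2,
                    theta_apical = 3)
  loc <- sdr(60, 1:4)
  # cells 1, 2, 3 in minicolumn 1; cell 3 has apical feedback support
  seg_create(il$basal, 1L, 1:4, 0.6)      # meets theta_basal
  seg_create(il$basal, 2L, 1:4, 0.6)      # meets theta_basal
  seg_create(il$basal, 3L, c(1, 2, 30), 0.6)  # only 2 bits: needs apical
  seg_create(il$apical, 3L, c(5, 6, 7, 8), 0.6)

  il_predict(il, loc, feedback = c(5L, 6L, 7L))
  expect_setequal(il$predicted, c(1L, 2L, 3L))
  il_activate(il, 1L)
  expect_identical(il$active, 3L)             # feedback tie-break
  expect_setequal(il$losers, c(1L, 2L))

  # without feedback the sub-threshold cell is not predicted
  il_predict(il, loc)
  expect_setequal(il$predicted, c(1L, 2L))
  il_activate(il, 1L)
  expect_setequal(il$active, c(1L, 2L))
})

test_that("a learned pair is re-coded by exactly one cell per minicolumn", {
  net <- small_net(seed = 2)
  lib <- small_library(3, seed = 6)
  rng <- rng_stream(11)
  for (oid in 1:3) net_train_object(net, lib, oid, rng)
  il <- net$columns[[1]]$il
  for (oid in 1:3) {
    obj <- lib$objects[[oid]]
    for (p in seq_along(obj$slots)) {
      il_predict(il, lib$location_pool[[obj$slots[p]]])
      il_activate(il, lib$feature_pool[[obj$feats[p]]]$active)
      expect_length(il$burst_cols, 0)
      expect_length(il$active, il$s_in)   # one winner per minicolumn
      expect_identical(
        as.integer(table(columnet:::il_col_of_cell(il, il$active))),
        rep(1L, il$s_in))
    }
  }
})

test_that("burst learning grows one full-sampling segment; re-presentation reinforces it", {
  il <- input_layer(n_in = 6, m = 4, s_in = 3, n_ext = 60, theta_basal = 3)
  loc <- sdr(60, c(3, 9, 15, 21, 27))
  r <- rng_stream(1)
  il_predict(il, loc)
  il_activate(il, c(1L, 4L))
  il_learn_basal(il, loc, r)
  expect_length(il$winners, 2)
  expect_identical(il$basal$n_seg, 2L)
  for (i in 1:2) {
    expect_setequal(il$basal$syn[[i]], loc$active)
    expect_true(all(il$basal$perm[[i]] == 0.6))  # connected at birth
  }

  # second exposure: predicted, no new segment, permanences rise
  il_predict(il, loc)
  il_activate(il, c(1L, 4L))
  expect_length(il$burst_cols, 0)
  il_learn_basal(il, loc, r)
  expect_identical(il$basal$n_seg, 2L)
  expect_true(all(seg_all_perms(il$basal) == 0.7))
})

test_that("segments predicting a losing cell are punished on their active synapses", {
  il <- input_layer(n_in = 4, m = 4, s_in = 2, n_ext = 60, n_out = 50,
                    theta_basal = 4, theta_basal_apical = 2,
                    theta_apical = 3, p_punish = 0.002)
  loc <- sdr(60, 1:4)
  seg_create(il$basal, 1L, 1:4, 0.6)
  seg_create(il$basal, 3L, 1:4, 0.6)
  seg_create(il$apical, 3L, c(5, 6, 7), 0.6)
  il_predict(il, loc, feedback = c(5L, 6L, 7L))
  il_activate(il, 1L)
  expect_identical(il$active, 3L)
  il_learn_basal(il, loc, rng_stream(2))
  expect_true(all(il$basal$perm[[1]] == 0.6 - 0.002))  # loser punished
  expect_true(all(il$basal$perm[[2]] == 0.7))          # winner reinforced
})

test_that("apical learning samples the output code once and then reinforces", {
  il <- input_layer(n_in = 6, m = 4, s_in = 2, n_ext = 60, n_out = 100,
                    theta_basal = 3)
  loc <- sdr(60, 1:5)
  code <- as.integer(c(4, 9, 23, 42, 77, 90))
  r <- rng_stream(3)
  il_predict(il, loc); il_activate(il, 1L); il_learn_basal(il, loc, r)
  il_learn_apical(il, code)
  expect_identical(il$apical$n_seg, 1L)
  expect_setequal(il$apical$syn[[1]], code)

  il_predict(il, loc); il_activate(il, 1L); il_learn_basal(il, loc, r)
  il_learn_apical(il, code)
  expect_identical(il$apical$n_seg, 1L)     # matched, not duplicated
  expect_true(all(il$apical$perm[[1]] == 0.7))

  il_learn_apical(il, integer(0))           # empty feedback: no-op
  expect_identical(il$apical$n_seg, 1L)
})

test_that("permanences stay within [0, 1] under arbitrary training schedules", {
  net <- small_net(seed = 4)
  lib <- small_library(6, seed = 9)
  rng <- rng_stream(13)
  for (rep in 1:2) {
    for (oid in 1:6) net_train_object(net, lib, oid, rng)
  }
  il <- net$columns[[1]]$il; ol <- net$columns[[1]]$ol
  for (st in list(il$basal, il$apical, ol$lateral)) {
    pm <- seg_all_perms(st)
    expect_true(all(pm >= 0 & pm <= 1))
  }
  prox_pm <- unlist(lapply(seq_len(ol$n_out), function(k)
    ol_proximal(ol, k)$perms))
  expect_true(all(prox_pm >= 0 & prox_pm <= 1))
})
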