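seg_create <- columnet:::seg_create

# output layer with deterministic, empty-ish initial connectivity helpers
bare_ol <- function(n_out = 100L, s_out = 5L, theta_proximal = 3L,
                    theta_lateral = 4L, n_in_cells = 60L, seed = 1L,
                    n_columns = 1L, col = 1L) {
  output_layer(n_out = n_out, s_out = s_out, n_in_cells = n_in_cells,
               n_columns = n_columns, col = col,
               theta_proximal = theta_proximal,
               theta_lateral = theta_lateral,
               init_frac = 0, rng = rng_stream(seed))
}

set_prox <- function(ol, cell, rows, perms) {
  ol$prox[[as.character(cell)]] <- list(rows = as.integer(rows),
                                        perms = perms)
  for (r in rows[perms >= ol$connected_perm]) {
    key <- as.character(r)
    ol$prox_conn[[key]] <- c(ol$prox_conn[[key]], cell)
  }
}

test_that("feedforward overlap counts connected synapses onto active input cells", {
  ol <- bare_ol()
  a_in <- as.integer(c(2, 5, 8, 11, 14, 17, 20, 23, 26, 29))
  set_prox(ol, 7L, a_in, rep(0.6, 10))            # fully connected
  set_prox(ol, 8L, a_in, rep(0.3, 10))            # below threshold
  set_prox(ol, 9L, c(a_in[1:4], 31L, 32L), rep(0.6, 6))
  o <- ol_feedforward(ol, a_in)
  expect_identical(o[7], 10L)
  expect_identical(o[8], 0L)
  expect_identical(o[9], 4L)
  expect_identical(o[10], 0L)                     # no synapses at all
  expect_identical(ol_feedforward(ol, integer(0)), integer(100))
  expect_error(ol_feedforward(ol, 1000L), "input layer size")
})

test_that("activation after reset is the union of feedforward candidates", {
  ol <- bare_ol()
  a_in <- as.integer(1:10)
  for (k in c(3L, 14L, 25L)) set_prox(ol, k, a_in, rep(0.6, 10))
  set_prox(ol, 30L, 1:2, rep(0.6, 2))             # below count threshold
  act <- ol_select_active(ol, ol_feedforward(ol, a_in),
                          prev_abar = integer(0))
  expect_setequal(act, c(3L, 14L, 25L))
})

test_that("the lateral vote keeps supported cells and drops unsupported ones", {
  ol <- bare_ol(s_out = 3L)
  a_in <- as.integer(1:10)
  supported <- c(3L, 14L, 25L); unsupported <- c(40L, 41L, 42L)
  for (k in c(supported, unsupported)) set_prox(ol, k, a_in, rep(0.6, 10))
  prev <- as.integer(60:70)
  for (k in supported) seg_create(ol$lateral, k, prev[1:6], 0.6, src = 1L)
  act <- ol_select_active(ol, ol_feedforward(ol, a_in), prev)
  expect_setequal(act, supported)

  # fewer than s_out supported cells -> cutoff zero, everything passes
  ol2 <- bare_ol(s_out = 5L)
  for (k in c(supported, unsupported)) set_prox(ol2, k, a_in, rep(0.6, 10))
  for (k in supported) seg_create(ol2$lateral, k, prev[1:6], 0.6, src = 1L)
  act2 <- ol_select_active(ol2, ol_feedforward(ol2, a_in), prev)
  expect_setequal(act2, c(supported, unsupported))
})

test_that("select_active matches a brute-force rescore on random instances", {
  r <- rng_stream(21)
  ol <- bare_ol(n_out = 80L, s_out = 4L, theta_proximal = 2L,
                theta_lateral = 3L)
  for (k in seq_len(80)) {
    rows <- with_rng(r, sample.int(60, 8))
    set_prox(ol, k, rows, with_rng(r, runif(8)))
  }
  for (i in 1:40) {
    cell <- with_rng(r, sample.int(80, 1))
    bits <- with_rng(r, sample.int(80, 6))
    seg_create(ol$lateral, cell, bits, with_rng(r, runif(1)), src = 1L)
  }
  ol$lateral <- columnet:::seg_store_from_list(
    columnet:::seg_store_to_list(ol$lateral))
  for (trial in 1:25) {
    a_in <- with_rng(r, sample.int(60, 10))
    prev <- with_rng(r, sample.int(80, 15))
    act <- ol_select_active(ol, ol_feedforward(ol, a_in), prev)
    expect_identical(sort(act), brute_select_active(ol, a_in, prev))
  }
})

test_that("proximal learning grows at most s_in connected synapses per clamped cell", {
  ol <- bare_ol()
  clamped <- as.integer(c(5, 6, 7))
  a_in <- as.integer(seq(3, 30, by = 3))
  other <- as.integer(c(50, 51))              # another pair's synapses
  set_prox(ol, 5L, other, rep(0.6, 2))
  ol_learn_proximal(ol, a_in, clamped)
  for (k in clamped) {
    p <- ol_proximal(ol, k)
    expect_setequal(setdiff(p$rows, other), a_in)
    expect_true(all(p$perms[match(a_in, p$rows)] == 0.6))
  }
  untouched <- ol_proximal(ol, 9L)            # inactive cells untouched
  expect_length(untouched$rows, 0)

  # re-sensation reinforces; the other pair's synapses decay
  ol_learn_proximal(ol, a_in, clamped)
  p <- ol_proximal(ol, 5L)
  expect_true(all(p$perms[match(a_in, p$rows)] == 0.7))
  expect_true(all(p$perms[match(other, p$rows)] == 0.6 - 2 * ol$p_ff_minus))
})

test_that("lateral learning keeps one single-source segment per column, self excluded", {
  ol <- bare_ol(n_columns = 1L)
  code <- as.integer(c(5, 9, 13, 17, 21, 25))
  ol_learn_lateral(ol, list(code))
  st <- ol$lateral
  expect_identical(st$n_seg, length(code))
  for (i in seq_len(st$n_seg)) {
    expect_setequal(st$syn[[i]], setdiff(code, st$cell[i]))  # no self
    expect_identical(st$src[i], 1L)
  }

  # three columns: one segment per source column on every active cell
  ols <- lapply(1:3, function(c)
    bare_ol(n_columns = 3L, col = c, seed = c))
  codes <- lapply(1:3, function(c) as.integer(c * 10 + 1:5))
  for (c in 1:3) ol_learn_lateral(ols[[c]], codes)
  for (c in 1:3) {
    st <- ols[[c]]$lateral
    expect_identical(st$n_seg, 15L)  # 5 cells x 3 sources
    for (i in seq_len(st$n_seg)) {
      src <- st$src[i]
      lo <- (src - 1L) * ols[[c]]$n_out
      expect_true(all(st$syn[[i]] > lo & st$syn[[i]] <= lo + ols[[c]]$n_out))
    }
  }
})

test_that("lateral single-source constraint survives training a whole library", {
  net <- small_net(num_columns = 2L, seed = 3)
  lib <- small_library(5, seed = 2)
  rng <- rng_stream(17)
  for (oid in 1:5) net_train_object(net, lib, oid, rng)
  for (c in 1:2) {
    st <- net$columns[[c]]$ol$lateral
    n_out <- net$columns[[c]]$ol$n_out
    for (i in seq_len(st$n_seg)) {
      src_of_syn <- (st$syn[[i]] - 1L) %/% n_out + 1L
      expect_identical(unique(src_of_syn), st$src[i])
      gcell <- (c - 1L) * n_out + st$cell[i]
      expect_false(gcell %in% st$syn[[i]])
    }
  }
})

test_that("new object codes have s_out cells and low mutual overlap", {
  ol <- output_layer(n_out = 512L, s_out = 10L, n_in_cells = 60L,
                     rng = rng_stream(5))
  r <- rng_stream(31)
  codes <- lapply(1:20, function(i)
    ol_select_new_code(ol, with_rng(r, sample.int(60, 10)), r))
  for (cd in codes) expect_length(cd, 10)
  ov <- utils::combn(20, 2, function(ij)
    length(intersect(codes[[ij[1]]], codes[[ij[2]]])))
  expect_lt(max(ov), 8)
})
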