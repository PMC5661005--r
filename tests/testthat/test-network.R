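# Build the two-object (cube/wedge style) demo world on the full-size
# geometry and train a single column on both objects.
trained_demo <- function(seed = 3) {
  lib <- demo_shared_feature_library(rng_stream(seed))
  net <- cortical_network(num_columns = 1, seed = seed)
  rng <- rng_stream(seed + 100)
  net_train_object(net, lib, 1, rng)
  net_train_object(net, lib, 2, rng)
  list(net = net, lib = lib)
}

demo_stream <- function(lib, object_id, positions) {
  obj <- lib$objects[[object_id]]
  lapply(positions, function(p) list(list(
    slot = obj$slots[p], feat = obj$feats[p],
    location = lib$location_pool[[obj$slots[p]]],
    feature = lib$feature_pool[[obj$feats[p]]])))
}

test_that("shared-feature inference follows union, narrowing, persistence exactly", {
  d <- trained_demo()
  code1 <- net_stored_code(d$net, 1)[[1]]
  code2 <- net_stored_code(d$net, 2)[[1]]

  # touch the shared pair, then the distinctive pair, then the other
  # shared pair of object 1
  res <- net_infer(d$net, demo_stream(d$lib, 1, c(1, 2, 3)))
  expect_identical(sort(res$active[[1]][[1]]), sort(union(code1, code2)))
  expect_identical(sort(res$active[[2]][[1]]), sort(code1))
  expect_identical(sort(res$active[[3]][[1]]), sort(code1))
  expect_identical(res$classification, c(NA_integer_, 1L, 1L))

  # and symmetrically for object 2
  res2 <- net_infer(d$net, demo_stream(d$lib, 2, c(1, 2, 3)))
  expect_identical(sort(res2$active[[1]][[1]]), sort(union(code1, code2)))
  expect_identical(res2$classification[2:3], c(2L, 2L))
})

test_that("output activity narrows monotonically on noise-free streams", {
  # full-size column so chance feedforward candidates are impossible
  net <- cortical_network(num_columns = 1, seed = 8)
  lib <- generate_library(6, feature_pool_size = 4, rng = rng_stream(5))
  rng <- rng_stream(2)
  for (oid in 1:6) net_train_object(net, lib, oid, rng)
  for (oid in c(1, 4, 6)) {
    st <- sensation_stream(lib, oid, 8, 1, rng)
    res <- net_infer(net, st)
    expect_true(all(diff(res$n_active[, 1]) <= 0))
  }
})

test_that("reset clears activity but never touches synapses; reset is idempotent", {
  d <- trained_demo()
  net <- d$net
  perms_before <- columnet:::seg_all_perms(net$columns[[1]]$il$basal)
  net_infer(net, demo_stream(d$lib, 1, c(1, 2)))
  net_reset(net)
  expect_length(net$columns[[1]]$ol$active, 0)
  expect_length(net$prev_abar, 0)
  snap <- columnet:::seg_store_to_list(net$columns[[1]]$il$basal)
  net_reset(net)
  expect_identical(columnet:::seg_store_to_list(net$columns[[1]]$il$basal),
                   snap)
  expect_identical(columnet:::seg_all_perms(net$columns[[1]]$il$basal),
                   perms_before)
})

test_that("classification demands a unique above-threshold match in every column", {
  d <- trained_demo()
  net <- d$net
  code1 <- net_stored_code(net, 1)[[1]]
  code2 <- net_stored_code(net, 2)[[1]]
  expect_identical(net_classify(net, list(code1)), 1L)
  expect_identical(net_classify(net, list(code2)), 2L)
  expect_identical(net_classify(net, list(union(code1, code2))),
                   NA_integer_)  # both above threshold
  expect_identical(net_classify(net, list(integer(0))), NA_integer_)
  expect_identical(net_classify(net, list(code1[1:10])), NA_integer_)
})

test_that("a single-object world is recognized at the first sensation", {
  net <- small_net(seed = 12)
  lib <- small_library(1, seed = 3)
  rng <- rng_stream(4)
  net_train_object(net, lib, 1, rng)
  st <- sensation_stream(lib, 1, 3, 1, rng)
  res <- net_infer(net, st)
  expect_identical(res$classification[1], 1L)
})

test_that("trained objects are recognized within the test budget end to end", {
  net <- small_net(seed = 21)
  lib <- small_library(8, feature_pool_size = 6, seed = 7)
  net_train_library(net, lib, rng_stream(5))
  rng <- rng_stream(6)
  firsts <- vapply(1:8, function(oid)
    as.integer(first_recognition(net, lib, oid, 12, rng)), 0L)
  expect_false(anyNA(firsts))
  expect_true(all(firsts <= 12))
})

test_that("identical seeds give identical activity traces; different seeds differ", {
  run_trace <- function(seed) {
    net <- small_net(seed = seed)
    lib <- small_library(4, seed = seed + 1)
    net_train_library(net, lib, rng_stream(seed + 2))
    res <- net_infer(net, sensation_stream(lib, 2, 6, 1,
                                           rng_stream(seed + 3)))
    res$active
  }
  expect_identical(run_trace(5), run_trace(5))
  expect_false(identical(run_trace(5), run_trace(6)))
})

test_that("stored codes for distinct objects stay far below the confusion threshold", {
  net <- small_net(seed = 9)
  lib <- small_library(8, seed = 4)
  expect_silent(net_train_library(net, lib, rng_stream(3)))  # no collisions
  codes <- lapply(1:8, function(o) net_stored_code(net, o)[[1]])
  ov <- utils::combn(8, 2, function(ij)
    length(intersect(codes[[ij[1]]], codes[[ij[2]]])))
  expect_true(all(ov < net$classify_threshold))
})

test_that("multi-column networks converge at least as fast as one column", {
  # paired seeds: same world, same experiment seed, only the column count
  # changes; full-size columns on a small, heavily shared world
  firsts <- function(num_columns, seed) {
    lib <- generate_library(10, feature_pool_size = 5,
                            rng = rng_stream(seed))
    net <- cortical_network(num_columns = num_columns, seed = seed)
    net_train_library(net, lib, rng_stream(seed + 50))
    rng <- rng_stream(seed + 90)
    mean(vapply(1:10, function(oid) {
      f <- first_recognition(net, lib, oid, 12, rng)
      as.numeric(if (is.na(f)) 13L else f)
    }, 0))
  }
  m1 <- mean(vapply(1:2, function(s) firsts(1L, s), 0))
  m3 <- mean(vapply(1:2, function(s) firsts(3L, s), 0))
  expect_lte(m3, m1)
})

test_that("sensation streams with the wrong column count are rejected", {
  d <- trained_demo()
  st <- sensation_stream(d$lib, 1, 2, 2, rng_stream(1))
  expect_error(net_infer(d$net, st), "column count")
})

test_that("a checkpointed network restores to identical inference behavior", {
  net <- small_net(seed = 33)
  lib <- small_library(4, seed = 8)
  net_train_library(net, lib, rng_stream(21))
  path <- tempfile(fileext = ".json")
  net_checkpoint(net, path)
  back <- net_restore(path)

  for (oid in 1:4) {
    expect_identical(net_stored_code(back, oid), net_stored_code(net, oid))
  }
  st <- sensation_stream(lib, 2, 6, 1, rng_stream(77))
  r1 <- net_infer(net, st)
  r2 <- net_infer(back, st)
  expect_identical(r2$active, r1$active)
  expect_identical(r2$classification, r1$classification)
})
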