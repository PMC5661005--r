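#' Seeded simulation experiments
#'
#' The three simulation studies — convergence speed, object capacity, and
#' noise robustness — plus the ideal-observer comparison, packaged as
#' reproducible runs. Every experiment takes one integer seed; independent
#' child streams (library generation, network initialization, training
#' order, sensation order, noise injection) are derived from it with
#' [derive_seed()], so a result is a pure function of its configuration
#' and seed. Results are returned as an `experiment_result`: a plain
#' per-observation data frame (`records`) plus the echoed configuration;
#' aggregates are always recomputed from the records by
#' [result_aggregate()].
#'
#' @name experiments
NULL

new_result <- function(name, records, config) {
  structure(list(experiment = name, records = records, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: %d records\n",
              x$experiment, nrow(x$records)))
  invisible(x)
}

#' Aggregate an experiment's per-object records
#'
#' Groups the raw records and recomputes mean sensations-to-recognition and
#' recognition accuracy. This is the only aggregation path: stored
#' summaries do not exist, so aggregates are reproducible from the records
#' by construction.
#'
#' @param result An `experiment_result`.
#' @param by Character vector of grouping columns (default: all
#'   configuration-like columns present).
#' @return A data frame with columns `n`, `accuracy` and
#'   `mean_sensations` (mean first correct sensation among recognized
#'   objects) per group.
#' @export
result_aggregate <- function(result,
                             by = intersect(
                               c("num_objects", "feature_pool_size",
                                 "num_columns", "n_in", "n_out", "channel",
                                 "noise", "model", "seed"),
                               names(result$records))) {
  rec <- result$records
  if (length(by) == 0L) by <- NULL
  groups <- if (is.null(by)) list(rep.int(1L, nrow(rec))) else rec[by]
  agg <- aggregate(
    rec[c("recognized", "first_correct")],
    by = groups,
    FUN = function(x) mean(x, na.rm = TRUE)
  )
  cnt <- aggregate(list(n = rec$recognized), by = groups, FUN = length)
  agg$n <- cnt$n
  names(agg)[names(agg) == "recognized"] <- "accuracy"
  names(agg)[names(agg) == "first_correct"] <- "mean_sensations"
  agg
}

# Train a fresh network on `object_ids` of `library` and test each object
# with a K-sensation stream (optionally corrupted); one record per object.
test_trained_network <- function(net, library, object_ids, K, seed,
                                 noise = 0, channel = c("none", "sensory",
                                                        "location")) {
  channel <- match.arg(channel)
  srng <- rng_stream(derive_seed(seed, "sensation-order"))
  nrng <- rng_stream(derive_seed(seed, "noise"))
  out <- lapply(object_ids, function(oid) {
    st <- sensation_stream(library, oid, K, net$num_columns, srng)
    if (channel != "none" && noise > 0) {
      st <- lapply(st, function(sens) lapply(sens, function(e) {
        if (channel == "sensory") {
          e$feature <- sdr_corrupt(e$feature, noise, nrng)
        } else {
          e$location <- sdr_corrupt(e$location, noise, nrng)
        }
        e
      }))
    }
    res <- net_infer(net, st)
    first <- which(res$classification == oid)[1L]
    # diagnostic: once recognized, did the classification hold to the end?
    persisted <- !is.na(first) &&
      all(res$classification[first:length(st)] == oid, na.rm = FALSE)
    data.frame(object_id = oid,
               first_correct = if (is.na(first)) NA_integer_ else first,
               recognized = !is.na(first),
               persisted = persisted)
  })
  do.call(rbind, out)
}

build_network <- function(seed, num_columns, ...) {
  cortical_network(num_columns = num_columns, ...,
                   seed = derive_seed(seed, "network-init"))
}

# Library whose code geometry matches the network arguments in `dots`
# (feature codes live on the minicolumn space; their sparsity is the
# winner-minicolumn count s_in).
exp_library <- function(num_objects, feature_pool_size, seed, dots) {
  generate_library(
    num_objects, feature_pool_size = feature_pool_size,
    rng = rng_stream(derive_seed(seed, "library")),
    n_in = if (is.null(dots$n_in)) 150L else dots$n_in,
    n_ext = if (is.null(dots$n_ext)) 2400L else dots$n_ext,
    bits_active = if (is.null(dots$s_in)) 10L else dots$s_in)
}

#' Convergence experiment: sensations needed to recognize an object
#'
#' Trains a network on a library and records, for every tested object, the
#' first sensation at which it is unambiguously recognized. Sweeping the
#' object count, feature pool size, or column count reproduces the three
#' convergence findings: recognition needs more sensations with more stored
#' objects, fewer with a richer feature pool, and far fewer with more
#' columns.
#'
#' @param num_objects Library size (objects are 10 features over 10 shared
#'   location slots by default).
#' @param feature_pool_size Distinct features objects draw from.
#' @param num_columns Cortical columns.
#' @param K Test sensations per object (default 20).
#' @param seed Integer experiment seed.
#' @param n_test_objects Number of objects tested (default: all).
#' @param ... Further arguments to [cortical_network()] (e.g. scaled-down
#'   layer sizes).
#' @return An `experiment_result`.
#' @export
run_convergence <- function(num_objects = 100L, feature_pool_size = 10L,
                            num_columns = 1L, K = 20L, seed = 1L,
                            n_test_objects = num_objects, ...) {
  lib <- exp_library(num_objects, feature_pool_size, seed, list(...))
  net <- build_network(seed, num_columns, ...)
  net_train_library(net, lib, rng_stream(derive_seed(seed, "training")))
  test_ids <- seq_len(min(n_test_objects, num_objects))
  rec <- test_trained_network(net, lib, test_ids, K, seed)
  rec$num_objects <- num_objects
  rec$feature_pool_size <- feature_pool_size
  rec$num_columns <- num_columns
  rec$seed <- seed
  new_result("convergence", rec,
             list(num_objects = num_objects,
                  feature_pool_size = feature_pool_size,
                  num_columns = num_columns, K = K, seed = seed))
}

#' Capacity experiment: recognition accuracy versus stored objects
#'
#' Trains one network incrementally on a growing set of objects drawn from
#' a large feature pool (default 5,000 features, so feature/location pairs
#' are rarely shared) and measures recognition accuracy over all trained
#' objects at each checkpoint with short test streams (K = 3). Accuracy
#' stays perfect up to the column's pooling capacity and degrades beyond
#' it; capacity grows with minicolumn count and output-layer size.
#'
#' @param object_counts Increasing checkpoints at which accuracy is
#'   measured (the network keeps training between checkpoints).
#' @param feature_pool_size Feature pool (default 5,000).
#' @param num_columns Cortical columns.
#' @param K Test sensations (default 3).
#' @param seed Integer experiment seed.
#' @param n_test_objects Cap on tested objects per checkpoint (default:
#'   all trained).
#' @param ... Further arguments to [cortical_network()].
#' @return An `experiment_result` with one record per (checkpoint, object).
#' @export
run_capacity <- function(object_counts = c(100L, 200L, 300L, 400L),
                         feature_pool_size = 5000L, num_columns = 1L,
                         K = 3L, seed = 1L,
                         n_test_objects = Inf, ...) {
  object_counts <- sort(as.integer(object_counts))
  total <- max(object_counts)
  lib <- exp_library(total, feature_pool_size, seed, list(...))
  net <- build_network(seed, num_columns, ...)
  trng <- rng_stream(derive_seed(seed, "training"))
  order_ids <- with_rng(trng, sample.int(total))
  trained <- 0L
  out <- list()
  for (ckpt in object_counts) {
    while (trained < ckpt) {
      trained <- trained + 1L
      net_train_object(net, lib, order_ids[trained], trng)
    }
    ids <- order_ids[seq_len(trained)]
    if (is.finite(n_test_objects) && n_test_objects < length(ids)) {
      ids <- with_rng(trng, sample(ids, n_test_objects))
    }
    rec <- test_trained_network(net, lib, ids, K,
                                derive_seed(seed, paste0("test", ckpt)))
    rec$num_objects <- ckpt
    rec$seed <- seed
    out[[as.character(ckpt)]] <- rec
  }
  rec <- do.call(rbind, out)
  rec$num_columns <- num_columns
  new_result("capacity", rec,
             list(object_counts = object_counts,
                  feature_pool_size = feature_pool_size,
                  num_columns = num_columns, K = K, seed = seed))
}

#' Noise robustness experiment
#'
#' Trains a single-column network, then corrupts either the sensory or the
#' location input independently at every sensation ([sdr_corrupt()]:
#' a fraction of active bits flipped off and replaced, sparsity preserved)
#' and measures recognition accuracy within `K` touches across a noise
#' grid. Sensory noise removes feedforward evidence directly; location
#' noise erodes the basal context match, which tolerates up to 4 of 10
#' flipped bits before minicolumns burst.
#'
#' @param noise_levels Noise grid (default 0 to 0.6 in steps of 0.1).
#' @param channels Input channels to corrupt (`"sensory"`, `"location"`).
#' @param num_objects Library size (default 30).
#' @param feature_pool_size Feature pool (default 100).
#' @param K Sensations per test (default 30).
#' @param seed Integer experiment seed.
#' @param n_test_objects Objects tested per noise level (default: all).
#' @param ... Further arguments to [cortical_network()].
#' @return An `experiment_result` with records per (channel, noise,
#'   object).
#' @export
run_noise <- function(noise_levels = seq(0, 0.6, by = 0.1),
                      channels = c("sensory", "location"),
                      num_objects = 30L, feature_pool_size = 100L,
                      K = 30L, seed = 1L,
                      n_test_objects = num_objects, ...) {
  lib <- exp_library(num_objects, feature_pool_size, seed, list(...))
  net <- build_network(seed, 1L, ...)
  net_train_library(net, lib, rng_stream(derive_seed(seed, "training")))
  ids <- seq_len(min(n_test_objects, num_objects))
  out <- list()
  for (ch in channels) {
    for (nu in noise_levels) {
      rec <- test_trained_network(
        net, lib, ids, K,
        derive_seed(seed, paste("noise", ch, nu)),
        noise = nu, channel = if (nu > 0) ch else "none")
      rec$channel <- ch
      rec$noise <- nu
      rec$seed <- seed
      out[[paste(ch, nu)]] <- rec
    }
  }
  rec <- do.call(rbind, out)
  new_result("noise", rec,
             list(noise_levels = noise_levels, channels = channels,
                  num_objects = num_objects,
                  feature_pool_size = feature_pool_size, K = K,
                  seed = seed))
}

#' Network versus ideal observers on identical streams
#'
#' Feeds the very same sensation streams to the trained network, to an
#' ideal observer that memorizes (location, feature) pairs, and to one that
#' sees only features. Returns cumulative recognition (recognized by
#' sensation t) per model, object and sensation. The with-location
#' observer upper-bounds any model consuming the same observations; the
#' feature-only observer shows what the location signal buys.
#'
#' @param num_objects Library size (default 100).
#' @param feature_pool_size Feature pool (default 10).
#' @param num_columns Columns (the observers receive the same
#'   `num_columns` observations per sensation).
#' @param K Sensations (default 20).
#' @param seed Integer experiment seed.
#' @param n_test_objects Objects tested (default: all).
#' @param ... Further arguments to [cortical_network()].
#' @return An `experiment_result`; records have columns `model`
#'   (`network`, `ideal_location`, `ideal_feature`), `object_id`,
#'   `first_correct`, `recognized`.
#' @export
run_ideal_comparison <- function(num_objects = 100L,
                                 feature_pool_size = 10L,
                                 num_columns = 1L, K = 20L, seed = 1L,
                                 n_test_objects = num_objects, ...) {
  lib <- exp_library(num_objects, feature_pool_size, seed, list(...))
  net <- build_network(seed, num_columns, ...)
  net_train_library(net, lib, rng_stream(derive_seed(seed, "training")))
  obs_loc <- ideal_observer(lib, "with_location")
  obs_feat <- ideal_observer(lib, "feature_only")
  srng <- rng_stream(derive_seed(seed, "sensation-order"))
  ids <- seq_len(min(n_test_objects, num_objects))
  out <- list()
  for (oid in ids) {
    st <- sensation_stream(lib, oid, K, num_columns, srng)
    res <- net_infer(net, st)
    first_net <- which(res$classification == oid)[1L]
    r_loc <- io_run_stream(obs_loc, st, oid)
    r_feat <- io_run_stream(obs_feat, st, oid)
    out[[as.character(oid)]] <- data.frame(
      model = c("network", "ideal_location", "ideal_feature"),
      object_id = oid,
      first_correct = c(first_net, r_loc$recognized_at,
                        r_feat$recognized_at),
      recognized = !is.na(c(first_net, r_loc$recognized_at,
                            r_feat$recognized_at)))
  }
  rec <- do.call(rbind, out)
  rec$seed <- seed
  new_result("ideal_comparison", rec,
             list(num_objects = num_objects,
                  feature_pool_size = feature_pool_size,
                  num_columns = num_columns, K = K, seed = seed))
}

#' Cumulative accuracy-versus-sensations curve
#'
#' Fraction of tested objects recognized by each sensation count, from an
#' experiment's records.
#'
#' @param result An `experiment_result`.
#' @param K Maximum sensation count for the curve.
#' @param by Optional grouping column (e.g. `"model"`, `"noise"`).
#' @return A data frame with columns `sensations`, `accuracy` (and the
#'   grouping column when given).
#' @export
accuracy_curve <- function(result, K, by = NULL) {
  rec <- result$records
  groups <- if (is.null(by)) list(all = seq_len(nrow(rec))) else
    split(seq_len(nrow(rec)), rec[[by]])
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    fc <- rec$first_correct[idx]
    data.frame(group = g, sensations = seq_len(K),
               accuracy = vapply(seq_len(K), function(t)
                 mean(!is.na(fc) & fc <= t), 0))
  })
  out <- do.call(rbind, out)
  if (is.null(by)) out$group <- NULL else names(out)[1] <- by
  out
}

#' Write an experiment result to disk
#'
#' Records go to `<path>.csv`; the configuration echo (including the seed)
#' to `<path>.json`. Together they reproduce the run exactly.
#'
#' @param result An `experiment_result`.
#' @param path Output path stem (without extension).
#' @return Invisibly the two file paths.
#' @export
result_write <- function(result, path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.csv(result$records, csv, row.names = FALSE)
  jsonlite::write_json(
    list(experiment = result$experiment, config = result$config),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
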