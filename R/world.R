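#' Synthetic object library
#'
#' The simulator's stand-in for a world of objects explored by a moving
#' sensor. An object is an unordered set of (location, feature) pairs: each
#' of its location slots carries one sensory feature. Feature codes are
#' random SDRs over the minicolumn space (`n_in` bits, 10 active); location
#' codes are random SDRs over the external location space (`n_ext` bits, 10
#' active). The location pool is shared across objects — slot i of every
#' object reuses location code i — so the same feature/location pair can
#' occur in several objects and a single sensation is genuinely ambiguous.
#'
#' @param num_objects Number of distinct objects to generate.
#' @param features_per_object Location slots (and features) per object;
#'   default 10.
#' @param feature_pool_size Number of distinct feature codes objects draw
#'   from. Small pools (5-30) give heavily shared features; a large pool
#'   (e.g. 5,000) gives nearly unique pairs.
#' @param num_locations Size of the shared location pool; defaults to
#'   `features_per_object`.
#' @param rng An [rng_stream()].
#' @param n_in Feature code width in bits (default 150 minicolumns).
#' @param n_ext Location code width in bits (default 2,400).
#' @param bits_active Active bits per code (default 10).
#' @return An object of class `object_library`: feature/location pools plus
#'   per-object slot and feature index vectors.
#' @export
generate_library <- function(num_objects,
                             features_per_object = 10L,
                             feature_pool_size = 10L,
                             num_locations = features_per_object,
                             rng = rng_stream(1),
                             n_in = 150L,
                             n_ext = 2400L,
                             bits_active = 10L) {
  num_objects <- as.integer(num_objects)
  features_per_object <- as.integer(features_per_object)
  feature_pool_size <- as.integer(feature_pool_size)
  num_locations <- as.integer(num_locations)
  stopifnot(num_objects >= 1L, features_per_object >= 1L,
            feature_pool_size >= 1L)
  if (num_locations < features_per_object) {
    stop("`num_locations` must be at least `features_per_object`",
         call. = FALSE)
  }
  log_space <- lchoose(num_locations, features_per_object) +
    features_per_object * log(feature_pool_size)
  if (log_space < log(num_objects)) {
    stop(sprintf(paste0(
      "infeasible library: only C(%d,%d) * %d^%d possible objects, ",
      "fewer than the %d requested"),
      num_locations, features_per_object, feature_pool_size,
      features_per_object, num_objects), call. = FALSE)
  }
  feature_pool <- lapply(seq_len(feature_pool_size), function(i)
    random_sdr(n_in, bits_active, rng))
  location_pool <- lapply(seq_len(num_locations), function(i)
    random_sdr(n_ext, bits_active, rng))

  objects <- vector("list", num_objects)
  seen <- new.env(parent = emptyenv())
  for (o in seq_len(num_objects)) {
    repeat {
      slots <- if (num_locations == features_per_object) {
        seq_len(features_per_object)
      } else {
        sort(with_rng(rng, sample.int(num_locations, features_per_object)))
      }
      feats <- with_rng(rng,
        sample.int(feature_pool_size, features_per_object, replace = TRUE))
      key <- paste(slots, feats, sep = ":", collapse = "|")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        objects[[o]] <- list(object_id = o, slots = slots, feats = feats)
        break
      }
    }
  }
  structure(
    list(
      feature_pool = feature_pool,
      location_pool = location_pool,
      objects = objects,
      n_in = as.integer(n_in),
      n_ext = as.integer(n_ext),
      bits_active = as.integer(bits_active),
      features_per_object = features_per_object,
      feature_pool_size = feature_pool_size,
      num_locations = num_locations
    ),
    class = "object_library"
  )
}

#' @export
print.object_library <- function(x, ...) {
  cat(sprintf(
    "<object_library> %d objects, %d pairs each; %d features, %d locations\n",
    length(x$objects), x$features_per_object, x$feature_pool_size,
    x$num_locations))
  invisible(x)
}

object_pairs <- function(library, object_id) {
  object_id <- as.integer(object_id)
  if (length(object_id) != 1L || is.na(object_id) || object_id < 1L ||
      object_id > length(library$objects)) {
    stop("unknown object_id", call. = FALSE)
  }
  library$objects[[object_id]]
}

#' Build a two-object demonstration library with shared features
#'
#' Two three-feature objects sharing their first and last feature/location
#' pair while differing in the middle one (the classic cube-versus-wedge
#' disambiguation setup): sensing the shared pair is ambiguous, sensing the
#' middle pair identifies the object. Useful for tracing the
#' union-then-narrowing behavior of the output layer step by step.
#'
#' @param rng An [rng_stream()].
#' @param n_in,n_ext,bits_active Code dimensions as in [generate_library()].
#' @return An `object_library` with objects 1 ("cube") and 2 ("wedge").
#' @export
demo_shared_feature_library <- function(rng = rng_stream(1),
                                        n_in = 150L, n_ext = 2400L,
                                        bits_active = 10L) {
  feature_pool <- lapply(1:4, function(i) random_sdr(n_in, bits_active, rng))
  location_pool <- lapply(1:4, function(i) random_sdr(n_ext, bits_active, rng))
  objects <- list(
    list(object_id = 1L, slots = c(1L, 2L, 3L), feats = c(1L, 2L, 3L)),
    list(object_id = 2L, slots = c(1L, 4L, 3L), feats = c(1L, 4L, 3L))
  )
  structure(
    list(feature_pool = feature_pool, location_pool = location_pool,
         objects = objects, n_in = as.integer(n_in),
         n_ext = as.integer(n_ext), bits_active = as.integer(bits_active),
         features_per_object = 3L, feature_pool_size = 4L,
         num_locations = 4L),
    class = "object_library"
  )
}

# One sensation: per-column list of (slot, location sdr, feature sdr).
make_sensation <- function(library, obj, positions) {
  lapply(positions, function(p) {
    list(slot = obj$slots[p],
         feat = obj$feats[p],
         location = library$location_pool[[obj$slots[p]]],
         feature = library$feature_pool[[obj$feats[p]]])
  })
}

#' Generate a test-time sensation stream over one object
#'
#' Simulates `num_columns` sensor patches exploring one object for
#' `num_sensations` steps. Slot visits are drawn sequentially from a queue
#' of random permutations of the object's slots, so every slot is visited
#' before any repeats; within one sensation the columns always touch
#' pairwise distinct slots.
#'
#' @param library An `object_library`.
#' @param object_id Object to explore.
#' @param num_sensations Number of steps (K; the convergence experiments use
#'   20, the capacity experiment 3, the noise experiment 30).
#' @param num_columns Sensor patches sensing simultaneously; must not
#'   exceed `features_per_object`.
#' @param rng An [rng_stream()].
#' @return List of `num_sensations` sensations; each is a per-column list
#'   with elements `slot`, `location` (sdr), `feature` (sdr).
#' @export
sensation_stream <- function(library, object_id, num_sensations,
                             num_columns = 1L, rng = rng_stream(1)) {
  obj <- object_pairs(library, object_id)
  n_slots <- length(obj$slots)
  num_columns <- as.integer(num_columns)
  if (num_columns > n_slots) {
    stop("`num_columns` exceeds the number of location slots", call. = FALSE)
  }
  queue <- integer(0)
  out <- vector("list", num_sensations)
  for (t in seq_len(num_sensations)) {
    chosen <- integer(0)
    while (length(chosen) < num_columns) {
      if (length(queue) == 0L) {
        queue <- with_rng(rng, sample.int(n_slots))
      }
      pick <- which(!(queue %in% chosen))[1]
      if (is.na(pick)) {          # rest of queue collides; start a new cycle
        queue <- c(queue, with_rng(rng, sample.int(n_slots)))
        pick <- which(!(queue %in% chosen))[1]
      }
      chosen <- c(chosen, queue[pick])
      queue <- queue[-pick]
    }
    out[[t]] <- make_sensation(library, obj, chosen)
  }
  out
}

#' Generate a training sensation stream over one object
#'
#' During learning the network senses each feature of the object
#' `passes` times (default 3). Each pass is one random permutation of the
#' object's slots; with several columns, the permutation is rotated by one
#' position per column so that every column covers every slot each pass
#' while columns always touch distinct slots simultaneously.
#'
#' @param library An `object_library`.
#' @param object_id Object to train on.
#' @param passes Passes over all slots (default 3).
#' @param num_columns Simultaneous sensor patches.
#' @param rng An [rng_stream()].
#' @return List of `passes * features_per_object` sensations in the format
#'   of [sensation_stream()].
#' @export
training_stream <- function(library, object_id, passes = 3L,
                            num_columns = 1L, rng = rng_stream(1)) {
  obj <- object_pairs(library, object_id)
  n_slots <- length(obj$slots)
  num_columns <- as.integer(num_columns)
  if (num_columns > n_slots) {
    stop("`num_columns` exceeds the number of location slots", call. = FALSE)
  }
  out <- vector("list", passes * n_slots)
  t <- 0L
  for (p in seq_len(passes)) {
    perm <- with_rng(rng, sample.int(n_slots))
    for (j in seq_len(n_slots)) {
      t <- t + 1L
      positions <- perm[((j - 1L + seq_len(num_columns) - 1L) %% n_slots) + 1L]
      out[[t]] <- make_sensation(library, obj, positions)
    }
  }
  out
}

#' Serialize an object library to JSON
#'
#' Pools and per-object pair lists round-trip exactly (0-based bit indices,
#' 1-based pool indices), so an experiment's world can be re-run
#' bit-identically from a saved file.
#'
#' @param library An `object_library`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
library_to_json <- function(library, path = NULL) {
  payload <- list(
    n_in = library$n_in, n_ext = library$n_ext,
    bits_active = library$bits_active,
    features_per_object = library$features_per_object,
    feature_pool_size = library$feature_pool_size,
    num_locations = library$num_locations,
    feature_pool = lapply(library$feature_pool, function(s) s$active - 1L),
    location_pool = lapply(library$location_pool, function(s) s$active - 1L),
    objects = lapply(library$objects, function(o)
      list(object_id = o$object_id, slots = o$slots, feats = o$feats))
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read an object library back from JSON
#'
#' @param path File path or JSON string from [library_to_json()].
#' @return An `object_library`.
#' @export
library_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(
    list(
      feature_pool = lapply(obj$feature_pool, function(a)
        sdr(obj$n_in, unlist(a, use.names = FALSE) + 1L)),
      location_pool = lapply(obj$location_pool, function(a)
        sdr(obj$n_ext, unlist(a, use.names = FALSE) + 1L)),
      objects = lapply(obj$objects, function(o)
        list(object_id = as.integer(o$object_id),
             slots = as.integer(unlist(o$slots)),
             feats = as.integer(unlist(o$feats)))),
      n_in = as.integer(obj$n_in), n_ext = as.integer(obj$n_ext),
      bits_active = as.integer(obj$bits_active),
      features_per_object = as.integer(obj$features_per_object),
      feature_pool_size = as.integer(obj$feature_pool_size),
      num_locations = as.integer(obj$num_locations)
    ),
    class = "object_library"
  )
}
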