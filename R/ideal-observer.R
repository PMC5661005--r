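#' Ideal-observer baselines
#'
#' Non-biological reference models for the recognition task. The observer
#' memorizes every object's (location, feature) pair set exactly. During a
#' test it accumulates the set of observed pairs and scores each object by
#' the overlap between the observed set and the object's memorized set; the
#' test object is recognized once it is the strict unique maximizer. The
#' `feature_only` variant projects pairs onto bare feature identities
#' before scoring, modeling a system with no access to a location signal:
#' objects that differ only in where their features sit can then never be
#' told apart. Duplicate observations carry no new information and are
#' ignored (set semantics).
#'
#' The with-location observer is an upper reference for the column network:
#' it makes the best possible use of every sensation.
#'
#' @param library An `object_library`.
#' @param mode `"with_location"` (default) or `"feature_only"`.
#' @return Mutable object of class `ideal_observer`.
#' @export
ideal_observer <- function(library, mode = c("with_location", "feature_only")) {
  mode <- match.arg(mode)
  if (length(library$objects) == 0L) {
    stop("the library holds no objects", call. = FALSE)
  }
  obs <- new.env(parent = emptyenv())
  obs$mode <- mode
  obs$object_ids <- vapply(library$objects, `[[`, 0L, "object_id")
  obs$memory <- lapply(library$objects, function(o) {
    if (mode == "with_location") {
      unique(paste(o$slots, o$feats, sep = ":"))
    } else {
      unique(as.character(o$feats))
    }
  })
  obs$observed <- character(0)
  class(obs) <- "ideal_observer"
  obs
}

#' @export
print.ideal_observer <- function(x, ...) {
  cat(sprintf("<ideal_observer> mode=%s, %d objects, %d pairs observed\n",
              x$mode, length(x$memory), length(x$observed)))
  invisible(x)
}

#' Clear the observer's accumulated observations
#'
#' @param obs An [ideal_observer()].
#' @return Invisibly `obs`.
#' @export
io_reset <- function(obs) {
  obs$observed <- character(0)
  invisible(obs)
}

#' Feed observations to the observer and rank the objects
#'
#' Appends the new (slot, feature) observations to the observed set and
#' returns the per-object overlap scores. Scores are non-decreasing in the
#' number of sensations.
#'
#' @param obs An [ideal_observer()].
#' @param slots,feats Integer vectors (equal length): the location slots
#'   and feature indices observed this sensation (one entry per simulated
#'   sensor patch).
#' @return Named list: `scores` (integer vector over objects),
#'   `prediction` (object id with maximal score; ties broken toward the
#'   smallest id), `unique` (logical: is the maximizer strict).
#' @export
io_observe <- function(obs, slots, feats) {
  stopifnot(length(slots) == length(feats), length(slots) >= 1L)
  keys <- if (obs$mode == "with_location") {
    paste(slots, feats, sep = ":")
  } else {
    as.character(feats)
  }
  obs$observed <- unique(c(obs$observed, keys))
  scores <- vapply(obs$memory, function(mem)
    sum(mem %in% obs$observed), 0L)
  top <- which(scores == max(scores))
  list(scores = scores,
       prediction = obs$object_ids[top[1L]],
       unique = length(top) == 1L)
}

#' Run the observer over a sensation stream
#'
#' Processes the same streams the network sees. The object counts as
#' recognized at the first sensation where it is the strict unique
#' top-scoring object; once recognized on full pair sets, recognition
#' persists.
#'
#' @param obs An [ideal_observer()] (reset first).
#' @param sensations A stream from [sensation_stream()].
#' @param true_id The identity of the sensed object.
#' @return List: `recognized_at` (first such sensation or `NA`),
#'   `recognized` (logical vector per sensation: strict unique and
#'   correct).
#' @export
io_run_stream <- function(obs, sensations, true_id) {
  io_reset(obs)
  K <- length(sensations)
  rec <- logical(K)
  for (t in seq_len(K)) {
    slots <- vapply(sensations[[t]], `[[`, 0L, "slot")
    feats <- vapply(sensations[[t]], `[[`, 0L, "feat")
    r <- io_observe(obs, slots, feats)
    rec[t] <- r$unique && r$prediction == true_id
  }
  first <- which(rec)[1L]
  list(recognized_at = if (is.na(first)) NA_integer_ else first,
       recognized = rec)
}
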