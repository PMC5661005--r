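#' Sparse distributed representations (SDRs)
#'
#' An SDR is a high-dimensional binary vector with few active bits, stored
#' as its size plus the sorted set of active indices. SDRs are the universal
#' currency of the simulator: sensory feature codes (over the minicolumn
#' space), allocentric location codes (2,400 bits, 10 active in the default
#' configuration), and layer activity are all SDRs. Similarity between SDRs
#' is the overlap of their active sets.
#'
#' Indices are 1-based inside R (the native indexing convention); the JSON
#' serialization ([sdr_to_json()]) emits 0-based indices for interchange
#' with other implementations.
#'
#' @param size Positive integer, total number of bits.
#' @param active Integer vector of distinct active indices in `[1, size]`
#'   (any order; stored sorted).
#' @return An object of class `sdr` with fields `size` and `active`.
#' @examples
#' x <- sdr(10, c(3, 7))
#' sdr_overlap(x, x)
#' @export
sdr <- function(size, active = integer(0)) {
  size <- as.integer(size)
  active <- as.integer(active)
  if (length(size) != 1L || is.na(size) || size <= 0L) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  if (anyNA(active) || anyDuplicated(active) ||
      (length(active) && (min(active) < 1L || max(active) > size))) {
    stop("`active` must be distinct indices in [1, size]", call. = FALSE)
  }
  structure(list(size = size, active = sort(active)), class = "sdr")
}

#' @export
print.sdr <- function(x, ...) {
  cat(sprintf("<sdr> %d/%d bits active\n", length(x$active), x$size))
  invisible(x)
}

#' @export
format.sdr <- function(x, ...) {
  sprintf("sdr(%d; %s)", x$size, paste(x$active, collapse = ","))
}

#' Generate a random SDR
#'
#' Samples exactly `num_active` of `size` indices uniformly without
#' replacement from the given stream. Used to create random feature and
#' location codes: e.g. the default location space is 2,400 bits with 10
#' active, the default feature space 150 bits (one per minicolumn) with 10
#' active.
#'
#' @param size Number of bits.
#' @param num_active Number of active bits; must not exceed `size`.
#' @param rng An [rng_stream()].
#' @return An [sdr()].
#' @export
random_sdr <- function(size, num_active, rng) {
  size <- as.integer(size)
  num_active <- as.integer(num_active)
  if (num_active < 0L || num_active > size) {
    stop("`num_active` must lie in [0, size]", call. = FALSE)
  }
  act <- if (num_active == 0L) integer(0) else
    with_rng(rng, sample.int(size, num_active))
  sdr(size, act)
}

#' Overlap between two SDRs
#'
#' Number of bits active in both; the similarity measure underlying
#' classification ("output activity overlaps the stored representation").
#'
#' @param a,b SDRs of identical size.
#' @return Non-negative integer count.
#' @export
sdr_overlap <- function(a, b) {
  stopifnot(inherits(a, "sdr"), inherits(b, "sdr"))
  if (a$size != b$size) stop("SDR sizes differ", call. = FALSE)
  length(intersect(a$active, b$active))
}

# round() half-away-from-zero, so a noise grid in steps of 0.1 applied to
# 10-active codes yields integer flip counts 0..7.
round_half_up <- function(x) floor(x + 0.5)

#' Corrupt an SDR with sparsity-preserving bit noise
#'
#' Flips a fraction of the active bits to inactive and activates the same
#' number of previously inactive bits, chosen uniformly, so the number of
#' active bits is unchanged. `noise_level` is the fraction of active bits
#' replaced; the flip count is `round(noise_level * n_active)` with halves
#' rounded away from zero.
#'
#' @param x An [sdr()].
#' @param noise_level Fraction in \[0, 1\].
#' @param rng An [rng_stream()].
#' @return A corrupted [sdr()] with the same size and activity count.
#' @export
sdr_corrupt <- function(x, noise_level, rng) {
  stopifnot(inherits(x, "sdr"))
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      is.na(noise_level) || noise_level < 0 || noise_level > 1) {
    stop("`noise_level` must be a single value in [0, 1]", call. = FALSE)
  }
  n_act <- length(x$active)
  k <- as.integer(round_half_up(noise_level * n_act))
  if (k == 0L) return(x)
  if (x$size - n_act < k) {
    stop("not enough inactive bits to keep sparsity constant", call. = FALSE)
  }
  with_rng(rng, {
    drop <- sample(x$active, k)
    inactive <- setdiff(seq_len(x$size), x$active)
    add <- if (length(inactive) == 1L) inactive else sample(inactive, k)
    sdr(x$size, c(setdiff(x$active, drop), add))
  })
}

#' Convert an SDR to a dense 0/1 vector
#'
#' @param x An [sdr()].
#' @return Integer vector of length `x$size`.
#' @export
sdr_dense <- function(x) {
  stopifnot(inherits(x, "sdr"))
  out <- integer(x$size)
  out[x$active] <- 1L
  out
}

#' Exact count of unique sparse codes
#'
#' The number of distinct SDRs with `w` of `n` bits active is the binomial
#' coefficient C(n, w). For the default input layer (150 minicolumns, 10
#' active) this is 1,169,554,298,222,310 (~1.2e15), which is why code-space
#' exhaustion is never the capacity bottleneck. Computed exactly with
#' arbitrary-precision integer arithmetic and returned as a decimal digit
#' string.
#'
#' @param n Total number of bits (positive integer).
#' @param w Number of active bits, `0 <= w <= n`.
#' @return Character scalar: the exact decimal value of C(n, w).
#' @examples
#' count_unique_codes(150, 10)
#' @export
count_unique_codes <- function(n, w) {
  n <- as.integer(n)
  w <- as.integer(w)
  if (is.na(n) || is.na(w) || n < 1L || w < 0L || w > n) {
    stop("need 0 <= w <= n with n >= 1", call. = FALSE)
  }
  w <- min(w, n - w)
  # big integer as little-endian base-1e4 digit vector
  big <- 1
  big_mul <- function(x, m) {
    x <- x * m
    carry <- 0
    for (i in seq_along(x)) {
      v <- x[i] + carry
      x[i] <- v %% 10000
      carry <- v %/% 10000
    }
    while (carry > 0) {
      x <- c(x, carry %% 10000)
      carry <- carry %/% 10000
    }
    x
  }
  big_div <- function(x, d) {  # exact division by small integer
    rem <- 0
    for (i in rev(seq_along(x))) {
      v <- rem * 10000 + x[i]
      x[i] <- v %/% d
      rem <- v %% d
    }
    stopifnot(rem == 0)
    while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
    x
  }
  if (w >= 1L) {
    for (i in seq_len(w)) {
      big <- big_mul(big, n - i + 1)
      big <- big_div(big, i)  # C(n, i) is integral, so division is exact
    }
  }
  digits <- rev(big)
  paste0(
    as.character(digits[1]),
    paste(sprintf("%04d", digits[-1]), collapse = "")
  )
}

#' Serialize an SDR to JSON
#'
#' Emits `{"size": n, "active": [...]}` with 0-based indices.
#'
#' @param x An [sdr()].
#' @return A JSON string.
#' @export
sdr_to_json <- function(x) {
  stopifnot(inherits(x, "sdr"))
  jsonlite::toJSON(
    list(size = x$size, active = x$active - 1L),
    auto_unbox = TRUE
  )
}

#' Deserialize an SDR from JSON
#'
#' @param txt JSON produced by [sdr_to_json()] (0-based indices).
#' @return An [sdr()].
#' @export
sdr_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  sdr(obj$size, as.integer(obj$active) + 1L)
}
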