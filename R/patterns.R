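#' Binary spaced-seed patterns
#'
#' A spaced pattern is a binary mask of match positions (`1`) and don't-care
#' positions (`0`). Occurrences of a spaced word defined by a pattern must
#' agree at all match positions; don't-care positions may mismatch. Patterns
#' are kept in canonical form: the first symbol is always `1` (a leading `0`
#' would merely shift every occurrence coordinate).
#'
#' @param mask a character string of `0`/`1` symbols (e.g. `"1101001"`), or
#'   an integer/logical vector of the same.
#' @return an object of class `spaced_pattern` with elements `mask`
#'   (integer vector of 0/1), `length` and `weight`.
#' @examples
#' p <- spaced_pattern("1101001")
#' p$weight  # 4
#' @export
spaced_pattern <- function(mask) {
  if (is.character(mask)) {
    stopifnot(length(mask) == 1L, nzchar(mask))
    mask <- suppressWarnings(as.integer(strsplit(mask, "", fixed = TRUE)[[1]]))
    if (anyNA(mask)) stop("invalid pattern: mask must contain only 0/1 symbols")
  }
  mask <- as.integer(mask)
  if (length(mask) < 1L) stop("invalid pattern: empty mask")
  if (anyNA(mask) || !all(mask %in% c(0L, 1L)))
    stop("invalid pattern: mask must contain only 0/1 symbols")
  if (mask[1] != 1L)
    stop("invalid pattern: canonical patterns start with a match position (1)")
  w <- sum(mask)
  structure(
    list(mask = mask, length = length(mask), weight = w),
    class = "spaced_pattern"
  )
}

#' @export
format.spaced_pattern <- function(x, ...) paste(x$mask, collapse = "")

#' @export
print.spaced_pattern <- function(x, ...) {
  cat(sprintf("<spaced_pattern> length %d, weight %d\n%s\n",
              x$length, x$weight, format(x)))
  invisible(x)
}

#' @export
as.character.spaced_pattern <- function(x, ...) format(x)

#' Weight of a binary mask
#'
#' Counts the match positions (`1` symbols) of a pattern mask.
#'
#' @param mask as in [spaced_pattern()], or a `spaced_pattern`.
#' @return the number of `1` symbols (the pattern weight `w`).
#' @examples
#' weight_of("1101001")  # 4
#' @export
weight_of <- function(mask) {
  if (inherits(mask, "spaced_pattern")) return(mask$weight)
  spaced_pattern_like(mask)$weight
}

# accept raw masks that need not start with 1 (weight is mask arithmetic,
# not a canonical-pattern operation)
spaced_pattern_like <- function(mask) {
  if (is.character(mask)) {
    stopifnot(length(mask) == 1L, nzchar(mask))
    mask <- suppressWarnings(as.integer(strsplit(mask, "", fixed = TRUE)[[1]]))
  }
  mask <- as.integer(mask)
  if (length(mask) < 1L || anyNA(mask) || !all(mask %in% c(0L, 1L)))
    stop("invalid pattern: mask must contain only 0/1 symbols")
  list(mask = mask, length = length(mask), weight = sum(mask))
}

#' Overlap complexity of a pattern pair
#'
#' The overlap complexity (OC) accumulates, over every nonzero relative
#' shift of the two masks against each other, `2^sigma(s)` where `sigma(s)`
#' is the number of aligned positions at which both masks carry a `1`.
#' For `p == q` (self-OC) shifts `1 .. l-1` in one direction are counted
#' (the reverse shifts are mirror images); for distinct patterns both
#' directions and the zero shift are counted. Lower OC correlates with
#' higher seed sensitivity.
#'
#' @param p,q `spaced_pattern` objects (or masks coercible by
#'   [spaced_pattern()]). `q` defaults to `p` (self-OC).
#' @return a nonnegative number.
#' @examples
#' overlap_complexity(spaced_pattern("11"))  # 2
#' @export
overlap_complexity <- function(p, q = p) {
  self <- identical(p, q)
  if (!inherits(p, "spaced_pattern")) p <- spaced_pattern(p)
  if (!inherits(q, "spaced_pattern")) q <- spaced_pattern(q)
  # sigma(s) = #{(i, j) : i in ones(p), j in ones(q), i - j = s}: tally the
  # pairwise differences of match positions instead of sliding the masks
  # (O(w^2) rather than O(l^2)).
  ip <- which(p$mask == 1L)
  iq <- which(q$mask == 1L)
  d <- as.vector(outer(ip, iq, "-"))
  if (self) {
    shifts <- seq_len(p$length - 1L)
    d <- d[d > 0L]
  } else {
    shifts <- seq.int(-(q$length - 1L), p$length - 1L)
  }
  if (!length(shifts)) return(0)
  sigma <- tabulate(match(d, shifts), nbins = length(shifts))
  sum(2^sigma)
}

#' Generate a low-overlap-complexity pattern
#'
#' Draws a random canonical pattern of the requested length and weight and
#' hill-climbs its self overlap complexity by repeated random 1/0 swaps
#' (position 1 stays a match position), accepting a swap iff the OC does
#' not increase. This follows the probabilistic seed-design strategy of
#' OC-minimizing tools; the optimization is a preprocessing nicety, not the
#' accuracy driver of the pipeline.
#'
#' @param length pattern length `l` (default 110).
#' @param weight number of match positions `w` (default 10).
#' @param seed RNG seed; a fixed seed gives a bit-identical pattern.
#' @param iterations swap-proposal budget (default 10000).
#' @return a [spaced_pattern()].
#' @examples
#' p <- generate_pattern(20, 5, seed = 1)
#' @export
generate_pattern <- function(length = 110L, weight = 10L, seed = NULL,
                             iterations = 10000L) {
  length <- as.integer(length); weight <- as.integer(weight)
  if (is.na(length) || is.na(weight) || length < 1L || weight < 1L ||
      weight > length)
    stop("invalid parameters: need 1 <= weight <= length")
  if (weight == length)
    return(spaced_pattern(rep(1L, length)))
  with_seed(seed, {
    mask <- rep(0L, length)
    mask[1] <- 1L
    if (weight > 1L)
      mask[sample(2:length, weight - 1L)] <- 1L
    cur <- overlap_complexity(spaced_pattern(mask))
    ones <- setdiff(which(mask == 1L), 1L)
    zeros <- which(mask == 0L)
    if (length(ones) && length(zeros)) {
      for (i in seq_len(iterations)) {
        cand <- mask
        drop <- ones[sample.int(length(ones), 1L)]
        add <- zeros[sample.int(length(zeros), 1L)]
        cand[drop] <- 0L
        cand[add] <- 1L
        oc <- overlap_complexity(spaced_pattern(cand))
        if (oc <= cur) {
          mask <- cand
          cur <- oc
          ones <- setdiff(which(mask == 1L), 1L)
          zeros <- which(mask == 0L)
        }
      }
    }
    spaced_pattern(mask)
  })
}
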