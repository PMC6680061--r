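#' Events vector constructor
#'
#' An events vector is the delta encoding of coverage for one contig within
#' one partition: `deltas[k]` holds the net number of alignment blocks
#' starting at genomic position `offset + k - 1` minus the number ending
#' just before it. Coverage is recovered by cumulative sum. The array spans
#' only the covered extent of the partition (plus one trailing position for
#' the final decrements), not the whole contig.
#'
#' @param contig reference sequence name.
#' @param offset 1-based genomic position of `deltas[1]`.
#' @param deltas integer delta array.
#' @param partition partition ordinal, for bookkeeping.
#' @return An `events_vector` object.
#' @export
events_vector <- function(contig, offset, deltas, partition = NA_integer_) {
  structure(list(partition = as.integer(partition), contig = contig,
                 offset = as.integer(offset), deltas = as.integer(deltas)),
            class = "events_vector")
}

#' @export
print.events_vector <- function(x, ...) {
  cat(sprintf("<events_vector> partition=%s contig=%s offset=%d length=%d sum=%d\n",
              x$partition, x$contig, x$offset, length(x$deltas),
              sum(x$deltas)))
  invisible(x)
}

#' Partial coverage constructor
#'
#' A partial coverage vector holds per-base depth for one contig within one
#' partition, trimmed so its first and last elements are nonzero. `width`
#' records the counter width the values fit in: `"short"` (<= 65535, the
#' compact counter range), `"int"` (wider, promoted), or `"numeric"`
#' (promoted past the 32-bit integer range). Promotion is checked — counters
#' never wrap around.
#'
#' @param contig reference sequence name.
#' @param start 1-based genomic position of `values[1]`.
#' @param values non-negative depth values.
#' @param partition partition ordinal.
#' @return A `partial_coverage` object.
#' @export
partial_coverage <- function(contig, start, values, partition = NA_integer_) {
  width <- counter_width(values)
  structure(list(partition = as.integer(partition), contig = contig,
                 start = as.integer(start), values = values, width = width),
            class = "partial_coverage")
}

counter_width <- function(values) {
  if (!length(values)) return("short")
  if (is.double(values)) return("numeric")
  if (max(values) > 65535L) "int" else "short"
}

pc_end <- function(pc) pc$start + length(pc$values) - 1L

pc_empty <- function(pc) length(pc$values) == 0L

#' @export
print.partial_coverage <- function(x, ...) {
  if (pc_empty(x)) {
    cat(sprintf("<partial_coverage> partition=%s contig=%s (empty)\n",
                x$partition, x$contig))
  } else {
    cat(sprintf("<partial_coverage> partition=%s contig=%s span=%d-%d max=%s width=%s\n",
                x$partition, x$contig, x$start, pc_end(x),
                format(max(x$values)), x$width))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname partial_coverage
#' @param x a `partial_coverage` object.
#' @param ... unused.
#' @method tidy partial_coverage
#' @export
tidy.partial_coverage <- function(x, ...) {
  if (pc_empty(x)) {
    return(tibble(contig = character(), pos = integer(), coverage = integer()))
  }
  tibble(contig = x$contig,
         pos = seq(x$start, length.out = length(x$values)),
         coverage = x$values)
}

#' @rdname partial_coverage
#' @method glance partial_coverage
#' @export
glance.partial_coverage <- function(x, ...) {
  v <- x$values
  tibble(contig = x$contig,
         start = if (pc_empty(x)) NA_integer_ else x$start,
         end = if (pc_empty(x)) NA_integer_ else pc_end(x),
         n_covered = sum(v > 0),
         mean_coverage = if (length(v)) mean(v) else NA_real_,
         max_coverage = if (length(v)) max(v) else NA_real_,
         width = x$width)
}

#' Build per-contig events vectors from alignment blocks
#'
#' For every block `(start, len)` the delta at genomic position `start` is
#' incremented and the delta at `start + len` decremented; the array spans
#' `[min start, max end + 1]` per contig, with the genomic offset recorded.
#'
#' @param blocks tibble of alignment blocks (`contig`, `start`, `len`), as
#'   from [alignment_blocks()].
#' @param partition partition ordinal recorded on the result.
#' @param contig_lengths optional named vector of contig lengths; when
#'   given, a block extending beyond its contig raises an error naming the
#'   contig and position.
#' @return Named list of [events_vector()] objects, one per contig present,
#'   in order of first appearance.
#' @examples
#' b <- tibble::tibble(contig = "chr1", start = c(1L, 2L), len = c(3L, 3L))
#' build_events(b)[["chr1"]]$deltas   # +1 +1 0 -1 -1
#' @export
build_events <- function(blocks, partition = NA_integer_, contig_lengths = NULL) {
  if (nrow(blocks) == 0L) return(list())
  out <- list()
  for (ctg in unique(blocks$contig)) {
    b <- blocks[blocks$contig == ctg, ]
    s <- as.integer(b$start)
    e <- s + as.integer(b$len)        # first position after the block
    if (!is.null(contig_lengths) && !is.na(contig_lengths[ctg]) &&
        max(e) - 1L > contig_lengths[ctg]) {
      abort(sprintf("alignment block ends at %s:%d beyond contig length %d",
                    ctg, max(e) - 1L, contig_lengths[ctg]))
    }
    offset <- min(s)
    nbins <- max(e) - offset + 1L
    deltas <- tabulate(s - offset + 1L, nbins) - tabulate(e - offset + 1L, nbins)
    out[[ctg]] <- events_vector(ctg, offset, deltas, partition)
  }
  out
}

#' Convert an events vector to partial coverage
#'
#' Computes the running (cumulative) sum of the deltas — depth at position
#' `j` is the sum of all events at positions `<= j` — then trims leading and
#' trailing zero runs, adjusting the start. A cumulative sum that would
#' overflow the integer range is recomputed in doubles (checked promotion);
#' a negative prefix sum signals a malformed events vector and errors.
#'
#' @param events an [events_vector()].
#' @return A [partial_coverage()]; empty (zero-length values) when all
#'   deltas are zero.
#' @examples
#' ev <- events_vector("chr1", 1L, c(1L, 1L, 0L, -1L, -1L))
#' events_to_partial(ev)$values   # 1 2 2 1
#' @export
events_to_partial <- function(events) {
  cs <- suppressWarnings(cumsum(events$deltas))
  if (anyNA(cs)) cs <- cumsum(as.numeric(events$deltas))   # promote, never wrap
  if (any(cs < 0)) {
    abort(sprintf("negative prefix sum in events vector for %s: malformed input",
                  events$contig))
  }
  nz <- which(cs != 0)
  if (!length(nz)) {
    return(partial_coverage(events$contig, events$offset,
                            if (is.double(cs)) numeric() else integer(),
                            events$partition))
  }
  first <- nz[1]
  last <- nz[length(nz)]
  partial_coverage(events$contig, events$offset + first - 1L,
                   cs[first:last], events$partition)
}

#' Render per-base coverage records
#'
#' One record per position. By default positions with zero coverage are
#' omitted (the `samtools depth` convention); with `include_zeros` every
#' position `1..contig_length` is emitted.
#'
#' @param cov a final (post-merge) [partial_coverage()].
#' @param include_zeros emit zero-coverage positions.
#' @param contig_length contig length from the header; required when
#'   `include_zeros`.
#' @return Tibble with columns `contig`, `start`, `end`, `coverage`
#'   (`start == end` for per-base records).
#' @export
to_per_base <- function(cov, include_zeros = FALSE, contig_length = NULL) {
  if (include_zeros) {
    stopifnot(!is.null(contig_length))
    full <- integer(contig_length)
    if (!pc_empty(cov)) {
      full[seq(cov$start, length.out = length(cov$values))] <- cov$values
    }
    pos <- seq_len(contig_length)
    return(tibble(contig = cov$contig, start = pos, end = pos, coverage = full))
  }
  if (pc_empty(cov)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  coverage = integer()))
  }
  pos <- seq(cov$start, length.out = length(cov$values))
  keep <- cov$values > 0
  tibble(contig = cov$contig, start = pos[keep], end = pos[keep],
         coverage = cov$values[keep])
}

#' Render equal-coverage blocks
#'
#' Maximal runs of adjacent positions with equal coverage are merged into a
#' single interval. The representation is lossless: expanding the blocks
#' back to per-base reproduces the per-base output exactly. Zero-coverage
#' runs are emitted only under `include_zeros`.
#'
#' @inheritParams to_per_base
#' @return Tibble with columns `contig`, `start`, `end`, `coverage`.
#' @examples
#' pc <- partial_coverage("chr1", 1L, c(1L, 2L, 2L, 1L))
#' to_blocks(pc)   # (1,1,1) (2,3,2) (4,4,1)
#' @export
to_blocks <- function(cov, include_zeros = FALSE, contig_length = NULL) {
  if (include_zeros) {
    stopifnot(!is.null(contig_length))
    vec <- integer(contig_length)
    if (!pc_empty(cov)) {
      vec[seq(cov$start, length.out = length(cov$values))] <- cov$values
    }
    base <- 1L
  } else {
    if (pc_empty(cov)) {
      return(tibble(contig = character(), start = integer(), end = integer(),
                    coverage = integer()))
    }
    vec <- cov$values
    base <- cov$start
  }
  if (!length(vec)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  coverage = integer()))
  }
  r <- rle(as.vector(vec))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- tibble(contig = cov$contig, start = base + starts - 1L,
                end = base + ends - 1L, coverage = r$values)
  if (!include_zeros) out <- out[out$coverage > 0, ]
  out
}

#' Render fixed-length window means
#'
#' Tiles the contig from position 1 in non-overlapping windows of `window`
#' bases (`[1, w]`, `[w+1, 2w]`, ...; the terminal window may be shorter)
#' and reports the arithmetic mean of per-base coverage over each window's
#' actual positions, zeros included.
#'
#' @inheritParams to_per_base
#' @param window window size in bases (>= 1).
#' @return Tibble with columns `contig`, `start`, `end`, `coverage`
#'   (`coverage` is a double: the window mean).
#' @examples
#' pc <- partial_coverage("chr1", 1L, c(1L, 2L, 2L, 1L))
#' to_windows(pc, window = 2, contig_length = 6)$coverage   # 1.5 1.5 0
#' @export
to_windows <- function(cov, window, contig_length) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) abort("window size must be >= 1")
  stopifnot(!is.null(contig_length), contig_length >= 1L)
  full <- numeric(contig_length)
  if (!pc_empty(cov)) {
    full[seq(cov$start, length.out = length(cov$values))] <- cov$values
  }
  idx <- ((seq_len(contig_length) - 1L) %/% window) + 1L
  sums <- as.vector(rowsum(full, idx))
  lens <- tabulate(idx)
  wins <- seq_along(lens)
  tibble(contig = cov$contig,
         start = (wins - 1L) * window + 1L,
         end = pmin(wins * window, as.integer(contig_length)),
         coverage = sums / lens)
}
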