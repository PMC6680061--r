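#' Detect a genomic overlap between consecutive partial coverage vectors
#'
#' Partition boundaries cut the read stream at arbitrary reads, so the tail
#' of one partition's coverage vector and the head of the next may cover the
#' same genomic positions. The overlap length is
#' `end(left) - start(right) + 1` when positive. Vectors on different
#' contigs never overlap; abutting extents (`end(left) + 1 == start(right)`)
#' do not overlap.
#'
#' @param left,right [partial_coverage()] vectors from consecutive holders
#'   of one contig, in partition order.
#' @return An `overlap` object, or `NULL` when the extents do not intersect.
#' @examples
#' left <- partial_coverage("chr3", 81L, rep(1L, 24), partition = 1L)
#' right <- partial_coverage("chr3", 101L, rep(2L, 14), partition = 2L)
#' detect_overlap(left, right)   # length 4, chr3:101-104
#' @export
detect_overlap <- function(left, right) {
  if (!identical(left$contig, right$contig)) return(NULL)
  if (pc_empty(left) || pc_empty(right)) return(NULL)
  if (right$start < left$start) {
    abort(sprintf("partials out of coordinate order on %s: partition %s starts at %d before partition %s at %d",
                  left$contig, right$partition, right$start,
                  left$partition, left$start))
  }
  l_end <- pc_end(left)
  if (right$start > l_end) return(NULL)
  structure(list(left_partition = left$partition,
                 right_partition = right$partition,
                 contig = left$contig,
                 start = right$start,
                 length = l_end - right$start + 1L),
            class = "overlap")
}

#' @export
print.overlap <- function(x, ...) {
  cat(sprintf("<overlap> %s:%d-%d (length %d) between partitions %s and %s\n",
              x$contig, x$start, x$start + x$length - 1L, x$length,
              x$left_partition, x$right_partition))
  invisible(x)
}

# trim zero runs at both ends of a partial coverage vector
trim_pc <- function(pc) {
  nz <- which(pc$values != 0)
  if (!length(nz)) {
    return(partial_coverage(pc$contig, pc$start,
                            if (is.double(pc$values)) numeric() else integer(),
                            pc$partition))
  }
  first <- nz[1]
  last <- nz[length(nz)]
  partial_coverage(pc$contig, pc$start + first - 1L,
                   pc$values[first:last], pc$partition)
}

#' Correct an overlap between consecutive partial coverage vectors
#'
#' The `l` tail values of the left vector are added elementwise to the `l`
#' head values of the right vector, then the last `l` elements of the left
#' vector are removed. Total coverage mass (the sum over both vectors) is
#' unchanged. When the left vector extends past the right vector's end —
#' a single long alignment block spanning more than one downstream
#' partition — the right vector is first zero-padded to the overlap extent,
#' so the carried tail cascades into the next comparison.
#'
#' @param left,right [partial_coverage()] vectors.
#' @param ov the [detect_overlap()] result for `(left, right)`.
#' @return List with corrected `left` and `right` partial coverage vectors
#'   (either may be empty after trimming).
#' @export
apply_correction <- function(left, right, ov) {
  l <- ov$length
  lv <- left$values
  if (l > length(lv)) {
    abort("overlap longer than the left coverage vector: inconsistent merge state")
  }
  rv <- right$values
  if (length(rv) < l) {          # left spans past right's extent: pad, cascade
    pad <- l - length(rv)
    rv <- c(rv, if (is.double(rv)) numeric(pad) else integer(pad))
  }
  tail_vals <- lv[(length(lv) - l + 1L):length(lv)]
  head_sum <- rv[seq_len(l)] + tail_vals
  if (anyNA(head_sum)) {         # integer overflow: promote, never wrap
    head_sum <- as.numeric(rv[seq_len(l)]) + as.numeric(tail_vals)
    rv <- as.numeric(rv)
  }
  rv[seq_len(l)] <- head_sum
  new_left <- partial_coverage(left$contig, left$start,
                               lv[seq_len(length(lv) - l)], left$partition)
  new_right <- partial_coverage(right$contig, right$start, rv, right$partition)
  list(left = trim_pc(new_left), right = trim_pc(new_right))
}

#' Merge per-partition partial coverage into final per-contig coverage
#'
#' Folds each contig's partial vectors left to right in partition order:
#' detect the overlap with the next holder, apply the tail-trim/head-add
#' correction, and let the corrected right vector participate in the next
#' comparison (which handles reads spanning several downstream partitions).
#' The result per contig is an ordered, non-overlapping, gap-allowed set of
#' coverage vectors whose concatenation is the final coverage.
#'
#' @param partials list of [partial_coverage()] objects from all partitions
#'   of one run, in partition order.
#' @return Named list (by contig, in order of first appearance) of lists of
#'   non-overlapping [partial_coverage()] vectors.
#' @export
merge_partials <- function(partials) {
  partials <- Filter(Negate(pc_empty), partials)
  if (!length(partials)) return(list())
  parts <- vapply(partials, function(p) p$partition, integer(1))
  if (is.unsorted(parts)) {
    abort("partial coverage vectors are out of partition order")
  }
  contigs <- unique(vapply(partials, function(p) p$contig, character(1)))
  out <- list()
  for (ctg in contigs) {
    pcs <- Filter(function(p) identical(p$contig, ctg), partials)
    done <- list()
    current <- pcs[[1]]
    for (nxt in pcs[-1]) {
      ov <- detect_overlap(current, nxt)
      if (is.null(ov)) {
        done[[length(done) + 1L]] <- current
        current <- nxt
      } else {
        corrected <- apply_correction(current, nxt, ov)
        if (!pc_empty(corrected$left)) {
          done[[length(done) + 1L]] <- corrected$left
        }
        current <- corrected$right
      }
    }
    if (!pc_empty(current)) done[[length(done) + 1L]] <- current
    out[[ctg]] <- done
  }
  out
}

# splice non-overlapping per-contig vectors into one vector over their
# joint extent (gaps become zeros; they are dropped again at render time
# unless zeros were requested)
combine_contig <- function(pcs, contig) {
  if (!length(pcs)) return(partial_coverage(contig, 1L, integer()))
  starts <- vapply(pcs, function(p) p$start, integer(1))
  ends <- vapply(pcs, pc_end, integer(1))
  offset <- min(starts)
  span <- max(ends) - offset + 1L
  dbl <- any(vapply(pcs, function(p) is.double(p$values), logical(1)))
  vals <- if (dbl) numeric(span) else integer(span)
  for (p in pcs) {
    vals[seq(p$start - offset + 1L, length.out = length(p$values))] <- p$values
  }
  partial_coverage(contig, offset, vals)
}

render_contig <- function(cov, result_type, window, include_zeros, contig_length) {
  switch(result_type,
    "per-base" = to_per_base(cov, include_zeros = include_zeros,
                             contig_length = contig_length),
    "blocks" = to_blocks(cov, include_zeros = include_zeros,
                         contig_length = contig_length),
    "windows" = to_windows(cov, window = window, contig_length = contig_length))
}

slice_partials <- function(slice, part_idx, count_deletions, contig_lengths) {
  blocks <- alignment_blocks(slice, count_deletions = count_deletions)
  evs <- build_events(blocks, partition = part_idx,
                      contig_lengths = contig_lengths)
  lapply(evs, events_to_partial)
}

#' Compute depth of coverage from a SAM/BAM file
#'
#' End-to-end event-based coverage pipeline: read and filter alignments,
#' split the stream into `n_partitions` slices, build per-slice events
#' vectors and partial coverage (optionally on a pool of forked workers),
#' correct overlaps between consecutive partitions, and render one of the
#' three result types. The output is a pure function of the file contents
#' and parameters: it is identical for every partition count and worker
#' count, and across repeated runs.
#'
#' @param path path to a coordinate-sorted SAM or BAM file.
#' @param result_type `"per-base"`, `"blocks"`, or `"windows"`.
#' @param window window size in bases; required for `"windows"`.
#' @param n_partitions number of read-stream slices (>= 1).
#' @param workers number of parallel workers for the per-slice stage.
#' @param filter a [read_filter()].
#' @param count_deletions count deleted (`D`) reference positions as
#'   covered (default `TRUE`, pileup semantics).
#' @param include_zeros emit zero-coverage positions/blocks (windows always
#'   include zeros in their means).
#' @return Tibble with columns `contig`, `start`, `end`, `coverage`, sorted
#'   by (contig order in header, `start`).
#' @examples
#' sam <- generate_fixture(fixture_spec(n_reads = 100, seed = 42),
#'                         tempfile(fileext = ".sam"))
#' compute_coverage(sam$path, "blocks", n_partitions = 4)
#' @export
compute_coverage <- function(path,
                             result_type = c("per-base", "blocks", "windows"),
                             window = NULL,
                             n_partitions = 1L,
                             workers = 1L,
                             filter = read_filter(),
                             count_deletions = TRUE,
                             include_zeros = FALSE) {
  result_type <- match.arg(result_type)
  if (result_type == "windows" && is.null(window)) {
    abort("result_type = \"windows\" requires a window size")
  }
  reads <- read_alignments(path, filter)
  contigs <- attr(reads, "contigs")
  contig_lengths <- setNames(contigs$length, contigs$name)
  reads <- partition_reads(reads, n_partitions)
  slices <- if (nrow(reads)) split(reads, reads$partition) else list()
  run_one <- function(i) {
    slice_partials(slices[[i]], as.integer(names(slices)[i]),
                   count_deletions, contig_lengths)
  }
  per_slice <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(slices), run_one, mc.cores = workers)
  } else {
    lapply(seq_along(slices), run_one)
  }
  partials <- unlist(per_slice, recursive = FALSE, use.names = FALSE)
  merged <- merge_partials(if (is.null(partials)) list() else partials)

  emit_all <- include_zeros || result_type == "windows"
  pieces <- lapply(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs$name[i]
    pcs <- merged[[ctg]]
    if (is.null(pcs) && !emit_all) return(NULL)
    cov <- combine_contig(if (is.null(pcs)) list() else pcs, ctg)
    render_contig(cov, result_type, window, include_zeros, contigs$length[i])
  })
  out <- bind_rows(pieces)
  if (!nrow(out)) {
    out <- tibble(contig = character(), start = integer(), end = integer(),
                  coverage = if (result_type == "windows") numeric() else integer())
  }
  attr(out, "n_reads") <- nrow(reads)
  out
}
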