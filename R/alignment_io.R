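#' Read filter
#'
#' Builds the filter applied to every alignment before it contributes to
#' coverage. A read is kept iff `bitwAnd(flag, exclude_flags) == 0` and
#' `mapq >= min_mapq`. The defaults match `samtools depth`: exclude
#' unmapped, secondary, QC-fail and duplicate reads (mask `0x704`), no
#' mapping-quality cutoff.
#'
#' @param exclude_flags integer SAM FLAG bitmask; any read with one of these
#'   bits set is dropped. See [sam_flags].
#' @param min_mapq minimum mapping quality, inclusive.
#' @return A `read_filter` object.
#' @examples
#' read_filter()                       # samtools depth defaults
#' read_filter(min_mapq = 20)          # additionally require MAPQ >= 20
#' @export
read_filter <- function(exclude_flags = DEFAULT_EXCLUDE, min_mapq = 0L) {
  exclude_flags <- as.integer(exclude_flags)
  min_mapq <- as.integer(min_mapq)
  stopifnot(length(exclude_flags) == 1L, !is.na(exclude_flags),
            length(min_mapq) == 1L, !is.na(min_mapq))
  structure(list(exclude_flags = exclude_flags, min_mapq = min_mapq),
            class = "read_filter")
}

#' @export
print.read_filter <- function(x, ...) {
  cat(sprintf("<read_filter> exclude_flags=0x%X, min_mapq=%d\n",
              x$exclude_flags, x$min_mapq))
  invisible(x)
}

# Resolve a SAM or BAM path to a BAM path scanBam can read.
# SAM text input is converted to a temporary BAM.
as_bam_path <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    return(path)  # BGZF/gzip container -> BAM
  }
  Rsamtools::asBam(path, tempfile("eventcov_"), overwrite = TRUE,
                   indexDestination = FALSE)
}

sam_sort_order <- function(header_text) {
  hd <- header_text[["@HD"]]
  if (is.null(hd)) return(NA_character_)
  so <- grep("^SO:", hd, value = TRUE)
  if (!length(so)) return(NA_character_)
  sub("^SO:", "", so[1])
}

keep_read <- function(flag, mapq, filter) {
  mq <- ifelse(is.na(mapq), 0L, mapq)
  bitwAnd(flag, filter$exclude_flags) == 0L & mq >= filter$min_mapq
}

#' Read and filter alignments from a SAM/BAM file
#'
#' Loads mapped reads in file (coordinate) order, applies a [read_filter()],
#' and returns one row per kept read. The reference dictionary from the file
#' header is attached as the `"contigs"` attribute (a tibble with `name` and
#' `length`), preserving header order — all downstream output is sorted in
#' that order. The input must be coordinate-sorted: the header `SO` tag is
#' trusted when present; otherwise a monotonicity check rejects the first
#' out-of-order record.
#'
#' @param path path to a SAM (text) or BAM (BGZF) file.
#' @param filter a [read_filter()]; unmapped reads are never yielded
#'   regardless of the mask.
#' @return Tibble with columns `qname`, `contig`, `start` (1-based leftmost
#'   mapped position), `cigar`, `flag`, `mapq`, in file order.
#' @examples
#' sam <- generate_fixture(fixture_spec(n_reads = 50, seed = 1),
#'                         tempfile(fileext = ".sam"))
#' reads <- read_alignments(sam$path)
#' attr(reads, "contigs")
#' @export
read_alignments <- function(path, filter = read_filter()) {
  if (!file.exists(path)) {
    abort(paste0("cannot open alignment file: ", path))
  }
  bam <- as_bam_path(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  contigs <- tibble(name = names(hdr$targets), length = unname(hdr$targets))
  so <- sam_sort_order(hdr$text)
  if (!is.na(so) && !identical(so, "coordinate")) {
    abort(sprintf("input must be coordinate-sorted (header says SO:%s)", so))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  reads <- tibble(
    qname = res$qname,
    contig = as.character(res$rname),
    start = res$pos,
    cigar = res$cigar,
    flag = res$flag,
    mapq = res$mapq
  )
  mapped <- bitwAnd(reads$flag, sam_flags[["UNMAP"]]) == 0L
  bad <- which(mapped & (is.na(reads$cigar) | is.na(reads$start) | reads$start < 1L))
  if (length(bad)) {
    abort(sprintf("malformed alignment record at ordinal %d: mapped read without valid POS/CIGAR",
                  bad[1]))
  }
  if (is.na(so)) {
    m <- reads[mapped, ]
    idx <- match(m$contig, contigs$name)
    if (nrow(m) > 1L) {
      key_prev <- idx[-nrow(m)] * 2^32 + m$start[-nrow(m)]
      key_next <- idx[-1L] * 2^32 + m$start[-1L]
      viol <- which(key_next < key_prev)
      if (length(viol)) {
        abort(sprintf("input must be coordinate-sorted: record %d is out of order",
                      viol[1] + 1L))
      }
    }
  }
  keep <- mapped & keep_read(reads$flag, reads$mapq, filter)
  out <- reads[keep, , drop = FALSE]
  attr(out, "contigs") <- contigs
  out
}

validate_cigars <- function(cigar) {
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("unknown or malformed CIGAR at record %d: '%s'", i, cigar[i]))
  }
  invisible(TRUE)
}

#' Extract reference-contiguous alignment blocks from reads
#'
#' Derives, for every read, the maximal reference-contiguous covered
#' intervals from its CIGAR. Reference-consuming base-covered operations are
#' `M`, `=`, `X`; `D` (deletion) is covered iff `count_deletions` (the
#' default, matching pileup semantics where a read spanning a deletion still
#' contributes to depth at the deleted positions); `N` (reference skip,
#' spliced reads) is never covered and always splits blocks; `I`, `S`, `H`,
#' `P` consume no reference and never split a block. Reference-adjacent
#' covered segments are merged.
#'
#' @param reads tibble with at least `contig`, `start`, `cigar` columns
#'   (as from [read_alignments()]).
#' @param count_deletions logical; count deleted reference positions as
#'   covered.
#' @return Tibble with columns `read` (row index into `reads`), `contig`,
#'   `start` (1-based first covered position), `len` (block length, >= 1).
#' @examples
#' reads <- tibble::tibble(contig = "chr1", start = 1L, cigar = "10M100N10M")
#' alignment_blocks(reads)   # two blocks split by the skipped intron
#' @export
alignment_blocks <- function(reads, count_deletions = TRUE) {
  if (nrow(reads) == 0L) {
    return(tibble(read = integer(), contig = character(),
                  start = integer(), len = integer()))
  }
  validate_cigars(reads$cigar)
  ops <- if (count_deletions) c("M", "=", "X", "D") else c("M", "=", "X")
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = as.integer(reads$start), ops = ops,
    reduce.ranges = TRUE, drop.empty.ranges = TRUE)
  nb <- lengths(rng)
  flat <- unlist(rng, use.names = FALSE)
  tibble(
    read = rep(seq_len(nrow(reads)), nb),
    contig = rep(reads$contig, nb),
    start = IRanges::start(flat),
    len = IRanges::width(flat)
  )
}

#' Extract alignment blocks from a single CIGAR
#'
#' Single-read convenience wrapper around [alignment_blocks()].
#'
#' @param start 1-based leftmost mapped position.
#' @param cigar CIGAR string.
#' @param count_deletions logical; see [alignment_blocks()].
#' @return Tibble with columns `start`, `len`; zero rows when the CIGAR
#'   consumes no reference bases.
#' @examples
#' extract_blocks(50, "5S10M3D10M")                          # one merged block
#' extract_blocks(50, "5S10M3D10M", count_deletions = FALSE) # split at the deletion
#' @export
extract_blocks <- function(start, cigar, count_deletions = TRUE) {
  b <- alignment_blocks(tibble(contig = "", start = as.integer(start),
                               cigar = cigar),
                        count_deletions = count_deletions)
  b[c("start", "len")]
}

#' Split a read stream into ordered partitions
#'
#' Assigns each read to one of up to `n` contiguous slices of near-equal
#' size (counts differ by at most one). Boundaries are by read count, not by
#' contig: a slice may span a contig boundary and two slices may cover
#' overlapping genomic ranges — the merge step corrects for that. When there
#' are fewer reads than partitions the result collapses to singleton slices.
#'
#' @param reads tibble of reads in coordinate order.
#' @param n requested partition count (>= 1).
#' @return The input tibble with an added integer `partition` column
#'   (1-based, contiguous); attributes are preserved.
#' @examples
#' reads <- tibble::tibble(contig = "chr1", start = 1:10, cigar = "5M")
#' table(partition_reads(reads, 3)$partition)   # sizes 4, 3, 3
#' @export
partition_reads <- function(reads, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("partition count must be >= 1")
  N <- nrow(reads)
  sizes <- rep(N %/% n, n)
  extra <- N %% n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes <- sizes[sizes > 0L]
  out <- reads
  out$partition <- rep(seq_along(sizes), sizes)
  attr(out, "contigs") <- attr(reads, "contigs")
  out
}
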