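#' Specification for a synthetic alignment fixture
#'
#' Describes a reproducible synthetic read layout: contigs, read count,
#' read length, a CIGAR grammar (per-read probabilities and length ranges
#' for insertions, deletions, reference skips and soft clips), fractions of
#' reads carrying duplicate/secondary/QC-fail flags or left unmapped, and a
#' MAPQ range. Coverage depends only on the layout, so no base sequence or
#' quality model is included. Given a seed, generation is fully
#' reproducible.
#'
#' Defaults emulate a small short-read whole-genome sample: 100 bp reads,
#' uniform starts over two contigs, occasional short indels, rare spliced
#' skips, and the flag fractions a deduplicated library would show (5%
#' duplicates, 2% secondary, 1% QC-fail, 2% unmapped).
#'
#' @param contigs named integer vector of contig lengths, in header order.
#' @param n_reads total number of reads (mapped + unmapped).
#' @param read_length query length in bases.
#' @param p_insertion,p_deletion,p_skip per-event inclusion probability for
#'   each of up to two internal I/D/N events per read.
#' @param p_softclip probability of a soft clip at each read end.
#' @param ins_len,del_len,skip_len,clip_len inclusive length ranges.
#' @param frac_duplicate,frac_secondary,frac_qcfail,frac_unmapped fractions
#'   of reads flagged accordingly (independent draws).
#' @param mapq_range inclusive MAPQ sampling range.
#' @param seed RNG seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(contigs = c(chr1 = 10000L, chr2 = 8000L),
                         n_reads = 1000L,
                         read_length = 100L,
                         p_insertion = 0.15, p_deletion = 0.15, p_skip = 0.05,
                         p_softclip = 0.10,
                         ins_len = c(1L, 5L), del_len = c(1L, 5L),
                         skip_len = c(20L, 200L), clip_len = c(1L, 10L),
                         frac_duplicate = 0.05, frac_secondary = 0.02,
                         frac_qcfail = 0.01, frac_unmapped = 0.02,
                         mapq_range = c(0L, 60L),
                         seed = 1L) {
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)),
            n_reads >= 0L, read_length >= 1L)
  structure(as.list(environment()), class = "fixture_spec")
}

rint <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(seq(range[1], range[2]), 1L)
}

# Build one CIGAR from the grammar. Returns the op table (op, len) —
# the truth blocks are derived from it with a plain cursor walk, never
# through the package's CIGAR parser.
random_cigar <- function(spec) {
  L <- spec$read_length
  clip5 <- if (stats::runif(1) < spec$p_softclip) rint(spec$clip_len) else 0L
  clip3 <- if (stats::runif(1) < spec$p_softclip) rint(spec$clip_len) else 0L
  events <- list()
  for (k in 1:2) {
    if (stats::runif(1) < spec$p_insertion) {
      events[[length(events) + 1L]] <- c("I", rint(spec$ins_len))
    }
    if (stats::runif(1) < spec$p_deletion) {
      events[[length(events) + 1L]] <- c("D", rint(spec$del_len))
    }
    if (stats::runif(1) < spec$p_skip) {
      events[[length(events) + 1L]] <- c("N", rint(spec$skip_len))
    }
  }
  if (length(events) > 1L) events <- sample(events)
  repeat {
    ins_total <- sum(vapply(events, function(e) {
      if (e[1] == "I") as.integer(e[2]) else 0L
    }, integer(1)))
    m_total <- L - clip5 - clip3 - ins_total
    if (m_total >= length(events) + 1L) break
    events <- events[-length(events)]          # too many events for the read
  }
  k <- length(events) + 1L
  cuts <- if (k > 1L) sort(sample(seq_len(m_total - 1L), k - 1L)) else integer()
  m_lens <- diff(c(0L, cuts, m_total))
  op <- character()
  len <- integer()
  if (clip5 > 0L) { op <- "S"; len <- clip5 }
  for (i in seq_len(k)) {
    op <- c(op, "M"); len <- c(len, m_lens[i])
    if (i <= length(events)) {
      op <- c(op, events[[i]][1]); len <- c(len, as.integer(events[[i]][2]))
    }
  }
  if (clip3 > 0L) { op <- c(op, "S"); len <- c(len, clip3) }
  list(op = op, len = len,
       cigar = paste0(len, op, collapse = ""),
       ref_span = sum(len[op %in% c("M", "D", "N")]))
}

# Truth blocks by direct cursor walk over the generator's own op table
# (D counted as covered, N splits) — independent of any parsing code.
ops_to_blocks <- function(op, len, start) {
  blocks <- list()
  cur <- start
  bstart <- NA_integer_
  blen <- 0L
  for (i in seq_along(op)) {
    o <- op[i]
    n <- len[i]
    if (o %in% c("M", "D")) {
      if (blen == 0L) bstart <- cur
      blen <- blen + n
      cur <- cur + n
    } else if (o == "N") {
      if (blen > 0L) {
        blocks[[length(blocks) + 1L]] <- c(bstart, blen)
        blen <- 0L
      }
      cur <- cur + n
    }
    # I, S consume no reference
  }
  if (blen > 0L) blocks[[length(blocks) + 1L]] <- c(bstart, blen)
  tibble(start = vapply(blocks, `[`, integer(1), 1L),
         len = vapply(blocks, `[`, integer(1), 2L))
}

#' Generate a synthetic coordinate-sorted SAM/BAM fixture
#'
#' Writes a spec-conformant, coordinate-sorted alignment file with a correct
#' header, and returns the per-read truth recorded during generation —
#' including each mapped read's alignment blocks derived by a direct cursor
#' walk over the generated operations (before any filtering), so the truth
#' shares no code with the package's CIGAR parser.
#'
#' @param spec a [fixture_spec()].
#' @param out_path output path; a `.bam` extension selects BAM output (via
#'   conversion of the generated SAM), anything else writes SAM text.
#' @return List with `path` (the written file) and `reads`, a tibble with
#'   one row per read: `qname`, `contig`, `start`, `cigar`, `flag`, `mapq`,
#'   `ref_span`, and a `blocks` list-column of per-read block tibbles
#'   (deletions counted).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_reads = 20, seed = 3),
#'                        tempfile(fileext = ".sam"))
#' fx$reads$cigar[1:3]
#' @export
generate_fixture <- function(spec, out_path) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec, out_path))
}

generate_fixture_impl <- function(spec, out_path) {
  n <- spec$n_reads
  contig_names <- names(spec$contigs)
  rows <- vector("list", n)
  n_unmapped <- round(spec$frac_unmapped * n)
  unmapped_idx <- if (n_unmapped > 0L) sample(n, n_unmapped) else integer()
  for (i in seq_len(n)) {
    if (i %in% unmapped_idx) {
      rows[[i]] <- list(contig = NA_character_, start = NA_integer_,
                        cigar = "*", flag = sam_flags[["UNMAP"]],
                        mapq = 0L, ref_span = NA_integer_,
                        blocks = list(tibble(start = integer(), len = integer())))
      next
    }
    cg <- random_cigar(spec)
    eligible <- contig_names[spec$contigs >= cg$ref_span]
    if (!length(eligible)) {
      abort(sprintf("impossible fixture spec: read span %d exceeds every contig length",
                    cg$ref_span))
    }
    w <- as.numeric(spec$contigs[eligible])
    ctg <- if (length(eligible) == 1L) eligible else
      sample(eligible, 1L, prob = w / sum(w))
    max_start <- spec$contigs[[ctg]] - cg$ref_span + 1L
    start <- if (max_start == 1L) 1L else sample(max_start, 1L)
    flag <- if (stats::runif(1) < 0.5) sam_flags[["REVERSE"]] else 0L
    if (stats::runif(1) < spec$frac_duplicate)  flag <- bitwOr(flag, sam_flags[["DUP"]])
    if (stats::runif(1) < spec$frac_secondary)  flag <- bitwOr(flag, sam_flags[["SECONDARY"]])
    if (stats::runif(1) < spec$frac_qcfail)     flag <- bitwOr(flag, sam_flags[["QCFAIL"]])
    mapq <- rint(spec$mapq_range)
    rows[[i]] <- list(contig = ctg, start = start, cigar = cg$cigar,
                      flag = as.integer(flag), mapq = mapq,
                      ref_span = cg$ref_span,
                      blocks = list(ops_to_blocks(cg$op, cg$len, start)))
  }
  truth <- bind_rows(lapply(rows, as_tibble))
  if (nrow(truth)) {
    cidx <- match(truth$contig, contig_names)
    ord <- order(is.na(cidx), cidx, truth$start, method = "radix")
    truth <- truth[ord, ]
    truth$qname <- sprintf("r%06d", seq_len(nrow(truth)))
    truth <- truth[c("qname", "contig", "start", "cigar", "flag", "mapq",
                     "ref_span", "blocks")]
  } else {
    truth <- tibble(qname = character(), contig = character(),
                    start = integer(), cigar = character(), flag = integer(),
                    mapq = integer(), ref_span = integer(), blocks = list())
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contig_names, spec$contigs))
  body <- character()
  if (nrow(truth)) {
    mapped <- !is.na(truth$contig)
    body <- ifelse(mapped,
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
              truth$qname, truth$flag, truth$contig, truth$start,
              truth$mapq, truth$cigar),
      sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", truth$qname, truth$flag))
  }
  if (grepl("\\.bam$", out_path)) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(c(header, body), tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", out_path), overwrite = TRUE,
                     indexDestination = FALSE)
    unlink(tmp)
  } else {
    writeLines(c(header, body), out_path)
  }
  list(path = out_path, reads = truth)
}

#' Brute-force pileup coverage oracle
#'
#' The slow, trusted reference: for every kept read it walks the CIGAR
#' operation by operation with an independent regex parser and increments a
#' per-base counter for each covered reference position, under the same
#' deletion/skip policy as the event-based path. It shares no extraction
#' code with the coverage pipeline, so agreement between the two is
#' evidence of correctness rather than a tautology.
#'
#' @inheritParams compute_coverage
#' @return Tibble with columns `contig`, `pos`, `coverage` (positions with
#'   nonzero depth only), sorted by (contig header order, position).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_reads = 30, seed = 5),
#'                        tempfile(fileext = ".sam"))
#' pileup_oracle(fx$path)
#' @export
pileup_oracle <- function(path, filter = read_filter(), count_deletions = TRUE) {
  reads <- read_alignments(path, filter)
  contigs <- attr(reads, "contigs")
  counters <- lapply(setNames(contigs$length, contigs$name), integer)
  covered_ops <- if (count_deletions) c("M", "=", "X", "D") else c("M", "=", "X")
  for (i in seq_len(nrow(reads))) {
    parts <- regmatches(reads$cigar[i],
                        gregexpr("[0-9]+[A-Z=]", reads$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", parts))
    ops <- sub("^[0-9]+", "", parts)
    if (any(!ops %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X"))) {
      abort(sprintf("unknown CIGAR operation in record %d: '%s'",
                    i, reads$cigar[i]))
    }
    ctg <- reads$contig[i]
    p <- reads$start[i]
    for (j in seq_along(ops)) {
      o <- ops[j]
      n <- lens[j]
      if (o %in% covered_ops) {
        counters[[ctg]][p:(p + n - 1L)] <- counters[[ctg]][p:(p + n - 1L)] + 1L
      }
      if (o %in% c("M", "=", "X", "D", "N")) p <- p + n
    }
  }
  pieces <- lapply(contigs$name, function(ctg) {
    cnt <- counters[[ctg]]
    nz <- which(cnt > 0L)
    tibble(contig = ctg, pos = nz, coverage = cnt[nz])
  })
  bind_rows(pieces)
}
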