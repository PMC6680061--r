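# Hand-built SAM layouts for targeted tests.
# reads: data frame with qname, flag, contig, pos, mapq, cigar.
write_test_sam <- function(reads, contigs, path = tempfile(fileext = ".sam"),
                           so = "coordinate") {
  hd <- if (is.na(so)) character() else sprintf("@HD\tVN:1.6\tSO:%s", so)
  header <- c(hd, sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                          as.integer(contigs)))
  body <- if (nrow(reads)) {
    mapped <- bitwAnd(reads$flag, 4L) == 0L
    ifelse(mapped,
           sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   reads$qname, reads$flag, reads$contig, reads$pos,
                   reads$mapq, reads$cigar),
           sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*",
                   reads$qname, reads$flag))
  } else character()
  writeLines(c(header, body), path)
  path
}

simple_read <- function(qname, contig, pos, cigar, flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, contig = contig, pos = pos,
             mapq = mapq, cigar = cigar, stringsAsFactors = FALSE)
}

# independent flag/MAPQ keep rule for filter-contract checks
truth_keep <- function(flag, mapq, exclude_flags = 1796L, min_mapq = 0L) {
  bitwAnd(flag, 4L) == 0L &
    bitwAnd(flag, exclude_flags) == 0L &
    ifelse(is.na(mapq), 0L, mapq) >= min_mapq
}

# sum of covered positions of kept reads, from the generator truth table
truth_mass <- function(truth, exclude_flags = 1796L, min_mapq = 0L) {
  keep <- !is.na(truth$contig) &
    truth_keep(truth$flag, truth$mapq, exclude_flags, min_mapq)
  sum(vapply(truth$blocks[keep], function(b) sum(b$len), integer(1)))
}
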