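#' Plot coverage records
#'
#' Draws depth along the genome, one panel per contig. Per-base and block
#' records are drawn as a step profile; window records as bars at the
#' window midpoints.
#'
#' @param records coverage tibble from [compute_coverage()].
#' @return A ggplot object.
#' @examples
#' fx <- generate_fixture(fixture_spec(n_reads = 200, seed = 11),
#'                        tempfile(fileext = ".sam"))
#' plot_coverage(compute_coverage(fx$path, "blocks"))
#' @export
plot_coverage <- function(records) {
  stopifnot(all(c("contig", "start", "end", "coverage") %in% names(records)))
  df <- records
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start - 0.5,
                                       xend = .data$end + 0.5,
                                       y = .data$coverage,
                                       yend = .data$coverage)) +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "depth of coverage") +
    ggplot2::theme_minimal()
}
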