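#' @export
plot.coverage_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(rbind(x$n_mapped, x$n_edited), beside = TRUE,
                          names.arg = x$locus, col = c("grey70", "black"),
                          ylab = "reads", las = 2, ...)
  graphics::legend("topright", fill = c("grey70", "black"),
                   legend = c("mapped", sprintf("edited (>=%s sites)", 5)),
                   bty = "n")
  invisible(x)
}
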