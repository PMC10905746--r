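#' Plot the super-enhancer rank curve
#'
#' Hockey-stick plot of rescaled rank versus rescaled signal density with
#' the tangent cutoff marked.
#'
#' @param se result of [call_super_enhancers()].
#' @param ... passed to [plot()].
#' @export
plot_se_curve <- function(se, ...) {
  cv <- se$curve
  plot(cv$x, cv$y, type = "l", xlab = "scaled rank",
       ylab = "scaled signal density", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  if (!is.na(se$cutoff_rank)) {
    graphics::abline(v = cv$x[se$cutoff_rank], lty = 3, col = "red")
    flagged <- cv$rank > se$cutoff_rank
    graphics::points(cv$x[flagged], cv$y[flagged], col = "red", pch = 16,
                     cex = 0.6)
  }
  invisible(se)
}

#' Plot coverage metaprofiles
#'
#' Mean signal around region midpoints for one or more region classes.
#'
#' @param profiles named list of mean-profile vectors (equal length), e.g.
#'   `results$profiles` from [run_pipeline()].
#' @param flank half-width in bp used to label the x axis.
#' @param ... passed to [matplot()].
#' @export
plot_coverage_profiles <- function(profiles, flank = 2000, ...) {
  m <- do.call(cbind, profiles)
  x <- seq(-flank, flank, length.out = nrow(m))
  graphics::matplot(x, m, type = "l", lty = 1, xlab = "distance from midpoint (bp)",
                    ylab = "normalized coverage", ...)
  graphics::legend("topright", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), bty = "n")
  invisible(profiles)
}
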