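## Dataset-targeting diagnostics: how closely does one dataset's bounding-box
## geometry match another's? Summarised by the Jensen-Shannon divergence
## between ln(width/height) histograms on shared bins.

# Jensen-Shannon divergence (nats) between two probability vectors
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Compare the aspect-ratio distributions of two datasets
#'
#' Pools both datasets' ln(width/height) values to fix a shared binning,
#' normalises the two histograms, and reports their Jensen-Shannon
#' divergence (symmetric, bounded by ln 2 in nats, zero only for identical
#' histograms). Candidate training sets can be ranked against a target set
#' by this divergence; the ordering is deterministic.
#'
#' @param dataset_a,dataset_b `coco_dataset` objects, paths to COCO JSON
#'   files, or n x 4 box matrices.
#' @param bins number of shared bins (default 50).
#' @return an object of class `density_comparison`: `values_a`, `values_b`,
#'   `divergence`, `breaks`, `density_a`, `density_b`.
#' @export
compare_aspect_distributions <- function(dataset_a, dataset_b, bins = 50L) {
  get_vals <- function(x) {
    if (is.character(x)) x <- read_coco(x)
    aspect_log_ratio(x, bins = 2L)$values
  }
  va <- get_vals(dataset_a)
  vb <- get_vals(dataset_b)
  if (length(va) == 0L || length(vb) == 0L) {
    stop("both datasets must contain at least one box")
  }
  rng <- range(c(va, vb))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  ha <- graphics::hist(va, breaks = brk, plot = FALSE)$counts
  hb <- graphics::hist(vb, breaks = brk, plot = FALSE)$counts
  structure(list(values_a = va, values_b = vb,
                 divergence = js_divergence(ha / sum(ha), hb / sum(hb)),
                 breaks = brk,
                 density_a = ha / sum(ha) / diff(brk),
                 density_b = hb / sum(hb) / diff(brk)),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf("density_comparison: JS divergence %.4f nats (max %.4f)\n",
              x$divergence, log(2)))
  invisible(x)
}

#' Plot an aspect-ratio density comparison to PNG
#'
#' @param cmp a `density_comparison`.
#' @param path output PNG path.
#' @param labels legend labels for the two datasets.
#' @return `path`, invisibly.
#' @export
plot_aspect_comparison <- function(cmp, path,
                                   labels = c("dataset A", "dataset B")) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  mids <- (cmp$breaks[-1] + cmp$breaks[-length(cmp$breaks)]) / 2
  ylim <- c(0, max(cmp$density_a, cmp$density_b) * 1.05)
  graphics::plot(mids, cmp$density_a, type = "l", col = "steelblue", lwd = 2,
                 xlab = "ln(width / height)", ylab = "probability density",
                 ylim = ylim,
                 main = sprintf("JS divergence = %.3f nats", cmp$divergence))
  graphics::lines(mids, cmp$density_b, col = "firebrick", lwd = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = labels, lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(path)
}
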