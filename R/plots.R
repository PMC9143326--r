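#' Plot pre/post repletion level distributions
#'
#' Overlaid histograms of electrolyte levels at repletion initiation (pre) and
#' at the first measurement after infusion end (post), with the reference
#' range shaded.
#'
#' @param x a \code{"pre_post_report"}.
#' @param ... passed to [graphics::hist()].
#' @export
plot.pre_post_report <- function(x, ...) {
  pre <- x$pre[!is.na(x$pre)]
  post <- x$post[!is.na(x$post)]
  rng <- range(c(pre, post, x$reference_range))
  brk <- pretty(rng, n = 30)
  hp <- graphics::hist(pre, breaks = brk, plot = FALSE)
  hq <- graphics::hist(post, breaks = brk, plot = FALSE)
  ylim <- c(0, max(hp$counts, hq$counts))
  graphics::plot(hp, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, ylim = ylim, main = paste0(
                   x$electrolyte, ": pre (red) / post (green) repletion levels"),
                 xlab = paste(x$electrolyte, "level"), ...)
  graphics::plot(hq, col = grDevices::adjustcolor("forestgreen", 0.5),
                 border = NA, add = TRUE)
  graphics::rect(x$reference_range[1L], 0, x$reference_range[2L], ylim[2L],
                 col = grDevices::adjustcolor("gray", 0.3), border = NA)
  invisible(x)
}

#' Plot historical vs. policy dose-level frequencies
#'
#' @param x a \code{"frequency_report"}.
#' @param ... unused.
#' @export
plot.frequency_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  m_po <- rbind(historical = as.numeric(x$po_levels$historical),
                policy = as.numeric(x$po_levels$policy))
  graphics::barplot(m_po, beside = TRUE, names.arg = paste0("PO", seq_len(ncol(m_po))),
                    legend.text = TRUE, main = "Oral dose levels")
  m_iv <- rbind(historical = as.numeric(x$iv_levels$historical),
                policy = as.numeric(x$iv_levels$policy))
  graphics::barplot(m_iv, beside = TRUE, names.arg = paste0("IV", seq_len(ncol(m_iv))),
                    main = "IV dose/duration levels")
  invisible(x)
}

#' Plot a single-visit trajectory overlay
#'
#' Measured levels across hours into admission with historical and recommended
#' repletion marks; IV infusion spans are drawn as horizontal segments.
#'
#' @param x a \code{"trajectory_overlay"}.
#' @param reference_range optional (low, high) band to shade.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_overlay <- function(x, reference_range = NULL, ...) {
  graphics::plot(x$hours, x$measured_level, type = "b", pch = 16,
                 xlab = "hours into admission", ylab = "measured level", ...)
  if (!is.null(reference_range)) {
    graphics::rect(min(x$hours), reference_range[1L], max(x$hours) + 6,
                   reference_range[2L],
                   col = grDevices::adjustcolor("gray", 0.3), border = NA)
  }
  y0 <- min(x$measured_level, na.rm = TRUE)
  hist_rep <- x$historical_action != ""
  pol_rep <- x$policy_action != ""
  graphics::points(x$hours[hist_rep], rep(y0, sum(hist_rep)), pch = 25,
                   bg = "firebrick")
  graphics::points(x$hours[pol_rep], rep(y0 - 0.05 * abs(y0), sum(pol_rep)),
                   pch = 24, bg = "forestgreen")
  ok <- !is.na(x$hist_iv_start)
  if (any(ok)) graphics::segments(x$hist_iv_start[ok], y0, x$hist_iv_end[ok],
                                  y0, col = "firebrick", lwd = 3)
  invisible(x)
}

#' Plot Q-value distributions of two evaluated policies
#'
#' Density overlay of per-state-action value estimates — the standard visual
#' comparison of a learned policy against logged behavior.
#'
#' @param values_policy,values_historical numeric vectors of Q-value estimates
#'   (e.g. from [policy_value()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot_q_distributions <- function(values_policy, values_historical, ...) {
  dp <- stats::density(values_policy)
  dh <- stats::density(values_historical)
  graphics::plot(dh, col = "firebrick", lwd = 2,
                 xlim = range(c(dp$x, dh$x)), ylim = c(0, max(dp$y, dh$y)),
                 main = "Estimated Q-value distributions",
                 xlab = "estimated value", ...)
  graphics::lines(dp, col = "forestgreen", lwd = 2)
  graphics::legend("topleft", legend = c("historical", "learned policy"),
                   col = c("firebrick", "forestgreen"), lwd = 2, bty = "n")
  invisible(NULL)
}
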