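#' Compute the Rx statistic from per-chromosome read counts
#'
#' For each autosome i, the length-normalised ratio
#' `r_i = (N_X / L_X) / (N_i / L_i)` compares X-chromosome read density to
#' that autosome's; Rx is the mean of the 22 ratios, with a normal 95%
#' confidence interval `Rx +/- 1.96 * SD / sqrt(22)` from their sample
#' standard deviation. Rx is approximately 1 for XX individuals and 0.5 for
#' XY. Y-chromosome reads play no part in the statistic.
#'
#' @param counts A tibble with columns `chrom`, `n_reads`, `length_bp`
#'   covering chromosomes 1-22 and X (a `chr` prefix is tolerated).
#' @return An object of class `rx_result`: a list with `ratios` (tibble:
#'   `chrom`, `ratio`), `rx`, `sd`, `ci_half_width`, `ci_low`, `ci_high`
#'   and `assignment` (see [assign_sex()]). Values are unrounded; rounding
#'   is presentation-only.
#' @export
#' @examples
#' counts <- simulate_chromosome_counts("female", 1e5, seed = 1)
#' compute_rx(counts)
compute_rx <- function(counts) {
  check_columns(counts, c("chrom", "n_reads", "length_bp"), "counts")
  counts <- counts %>% mutate(chrom = normalise_chrom(.data$chrom))
  autosomes <- as.character(1:22)
  missing <- setdiff(c(autosomes, "X"), counts$chrom)
  if (length(missing) > 0L) {
    abort(sprintf("`counts` is missing chromosome(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(counts$length_bp <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  x_row <- counts[counts$chrom == "X", ][1, ]
  auto <- counts[match(autosomes, counts$chrom), ]
  if (any(auto$n_reads == 0)) {
    abort("every autosome needs at least one read; X:autosome ratios are undefined otherwise")
  }
  x_density <- x_row$n_reads / x_row$length_bp
  ratios <- x_density / (auto$n_reads / auto$length_bp)
  rx <- mean(ratios)
  s <- sd(ratios)
  half <- 1.96 * s / sqrt(22)
  res <- structure(
    list(
      ratios = tibble(chrom = autosomes, ratio = ratios),
      rx = rx, sd = s,
      ci_half_width = half,
      ci_low = rx - half,
      ci_high = rx + half
    ),
    class = "rx_result"
  )
  res$assignment <- assign_sex(res)
  res
}

#' Assign biological sex from an Rx confidence interval
#'
#' The decision rule: male if the upper bound of the 95% CI is below 0.60,
#' female if the lower bound is above 0.80 (both strict), otherwise
#' inconclusive.
#'
#' @param rx_result An `rx_result` from [compute_rx()] or [rx_table()].
#' @return `"female"`, `"male"` or `"inconclusive"`.
#' @export
assign_sex <- function(rx_result) {
  stopifnot(inherits(rx_result, "rx_result"))
  if (rx_result$ci_high < 0.60) {
    "male"
  } else if (rx_result$ci_low > 0.80) {
    "female"
  } else {
    "inconclusive"
  }
}

#' Rx confidence bounds from summary statistics
#'
#' Recomputes the confidence half-width, bounds and sex assignment from a
#' reported (Rx, SD) pair — the arithmetic used when auditing published Rx
#' tables, where only the mean and standard deviation of the 22 ratios are
#' printed.
#'
#' @param rx Mean of the 22 X:autosome ratios.
#' @param sd Their sample standard deviation.
#' @return An `rx_result` (without per-chromosome ratios).
#' @export
#' @examples
#' rx_table(0.965, 0.231) # half-width 0.097 to 3 d.p.
rx_table <- function(rx, sd) {
  stopifnot(is.numeric(rx), is.numeric(sd), length(rx) == 1L,
            length(sd) == 1L, sd >= 0)
  half <- 1.96 * sd / sqrt(22)
  res <- structure(
    list(
      ratios = tibble(chrom = character(), ratio = numeric()),
      rx = rx, sd = sd,
      ci_half_width = half,
      ci_low = rx - half,
      ci_high = rx + half
    ),
    class = "rx_result"
  )
  res$assignment <- assign_sex(res)
  res
}

#' @export
print.rx_result <- function(x, ...) {
  cat(sprintf(
    "<rx_result> Rx %.3f (SD %.3f, 95%% CI %.3f-%.3f) -> %s\n",
    x$rx, x$sd, x$ci_low, x$ci_high, x$assignment
  ))
  invisible(x)
}

#' @rdname tidy_sparsekin
#' @export
tidy.rx_result <- function(x, ...) x$ratios

#' @rdname tidy_sparsekin
#' @export
glance.rx_result <- function(x, ...) {
  tibble(
    rx = x$rx, sd = x$sd, ci = x$ci_half_width,
    ci_low = x$ci_low, ci_high = x$ci_high,
    assignment = x$assignment
  )
}

#' @rdname autoplot_sparsekin
#' @export
autoplot.rx_result <- function(object, ...) {
  if (nrow(object$ratios) == 0L) {
    abort("this rx_result carries no per-chromosome ratios to plot")
  }
  dat <- object$ratios %>%
    mutate(chrom = factor(.data$chrom, levels = as.character(1:22)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$rx, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(0.60, 0.80), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = "autosome", y = "X : autosome ratio (length-normalised)",
      title = sprintf("Rx = %.3f (%s)", object$rx, object$assignment),
      subtitle = "dashed lines: 0.60 (male) / 0.80 (female) thresholds"
    ) +
    ggplot2::theme_minimal()
}
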