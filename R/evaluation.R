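#' Exact two-sided sign test on forced-choice counts
#'
#' For paired forced-choice wins `wins_a : wins_b` (no ties exist under a
#' forced choice), tests the fair-coin null by the exact binomial tail:
#' with `n = wins_a + wins_b` and `k = max(wins_a, wins_b)`,
#' `p = min(1, 2 * P[X >= k])` for `X ~ Binomial(n, 1/2)`, computed by
#' exact summation (no normal approximation).
#'
#' @param wins_a,wins_b nonnegative win counts of the two arms.
#' @return object of class `sign_test_result`: list with `p_two_sided`,
#'   `n`, `k`.
#' @export
sign_test <- function(wins_a, wins_b) {
  check_scalar(wins_a, "wins_a", 0, integerish = TRUE)
  check_scalar(wins_b, "wins_b", 0, integerish = TRUE)
  n <- as.integer(wins_a + wins_b)
  stop_if(n < 1L, "need at least one comparison")
  k <- as.integer(max(wins_a, wins_b))
  # P[X >= k] under Binomial(n, 1/2); pbinom sums the exact pmf
  tail <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  structure(list(p_two_sided = min(1, 2 * tail), n = n, k = k),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("Exact sign test: k = %d of n = %d, two-sided p = %.4g\n",
              x$k, x$n, x$p_two_sided))
  invisible(x)
}

#' Win percentage of the focus-stacked arm
#'
#' @param wins_a wins of the focus-stacked arm.
#' @param n total number of comparisons.
#' @return `100 * wins_a / n`, rounded to one decimal (the convention of
#'   the clinical summary tables).
#' @export
win_percentage <- function(wins_a, n) {
  check_scalar(wins_a, "wins_a", 0, integerish = TRUE)
  check_scalar(n, "n", 1, integerish = TRUE)
  stop_if(wins_a > n, "`wins_a` cannot exceed `n`")
  round(100 * wins_a / n, 1)
}

#' Objective paired evaluation of merged vs baseline images
#'
#' Runs the forced-choice Laplacian-energy comparison ([compare_pair()])
#' over a list of image pairs, aggregates the win counts, applies the exact
#' sign test, and summarises each arm's energy as mean and sample SD
#' (denominator `n - 1`). This reproduces the objective row of a
#' merged-vs-best-focused comparison table.
#'
#' @param pairs list of pairs; each element is a list (or length-2 list)
#'   with the merged image first and the baseline image second, both
#'   grayscale matrices of matching size.
#' @param label text label for the comparison.
#' @param kernel Laplacian kernel, see [laplacian_map()].
#' @return object of class `paired_evaluation`: list with `wins_a`,
#'   `wins_b`, `n`, `percentage_a`, `sign_test` (a `sign_test_result`),
#'   `energy_a` / `energy_b` (per-pair energies) and `summary`
#'   (one-row data frame mirroring the table row).
#' @export
evaluate_objective <- function(pairs, label = "Energy of Laplacian",
                               kernel = "4-neighbor") {
  stop_if(!is.list(pairs) || length(pairs) == 0L, "`pairs` must be a nonempty list")
  energy_a <- numeric(length(pairs))
  energy_b <- numeric(length(pairs))
  wins <- character(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    stop_if(length(pr) < 2L, "each pair needs two images")
    a <- pr[[1]]; b <- pr[[2]]
    wins[i] <- compare_pair(a, b, kernel)
    energy_a[i] <- laplacian_energy(a, kernel)
    energy_b[i] <- laplacian_energy(b, kernel)
  }
  wins_a <- sum(wins == "A"); wins_b <- sum(wins == "B")
  st <- sign_test(wins_a, wins_b)
  n <- length(pairs)
  summary <- data.frame(
    assessment = label,
    wins_merged = wins_a,
    wins_baseline = wins_b,
    percentage_merged = win_percentage(wins_a, n),
    p_value = st$p_two_sided,
    energy_merged_mean = mean(energy_a),
    energy_merged_sd = if (n > 1L) stats::sd(energy_a) else NA_real_,
    energy_baseline_mean = mean(energy_b),
    energy_baseline_sd = if (n > 1L) stats::sd(energy_b) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(wins_a = wins_a, wins_b = wins_b, n = n,
                 percentage_a = win_percentage(wins_a, n),
                 sign_test = st, energy_a = energy_a, energy_b = energy_b,
                 summary = summary, label = label),
            class = "paired_evaluation")
}

#' @export
print.paired_evaluation <- function(x, ...) {
  cat(sprintf("%s: %d : %d (%.1f%%), two-sided sign-test p = %.4g\n",
              x$label, x$wins_a, x$wins_b, x$percentage_a,
              x$sign_test$p_two_sided))
  cat(sprintf("  energy %.3f +/- %.3f (merged) vs %.3f +/- %.3f (baseline)\n",
              x$summary$energy_merged_mean, x$summary$energy_merged_sd,
              x$summary$energy_baseline_mean, x$summary$energy_baseline_sd))
  invisible(x)
}
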