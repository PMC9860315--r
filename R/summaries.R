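#' Median-based group summaries with bootstrap confidence intervals
#'
#' For each group: n, median, quartiles, and a seeded percentile-bootstrap
#' 95% confidence interval of the median (the summary style used for
#' per-worm behavioral metrics, which are typically skewed).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with columns `group`, `n`, `median`, `ci_lo`, `ci_hi`,
#'   `q1`, `q3`. Empty groups are excluded with a warning.
#' @export
summarize_groups <- function(values_by_group, conf = 0.95, n_boot = 2000,
                             seed = 1) {
  if (!is.list(values_by_group) || is.null(names(values_by_group))) {
    stop_input("`values_by_group` must be a named list")
  }
  keep <- lengths(values_by_group) > 0L
  if (any(!keep)) {
    warning("excluding empty group(s): ",
            paste(names(values_by_group)[!keep], collapse = ", "))
  }
  values_by_group <- values_by_group[keep]
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- lapply(names(values_by_group), function(g) {
      x <- values_by_group[[g]]
      boots <- vapply(seq_len(n_boot), function(b) {
        median(sample(x, replace = TRUE))
      }, numeric(1))
      qs <- quantile(x, c(0.25, 0.75), names = FALSE)
      ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      data.frame(group = g, n = length(x), median = median(x),
                 ci_lo = ci[1L], ci_hi = ci[2L], q1 = qs[1L], q3 = qs[2L])
    })
    do.call(rbind, rows)
  })
}
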