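#' Two-sample proportion z test on altered-step counts
#'
#' Compares the proportion of altered steps (steps whose folded interlimb
#' phase falls outside the control variability band) between two
#' conditions. The statistic is
#' z = (p2 - p1) / sqrt(p1 (1 - p1) / n1 + p2 (1 - p2) / n2)
#' with the unpooled standard error and no continuity correction; the
#' two-tailed p-value comes from the standard normal. A pooled-SE variant
#' is available via \code{pooled = TRUE}.
#'
#' @param x1,n1 altered and total step counts in the first condition.
#' @param x2,n2 altered and total step counts in the second condition.
#' @param pooled use the pooled standard error instead of the unpooled
#'   default.
#' @return object of class \code{prop_comparison}: list with counts,
#'   proportions \code{p1}, \code{p2}, \code{z} (sign follows
#'   \code{p2 - p1}) and two-tailed \code{p_value}.
#' @examples
#' two_proportion_z(26, 480, 135, 600)  # |z| = 8.57
#' @export
two_proportion_z <- function(x1, n1, x2, n2, pooled = FALSE) {
  counts <- c(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (n1 == 0 || n2 == 0) stop("sample sizes must be positive")
  if (x1 > n1 || x2 > n2) stop("altered count exceeds total count")
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (pooled) {
    pb <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  if (se == 0) {
    stop("standard error is zero (both proportions 0 or both 1); ",
         "z is undefined")
  }
  z <- (p2 - p1) / se
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
         p1 = p1, p2 = p2, z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         pooled = pooled),
    class = "prop_comparison"
  )
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-proportion z test (%s SE)\n  %d/%d [%.2f%%] vs %d/%d [%.2f%%]\n  z = %.2f, two-tailed p = %.4g\n",
    if (x$pooled) "pooled" else "unpooled",
    x$x1, x$n1, 100 * x$p1, x$x2, x$n2, 100 * x$p2,
    x$z, x$p_value
  ))
  invisible(x)
}

#' Tabulated proportion comparisons across limb pairs and contrasts
#'
#' Runs \code{\link{two_proportion_z}} on each row of a table of
#' altered/total counts, e.g. one row per (limb pair, condition contrast).
#' Rows whose statistic is undefined (zero standard error) are skipped
#' with a warning rather than aborting the report.
#'
#' @param counts data.frame with columns \code{x1}, \code{n1}, \code{x2},
#'   \code{n2}; any additional columns (pair, contrast, task labels) are
#'   carried through to the output.
#' @param pooled passed to \code{two_proportion_z}.
#' @return data.frame with the input label columns plus \code{pct1},
#'   \code{pct2} (percentages), \code{z} and \code{p_value}.
#' @examples
#' counts <- data.frame(pair = c("LR_fore", "LR_hind"),
#'                      x1 = c(26, 26), n1 = c(480, 480),
#'                      x2 = c(135, 177), n2 = c(600, 600))
#' proportion_report(counts)
#' @export
proportion_report <- function(counts, pooled = FALSE) {
  need <- c("x1", "n1", "x2", "n2")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("missing count columns: ", paste(miss, collapse = ", "))
  }
  label_cols <- setdiff(names(counts), need)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, , drop = FALSE]
    cmp <- tryCatch(
      two_proportion_z(r$x1, r$n1, r$x2, r$n2, pooled = pooled),
      error = function(e) {
        warning(sprintf("row %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(cmp)) return(NULL)
    cbind(
      r[, label_cols, drop = FALSE],
      data.frame(x1 = cmp$x1, n1 = cmp$n1, x2 = cmp$x2, n2 = cmp$n2,
                 pct1 = round(100 * cmp$p1, 2),
                 pct2 = round(100 * cmp$p2, 2),
                 z = cmp$z, p_value = cmp$p_value)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
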