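#' Rating table for reliability analysis
#'
#' Complete subjects x columns matrix of one measurement, where columns
#' are raters (inter-user design) or repetitions (intra-user design).
#'
#' @param x numeric matrix, rows = subjects (n >= 2), columns = raters or
#'   repeats (k >= 2); no missing cells.
#' @param label free text (measurement name, condition).
#' @return object of class `rating_table`.
#' @export
rating_table <- function(x, label = "") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("rating table needs >= 2 subjects and >= 2 columns",
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("rating table has missing or non-finite cells", call. = FALSE)
  structure(list(x = x, n = nrow(x), k = ncol(x),
                 label = as.character(label)),
            class = "rating_table")
}

#' Two-way crossed ANOVA mean squares (no replication)
#'
#' Decomposes a rating table into between-subject (rows), between-column
#' (raters/repeats) and residual mean squares, the building blocks of the
#' agreement intraclass correlation.
#'
#' @param tab a [rating_table] (or plain matrix).
#' @return list with `MSR`, `MSC`, `MSE`, degrees of freedom `dfR`,
#'   `dfC`, `dfE`, and `degenerate` (`TRUE` when the total sum of squares
#'   is zero, leaving the ICC undefined).
#' @export
anova_mean_squares <- function(tab) {
  if (!inherits(tab, "rating_table")) tab <- rating_table(tab)
  x <- tab$x; n <- tab$n; k <- tab$k
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  sse <- max(sse, 0)                    # guard tiny negative round-off
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)),
       dfR = n - 1L, dfC = k - 1L, dfE = (n - 1L) * (k - 1L),
       degenerate = sst < 1e-24 * max(1, grand^2))
}

#' Absolute-agreement single-rater intraclass correlation
#'
#' Two-way model ICC for absolute agreement of single measurements
#' (ICC(A,1) in the McGraw & Wong taxonomy).  The same computational form
#' serves the random-effects model (raters sampled from a population;
#' inter-user design) and the mixed-effects model (fixed raters;
#' intra-user repetitions) -- the `model` tag records the intended
#' interpretation.  The 95% confidence interval is the F-based interval
#' with Satterthwaite-approximated denominator degrees of freedom.
#'
#' @param tab a [rating_table] (or matrix).
#' @param model `"random"` (inter-user) or `"mixed"` (intra-user).
#' @param alpha two-sided error rate for the confidence interval.
#' @return object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `model`, `form`, `alpha`, `n`, `k`, `label`.
#' @export
icc_agreement_single <- function(tab, model = c("random", "mixed"),
                                 alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(alpha > 0, alpha < 1)
  if (!inherits(tab, "rating_table")) tab <- rating_table(tab)
  ms <- anova_mean_squares(tab)
  if (ms$degenerate)
    stop("ICC undefined: rating table has zero total variance",
         call. = FALSE)
  n <- tab$n; k <- tab$k
  msr <- ms$MSR; msc <- ms$MSC; mse <- ms$MSE
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # Satterthwaite df for the denominator of the CI pivot; in the
  # MSE -> 0 limit the df tend to k - 1 and the interval formulas below
  # remain finite, so only v needs the special case
  if (mse <= 0 || est >= 1) {
    v <- k - 1
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    fj <- msc / mse
    v <- (a * fj + b)^2 /
      ((a^2 * fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  }
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  ci <- c(lo, hi)
  structure(list(estimate = est, ci_low = min(ci[1], est),
                 ci_high = max(ci[2], est),
                 model = model, form = "absolute-agreement,single-rater",
                 alpha = alpha, n = n, k = k, label = tab$label),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) [%s] %s= %.4f (%.0f%% CI %.4f-%.4f), n=%d k=%d -> %s\n",
    x$model, if (nzchar(x$label)) paste0(x$label, " ") else "",
    x$estimate, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n, x$k,
    classify_icc(x$estimate)))
  invisible(x)
}

#' Classify an ICC estimate into the standard reliability bands
#'
#' Below 0.5: poor; 0.5 to below 0.75: moderate; 0.75 to below 0.9:
#' good; 0.9 and above: excellent.
#'
#' @param estimate ICC point estimate(s), each <= 1.
#' @return character vector of band labels.
#' @export
classify_icc <- function(estimate) {
  if (any(estimate > 1 + 1e-12))
    stop("ICC estimate exceeds 1", call. = FALSE)
  cut_lab <- c("poor", "moderate", "good", "excellent")
  idx <- findInterval(estimate, c(0.5, 0.75, 0.9)) + 1L
  cut_lab[idx]
}

#' Subjects needed for an ICC reliability study
#'
#' Closed-form sample size for testing H0: ICC = `rho0` against the
#' expected ICC `rho1` with `k` raters (Walter, Eliasziw & Donner):
#' \deqn{n = 1 + \frac{2k(z_{1-\alpha/2}+z_{power})^2}{(k-1)(\ln C_0)^2}}
#' with \eqn{C_0 = \frac{1 + k\rho_0/(1-\rho_0)}{1 + k\rho_1/(1-\rho_1)}},
#' rounded up to the next integer.
#'
#' @param rho0 minimum acceptable reliability (null), in (0, 1).
#' @param rho1 expected reliability, in (`rho0`, 1).
#' @param k raters or repetitions per subject (>= 2).
#' @param alpha two-tailed significance level.
#' @param power target power, in (0, 1).
#' @return required number of subjects (integer).
#' @export
icc_sample_size <- function(rho0, rho1, k, alpha = 0.05, power = 0.80) {
  if (!(rho0 > 0 && rho0 < 1) || !(rho1 > 0 && rho1 < 1))
    stop("rho0 and rho1 must lie in (0, 1)", call. = FALSE)
  if (rho1 <= rho0)
    stop("expected reliability rho1 must exceed rho0", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  c0 <- (1 + k * rho0 / (1 - rho0)) / (1 + k * rho1 / (1 - rho1))
  as.integer(ceiling(1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)))
}

# ---- study panels ---------------------------------------------------------

#' Assemble a long-format measurement panel
#'
#' @param reports list of `measurement_report`s.
#' @param subject,rater,repetition,condition vectors parallel to
#'   `reports` identifying each cell of the study design.
#' @return long data.frame with columns `subject`, `rater`,
#'   `repetition`, `condition`, `measurement`, `value`.
#' @export
panel_from_reports <- function(reports, subject, rater, repetition,
                               condition) {
  stopifnot(length(reports) == length(subject),
            length(reports) == length(rater),
            length(reports) == length(repetition),
            length(reports) == length(condition))
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(subject = as.character(subject[i]),
               rater = as.character(rater[i]),
               repetition = as.integer(repetition[i]),
               condition = as.character(condition[i]),
               measurement = names(r), value = as.numeric(r),
               stringsAsFactors = FALSE)
  }))
}

#' Per-measurement ICC tables for a reliability study panel
#'
#' Builds one subjects x columns [rating_table] per measurement and
#' condition and analyses it with [icc_agreement_single()].  The
#' intra-user design (one rater, >= 2 repetitions; columns = repetitions)
#' uses the mixed-effects model; the inter-user design (>= 2 raters, one
#' repetition; columns = raters) uses the random-effects model.  The
#' design must be complete; missing cells are an error naming the absent
#' combinations.
#'
#' @param panel long data.frame as from [panel_from_reports()] or
#'   [read_panel()].
#' @param design `"intra"` or `"inter"`.
#' @param alpha CI error rate.
#' @return data.frame with one row per measurement x condition:
#'   `measurement`, `condition`, `model`, `n`, `k`, `estimate`,
#'   `ci_low`, `ci_high`, `class`.
#' @export
reliability_table <- function(panel, design = c("inter", "intra"),
                              alpha = 0.05) {
  design <- match.arg(design)
  need <- c("subject", "rater", "repetition", "condition",
            "measurement", "value")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (design == "intra") {
    raters <- unique(panel$rater)
    if (length(raters) != 1L)
      panel <- panel[panel$rater == raters[1], , drop = FALSE]
    colvar <- "repetition"; model <- "mixed"
  } else {
    reps <- sort(unique(panel$repetition))
    panel <- panel[panel$repetition == reps[1], , drop = FALSE]
    colvar <- "rater"; model <- "random"
  }
  out <- list()
  for (cond in unique(panel$condition)) {
    pc <- panel[panel$condition == cond, , drop = FALSE]
    for (m in unique(pc$measurement)) {
      pm <- pc[pc$measurement == m, , drop = FALSE]
      subj <- sort(unique(pm$subject))
      cols <- sort(unique(pm[[colvar]]))
      key <- paste(pm$subject, pm[[colvar]])
      want <- as.vector(outer(subj, cols, paste))
      absent <- setdiff(want, key)
      if (length(absent))
        stop("incomplete panel for ", m, " / ", cond,
             ": missing cell(s) [subject ", colvar, "]: ",
             paste(absent, collapse = "; "), call. = FALSE)
      mat <- matrix(pm$value[match(want, key)],
                    nrow = length(subj),
                    dimnames = list(subj, cols))
      res <- icc_agreement_single(
        rating_table(mat, label = paste(m, cond)),
        model = model, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        measurement = m, condition = cond, model = model,
        n = res$n, k = res$k, estimate = res$estimate,
        ci_low = res$ci_low, ci_high = res$ci_high,
        class = classify_icc(res$estimate),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read / write long-format study panels
#'
#' CSV with columns `subject,rater,repetition,condition,measurement,value`.
#'
#' @param path file path.
#' @return `read_panel`: the panel data.frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "rater", "repetition", "condition",
            "measurement", "value")
  if (!all(need %in% names(df)))
    stop("panel CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df
}

#' @param panel panel data.frame.
#' @rdname read_panel
#' @return `write_panel`: `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
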