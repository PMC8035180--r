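#' Stack scattered samples onto a regular age grid with LOESS
#'
#' Pools all samples (across sections) and fits a locally weighted linear
#' regression (tricube kernel, degree 1) of value against age, evaluated at
#' each gridpoint with its standard error. Gridpoints outside the data span
#' are returned as missing values, never extrapolated. If `span` is not
#' supplied it is chosen by k-fold cross-validation over `span_grid` (see
#' [select_span_cv()]).
#'
#' @param samples Data frame with `age_ma` and `value` columns (any number
#'   of sections pooled); at least 10 rows.
#' @param grid Age grid (Ma, decreasing), e.g. from [make_age_grid()].
#'   Default: a 0.002 Myr grid spanning the data.
#' @param span LOESS span in (0, 1]; `NULL` to select by cross-validation.
#' @param cv_folds,span_grid Passed to [select_span_cv()] when `span` is
#'   `NULL`.
#' @return Data frame of class `"stacked_curve"`: `age_ma`, `center`, `se`,
#'   `n_local` (number of samples with non-zero local weight). The chosen
#'   `span` (and the CV table, if run) are attached as attributes.
#' @examples
#' x <- seq(252.2, 252.0, by = -0.005)
#' s <- data.frame(age_ma = x, value = 2 + 3 * (252.2 - x))
#' st <- fit_stack(s, span = 0.5)
#' max(abs(st$center - (2 + 3 * (252.2 - st$age_ma))))  # ~1e-12
#' @export
fit_stack <- function(samples, grid = NULL, span = NULL, cv_folds = 5,
                      span_grid = exp(seq(log(0.1), log(1), length.out = 8))) {
  stopifnot(all(c("age_ma", "value") %in% names(samples)))
  samples <- samples[is.finite(samples$age_ma) & is.finite(samples$value), ]
  if (nrow(samples) < 10L)
    stop("need at least 10 samples spanning the grid; got ", nrow(samples))
  if (is.null(grid))
    grid <- make_age_grid(max(samples$age_ma), min(samples$age_ma))
  cv_tab <- NULL
  if (is.null(span)) {
    cv_tab <- select_span_cv(samples, span_grid = span_grid, k = cv_folds)
    span <- cv_tab$span[which.min(cv_tab$cv_mse)]
  }
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")

  fit <- stats::loess(value ~ age_ma, data = samples, span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  inside <- grid >= min(samples$age_ma) & grid <= max(samples$age_ma)
  center <- se <- rep(NA_real_, length(grid))
  if (any(inside)) {
    pr <- stats::predict(fit, newdata = data.frame(age_ma = grid[inside]),
                         se = TRUE)
    center[inside] <- pr$fit
    se[inside] <- pr$se.fit
  }
  n <- nrow(samples)
  k <- max(2L, ceiling(span * n))
  n_local <- integer(length(grid))
  for (i in which(inside)) {
    d <- abs(samples$age_ma - grid[i])
    h <- sort(d, partial = k)[k]
    n_local[i] <- sum(d <= h)
  }
  out <- data.frame(age_ma = grid, center = center, se = se,
                    n_local = n_local)
  attr(out, "span") <- span
  attr(out, "cv") <- cv_tab
  class(out) <- c("stacked_curve", "data.frame")
  out
}

#' Choose a LOESS span by k-fold cross-validation
#'
#' Folds are assigned deterministically by interleaving samples in age order
#' (every k-th sample shares a fold), so the selection is reproducible
#' without a seed. For each candidate span the held-out squared prediction
#' error is averaged; spans whose local fit fails are scored `Inf`.
#'
#' @param samples Data frame with `age_ma` and `value`.
#' @param span_grid Candidate spans (default: 8 log-spaced values in
#'   `[0.1, 1]`).
#' @param k Number of folds (default 5).
#' @return Data frame with columns `span` and `cv_mse`.
#' @export
select_span_cv <- function(samples,
                           span_grid = exp(seq(log(0.1), log(1),
                                               length.out = 8)),
                           k = 5) {
  ord <- order(samples$age_ma)
  fold <- integer(nrow(samples))
  fold[ord] <- rep_len(seq_len(k), nrow(samples))
  cv <- vapply(span_grid, function(sp) {
    sse <- 0; m <- 0L
    for (f in seq_len(k)) {
      tr <- samples[fold != f, , drop = FALSE]
      te <- samples[fold == f, , drop = FALSE]
      te <- te[te$age_ma >= min(tr$age_ma) & te$age_ma <= max(tr$age_ma), ,
               drop = FALSE]
      if (nrow(te) == 0L) next
      pred <- tryCatch(suppressWarnings({
        ft <- stats::loess(value ~ age_ma, data = tr, span = sp, degree = 1,
                           control = stats::loess.control(surface = "direct"))
        stats::predict(ft, newdata = te)
      }), error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) return(Inf)
      sse <- sse + sum((pred - te$value)^2)
      m <- m + nrow(te)
    }
    if (m == 0L) Inf else sse / m
  }, numeric(1))
  data.frame(span = span_grid, cv_mse = cv)
}

#' Robustness refits of a stacked curve
#'
#' Two perturbation schemes for checking that the stack is not driven by a
#' single section or by uneven sampling: `subsample80` refits on random
#' subsets of the pooled samples (default fraction 0.8, seeded), and
#' `leave_section_out` refits once per excluded section. Refits left with
#' fewer than 10 samples are skipped with a message.
#'
#' @param samples Pooled samples; `leave_section_out` additionally requires
#'   a `section_id` column.
#' @param grid Age grid (Ma, decreasing); default as in [fit_stack()].
#' @param mode `"subsample80"` or `"leave_section_out"`.
#' @param n_reps Number of random subsamples (ignored for
#'   `leave_section_out`).
#' @param seed Integer seed for the random subsets.
#' @param fraction Subsample fraction (default 0.8; 1.0 reproduces the full
#'   fit).
#' @param span LOESS span shared by all refits; `NULL` selects by CV on the
#'   full data once and reuses it.
#' @return List of class `"stack_refits"`: `curves` (named list of
#'   `"stacked_curve"`), `mode`, `span`, `skipped`.
#' @export
robustness_refits <- function(samples, grid = NULL,
                              mode = c("subsample80", "leave_section_out"),
                              n_reps = 20, seed = 1L, fraction = 0.8,
                              span = NULL) {
  mode <- match.arg(mode)
  if (is.null(grid))
    grid <- make_age_grid(max(samples$age_ma), min(samples$age_ma))
  if (is.null(span)) {
    cv <- select_span_cv(samples)
    span <- cv$span[which.min(cv$cv_mse)]
  }
  curves <- list(); skipped <- character()
  if (mode == "subsample80") {
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    set.seed(seed)
    m <- round(fraction * nrow(samples))
    for (r in seq_len(n_reps)) {
      idx <- sort(sample.int(nrow(samples), m))
      nm <- sprintf("subsample_%03d", r)
      if (m < 10L) {
        message("refit '", nm, "' skipped: fewer than 10 samples")
        skipped <- c(skipped, nm); next
      }
      curves[[nm]] <- fit_stack(samples[idx, , drop = FALSE], grid,
                                span = span)
    }
  } else {
    if (!"section_id" %in% names(samples))
      stop("'leave_section_out' requires a 'section_id' column")
    for (sec in unique(samples$section_id)) {
      keep <- samples[samples$section_id != sec, , drop = FALSE]
      nm <- paste0("without_", sec)
      if (nrow(keep) < 10L) {
        message("refit '", nm, "' skipped: fewer than 10 samples")
        skipped <- c(skipped, nm); next
      }
      curves[[nm]] <- fit_stack(keep, grid, span = span)
    }
  }
  structure(list(curves = curves, mode = mode, span = span,
                 skipped = skipped),
            class = "stack_refits")
}

#' @export
print.stacked_curve <- function(x, ...) {
  cat(sprintf("Stacked curve: %d gridpoints, span = %s, %d missing\n",
              nrow(x),
              format(attr(x, "span")), sum(!is.finite(x$center))))
  NextMethod()
}

#' @export
plot.stacked_curve <- function(x, add_band = TRUE, ...) {
  ok <- is.finite(x$center)
  plot(x$age_ma[ok], x$center[ok], type = "l", xlim = rev(range(x$age_ma)),
       xlab = "Age (Ma)", ylab = "value", ...)
  if (add_band) {
    graphics::lines(x$age_ma[ok], x$center[ok] + x$se[ok], lty = 3)
    graphics::lines(x$age_ma[ok], x$center[ok] - x$se[ok], lty = 3)
  }
  invisible(x)
}
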