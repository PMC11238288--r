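#' Analysis of variance for a fitted response surface
#'
#' Produces the standard response-surface ANOVA: adjusted (type-III) sums of
#' squares for every model term and for the grouped sources (linear, square,
#' two-way interaction), the pooled residual, and the lack-of-fit /
#' pure-error split. The adjusted SS of a term (or group) is the increase in
#' residual SS when that term (group) is dropped from the full model; each
#' F statistic divides the source's mean square by the pooled error mean
#' square, and lack-of-fit is tested against pure error. Pure error is
#' computed from exact-replicate design points (the centre runs in a standard
#' CCD); when the design has no replicates the lack-of-fit rows are omitted.
#'
#' The returned table also carries the R-squared family — ordinary, adjusted
#' and PRESS-based predicted — as attributes, printed as a footer.
#'
#' @param object A fitted `"rsm"` model.
#' @param ... Unused.
#' @return A data frame of class `"rsm_anova"` with columns `source`, `df`,
#'   `adj_ss`, `adj_ms`, `f_value`, `p_value`, and attributes `r.squared`,
#'   `adj.r.squared`, `pred.r.squared`, `response`.
#' @examples
#' pj <- parsley_juice()
#' fit <- rsm(chlorophyll ~ time + amplitude + temperature,
#'            data = pj, factors = parsley_factors())
#' anova(fit)
#' @export
anova.rsm <- function(object, ...) {
  X <- object$model_matrix
  y <- object$y
  n <- length(y)
  p <- ncol(X)
  k <- length(object$factors)
  nm <- names(object$factors)

  sse_full <- sum(object$residuals^2)
  sst <- sum((y - mean(y))^2)
  ss_model <- sst - sse_full
  df_model <- p - 1
  df_error <- n - p
  ms_error <- sse_full / df_error

  drop_ss <- function(cols) {
    keep <- setdiff(seq_len(p), cols)
    sub <- stats::lm.fit(X[, keep, drop = FALSE], y)
    sum(sub$residuals^2) - sse_full
  }

  lin_idx <- 1 + seq_len(k)
  groups <- list()
  if (object$order == 2) {
    sq_idx <- 1 + k + seq_len(k)
    ia_idx <- setdiff(seq_len(p), c(1, lin_idx, sq_idx))
    groups <- list(
      list(label = "linear", idx = lin_idx, members = lin_idx),
      list(label = "square", idx = sq_idx, members = sq_idx),
      list(label = "2-way interaction", idx = ia_idx, members = ia_idx)
    )
  } else {
    groups <- list(list(label = "linear", idx = lin_idx, members = lin_idx))
  }

  rows <- list()
  add_row <- function(source, df, ss, with_f = TRUE) {
    ms <- ss / df
    f <- if (with_f && df_error > 0) ms / ms_error else NA_real_
    pv <- if (is.na(f)) NA_real_ else
      stats::pf(f, df, df_error, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, df = df, adj_ss = ss, adj_ms = ms,
      f_value = f, p_value = pv, stringsAsFactors = FALSE)
  }

  add_row("model", df_model, ss_model)
  for (g in groups) {
    add_row(g$label, length(g$idx), drop_ss(g$idx))
    for (j in g$members) add_row(colnames(X)[j], 1L, drop_ss(j))
  }

  # residual and its lack-of-fit / pure-error split
  rows[[length(rows) + 1L]] <- data.frame(
    source = "error", df = df_error, adj_ss = sse_full,
    adj_ms = ms_error, f_value = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)

  key <- apply(round(object$coded, 10), 1, paste, collapse = "/")
  reps <- split(y, key)
  ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
  df_pe <- n - length(reps)
  if (df_pe > 0 && df_error > df_pe) {
    df_lof <- df_error - df_pe
    ss_lof <- sse_full - ss_pe
    ms_pe <- ss_pe / df_pe
    f_lof <- (ss_lof / df_lof) / ms_pe
    rows[[length(rows) + 1L]] <- data.frame(
      source = "lack-of-fit", df = df_lof, adj_ss = ss_lof,
      adj_ms = ss_lof / df_lof, f_value = f_lof,
      p_value = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      source = "pure error", df = df_pe, adj_ss = ss_pe, adj_ms = ms_pe,
      f_value = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    source = "total", df = n - 1L, adj_ss = sst, adj_ms = NA_real_,
    f_value = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  s <- summary(object)
  structure(out, class = c("rsm_anova", "data.frame"),
            r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
            pred.r.squared = s$pred.r.squared, response = object$response)
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("Analysis of variance —", attr(x, "response"), "\n\n")
  disp <- data.frame(
    source = format(x$source, width = max(nchar(x$source))),
    DF = x$df,
    `adj SS` = sprintf("%10.2f", x$adj_ss),
    `adj MS` = ifelse(is.na(x$adj_ms), "", sprintf("%10.2f", x$adj_ms)),
    `F value` = ifelse(is.na(x$f_value), "", sprintf("%9.2f", x$f_value)),
    `P value` = ifelse(is.na(x$p_value), "", sprintf("%6.3f", x$p_value)),
    check.names = FALSE)
  print(disp, row.names = FALSE, right = TRUE)
  cat(sprintf("\nR-sq %.2f%%   adj R-sq %.2f%%   pred R-sq %.2f%%\n",
              100 * attr(x, "r.squared"), 100 * attr(x, "adj.r.squared"),
              100 * attr(x, "pred.r.squared")))
  invisible(x)
}
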