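#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition with the percentile group (decile) as the
#' repeated factor and the donor as the subject: the total sum of squares
#' splits into a subject term (absorbed), the decile effect, and the
#' subject x decile residual. `F = MS_effect / MS_error`, and the reported
#' effect size is partial eta squared,
#' `R2 = SS_effect / (SS_effect + SS_error)` (stated explicitly because the
#' convention is not universal). Decile levels missing in any donor are
#' dropped (complete-case on levels) and reported.
#'
#' @param table long data.frame with columns `donor`, `level` (or `decile`),
#'   `value`; or a donor x level numeric matrix.
#' @return an `rm_anova_result` list: `F`, `df_effect`, `df_error`, `p`,
#'   `R2`, `cell_means`, `dropped_levels`, `n_subjects`.
#' @export
rm_anova <- function(table) {
  if (is.matrix(table)) {
    table <- data.frame(donor = rep(rownames(table) %||% seq_len(nrow(table)),
                                    ncol(table)),
                        level = rep(colnames(table) %||% seq_len(ncol(table)),
                                    each = nrow(table)),
                        value = as.vector(table))
  }
  if ("decile" %in% names(table) && !"level" %in% names(table))
    names(table)[names(table) == "decile"] <- "level"
  table <- table[, c("donor", "level", "value")]
  table <- table[complete.cases(table), ]
  wide <- tapply(table$value, list(table$donor, table$level), mean)
  complete <- colSums(is.na(wide)) == 0
  dropped <- colnames(wide)[!complete]
  y <- wide[, complete, drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (k < 2L) stop("fewer than 2 complete decile levels (",
                   length(dropped), " dropped)")
  if (n < 2L) stop("need at least 2 subjects")
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_subject <- k * sum((row_m - grand)^2)
  ss_effect <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_error <- sum(resid^2)
  df_effect <- k - 1
  df_error <- (n - 1) * (k - 1)
  ms_error <- ss_error / df_error
  Fv <- if (ms_error > 0) (ss_effect / df_effect) / ms_error
        else if (ss_effect == 0) 0 else Inf
  p <- pf(Fv, df_effect, df_error, lower.tail = FALSE)
  denom <- ss_effect + ss_error
  structure(list(F = Fv, df_effect = df_effect, df_error = df_error, p = p,
                 R2 = if (denom > 0) ss_effect / denom else 0,
                 cell_means = col_m,
                 ss = c(subject = ss_subject, effect = ss_effect,
                        error = ss_error),
                 dropped_levels = dropped, n_subjects = n),
            class = "rm_anova_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f (%d subjects)\n",
              x$df_effect, x$df_error, x$F, x$p, x$R2, x$n_subjects))
  if (length(x$dropped_levels))
    cat("  dropped incomplete levels:", paste(x$dropped_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at `alpha_normality`; if both pass, an
#' equal-variance two-tailed Student's t test, otherwise a two-sided
#' Mann-Whitney U test. A constant group cannot pass a normality test and
#' routes to the rank test, except when both groups are constant and equal,
#' which is reported as the degenerate branch with p = 1.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alpha_normality normality gate level.
#' @return list: `test` (`"t-test"`, `"mann-whitney"` or `"degenerate"`),
#'   `statistic`, `p`, `shapiro_p` (length 2).
#' @export
two_group_test <- function(a, b, alpha_normality = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(test = "degenerate", statistic = 0, p = 1,
                  shapiro_p = c(NA_real_, NA_real_)))
  }
  sw <- function(x) tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  spa <- sw(a); spb <- sw(b)
  if (spa > alpha_normality && spb > alpha_normality) {
    ht <- t.test(a, b, var.equal = TRUE)
    list(test = "t-test", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = c(spa, spb))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    list(test = "mann-whitney", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = c(spa, spb))
  }
}

#' Lane-intensity normalization and one-tailed test
#'
#' Each antibody's lane totals are divided by the mean of the control lanes
#' (so the normalized control mean is 1 by construction), then cases are
#' compared to controls with a one-tailed Student's t test in the stated
#' direction, flagged at p < 0.05 and p < 0.01.
#'
#' @param table data.frame with columns `sample`, `group` (`control`/`case`),
#'   `antibody`, `intensity`.
#' @param direction alternative for cases vs controls: `"greater"` or
#'   `"less"`.
#' @return data.frame per antibody: `t`, `df`, `p`, `sig_05`, `sig_01`,
#'   with the normalized values in attribute `"normalized"`.
#' @export
lane_normalize_and_test <- function(table, direction = "greater") {
  stopifnot(all(c("sample", "group", "antibody", "intensity") %in% names(table)))
  if (!any(table$group == "case")) stop("no case lanes")
  res <- lapply(split(table, table$antibody), function(d) {
    ctrl <- d$intensity[d$group == "control"]
    if (!length(ctrl)) stop("no control lanes for ", d$antibody[1])
    if (mean(ctrl) <= 0) stop("control mean must be > 0")
    d$normalized <- d$intensity / mean(ctrl)
    ht <- t.test(d$normalized[d$group == "case"],
                 d$normalized[d$group == "control"],
                 alternative = direction, var.equal = TRUE)
    list(norm = d,
         row = data.frame(antibody = d$antibody[1],
                          t = unname(ht$statistic),
                          df = unname(ht$parameter), p = ht$p.value,
                          sig_05 = ht$p.value < 0.05,
                          sig_01 = ht$p.value < 0.01,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "normalized") <- do.call(rbind, lapply(res, `[[`, "norm"))
  out
}

#' Simulate a donor x decile NFT-fraction cohort
#'
#' Table-level generator matching the scene model's NFT law: in each
#' donor x decile cell, `neurons_per_cell` neurons are each NFT-positive
#' with probability `clamp(base_prob + donor_effect + slope * (decile-1)/9,
#' 0, 1)`; the cell value is the percent positive. With `slope = 0` this is
#' the null cohort used for type-I-error checks.
#'
#' @param n_donors subjects.
#' @param n_deciles repeated levels.
#' @param neurons_per_cell binomial size per cell.
#' @param base_prob baseline NFT probability.
#' @param slope increase in probability from decile 1 to decile `n_deciles`.
#' @param donor_sd SD of the per-donor probability shift.
#' @return long data.frame `donor`, `decile`, `value` (percent).
#' @export
simulate_nft_cohort <- function(n_donors = 6, n_deciles = 10,
                                neurons_per_cell = 40, base_prob = 0.05,
                                slope = 0, donor_sd = 0.02) {
  donor_eff <- rnorm(n_donors, 0, donor_sd)
  grid <- expand.grid(donor = seq_len(n_donors), decile = seq_len(n_deciles))
  p <- pmin(pmax(base_prob + donor_eff[grid$donor] +
                   slope * (grid$decile - 1) / (n_deciles - 1), 0), 1)
  data.frame(donor = paste0("donor", grid$donor), decile = grid$decile,
             value = 100 * rbinom(nrow(grid), neurons_per_cell, p) / neurons_per_cell,
             stringsAsFactors = FALSE)
}
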