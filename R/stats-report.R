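# Normality-gated paired inference, repeated-measures comparisons,
# multiple-testing adjustment, and report assembly.

test_result <- function(test_name, statistic, p_value, n,
                        normality_p = NA_real_, p_adjusted = NA_real_,
                        ...) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), p_adjusted = p_adjusted, n = n,
         normality_p = normality_p, ...),
    class = "pyloric_test")
}

#' @export
print.pyloric_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Classifies a sample (typically paired differences) as `"normal"` when
#' the Shapiro-Wilk p-value exceeds `alpha`, routing downstream paired
#' comparisons to a parametric or non-parametric test. A zero-variance
#' sample is degenerate and returned as `"non_normal"` with a warning.
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Gate level (default 0.05).
#' @return A list: `state` (`"normal"`/`"non_normal"`) and `p`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("normality gate needs n >= 3", call. = FALSE)
  if (sd(x) == 0) {
    warning("zero-variance sample: normality test degenerate")
    return(list(state = "non_normal", p = NA_real_))
  }
  p <- shapiro.test(x)$p.value
  list(state = if (p > alpha) "normal" else "non_normal", p = p)
}

#' Normality-gated paired comparison
#'
#' Tests paired differences with a two-sided paired Student's t-test when
#' the differences pass the Shapiro-Wilk gate, and with a two-sided
#' Wilcoxon signed-rank test (normal approximation) otherwise. Samples
#' whose differences are all exactly zero return a degenerate Wilcoxon
#' result (statistic 0, p = 1) with a warning.
#'
#' @param a,b Paired numeric vectors of equal length (`n >= 3`).
#' @param alpha Gate level passed to [normality_gate()].
#' @return A `pyloric_test` result with fields `test_name`
#'   (`"paired_t"` or `"wilcoxon_signed_rank"`), `statistic`, `p_value`,
#'   `n`, `normality_p`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired",
                                   call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  d <- a - b
  if (length(d) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (all(d == 0)) {
    warning("all paired differences are zero; returning degenerate result")
    return(test_result("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                       n = length(d)))
  }
  gate <- normality_gate(d, alpha = alpha)
  if (gate$state == "normal") {
    tt <- t.test(a, b, paired = TRUE)
    test_result("paired_t", tt$statistic, tt$p.value, length(d),
                normality_p = gate$p)
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
    test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value,
                length(d), normality_p = gate$p)
  }
}

#' One-way repeated-measures ANOVA with Tukey HSD contrasts
#'
#' Fits the within-subject one-way design as a randomized complete block
#' (`value ~ condition + subject`); with one observation per cell this F
#' statistic equals the one-way repeated-measures F with degrees of
#' freedom `(k - 1, (k - 1)(n - 1))`. When the omnibus test is
#' significant at `alpha`, Tukey Honestly Significant Difference
#' pairwise contrasts over conditions are appended.
#'
#' @param values Numeric responses.
#' @param condition Condition factor (every subject in every condition).
#' @param subject Subject/preparation identifier.
#' @param alpha Omnibus significance level gating the contrasts
#'   (default 0.05).
#' @return A list of class `rm_anova`: `f_statistic`, `df1`, `df2`,
#'   `p_value`, `n_subjects`, `n_conditions`, and `tukey` (data frame of
#'   contrasts with adjusted p-values, or `NULL` when the omnibus F is
#'   not significant).
#' @export
rm_anova_tukey <- function(values, condition, subject, alpha = 0.05) {
  condition <- factor(condition)
  subject <- factor(subject)
  if (nlevels(condition) < 2L) {
    stop("need at least two conditions", call. = FALSE)
  }
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  cells <- table(subject, condition)
  if (any(cells != 1L)) {
    stop("design must be complete: each subject once in every condition",
         call. = FALSE)
  }
  dat <- data.frame(y = values, condition = condition, subject = subject)
  fit <- aov(y ~ condition + subject, data = dat)
  tab <- summary(fit)[[1]]
  i <- grep("^condition", trimws(rownames(tab)))
  f <- tab[i, "F value"]
  p <- tab[i, "Pr(>F)"]
  tukey <- NULL
  if (is.finite(p) && p < alpha) {
    th <- TukeyHSD(fit, which = "condition")$condition
    tukey <- data.frame(contrast = rownames(th), diff = th[, "diff"],
                        lwr = th[, "lwr"], upr = th[, "upr"],
                        p_adj = th[, "p adj"], row.names = NULL)
  }
  structure(
    list(f_statistic = f, df1 = tab[i, "Df"],
         df2 = tab[nrow(tab), "Df"], p_value = p,
         n_subjects = nlevels(subject), n_conditions = nlevels(condition),
         tukey = tukey),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD contrasts:\n")
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with the test-family size `m` fixed in
#' advance (ten by default: five phases in each of two conditions).
#'
#' @param p_values Numeric p-values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = 10) {
  if (m < length(p_values)) {
    stop("`m` must be at least the number of tests", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors, `n >= 3`, non-degenerate.
#' @return A `pyloric_test` with `test_name = "pearson"`, the
#'   correlation as `statistic` (also under `r`), a two-sided `p_value`,
#'   and `df`.
#' @export
pearson_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero-variance input: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  test_result("pearson", ct$estimate, ct$p.value, length(x),
              r = unname(ct$estimate), df = unname(ct$parameter))
}

# ---- report assembly --------------------------------------------------

as_report_section <- function(x) {
  if (inherits(x, "phase_summary")) {
    return(list(phases = x$phases,
                delay_pdoff_lpon = x$delay_pdoff_lpon,
                pd_duration_ms = x$pd_duration_ms,
                duty_cycle = as.list(x$duty_cycle),
                n_cycles = x$n_cycles))
  }
  if (inherits(x, "jag_classification")) {
    return(list(p_dec_during_inc = x$p_dec_during_inc,
                p_inc_during_stable = x$p_inc_during_stable,
                n_increasing = x$n_increasing, n_stable = x$n_stable,
                thresholds = list(theta_T = x$theta_T,
                                  theta_f = x$theta_f,
                                  w_f = x$w_f, w_T = x$w_T)))
  }
  if (inherits(x, c("q10_fit", "phase_slope_fit", "pyloric_test",
                    "rm_anova", "ih_measurement"))) {
    return(unclass(x))
  }
  x
}

md_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else
      as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ",
                                              paste(r, collapse = " | "),
                                              " |"))
  paste(c(header, rule, body), collapse = "\n")
}

md_section <- function(name, x) {
  body <- if (is.data.frame(x)) {
    md_table(x)
  } else if (is.list(x)) {
    parts <- vapply(names(x), function(nm) {
      v <- x[[nm]]
      if (is.data.frame(v)) {
        paste0("**", nm, "**\n\n", md_table(v))
      } else {
        paste0("- ", nm, ": ",
               paste(formatC(unlist(v), digits = 4, format = "g"),
                     collapse = ", "))
      }
    }, character(1))
    paste(parts, collapse = "\n")
  } else {
    paste(formatC(x, digits = 4, format = "g"), collapse = ", ")
  }
  paste0("## ", name, "\n\n", body, "\n")
}

#' Assemble a machine- and human-readable report bundle
#'
#' Collects summaries from the analysis modules (phase summaries, Q10
#' fits, jag classifications, Ih measurements, test results, or plain
#' data frames/lists) into one deterministic JSON document and a
#' Markdown table set. Sections that are `NULL` are omitted rather than
#' emitted blank; identical inputs yield byte-identical output.
#'
#' @param sections Named list of summaries.
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.md` are written there.
#' @return Invisibly, a list with `json` and `markdown` strings.
#' @export
build_report <- function(sections, out_dir = NULL) {
  if (!is.list(sections)) stop("`sections` must be a list", call. = FALSE)
  sections <- Filter(Negate(is.null), sections)
  if (!length(sections)) stop("no sections to report", call. = FALSE)
  if (is.null(names(sections)) || any(!nzchar(names(sections)))) {
    stop("`sections` must be a named list", call. = FALSE)
  }
  conv <- lapply(sections, as_report_section)
  json <- jsonlite::toJSON(conv, auto_unbox = TRUE, digits = 10,
                           na = "null", null = "null", pretty = TRUE)
  md <- paste(
    c("# Pyloric analysis report", "",
      vapply(names(conv), function(nm) md_section(nm, conv[[nm]]),
             character(1))),
    collapse = "\n")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(json, file.path(out_dir, "report.json"))
    writeLines(md, file.path(out_dir, "report.md"))
  }
  invisible(list(json = as.character(json), markdown = md))
}
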