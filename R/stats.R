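#' Remove lab main effects from a dependent variable
#'
#' Centres the dependent variable per lab and restores the grand mean:
#' `value - mean(values in the row's lab) + grand mean`. This removes mean
#' differences between labs while leaving all within-lab contrasts exactly
#' unchanged; it is the conservative first step when group membership and
#' lab are confounded.
#'
#' @param data A data frame.
#' @param value Column (tidy-eval) holding the dependent variable.
#' @param lab Column identifying the lab; default `lab`.
#' @return `data` with the value column adjusted.
#' @examples
#' df <- data.frame(lab = rep(c("A", "B"), each = 3), y = c(1, 2, 3, 11, 12, 13))
#' remove_lab_effect(df, y)$y
#' @export
remove_lab_effect <- function(data, value, lab = lab) {
  val <- rlang::enquo(value)
  labq <- rlang::enquo(lab)
  v <- rlang::eval_tidy(val, data)
  l <- rlang::eval_tidy(labq, data)
  grand <- mean(v, na.rm = TRUE)
  lab_means <- tapply(v, l, mean, na.rm = TRUE)
  adj <- v - lab_means[as.character(l)] + grand
  data[[rlang::as_name(val)]] <- as.numeric(adj)
  data
}

#' Mixed repeated-measures ANOVA
#'
#' Classical univariate mixed-design ANOVA with one between-subject factor
#' and one or two within-subject factors, partitioned into the standard
#' error strata (subjects nested in the between factor; each within effect
#' tested against its interaction with subjects). Ordered within factors
#' (see `ordered`) receive orthogonal polynomial contrasts, which makes
#' [trend_contrasts()] available. No sphericity correction is applied (the
#' two-level within factors need none).
#'
#' The design must be complete per subject; subjects with missing cells are
#' excluded with a warning. Fewer than 2 subjects per group is an error.
#'
#' @param data Tidy data frame, one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-subject factor (default `"group"`).
#' @param within Character vector of within-subject factor names.
#' @param subject Name of the subject-identifier column.
#' @param ordered Character vector naming within factors to treat as
#'   ordered (proximal-to-distal level order taken from factor levels).
#' @return A `bow_anova` object; `tidy()` gives the effect table with
#'   `effect`, `df_num`, `df_den`, `statistic` (F), `p.value`.
#' @export
rm_anova <- function(data, dv, between = "group", within = "direction",
                     subject = "subject_id", ordered = NULL) {
  dat <- tibble::as_tibble(data)
  dat <- dat[!is.na(dat[[dv]]), ]
  dat[[subject]] <- factor(dat[[subject]])
  dat[[between]] <- factor(dat[[between]])
  for (w in within) {
    lv <- if (is.factor(dat[[w]])) levels(dat[[w]]) else unique(dat[[w]])
    dat[[w]] <- factor(dat[[w]], levels = lv, ordered = w %in% ordered)
  }
  # complete cases per subject
  n_cells <- prod(vapply(within, function(w) nlevels(dat[[w]]), numeric(1)))
  counts <- table(dat[[subject]])
  incomplete <- names(counts)[counts < n_cells]
  if (length(incomplete) > 0) {
    warn(sprintf(
      "rm_anova: excluding %d subject(s) with incomplete cells: %s",
      length(incomplete), paste(incomplete, collapse = ", ")
    ))
    dat <- dat[!dat[[subject]] %in% incomplete, ]
    dat[[subject]] <- droplevels(dat[[subject]])
  }
  per_group <- table(unique(dat[, c(subject, between)])[[between]])
  if (any(per_group < 2)) {
    abort("rm_anova needs at least 2 subjects per group")
  }

  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0(
    "Error(", subject, "/(", paste(within, collapse = " * "), "))"
  )
  fml <- stats::as.formula(paste0(dv, " ~ ", rhs, " + ", err))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- aov(fml, data = dat)

  table <- anova_table_from_aov(fit)
  structure(
    list(
      table = table, fit = fit, data = dat, dv = dv, between = between,
      within = within, subject = subject, ordered = ordered
    ),
    class = "bow_anova"
  )
}

# tidy effect table from a summary.aovlist
anova_table_from_aov <- function(fit, split = NULL) {
  sm <- if (is.null(split)) summary(fit) else summary(fit, split = split)
  purrr::map_dfr(names(sm), function(stratum) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    resid_row <- rn == "Residuals"
    df_den <- tab[resid_row, "Df"]
    if (length(df_den) == 0) {
      return(NULL)
    }
    keep <- !resid_row & !is.na(tab[["F value"]])
    tibble::tibble(
      stratum = sub("^Error: ", "", stratum),
      effect = gsub(" ", "", rn[keep]),
      df_num = tab[keep, "Df"],
      df_den = df_den,
      statistic = tab[keep, "F value"],
      p.value = tab[keep, "Pr(>F)"]
    )
  })
}

#' @export
print.bow_anova <- function(x, ...) {
  cat(sprintf(
    "<bow_anova> %s ~ %s * %s (subject: %s)\n", x$dv, x$between,
    paste(x$within, collapse = " * "), x$subject
  ))
  print(x$table)
  invisible(x)
}

#' @rdname rm_anova
#' @param x A `bow_anova` object.
#' @param ... Unused.
#' @export
tidy.bow_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.bow_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = nlevels(x$data[[x$subject]]),
    n_rows = nrow(x$data),
    n_effects = nrow(x$table)
  )
}

#' Polynomial trend contrasts of an ordered within factor
#'
#' Decomposes an ordered factor's effects into orthogonal polynomial trend
#' components (linear, quadratic, cubic for four levels), each tested with
#' 1 numerator df against the factor's own error stratum. The factor must
#' have been declared `ordered` in [rm_anova()].
#'
#' @param fit A `bow_anova`.
#' @param factor Name of the ordered within factor.
#' @return Tidy tibble with one row per effect x trend component.
#' @export
trend_contrasts <- function(fit, factor) {
  if (!factor %in% (fit$ordered %||% character(0))) {
    abort(sprintf(
      "'%s' was not fitted as an ordered factor; pass ordered = \"%s\" to rm_anova()",
      factor, factor
    ))
  }
  k <- nlevels(fit$data[[factor]])
  trends <- c("linear", "quadratic", "cubic", "quartic")[seq_len(k - 1)]
  split <- stats::setNames(
    list(stats::setNames(as.list(seq_len(k - 1)), trends)), factor
  )
  tab <- anova_table_from_aov(fit$fit, split = split)
  tab <- tab[grepl(":", tab$effect, fixed = TRUE) |
    grepl(factor, tab$effect, fixed = TRUE), ]
  tab <- tab[grepl(paste(trends, collapse = "|"), tab$effect), ]
  tab$trend <- sub(".*:\\s*(linear|quadratic|cubic|quartic).*", "\\1",
    tab$effect)
  tab$effect <- sub(":\\s*(linear|quadratic|cubic|quartic)", "", tab$effect)
  tab[, c("stratum", "effect", "trend", "df_num", "df_den", "statistic",
    "p.value")]
}

#' Pairwise post-hoc t-tests with Holm correction
#'
#' All pairwise comparisons between the levels of one factor, paired within
#' subjects (the default, for within-subject factors) or independent (for
#' between-subject factors), Holm step-down adjusted within the family of
#' comparisons. Cells with fewer than 2 values are skipped with a warning.
#'
#' @param data Tidy data frame.
#' @param dv Dependent-variable column name.
#' @param factor Factor column whose levels are compared.
#' @param subject Subject column (used to pair observations).
#' @param paired Paired (within-subject) or independent comparisons.
#' @param adjust P-adjustment method (see [stats::p.adjust()]).
#' @return Tibble: `level1`, `level2`, `estimate`, `statistic`, `df`,
#'   `p.value`, `p.adjusted`.
#' @export
posthoc_t <- function(data, dv, factor, subject = "subject_id",
                      paired = TRUE, adjust = "holm") {
  lv <- if (is.factor(data[[factor]])) {
    levels(droplevels(data[[factor]]))
  } else {
    unique(data[[factor]])
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    d1 <- data[data[[factor]] == pr[1], ]
    d2 <- data[data[[factor]] == pr[2], ]
    if (paired) {
      common <- intersect(d1[[subject]], d2[[subject]])
      x <- d1[[dv]][match(common, d1[[subject]])]
      y <- d2[[dv]][match(common, d2[[subject]])]
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]
      y <- y[keep]
      if (length(x) < 2) {
        warn(sprintf("posthoc_t: skipping %s vs %s (n < 2)", pr[1], pr[2]))
        return(NULL)
      }
      tt <- t.test(x, y, paired = TRUE)
    } else {
      x <- na.omit(d1[[dv]])
      y <- na.omit(d2[[dv]])
      if (length(x) < 2 || length(y) < 2) {
        warn(sprintf("posthoc_t: skipping %s vs %s (n < 2)", pr[1], pr[2]))
        return(NULL)
      }
      tt <- t.test(x, y, var.equal = TRUE)
    }
    tibble::tibble(
      level1 = pr[1], level2 = pr[2],
      estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value
    )
  })
  if (nrow(rows) > 0) {
    rows$p.adjusted <- p.adjust(rows$p.value, method = adjust)
  }
  rows
}

#' One-sample t-test against zero
#'
#' Two-sided test of whether a dependent variable systematically differs
#' from zero (the time of bow reversal, for the relative temporal
#' measures). A zero-variance sample is degenerate: p is 0 when the mean is
#' non-zero and 1 otherwise (logged).
#'
#' @param values Numeric vector (n >= 2 after NA removal).
#' @return Tibble: `estimate` (mean), `statistic` (t), `df`, `p.value`.
#' @export
one_sample_vs_zero <- function(values) {
  v <- na.omit(values)
  if (length(v) < 2) abort("one_sample_vs_zero needs n >= 2")
  if (sd(v) == 0) {
    warn("one_sample_vs_zero: zero variance; degenerate p value")
    return(tibble::tibble(
      estimate = mean(v),
      statistic = if (mean(v) == 0) 0 else Inf * sign(mean(v)),
      df = length(v) - 1,
      p.value = if (mean(v) == 0) 1 else 0
    ))
  }
  tt <- t.test(v, mu = 0)
  tibble::tibble(
    estimate = unname(tt$estimate), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p.value = tt$p.value
  )
}
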