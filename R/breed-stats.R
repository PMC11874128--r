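#' One-way ANOVA with Tukey HSD letters across populations
#'
#' Fits a one-way ANOVA of `values` on `group_labels`, runs Tukey's honest
#' significant difference over all group pairs (studentized-range
#' distribution with Tukey-Kramer standard errors for unbalanced groups,
#' via [stats::TukeyHSD()]), and derives a compact letter display at level
#' `alpha` by the insert-and-absorb algorithm: groups sharing a letter are
#' not significantly different. Group ordering in the display is by
#' decreasing mean (ties by label), so the letters are deterministic.
#'
#' With `method = "kruskal"` a rank-based alternative is used instead:
#' Kruskal-Wallis followed by pairwise Wilcoxon tests with Holm adjustment
#' (a Dunn-style multiple-comparison layer), feeding the same letter
#' algorithm.
#'
#' @param values numeric response (e.g. per-sample run counts in a class).
#' @param group_labels group (population) per observation.
#' @param alpha family-wise significance level, default 0.05.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return a `group_comparison`: list with `summary` (per-group n, mean,
#'   sd, letters), `f`, `p_value` (global test), `pairwise` (matrix of
#'   adjusted p-values), `alpha`, `method`.
#' @export
anova_tukey <- function(values, group_labels, alpha = 0.05,
                        method = c("anova", "kruskal")) {
  method <- match.arg(method)
  g <- factor(group_labels)
  stopifnot(length(values) == length(g), nlevels(g) >= 2,
            all(table(g) >= 2))
  groups <- levels(g)
  k <- length(groups)
  pw <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  if (method == "anova") {
    if (stats::var(values) == 0) {
      # no variation at all: nothing distinguishable
      f_stat <- 0; p_global <- 1
      pw[] <- 1; diag(pw) <- NA
    } else {
      fit <- stats::aov(values ~ g)
      an <- summary(fit)[[1]]
      f_stat <- an[["F value"]][1]
      p_global <- an[["Pr(>F)"]][1]
      if (is.na(f_stat)) { f_stat <- 0; p_global <- 1; pw[] <- 1; diag(pw) <- NA }
      else {
        tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
        pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
        for (i in seq_along(pairs)) {
          a <- pairs[[i]][1]; b <- pairs[[i]][2]
          pw[a, b] <- pw[b, a] <- tk[i, "p adj"]
        }
      }
    }
  } else {
    kw <- stats::kruskal.test(values, g)
    f_stat <- unname(kw$statistic)
    p_global <- kw$p.value
    pp <- stats::pairwise.wilcox.test(values, g, p.adjust.method = "holm",
                                      exact = FALSE)$p.value
    for (a in rownames(pp)) for (b in colnames(pp)) {
      if (!is.na(pp[a, b])) pw[a, b] <- pw[b, a] <- pp[a, b]
    }
    pw[is.na(pw) & row(pw) != col(pw)] <- 1
  }
  means <- tapply(values, g, mean)
  ord <- order(-means, groups)
  sig <- !is.na(pw) & pw < alpha
  letters <- compact_letters(sig[ord, ord, drop = FALSE])
  summary_df <- data.frame(group = groups[ord],
                           n = as.integer(table(g)[ord]),
                           mean = as.numeric(means[ord]),
                           sd = as.numeric(tapply(values, g, stats::sd)[ord]),
                           letters = letters, row.names = NULL)
  structure(list(summary = summary_df, f = f_stat, p_value = p_global,
                 pairwise = pw, alpha = alpha, method = method),
            class = "group_comparison")
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb: start with one letter column covering every group;
#' for each significantly different pair appearing in a shared column,
#' duplicate the column and remove one group from each copy; finally drop
#' columns that are subsets of others. Deterministic for a given group
#' order.
#'
#' @param sig logical k x k matrix, `TRUE` where the pair differs
#'   significantly (diagonal ignored).
#' @return character vector of letter strings, one per group (input
#'   order).
#' @export
compact_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))         # membership vectors
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!isTRUE(sig[i, j])) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb: drop columns contained in another
      drop <- logical(length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a == b || drop[b]) next
          if (all(!cols[[a]] | cols[[b]]) && !identical(cols[[a]], cols[[b]])) {
            drop[a] <- TRUE; break
          }
          if (a < b && identical(cols[[a]], cols[[b]])) drop[b] <- TRUE
        }
      }
      cols <- cols[!drop]
    }
  }
  # stable letter assignment: order columns by first member
  first <- vapply(cols, function(cc) which(cc)[1], numeric(1))
  cols <- cols[order(first)]
  lab <- vapply(seq_len(k), function(gi)
    paste(letters[which(vapply(cols, function(cc) cc[gi], logical(1)))],
          collapse = ""), character(1))
  lab
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the two-sided t-based p-value.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group comparison (", x$method, "), global p = ",
      signif(x$p_value, 4), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Population comparison tables for run counts per length class
#'
#' Builds the descriptive-plus-letters table of a run analysis: per length
#' class, the per-sample run counts are compared across populations with
#' [anova_tukey()].
#'
#' @param runset a `run_set`.
#' @param samples full sample sheet (`sample_id`, `population`).
#' @param alpha significance level.
#' @return data.frame: `length_class`, `population`, `n`, `mean`, `sd`,
#'   `letters`, `anova_p`.
#' @export
compare_run_counts <- function(runset, samples, alpha = 0.05) {
  runs <- runset$runs
  classes <- levels(runs$length_class)
  classes <- classes[classes %in% unique(as.character(runs$length_class)) |
                     !grepl("^<", classes)]
  out <- list()
  for (cl in classes) {
    counts <- vapply(samples$sample_id, function(s)
      sum(runs$sample_id == s & as.character(runs$length_class) == cl),
      numeric(1))
    cmp <- anova_tukey(counts, samples$population, alpha = alpha)
    df <- cmp$summary
    df <- data.frame(length_class = cl, population = df$group, n = df$n,
                     mean = df$mean, sd = df$sd, letters = df$letters,
                     anova_p = cmp$p_value)
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
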