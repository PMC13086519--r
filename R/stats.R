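# Group comparisons of intermediate maxima across phenotype classes:
# one-way ANOVA, Tukey(-Kramer) HSD pairwise tests with a compact letter
# display, and Shapiro-Wilk normality of the residuals. The F statistic and
# the studentized-range comparisons are computed directly from their
# defining sums of squares so that stats::aov / stats::TukeyHSD remain
# independent cross-checks.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way analysis of variance
#'
#' @param groups Named list of numeric vectors, >= 2 groups of >= 2 values.
#' @return List with `F`, `p`, the degrees of freedom `df = c(between,
#'   within)`, the mean squares and `mse`. A fully degenerate input (zero
#'   between- and within-group variance) returns `F = 0`, `p = 1`.
#' @export
one_way_anova <- function(groups) {
  groups <- .check_groups(groups)
  ni <- vapply(groups, length, 0L)
  mi <- vapply(groups, mean, 0)
  n <- sum(ni)
  k <- length(groups)
  grand <- sum(ni * mi) / n
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- k - 1L
  dfw <- n - k
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
    }
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  list(F = f, p = p, df = c(between = dfb, within = dfw),
       ms = c(between = ssb / dfb, within = ssw / dfw), mse = ssw / dfw,
       means = mi, n = ni)
}

#' Tukey(-Kramer) HSD pairwise comparisons
#'
#' Studentized-range tests of all group-mean differences; unequal group
#' sizes use the Tukey-Kramer standard error sqrt(MSE/2 (1/ni + 1/nj)).
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with one row per unordered pair: the two group names,
#'   the mean difference and the adjusted p value.
#' @export
tukey_hsd <- function(groups) {
  groups <- .check_groups(groups)
  a <- one_way_anova(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  diff <- a$means[pairs[1, ]] - a$means[pairs[2, ]]
  if (a$mse == 0) {
    p <- ifelse(diff == 0, 1, 0)
  } else {
    se <- sqrt(a$mse / 2 * (1 / a$n[pairs[1, ]] + 1 / a$n[pairs[2, ]]))
    p <- stats::ptukey(abs(diff) / se, k, a$df[["within"]],
                       lower.tail = FALSE)
  }
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             diff = unname(diff), p_adj = unname(p))
}

#' Compact letter display for Tukey HSD comparisons
#'
#' Groups sharing a letter are not significantly different at `alpha`.
#' Letters are assigned by the standard insert-and-absorb algorithm: start
#' from one set holding all groups, split every set containing a
#' significantly different pair, absorb subsets, then letter the surviving
#' sets in order of decreasing group means.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level (0.05 as printed in the source tables).
#' @return List with `letters` (named character vector) and the `pairwise`
#'   table from [tukey_hsd()].
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  pw <- tukey_hsd(groups)
  k <- length(groups)
  nms <- names(groups)
  sets <- list(seq_len(k))
  sig <- which(pw$p_adj <= alpha)
  for (r in sig) {
    i <- match(pw$group1[r], nms)
    j <- match(pw$group2[r], nms)
    new <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new <- c(new, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new <- c(new, list(s))
      }
    }
    new <- new[!duplicated(vapply(new, function(s) {
      paste(sort(s), collapse = ",")
    }, ""))]
    keep <- vapply(seq_along(new), function(a) {
      !any(vapply(seq_along(new), function(b) {
        a != b && length(new[[a]]) < length(new[[b]]) &&
          all(new[[a]] %in% new[[b]])
      }, logical(1)))
    }, logical(1))
    sets <- new[keep]
  }
  means <- vapply(groups, mean, 0)
  ord <- order(vapply(sets, function(s) -max(means[s]), 0))
  sets <- sets[ord]
  letters_per_group <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, "")
  names(letters_per_group) <- nms
  list(letters = letters_per_group, pairwise = pw, alpha = alpha)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard routine, with the input checks the
#' pipeline needs (3 <= n <= 5000, non-constant residuals).
#'
#' @param residuals Numeric vector of residuals.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(residuals)) == 0) {
    stop("residuals are constant; normality test undefined", call. = FALSE)
  }
  st <- stats::shapiro.test(residuals)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Group statistics table for phenotype-class comparisons
#'
#' For each variable: one-way ANOVA across the classes, Tukey HSD compact
#' letters, and Shapiro-Wilk on the pooled within-group residuals.
#'
#' @param df Data frame of per-run summaries.
#' @param variables Column names to compare (e.g. max NO2-, NO, N2O).
#' @param group Grouping column name (default `"label"`).
#' @param alpha Significance level.
#' @return A `group_stats` list keyed by variable.
#' @export
group_stats <- function(df, variables, group = "label", alpha = 0.05) {
  out <- lapply(variables, function(v) {
    g <- split(df[[v]], df[[group]])
    a <- one_way_anova(g)
    tl <- tukey_letters(g, alpha)
    resid <- unlist(lapply(g, function(x) x - mean(x)), use.names = FALSE)
    sw <- tryCatch(shapiro_wilk(resid), error = function(e) {
      list(W = NA_real_, p = NA_real_)
    })
    list(F = a$F, p = a$p, df = a$df, letters = tl$letters,
         pairwise = tl$pairwise, shapiro_W = sw$W, shapiro_p = sw$p)
  })
  names(out) <- variables
  structure(out, class = "group_stats")
}
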