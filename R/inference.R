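as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way ANOVA over treatment groups
#'
#' Standard between/within decomposition fitted with \code{stats::aov}; the
#' p-value comes from the F distribution.  When both the between- and
#' within-group variances are zero the F statistic is undefined and flagged.
#'
#' @param groups named list of numeric vectors, one per group, each with at
#'   least two values.
#' @return list with \code{f}, \code{p}, \code{df_between},
#'   \code{df_within}, \code{ms_within}, group \code{means} and \code{n},
#'   and \code{degenerate} (TRUE when F is undefined).
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least two values for variance estimation")
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("group values must be finite")
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups),
                                     vapply(groups, length, 0L))))
  # suppress anova's "essentially perfect fit" chatter: zero within-group
  # variance is handled explicitly downstream
  tab <- suppressWarnings(anova(aov(value ~ group, data = d)))
  out <- list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
              df_between = tab$Df[1], df_within = tab$Df[2],
              ms_within = tab$`Mean Sq`[2],
              means = vapply(groups, mean, 0),
              n = vapply(groups, length, 0L),
              degenerate = FALSE)
  if (!is.finite(out$f)) {
    if (tab$`Sum Sq`[1] == 0 && tab$`Sum Sq`[2] == 0) {
      out$degenerate <- TRUE   # no variation anywhere: F = 0/0
      out$f <- NA_real_; out$p <- NA_real_
    }
  }
  out
}

#' Balanced two-factor ANOVA
#'
#' Factorial decomposition for the balanced light x temperature design: main
#' effects, interaction and residual.  With balance, the type-I decomposition
#' is the unique one; unbalanced or incomplete cell layouts are rejected
#' rather than silently switching sum-of-squares conventions.
#'
#' @param cells data frame with columns \code{light}, \code{temperature},
#'   \code{value}; every light x temperature combination must be present with
#'   the same number of replicate values (at least two).
#' @return data frame with one row per term (\code{light},
#'   \code{temperature}, \code{light:temperature}, \code{Residuals}):
#'   \code{df}, \code{sum_sq}, \code{mean_sq}, \code{f}, \code{p}.  The four
#'   sums of squares add up to the total sum of squares.
#' @export
two_way_anova <- function(cells) {
  need <- c("light", "temperature", "value")
  if (!all(need %in% names(cells))) stop("cells must have columns ",
                                         paste(need, collapse = ", "))
  if (!all(is.finite(cells$value))) stop("cell values must be finite")
  tab0 <- table(cells$light, cells$temperature)
  if (any(tab0 == 0)) stop("missing cell(s): balanced designs only")
  if (length(unique(as.vector(tab0))) != 1 || any(tab0 < 2))
    stop("unbalanced design: every cell needs the same number (>= 2) of values")
  d <- data.frame(light = factor(cells$light),
                  temperature = factor(cells$temperature),
                  value = cells$value)
  tab <- suppressWarnings(anova(aov(value ~ light * temperature, data = d)))
  out <- data.frame(term = rownames(tab), df = tab$Df, sum_sq = tab$`Sum Sq`,
                    mean_sq = tab$`Mean Sq`, f = tab$`F value`,
                    p = tab$`Pr(>F)`)
  rownames(out) <- NULL
  # a flat response carries no information: 0/0 F ratios are undefined
  scale_ <- max(1, mean(d$value^2))
  if (sum(out$sum_sq) < 1e-12 * scale_ * nrow(d)) {
    out$f <- NA_real_
    out$p <- NA_real_
    attr(out, "degenerate") <- TRUE
    warning("response is constant: F ratios undefined", call. = FALSE)
  }
  out
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons using the studentized range distribution.
#' For groups i, j with pooled within-group mean square \eqn{MS_W}:
#' \deqn{q = \frac{|\bar y_i - \bar y_j|}{\sqrt{(MS_W/2)(1/n_i + 1/n_j)}}}
#' with the Tukey-Kramer form handling unequal group sizes; the adjusted
#' p-value is the upper tail of the studentized range distribution with
#' (k, N - k) parameters.  When \eqn{MS_W = 0} the comparison is degenerate:
#' pairs with distinct means are flagged significant with p = 0, equal-mean
#' pairs with p = 1.
#'
#' @param groups named list of numeric vectors (as
#'   \code{\link{one_way_anova}}).
#' @param alpha familywise significance level (default 0.05).
#' @return a \code{tukey_result} data frame: \code{group_i}, \code{group_j},
#'   \code{mean_diff} (mean_j - mean_i), \code{q}, \code{p_adj},
#'   \code{significant}.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  fit <- one_way_anova(groups)
  k <- length(groups)
  df_w <- fit$df_within
  msw <- fit$ms_within
  combs <- utils::combn(names(groups), 2)
  out <- do.call(rbind, apply(combs, 2, function(pair) {
    i <- pair[1]; j <- pair[2]
    diff_ <- fit$means[[j]] - fit$means[[i]]
    se <- sqrt(msw / 2 * (1 / fit$n[[i]] + 1 / fit$n[[j]]))
    if (msw <= 0) {
      q <- if (diff_ == 0) 0 else Inf
      p <- if (diff_ == 0) 1 else 0
    } else {
      q <- abs(diff_) / se
      p <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    }
    data.frame(group_i = i, group_j = j, mean_diff = diff_, q = q, p_adj = p)
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("tukey_result", "data.frame"))
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> %d pairwise comparisons at alpha = %g\n",
              nrow(x), attr(x, "alpha")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share at least one letter
#' exactly when their pairwise comparison is \emph{not} significant
#' (insert-and-absorb algorithm: start with all groups in one letter column,
#' split a column for every significant pair it still joins, then absorb
#' columns contained in others).
#'
#' @param pairwise a \code{\link{tukey_hsd}} result, or any data frame with
#'   \code{group_i}, \code{group_j} and logical \code{significant} covering
#'   every pair of groups.
#' @param groups optional character vector fixing the group order; defaults
#'   to order of first appearance.
#' @return a \code{letter_display}: named character vector of letter strings,
#'   e.g. \code{c(A = "a", B = "ab", C = "b")}.
#' @export
letter_display <- function(pairwise, groups = NULL) {
  groups <- groups %||% unique(c(pairwise$group_i, pairwise$group_j))
  cols <- list(groups)
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    g1 <- sig$group_i[r]; g2 <- sig$group_j[r]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col)
        new_cols <- c(new_cols, list(setdiff(col, g1), setdiff(col, g2)))
      else new_cols <- c(new_cols, list(col))
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols))
      if (i != j && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
        keep[i] <- FALSE
    cols <- new_cols[keep]
  }
  # order columns by their first group, so letters read naturally
  first <- vapply(cols, function(col) min(match(col, groups)), 0)
  cols <- cols[order(first)]
  letters_out <- vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, TRUE))],
          collapse = "")
  }, "")
  structure(letters_out, class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  print(setNames(as.character(x), names(x)))
  invisible(x)
}

#' Do two groups share a letter?
#'
#' Utility encoding the display's meaning: sharing a letter means "not
#' significantly different".
#'
#' @param display a \code{\link{letter_display}}.
#' @param g1,g2 group names.
#' @return logical.
#' @export
shares_letter <- function(display, g1, g2) {
  a <- strsplit(as.character(display[[g1]]), "")[[1]]
  b <- strsplit(as.character(display[[g2]]), "")[[1]]
  length(intersect(a, b)) > 0
}
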