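#' Kruskal-Wallis omnibus test with Dunn's pairwise comparisons
#'
#' Rank-based one-way comparison of two or more groups: tie-corrected
#' Kruskal-Wallis H (via [stats::kruskal.test()]) followed by Dunn's z tests
#' on pairwise mean-rank differences using the pooled tie-corrected rank
#' variance. Pairwise p-values are uncorrected by default, with any
#' [stats::p.adjust()] method available.
#'
#' @param data Data frame with a measurement column and a group column.
#' @param value,group Column names (tidy-eval) of the measurements and group
#'   labels.
#' @param p_adjust Multiplicity adjustment for the Dunn p-values
#'   (default `"none"`).
#' @return Object of class `kruskal_dunn`: `statistic` (H), `df`, `p_value`,
#'   and `pairwise` tibble (`group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(data, value, group, p_adjust = "none") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2) abort_param("group", "need at least 2 groups")
  if (any(is.na(v))) abort_param("value", "missing values not supported")
  n <- length(v)
  lv <- levels(g)

  if (length(unique(v)) < 2) {
    # fully tied data: no evidence of any difference
    pairs <- utils::combn(lv, 2)
    pw <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = 0, p_value = 1, p_adjusted = 1)
    return(structure(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          pairwise = pw, n = n),
                     class = "kruskal_dunn"))
  }

  kw <- stats::kruskal.test(v, g)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties)
  var_pool <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))

  pairs <- utils::combn(lv, 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    (rbar[[a]] - rbar[[b]]) /
      sqrt(var_pool * (1 / ng[[a]] + 1 / ng[[b]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  pw <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                       p_value = p,
                       p_adjusted = stats::p.adjust(p, method = p_adjust))
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pw, n = n),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  print(x$pairwise)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test reporting the U statistic (number of (a, b) pairs
#' with a > b, ties counting one half). For samples of at most 8 each the
#' two-sided p-value is computed by exhaustive enumeration of all group
#' assignments (exact even under ties); otherwise the tie-corrected normal
#' approximation is used.
#'
#' @param a,b Numeric samples.
#' @param exact_max Enumeration is used when both samples are at most this
#'   size (default 8).
#' @return Object of class `mann_whitney`: `u`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) {
    abort_param("a", "both samples must be non-empty")
  }
  na <- length(a); nb <- length(b)
  u_stat <- function(xa, xb) {
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u <- u_stat(a, b)
  mu <- na * nb / 2

  if (na <= exact_max && nb <= exact_max) {
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties)
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z <- if (sigma > 0) (u - mu) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  structure(list(u = u, p_value = p, method = method, n_a = na, n_b = nb),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %.1f, p = %.4g (%s; n = %d, %d)\n",
              x$u, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Two-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Thin wrapper around [stats::aov()] for two crossed factors with
#' interaction, followed by unadjusted pairwise t comparisons of the cell
#' means using the residual mean square (Fisher's least significant
#' difference).
#'
#' @param data Data frame.
#' @param value,factor1,factor2 Column names (tidy-eval).
#' @return List with `anova` (the ANOVA table as a tibble) and `pairwise`
#'   (cell-mean comparisons: estimate, t, df, p).
#' @export
anova_lsd <- function(data, value, factor1, factor2) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  f1 <- factor(rlang::eval_tidy(rlang::enquo(factor1), data))
  f2 <- factor(rlang::eval_tidy(rlang::enquo(factor2), data))
  df <- data.frame(v = v, f1 = f1, f2 = f2)
  fit <- stats::aov(v ~ f1 * f2, data = df)
  tab <- as.data.frame(summary(fit)[[1]])
  tab <- tibble::as_tibble(cbind(term = trimws(rownames(tab)), tab))
  mse <- tab$`Mean Sq`[tab$term == "Residuals"]
  dfe <- tab$Df[tab$term == "Residuals"]
  cells <- interaction(f1, f2, sep = ":", drop = TRUE)
  means <- tapply(v, cells, mean)
  ns <- tapply(v, cells, length)
  pairs <- utils::combn(names(means), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    t <- (means[[a]] - means[[b]]) / se
    tibble::tibble(cell1 = a, cell2 = b, estimate = means[[a]] - means[[b]],
                   t = t, df = dfe, p_value = 2 * stats::pt(-abs(t), dfe))
  }) |> dplyr::bind_rows()
  list(anova = tab, pairwise = pw)
}
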