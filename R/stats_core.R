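# Groups enter either as raw samples (named list of numeric vectors) or as
# summary statistics (data.frame label/n/mean/sd). Everything downstream
# works off the summaries plus the pooled error term, so the two modes agree
# exactly when the summaries are exact.

as_group_summaries <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("label", "n", "mean", "sd")
    if (!all(need %in% names(groups)))
      stop("summary-mode groups need columns label, n, mean, sd")
    out <- data.frame(label = as.character(groups$label),
                      n = as.integer(groups$n),
                      mean = as.numeric(groups$mean),
                      sd = as.numeric(groups$sd),
                      stringsAsFactors = FALSE)
  } else if (is.list(groups)) {
    if (is.null(names(groups)))
      names(groups) <- paste0("group", seq_along(groups))
    out <- data.frame(
      label = names(groups),
      n = vapply(groups, function(x) sum(is.finite(x)), integer(1)),
      mean = vapply(groups, function(x) mean(x[is.finite(x)]), numeric(1)),
      sd = vapply(groups, function(x) {
        x <- x[is.finite(x)]
        if (length(x) >= 2) stats::sd(x) else 0
      }, numeric(1)),
      stringsAsFactors = FALSE)
  } else stop("groups must be a named list of samples or a summary data.frame")
  if (any(out$n < 1)) stop("every group needs n >= 1")
  out
}

#' One-way ANOVA from raw samples or group summaries
#'
#' Pools the within-group variance as
#' `MSE = sum((n_i - 1) s_i^2) / sum(n_i - 1)` with `df_error = N - k`, and
#' forms the omnibus F from the between/within mean squares. In
#' summary-statistics mode the printed means and SDs are used exactly as
#' given, so published tables can be re-analyzed without the raw data.
#'
#' @param groups Named list of numeric vectors, or a data.frame with columns
#'   `label`, `n`, `mean`, `sd`.
#' @return List with `mse`, `df_error`, `F`, `p`, `grand_mean`, `k`, `N` and
#'   the normalized `summaries`.
#' @export
pooled_anova <- function(groups) {
  gs <- as_group_summaries(groups)
  k <- nrow(gs)
  if (k < 2) stop("pooled_anova: need >= 2 groups")
  if (sum(gs$n - 1) < 1) stop("pooled_anova: no within-group degrees of freedom")
  mse <- sum((gs$n - 1) * gs$sd^2) / sum(gs$n - 1)
  if (mse == 0) stop("pooled_anova: all within-group variances are zero")
  N <- sum(gs$n)
  grand <- sum(gs$n * gs$mean) / N
  msb <- sum(gs$n * (gs$mean - grand)^2) / (k - 1)
  Fstat <- msb / mse
  list(mse = mse, df_error = N - k, F = Fstat,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       grand_mean = grand, k = k, N = N, summaries = gs)
}

# Non-significance matrix of Duncan's stepwise range procedure over groups
# sorted by descending mean. Spans are processed widest first; a pair whose
# span lies inside a range already declared non-significant is absorbed
# (stepwise protection), so non-significant sets are contiguous intervals.
duncan_nonsig <- function(n, mean, mse, dfe, alpha, n_h = c("pair", "all")) {
  n_h <- match.arg(n_h)
  k <- length(mean)
  nonsig <- diag(TRUE, k)
  if (k < 2) return(nonsig)
  nh_all <- k / sum(1 / n)
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if (nonsig[i, j]) next
      alpha_p <- 1 - (1 - alpha)^(span - 1)
      nh <- if (n_h == "pair") 2 / (1 / n[i] + 1 / n[j]) else nh_all
      Rp <- stats::qtukey(1 - alpha_p, span, dfe) * sqrt(mse / nh)
      if ((mean[i] - mean[j]) < Rp) {
        nonsig[i:j, i:j] <- TRUE  # absorb: everything inside is non-significant
      }
    }
  }
  nonsig
}

# Compact letter display from a non-significance matrix over mean-sorted
# groups (insert-and-absorb: maximal non-significant intervals each get one
# letter). `increasing = TRUE` letters from the smallest mean upward, so the
# smallest group is "a" -- the convention of the tables this mirrors.
cld_letters <- function(nonsig, increasing = TRUE) {
  k <- nrow(nonsig)
  ints <- list()
  for (i in 1:k) for (j in i:k) {
    if (!all(nonsig[i:j, i:j])) next
    grows <- (i > 1 && all(nonsig[(i - 1):j, (i - 1):j])) ||
             (j < k && all(nonsig[i:(j + 1), i:(j + 1)]))
    if (!grows) ints[[length(ints) + 1]] <- c(i, j)
  }
  ints <- unique(ints)
  # groups are sorted by descending mean; letter order follows `increasing`
  ord <- if (increasing) order(-vapply(ints, `[`, 0L, 2), -vapply(ints, `[`, 0L, 1))
         else order(vapply(ints, `[`, 0L, 1), vapply(ints, `[`, 0L, 2))
  lets <- rep("", k)
  for (li in seq_along(ord)) {
    rng <- ints[[ord[li]]]
    lab <- if (li <= 26) letters[li] else paste0(letters[(li - 1) %/% 26], letters[(li - 1) %% 26 + 1])
    for (g in rng[1]:rng[2]) lets[g] <- paste0(lets[g], lab)
  }
  # print letters within each group alphabetically
  vapply(strsplit(lets, ""), function(x) paste(sort(x), collapse = ""), character(1))
}

#' Duncan's multiple range test with compact letter display
#'
#' Groups are sorted by descending mean; for a pair spanning `p` ordered
#' groups the least significant range is
#' `R_p = q(1 - (1 - alpha)^(p - 1); p, df_error) * sqrt(MSE / n_h)` with `q`
#' the studentized-range quantile and `n_h` the harmonic mean of the two
#' compared group sizes (Duncan with the Kramer unequal-n extension;
#' `n_h = "all"` uses the harmonic mean of all group sizes instead). A pair
#' inside a range already declared non-significant is non-significant
#' (stepwise protection). Letters are assigned by maximal non-significant
#' intervals; by default ascending means receive earlier letters, so the
#' smallest mean is "a".
#'
#' Degenerate input with zero pooled variance is handled without an error:
#' all-equal means give a single shared letter (p = 1), distinct means with
#' zero variance are all mutually significant (p = 0).
#'
#' @param groups Named list of numeric vectors or a summary data.frame
#'   (label, n, mean, sd).
#' @param alpha Protection level (default 0.05).
#' @param n_h `"pair"` (harmonic mean of the two groups compared, default) or
#'   `"all"`.
#' @param letters_increasing Letter orientation (default TRUE: smallest mean
#'   gets "a").
#' @return A `duncan_outcome`: `table` (label, n, mean, sd, letter; ordered
#'   by descending mean), `mse`, `df_error`, `alpha`, `F`, `p`, and the
#'   non-significance matrix `nonsig`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, n_h = c("pair", "all"),
                       letters_increasing = TRUE) {
  gs <- as_group_summaries(groups)
  k <- nrow(gs)
  if (k < 1) stop("duncan_mrt: need >= 1 group")
  ord <- order(-gs$mean)
  gs <- gs[ord, , drop = FALSE]
  mse0 <- if (sum(gs$n - 1) >= 1) sum((gs$n - 1) * gs$sd^2) / sum(gs$n - 1) else 0
  if (k == 1) {
    out <- list(table = cbind(gs, letter = "a"), mse = mse0,
                df_error = sum(gs$n) - 1, alpha = alpha,
                F = NA_real_, p = NA_real_, nonsig = diag(TRUE, 1))
    class(out) <- "duncan_outcome"
    return(out)
  }
  if (mse0 == 0) {
    # zero within-group variability: decide on means alone
    same <- abs(outer(gs$mean, gs$mean, `-`)) < .Machine$double.eps^0.5
    nonsig <- same
    p <- if (all(same)) 1 else 0
    lets <- cld_letters(nonsig, increasing = letters_increasing)
    out <- list(table = cbind(gs, letter = lets), mse = 0,
                df_error = sum(gs$n) - k, alpha = alpha, F = NA_real_, p = p,
                nonsig = nonsig)
    class(out) <- "duncan_outcome"
    return(out)
  }
  an <- pooled_anova(gs)
  nonsig <- duncan_nonsig(gs$n, gs$mean, an$mse, an$df_error, alpha, n_h = n_h)
  lets <- cld_letters(nonsig, increasing = letters_increasing)
  out <- list(table = cbind(gs, letter = lets), mse = an$mse,
              df_error = an$df_error, alpha = alpha, F = an$F, p = an$p,
              nonsig = nonsig)
  class(out) <- "duncan_outcome"
  out
}

#' @export
print.duncan_outcome <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$mse, x$df_error))
  if (is.finite(x$p %||% NA))
    cat(sprintf("omnibus F = %.4g, p = %.4g\n", x$F, x$p))
  tab <- x$table
  tab$display <- sprintf("%.1f ± %.1f %s (%d)", tab$mean, tab$sd, tab$letter, tab$n)
  print(tab[, c("label", "display")], row.names = FALSE)
  invisible(x)
}

#' Do two groups share a compact-display letter?
#' @param outcome A `duncan_outcome`.
#' @param a,b Group labels.
#' @return TRUE when the groups were declared non-significantly different.
#' @export
shares_letter <- function(outcome, a, b) {
  tab <- outcome$table
  ia <- match(a, tab$label); ib <- match(b, tab$label)
  if (is.na(ia) || is.na(ib)) stop("unknown group label")
  la <- strsplit(tab$letter[ia], "")[[1]]
  lb <- strsplit(tab$letter[ib], "")[[1]]
  length(intersect(la, lb)) > 0
}

#' Two-sample t test from group summaries
#'
#' Welch (default) or pooled-variance Student t from (n, mean, sd) pairs;
#' two-sided p. Raw numeric vectors are summarized first. With zero variance
#' in both groups the convention is p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param s1,s2 Numeric vector, or list/one-row data.frame with `n`, `mean`,
#'   `sd`.
#' @param mode `"welch"` or `"pooled"`.
#' @return List with `t`, `df`, `p`, `mode`.
#' @export
two_sample_t <- function(s1, s2, mode = c("welch", "pooled")) {
  mode <- match.arg(mode)
  norm1 <- function(s) {
    if (is.numeric(s) && length(s) > 1)
      list(n = length(s), mean = mean(s), sd = stats::sd(s))
    else as.list(s)[c("n", "mean", "sd")]
  }
  a <- norm1(s1); b <- norm1(s2)
  if (a$n < 2 || b$n < 2) stop("two_sample_t: need n >= 2 in each group")
  if (a$sd == 0 && b$sd == 0) {
    eq <- isTRUE(all.equal(a$mean, b$mean))
    return(list(t = if (eq) 0 else Inf * sign(a$mean - b$mean),
                df = a$n + b$n - 2, p = if (eq) 1 else 0, mode = mode))
  }
  d <- a$mean - b$mean
  if (mode == "welch") {
    se2 <- a$sd^2 / a$n + b$sd^2 / b$n
    t <- d / sqrt(se2)
    df <- se2^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- d / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mode = mode)
}

#' Pearson correlation with two-sided p value
#'
#' Pearson r over pairwise-complete observations and the usual two-sided p
#' from the t transform `t = r sqrt((n - 2) / (1 - r^2))`. With zero variance
#' in either vector the correlation is undefined and `NA` is returned.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `n`, `t`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: length mismatch")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) stop("pearson: need >= 3 pairwise-complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, n = n, t = NA_real_, p = NA_real_))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, n = n, t = Inf * sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Knockout percent reduction relative to wild type
#'
#' For each knockout line the reduction is `100 (wt - ko) / wt`; the reported
#' effect is the mean of the per-line reductions (not the reduction of the
#' pooled KO mean — averaging per line is what reproduces published averages).
#'
#' @param wt_mean Wild-type mean (must be > 0).
#' @param ko_means Numeric vector of knockout line means (>= 1 value).
#' @return Mean percent reduction.
#' @examples
#' percent_reduction(20.5, c(16.6, 16.8))  # 18.5 to one decimal
#' @export
percent_reduction <- function(wt_mean, ko_means) {
  if (!is.numeric(wt_mean) || wt_mean <= 0) stop("percent_reduction: wild-type mean must be > 0")
  if (!length(ko_means)) stop("percent_reduction: need >= 1 knockout mean")
  mean(100 * (wt_mean - ko_means) / wt_mean)
}

#' Format a Duncan outcome as a publication-style TSV
#'
#' One row per group in descending-mean order, column `display` formatted as
#' `mean +- SD letter (n)`.
#'
#' @param outcome A `duncan_outcome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duncan_tsv <- function(outcome, path) {
  tab <- data.table::as.data.table(outcome$table)
  tab$display <- sprintf("%.1f ± %.1f %s (%d)", tab$mean, tab$sd,
                         tab$letter, tab$n)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
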