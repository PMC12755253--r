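# Nonparametric group comparison and Likert-based preference analysis.
#
# Group comparison: Kruskal-Wallis omnibus test (tie-corrected H, chi-square
# reference) with Dunn's post-hoc z tests and Holm step-down adjustment.
# Preference analysis: pairwise winner rule on shared scoring instances,
# preference rate pi = W_a / (W_a + W_b) excluding ties, and a two-sided
# exact binomial test of pi = 0.5.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom. Implemented from the rank definition (and cross-checked against
#' `stats::kruskal.test` in the test suite). When all values are identical
#' the tie correction degenerates; H is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `H`, `p`, `df`, `degenerate`.
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4)))$H  # 2.4
#' @export
kruskalWallis <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 2 &&
              all(lengths(groups) > 0), "need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  H <- 12 / (n * (n + 1)) * sum(ni * (Rbar - (n + 1) / 2)^2)
  tie <- table(x)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  degenerate <- corr <= 0
  H <- if (degenerate) 0 else H / corr
  df <- length(groups) - 1L
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df,
       degenerate = degenerate)
}

.holm <- function(p) {
  # step-down: sort ascending, multiply k-th smallest by (m - k + 1),
  # enforce running maximum, cap at 1
  m <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Dunn's post-hoc test with Holm correction
#'
#' Pairwise Dunn z statistics on the joint ranks with tie correction,
#' two-sided normal p-values, and Holm step-down adjustment across all
#' pairs.
#'
#' @param groups List of numeric vectors.
#' @param labels Optional group names.
#' @return data.frame with columns `group1, group2, z, p_raw, p_holm`.
#' @export
dunnHolm <- function(groups, labels = NULL) {
  stopIfNot(is.list(groups) && length(groups) >= 2 &&
              all(lengths(groups) > 0), "need >= 2 non-empty groups")
  if (is.null(labels)) labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  tie <- table(x)
  tieTerm <- sum(tie^3 - tie) / (12 * (n - 1))
  sig2 <- n * (n + 1) / 12 - tieTerm
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(sig2 * (1 / ni[a] + 1 / ni[b]))
    if (se == 0) 0 else (Rbar[a] - Rbar[b]) / se
  })
  praw <- 2 * pnorm(-abs(z))
  data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
             z = as.numeric(z), p_raw = praw, p_holm = .holm(praw),
             stringsAsFactors = FALSE)
}

#' Winner of one scoring instance
#'
#' The method with the strictly higher Likert score wins; equal scores are
#' a tie.
#'
#' @param sA,sB Likert scores (1-5).
#' @return `"a"`, `"b"` or `"tie"`.
#' @export
likertWinner <- function(sA, sB) {
  stopIfNot(is.finite(sA) && is.finite(sB), "scores must be finite")
  if (sA > sB) "a" else if (sB > sA) "b" else "tie"
}

#' Pairwise preference rate
#'
#' `pi_{a>b} = W_a / (W_a + W_b)`, ties excluded.
#'
#' @param winsA,winsB Non-tied win counts for methods a and b.
#' @return Preference rate in `[0, 1]`.
#' @examples
#' round(preferenceRate(28, 5), 3)  # 0.848
#' @export
preferenceRate <- function(winsA, winsB) {
  stopIfNot(winsA >= 0 && winsB >= 0, "win counts must be nonnegative")
  stopIfNot(winsA + winsB > 0,
            "undefined preference: all comparisons are ties")
  winsA / (winsA + winsB)
}

#' Two-sided exact binomial test at p0 = 0.5
#'
#' Tail-doubling form: `p = min(1, 2 * P(X >= max(k, n - k)))` with
#' `X ~ Binomial(n, 0.5)`, computed by an exact sum of binomial
#' probabilities. At `p0 = 0.5` this coincides with the minimum-likelihood
#' two-sided test.
#'
#' @param k Number of successes (wins).
#' @param n Number of trials (non-tied comparisons).
#' @return Exact two-sided p-value.
#' @examples
#' exactBinomialTwoSided(28, 33)  # ~6.6e-5
#' @export
exactBinomialTwoSided <- function(k, n) {
  stopIfNot(n >= 1 && k >= 0 && k <= n && k == round(k) && n == round(n),
            "require integers 0 <= k <= n, n >= 1")
  kmax <- max(k, n - k)
  upper <- sum(exp(lchoose(n, kmax:n) - n * log(2)))
  min(1, 2 * upper)
}

#' Read a Likert score table
#'
#' @param path CSV with columns `dataset, reader, case, method, score`.
#' @return Validated data.frame (scores integer in 1..5).
#' @export
readLikert <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  .validateLikert(x)
  x
}

.validateLikert <- function(x) {
  need <- c("dataset", "reader", "case", "method", "score")
  stopIfNot(all(need %in% names(x)),
            paste("Likert table must have columns:",
                  paste(need, collapse = ", ")))
  stopIfNot(all(x$score == round(x$score)) &&
              all(x$score >= 1 & x$score <= 5),
            "scores must be integers in 1..5")
  inst <- interaction(x$dataset, x$reader, x$case, x$method, drop = TRUE)
  stopIfNot(!anyDuplicated(inst),
            "duplicated (instance, method) rows in Likert table")
  invisible(x)
}

#' Likert preference analysis
#'
#' For every unordered method pair, applies the winner rule over shared
#' scoring instances (instance = dataset x reader x case), counts wins and
#' ties, computes the preference rate (ties excluded) with its two-sided
#' exact binomial p-value, and aggregates each method's overall rate
#' (wins / (wins + losses) across all its pairs). Also returns per-method
#' Likert descriptives (mean, sample SD, median, IQR with interpolated
#' quartiles) and the full preference-rate matrix with a 50% diagonal.
#'
#' @param table Long-format data.frame with columns
#'   `dataset, reader, case, method, score`.
#' @return List with `pairs`, `overall`, `descriptives`, `matrix`.
#' @export
preferenceAnalysis <- function(table) {
  .validateLikert(table)
  methods <- sort(unique(table$method))
  inst <- paste(table$dataset, table$reader, table$case, sep = "\r")
  descriptives <- do.call(rbind, lapply(methods, function(m) {
    s <- table$score[table$method == m]
    q <- quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(method = m, n = length(s), mean = mean(s),
               sd = if (length(s) > 1) sd(s) else 0,
               median = median(s), q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
               stringsAsFactors = FALSE)
  }))
  if (length(methods) < 2) {
    return(list(pairs = data.frame(), overall = data.frame(),
                descriptives = descriptives, matrix = NULL))
  }
  scoreOf <- split(setNames(table$score, inst), table$method)
  cmb <- utils::combn(methods, 2)
  pairRows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    sa <- scoreOf[[a]]; sb <- scoreOf[[b]]
    shared <- intersect(names(sa), names(sb))
    if (length(shared) == 0) {
      return(data.frame(method_a = a, method_b = b, wins_a = NA_integer_,
                        wins_b = NA_integer_, ties = NA_integer_,
                        preference_rate = NA_real_, p_value = NA_real_,
                        shared = 0L, stringsAsFactors = FALSE))
    }
    wa <- sum(sa[shared] > sb[shared])
    wb <- sum(sb[shared] > sa[shared])
    ti <- length(shared) - wa - wb
    rate <- if (wa + wb > 0) preferenceRate(wa, wb) else NA_real_
    pv <- if (wa + wb > 0) exactBinomialTwoSided(wa, wa + wb) else NA_real_
    data.frame(method_a = a, method_b = b, wins_a = wa, wins_b = wb,
               ties = ti, preference_rate = rate, p_value = pv,
               shared = length(shared), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairRows)
  overall <- do.call(rbind, lapply(methods, function(m) {
    w <- sum(pairs$wins_a[pairs$method_a == m], na.rm = TRUE) +
      sum(pairs$wins_b[pairs$method_b == m], na.rm = TRUE)
    l <- sum(pairs$wins_b[pairs$method_a == m], na.rm = TRUE) +
      sum(pairs$wins_a[pairs$method_b == m], na.rm = TRUE)
    data.frame(method = m, wins = w, losses = l,
               overall_rate = if (w + l > 0) w / (w + l) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  mat <- matrix(NA_real_, length(methods), length(methods),
                dimnames = list(methods, methods))
  diag(mat) <- 0.5
  for (i in seq_len(nrow(pairs))) {
    if (!is.na(pairs$preference_rate[i])) {
      mat[pairs$method_a[i], pairs$method_b[i]] <- pairs$preference_rate[i]
      mat[pairs$method_b[i], pairs$method_a[i]] <- 1 - pairs$preference_rate[i]
    }
  }
  list(pairs = pairs, overall = overall, descriptives = descriptives,
       matrix = mat)
}
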