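# Rank-transform 2x2 within-subject repeated-measures ANOVA machinery,
# with a four-test normality screen.

#' Normality screen
#'
#' Runs Anderson-Darling, D'Agostino & Pearson, Shapiro-Wilk and
#' Kolmogorov-Smirnov (Lilliefors, i.e. with estimated mean/SD) tests at
#' `alpha` on each cell of values.  The downstream convention is to apply
#' the rank transform unconditionally as soon as any test fails for any
#' cell.
#'
#' @param cells Named list of numeric vectors (one per design cell).
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `cell`, `test`, `n`, `statistic`, `p`, `pass`
#'   (NA with a `skipped` flag when a cell has fewer than 3 values, or
#'   fewer than the test's own minimum).
#' @export
normality_screen <- function(cells, alpha = 0.05) {
  stopifnot(is.list(cells))
  tests <- list(
    anderson_darling = function(x) nortest::ad.test(x),
    dagostino_pearson = function(x) dagostino_pearson_test(x),
    shapiro_wilk = function(x) shapiro.test(x),
    kolmogorov_smirnov = function(x) nortest::lillie.test(x)
  )
  min_n <- c(anderson_darling = 8, dagostino_pearson = 9, shapiro_wilk = 3,
             kolmogorov_smirnov = 5)
  rows <- list()
  for (cell in names(cells)) {
    x <- cells[[cell]]
    for (tn in names(tests)) {
      skipped <- length(x) < 3 || length(x) < min_n[[tn]] || sd(x) == 0
      if (skipped) {
        rows[[length(rows) + 1]] <- data.frame(
          cell = cell, test = tn, n = length(x), statistic = NA_real_,
          p = NA_real_, pass = NA, skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      ht <- tests[[tn]](x)
      rows[[length(rows) + 1]] <- data.frame(
        cell = cell, test = tn, n = length(x),
        statistic = unname(ht$statistic), p = unname(ht$p.value),
        pass = ht$p.value >= alpha, skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "any_failed") <- any(!out$pass, na.rm = TRUE)
  out
}

#' D'Agostino & Pearson omnibus normality test
#'
#' The K^2 omnibus statistic combining the skewness transform Z(sqrt(b1))
#' (Johnson SU approximation) and the kurtosis transform Z(b2)
#' (Anscombe-Glynn); K^2 = Z1^2 + Z2^2 is chi-squared with 2 df under
#' normality.  Requires n >= 9.
#'
#' @param x Numeric vector.
#' @return An `htest` list with `statistic` (K^2) and `p.value`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 9) stop("dagostino_pearson_test needs n >= 9")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5              # sample skewness g1
  b2 <- m4 / m2^2                # sample kurtosis g2 + 3
  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  structure(list(statistic = c(K2 = k2),
                 p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 method = "D'Agostino & Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Rank transform
#'
#' Ranks 1..n over all values entering one analysis; ties receive average
#' ranks.  Monotone: the ordering of distinct values is preserved.
#'
#' @param values Numeric vector.
#' @return Numeric vector of (average) ranks.
#' @examples
#' rank_transform(c(3.2, 1.1, 5.0))  # 2 1 3
#' rank_transform(c(2, 2, 7))        # 1.5 1.5 3
#' @export
rank_transform <- function(values) {
  if (!length(values)) stop("no values to rank")
  rank(values, ties.method = "average")
}

#' 2x2 within-subject repeated-measures ANOVA
#'
#' Classical within-subject sums-of-squares decomposition for a two-factor
#' (lighting x phase), two-level design with subjects (boxes) crossed with
#' both factors.  Each effect (lighting, phase, interaction) is tested
#' against its own subject-by-effect error term with df 1 and
#' `n_subjects - 1`; partial eta squared is `SS_effect / (SS_effect +
#' SS_error)`.  A zero error SS with a positive effect SS yields
#' `F = Inf, p = 0`; sphericity is moot in a 2x2 design (1 df per effect).
#'
#' @param cells A `cell_means` data frame for one category and session type
#'   (columns `box`, `lighting`, `phase`, `value`), or any data frame with
#'   those columns.  Incomplete subjects are dropped with a warning.
#' @param rank_transformed Set `TRUE` if `value` already holds ranks (only
#'   affects the `note` field).
#' @return Data frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `partial_eta_sq`, `n_subjects`.
#' @export
rm_anova_2x2 <- function(cells, rank_transformed = FALSE) {
  d <- as.data.frame(cells)
  stopifnot(all(c("box", "lighting", "phase", "value") %in% names(d)))
  d$box <- as.character(d$box)
  # keep only subjects with all four cells
  tab <- table(d$box)
  complete <- names(tab)[tab == 4]
  if (length(complete) < length(tab))
    warning("dropping incomplete subjects: ",
            paste(setdiff(names(tab), complete), collapse = ", "))
  d <- d[d$box %in% complete, , drop = FALSE]
  n <- length(complete)
  if (n < 2) stop("need at least 2 complete subjects")

  A <- factor(d$lighting)
  B <- factor(d$phase)
  S <- factor(d$box)
  if (nlevels(A) != 2 || nlevels(B) != 2) stop("factors must have 2 levels")
  y <- d$value
  gm <- mean(y)
  m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_s <- tapply(y, S, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) -
                      outer(rep(1, 2), m_b) + gm)^2)
  ss_as <- 2 * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, 2), m_s) + gm)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, 2), m_s) + gm)^2)
  cell_resid <- y -
    m_ab[cbind(as.integer(A), as.integer(B))] -
    m_as[cbind(as.integer(A), as.integer(S))] -
    m_bs[cbind(as.integer(B), as.integer(S))] +
    m_a[as.integer(A)] + m_b[as.integer(B)] + m_s[as.integer(S)] - gm
  ss_abs <- sum(cell_resid^2)

  one <- function(effect, ss_eff, ss_err) {
    df1 <- 1L
    df2 <- n - 1L
    f <- if (ss_err > 0) (ss_eff / df1) / (ss_err / df2)
         else if (ss_eff > 0) Inf else 0
    p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
    peta <- if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0
    data.frame(effect = effect, F = f, df_num = df1, df_den = df2, p = p,
               partial_eta_sq = peta, n_subjects = n,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("lighting", ss_a, ss_as),
               one("phase", ss_b, ss_bs),
               one("interaction", ss_ab, ss_abs))
  attr(out, "rank_transformed") <- rank_transformed
  out
}

#' Run the full ANOVA battery
#'
#' One rank-transform 2x2 repeated-measures ANOVA per category x session
#' type (11 behaviors + 4 call types, both transition directions: 30
#' analyses in the full design).  Values are rank-transformed per analysis
#' (ranks are computed over the 4 x n values entering that ANOVA), mirroring
#' the rank-then-ANOVA procedure for non-normal data.  No multiplicity
#' correction is applied by default; set `p_adjust = "holm"` to add an
#' adjusted column.
#'
#' @param cells A `cell_means` data frame from [collapse_design()].
#' @param alpha Significance level for the `significant` flag.
#' @param rank Apply the rank transform (default TRUE).
#' @param p_adjust Optional method name for [stats::p.adjust()].
#' @return Data frame with one row per category x session type x effect:
#'   F, dfs, p, partial eta squared, significance flag; skipped analyses
#'   are recorded in the `skipped` attribute.
#' @export
run_battery <- function(cells, alpha = 0.05, rank = TRUE, p_adjust = NULL) {
  d <- as.data.frame(cells)
  combos <- expand.grid(category = c(behavior_categories(), call_types()),
                        session_type = c("dark_to_light", "light_to_dark"),
                        stringsAsFactors = FALSE)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(combos))) {
    sub <- d[d$category == combos$category[i] &
               d$session_type == combos$session_type[i], , drop = FALSE]
    if (!nrow(sub)) {
      skipped <- c(skipped,
                   paste(combos$category[i], combos$session_type[i]))
      next
    }
    if (rank) sub$value <- rank_transform(sub$value)
    res <- tryCatch(rm_anova_2x2(sub, rank_transformed = rank),
                    error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped,
                   paste(combos$category[i], combos$session_type[i]))
      next
    }
    res$category <- combos$category[i]
    res$session_type <- combos$session_type[i]
    rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no analyzable category/session combinations")
  out <- do.call(rbind, rows)
  out <- out[c("category", "session_type", "effect", "F", "df_num", "df_den",
               "p", "partial_eta_sq", "n_subjects")]
  if (!is.null(p_adjust)) out$p_adj <- stats::p.adjust(out$p, p_adjust)
  out$significant <- out$p < alpha
  attr(out, "skipped") <- skipped
  attr(out, "n_analyses") <- length(rows)
  rownames(out) <- NULL
  out
}
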