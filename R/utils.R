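## Small shared numerics.

.geomean <- function(x) exp(mean(log(x), na.rm = TRUE))

#' Unpaired Student's t-test with degenerate-variance handling
#'
#' Equal-variance (pooled) unpaired t-test, the convention used for the
#' per-time-point physiology and probe-count comparisons. If the pooled
#' variance is zero and the group means are equal the test is uninformative:
#' t = 0 and the one-tailed p is 0.5 (two-sided p = 1), with a warning.
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @param alternative "two.sided", "less" (mean(x) < mean(y)) or "greater".
#' @param varEqual pool the variances (default TRUE); FALSE gives Welch.
#' @return list(t, df, p)
#' @export
studentTTest <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         varEqual = TRUE) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 observations per group")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (varEqual) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) {
    if (mx == my) {
      warning("zero pooled variance with equal means: t = 0")
      t <- 0
    } else t <- sign(mx - my) * Inf
  } else t <- (mx - my) / se
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              less = pt(t, df),
              greater = pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

## Least-squares cosinor fit at a fixed period; returns mesor, amp, acrophase.
.cosinor <- function(y, t, period) {
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  cf <- qr.coef(qr(X), y)
  cf[is.na(cf)] <- 0
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (atan2(cf[3], cf[2]) * period / (2 * pi)) %% period
  list(mesor = cf[1], amp = unname(amp), phase = unname(phase))
}

## Upper-tail hypergeometric P(X >= k) drawing n from K successes in N.
.hyperTail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

## Dense relabel of positive module labels by decreasing size (ties: first
## occurrence), keeping 0 for unassigned.
.relabelBySize <- function(labels) {
  pos <- labels[labels > 0]
  if (!length(pos)) return(labels)
  tab <- table(pos)
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  map <- setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  storage.mode(out) <- "integer"
  out
}
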