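## Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## Ordinary least squares on (x, y); optionally anchored through the origin.
## Returns slope, intercept and r2 = 1 - SS_res/SS_tot (centred SS_tot).
## A perfectly flat, perfectly fit response (SS_tot ~ 0, SS_res ~ 0) gets
## r2 = 1; anchored fits can in principle give SS_res > SS_tot, so r2 is
## clamped into [0, 1].
ols <- function(x, y, anchored = FALSE) {
  stopifnot(length(x) == length(y))
  if (anchored) {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  res <- y - (intercept + slope * x)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) {
    if (ss_res <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  list(slope = slope, intercept = intercept,
       r_squared = min(1, max(0, r2)))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
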