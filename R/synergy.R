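# Loewe-additivity synergy scoring for drug-combination dose matrices.
# Effects are expressed as fraction of untreated control (1 = control,
# lower = deeper inhibition). Monotherapy margins are fitted with
# four-parameter Hill curves; the Loewe-expected effect E at a dose pair
# (a, b) solves a / D_A(E) + b / D_B(E) = 1, where D_X(E) is the
# monotherapy dose of drug X alone producing effect E. A combination is
# additive when the fractional equivalent doses sum to 1; observed
# inhibition deeper than the expectation is synergy (positive score),
# shallower is antagonism (negative score).

#' Hill dose-response parameters
#'
#' Four-parameter sigmoidal model
#' `E(d) = einf + (e0 - einf) / (1 + (d / ec50)^h)`.
#'
#' @param e0 effect at dose 0 (normalized control, default 1)
#' @param einf asymptotic effect at infinite dose
#' @param ec50 dose of half-maximal effect (input dose units), > 0
#' @param h Hill slope, > 0
#' @return list of class `HillParams`
#' @export
hill_params <- function(e0 = 1, einf, ec50, h) {
  stopifnot(ec50 > 0, h > 0)
  if (e0 == einf) stop("e0 must differ from einf (curve needs an inverse)")
  structure(list(e0 = e0, einf = einf, ec50 = ec50, h = h),
            class = "HillParams")
}

#' Evaluate a Hill curve
#' @param d dose(s), >= 0
#' @param params [hill_params()]
#' @return effect(s)
#' @export
hill_response <- function(d, params) {
  params$einf + (params$e0 - params$einf) / (1 + (d / params$ec50)^params$h)
}

#' Invert a Hill curve
#'
#' Closed form `d = ec50 * ((e0 - effect) / (effect - einf))^(1/h)`;
#' round-trips with [hill_response()]. Effects at or beyond the curve's
#' asymptotes are unreachable by any finite dose and return `NA` (callers
#' apply the infinite-dose convention).
#'
#' @param effect effect value strictly between `e0` and `einf`
#' @param params [hill_params()]
#' @return dose, or `NA_real_` when the effect is unreachable
#' @export
inverse_hill <- function(effect, params) {
  lo <- min(params$e0, params$einf); hi <- max(params$e0, params$einf)
  ifelse(effect > lo & effect < hi,
         params$ec50 * ((params$e0 - effect) / (effect - params$einf))^(1 / params$h),
         NA_real_)
}

#' Fit a Hill curve to monotherapy data
#'
#' Bounded Levenberg-Marquardt least squares (`e0` in \[0.8, 1.2\], `einf`
#' in \[0, 1.2\], `h` in \[0.1, 10\]) with multi-start over log-spaced
#' `ec50` seeds spanning the dosed range. Responses must be normalized to
#' control = 1 and include dose 0.
#'
#' @param doses >= 4 doses including 0
#' @param responses matching responses
#' @return list with `params` ([hill_params()] or `NULL`), `rss`,
#'   `degenerate` (TRUE when the response is flat and no usable inverse
#'   exists)
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), length(doses) >= 4,
            any(doses == 0))
  if (stats::var(responses) < 1e-10)
    return(list(params = NULL, rss = 0, degenerate = TRUE))
  dpos <- doses[doses > 0]
  seeds <- exp(seq(log(min(dpos) / 10), log(max(dpos) * 10), length.out = 12))
  e0_start <- min(max(responses[doses == 0][1], 0.8), 1.2)
  einf_start <- min(max(min(responses), 0), 1.2)
  dat <- data.frame(d = doses, y = responses)
  best <- NULL
  for (s in seeds) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ einf + (e0 - einf) / (1 + (d / ec50)^h),
                        data = dat,
                        start = list(e0 = e0_start, einf = einf_start,
                                     ec50 = s, h = 1),
                        lower = c(e0 = 0.8, einf = 0, ec50 = min(dpos) / 1e4,
                                  h = 0.1),
                        upper = c(e0 = 1.2, einf = 1.2, ec50 = max(dpos) * 1e4,
                                  h = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- as.list(stats::coef(fit))
      best <- list(params = hill_params(cf$e0, cf$einf, cf$ec50, cf$h),
                   rss = rss, degenerate = FALSE)
    }
  }
  if (is.null(best)) stop("Hill fit failed at every start")
  best
}

#' Loewe-additive expected effect of a dose combination
#'
#' Solves `dose_a / D_A(E) + dose_b / D_B(E) = 1` for E by bisection
#' (tolerance 1e-9 in E). When E is unreachable by one drug alone its term
#' is treated as 0 (equivalent dose infinite). `(0, 0)` returns the mean
#' baseline; single-drug margins return that drug's fitted curve exactly.
#'
#' @param dose_a,dose_b doses >= 0
#' @param hill_a,hill_b [hill_params()] of the monotherapies (must be
#'   inhibitory: `e0 > einf`)
#' @return expected effect (fraction of control)
#' @export
loewe_expected <- function(dose_a, dose_b, hill_a, hill_b) {
  stopifnot(inherits(hill_a, "HillParams"), inherits(hill_b, "HillParams"),
            dose_a >= 0, dose_b >= 0,
            hill_a$e0 > hill_a$einf, hill_b$e0 > hill_b$einf)
  if (dose_a == 0 && dose_b == 0) return((hill_a$e0 + hill_b$e0) / 2)
  if (dose_b == 0) return(hill_response(dose_a, hill_a))
  if (dose_a == 0) return(hill_response(dose_b, hill_b))
  fsum <- function(e) {
    da <- inverse_hill(e, hill_a)
    db <- inverse_hill(e, hill_b)
    ta <- if (is.na(da)) {
      if (e >= hill_a$e0) Inf else 0  # above baseline: zero-dose limit
    } else dose_a / da
    tb <- if (is.na(db)) {
      if (e >= hill_b$e0) Inf else 0
    } else dose_b / db
    ta + tb - 1
  }
  lo <- min(hill_a$einf, hill_b$einf)
  hi <- min(hill_a$e0, hill_b$e0)
  eps <- (hi - lo) * 1e-12
  lo <- lo + eps; hi <- hi - eps
  flo <- fsum(lo); fhi <- fsum(hi)
  if (flo > 0 || fhi < 0)
    stop("Loewe equation has no root in bracket (non-monotone inputs?): f(",
         signif(lo, 6), ")=", signif(flo, 4), ", f(", signif(hi, 6), ")=",
         signif(fhi, 4))
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (fsum(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Score a dose-response surface against Loewe additivity
#'
#' Fits Hill curves to the monotherapy margins of the observed matrix
#' (unless fits are supplied), builds the Loewe-expected surface, and
#' scores each cell as `100 * (expected - observed)`: positive when the
#' observed inhibition is deeper than the additive prediction (synergy),
#' negative for antagonism. Margin cells of the expected surface are the
#' fitted monotherapy curves themselves. Cells within `threshold`
#' percentage points of additivity are called `additive`.
#'
#' @param observed `DoseMatrix` with zero-dose margins
#' @param hill_a,hill_b optional [hill_params()]; fitted from the margins
#'   when `NULL`
#' @param threshold |score| (percentage points of control) below which a
#'   cell is called additive (default 5)
#' @return list of class `SynergySurface`: `doses_a`, `doses_b`,
#'   `observed`, `expected`, `score`, `verdict`, `hill_a`, `hill_b`
#' @export
synergy_score <- function(observed, hill_a = NULL, hill_b = NULL,
                          threshold = 5) {
  stopifnot(inherits(observed, "DoseMatrix"))
  da <- observed$doses_a; db <- observed$doses_b
  if (da[1] != 0 || db[1] != 0)
    stop("zero-dose monotherapy margins are required for Loewe scoring")
  if (is.null(hill_a)) {
    f <- fit_hill(da, observed$response[, 1])
    if (f$degenerate) stop("drug A margin is flat; Loewe expectation undefined")
    hill_a <- f$params
  }
  if (is.null(hill_b)) {
    f <- fit_hill(db, observed$response[1, ])
    if (f$degenerate) stop("drug B margin is flat; Loewe expectation undefined")
    hill_b <- f$params
  }
  expected <- matrix(NA_real_, length(da), length(db),
                     dimnames = dimnames(observed$response))
  for (i in seq_along(da)) for (j in seq_along(db))
    expected[i, j] <- loewe_expected(da[i], db[j], hill_a, hill_b)
  score <- 100 * (expected - observed$response)
  verdict <- matrix("additive", length(da), length(db),
                    dimnames = dimnames(score))
  verdict[score > threshold] <- "synergy"
  verdict[score < -threshold] <- "antagonism"
  structure(list(doses_a = da, doses_b = db,
                 observed = observed$response, expected = expected,
                 score = score, verdict = verdict,
                 hill_a = hill_a, hill_b = hill_b),
            class = "SynergySurface")
}

#' @export
print.SynergySurface <- function(x, ...) {
  cat("SynergySurface (score = 100 * (Loewe expected - observed))\n")
  print(round(x$score, 2))
  tab <- table(factor(x$verdict, c("synergy", "additive", "antagonism")))
  cat("verdicts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
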