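## Survival-assay statistics: Firth bias-reduced binomial logistic
## regression of larva-to-adult survival on toxin presence, exact
## binomial confidence intervals, and the 10%-survival tolerance call.

## Firth-penalized logistic fit for aggregated binomial data.
## X: design matrix, k successes, n trials per row. Maximizes
## l(beta) + log det I(beta) / 2 by Newton steps on the Jeffreys-adjusted
## score, with step halving.
## Penalized log-likelihood l(beta) + log det I(beta) / 2 for aggregated
## binomial data with design X.
.pen_ll <- function(X, k, n, beta) {
  p <- plogis(drop(X %*% beta))
  W <- n * p * (1 - p)
  I <- crossprod(X, X * W)
  as.numeric(sum(k * log(p) + (n - k) * log1p(-p)) +
               0.5 * determinant(I)$modulus)
}

.firth_fit <- function(X, k, n, maxit = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen_ll <- function(beta) .pen_ll(X, k, n, beta)
  ll <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    p <- plogis(drop(X %*% beta))
    W <- n * p * (1 - p)
    I <- crossprod(X, X * W)
    Iinv <- solve(I)
    h <- W * rowSums((X %*% Iinv) * X) # hat diagonal of W^1/2 X I^-1 X' W^1/2
    U <- drop(crossprod(X, k - n * p + h * (0.5 - p)))
    delta <- drop(Iinv %*% U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    beta <- beta + step * delta
    ll <- pen_ll(beta)
    if (sqrt(sum((step * delta)^2)) < tol) { converged <- TRUE; break }
  }
  p <- plogis(drop(X %*% beta))
  W <- n * p * (1 - p)
  I <- crossprod(X, X * W)
  list(coefficients = beta, vcov = solve(I), pen_loglik = as.numeric(ll),
       fitted = p, converged = converged, iterations = iter)
}

#' Firth bias-reduced logistic regression of survival on toxin presence
#'
#' Fits `logit P(survive) = b0 + b1 * toxin` to one species' vial records
#' by penalized maximum likelihood (Jeffreys-prior penalty,
#' `l(b) + log det I(b) / 2`), which keeps estimates finite even under
#' complete separation (no survivors on toxin). Both the Wald chi-square
#' and the penalized likelihood-ratio chi-square for the toxin effect are
#' reported (df = 1); individual larvae are the unit of analysis, pooled
#' across vials.
#'
#' @param records survival data frame (columns `dose`, `n_larvae`,
#'   `n_survived`) for a single species, with a control (`dose == 0`) and
#'   a toxin (`dose > 0`) arm.
#' @return object of class `firth_glm`.
#' @export
firth_logistic <- function(records) {
  records <- validate_survival_records(records)
  if (length(unique(records$species)) > 1L)
    stop("fit one species at a time")
  arm <- as.integer(records$dose > 0)
  if (length(unique(arm)) < 2L)
    stop("both a control and a toxin arm are required")
  k <- tapply(records$n_survived, arm, sum)
  n <- tapply(records$n_larvae, arm, sum)
  k <- as.numeric(k[c("0", "1")]); n <- as.numeric(n[c("0", "1")])
  X <- cbind(intercept = c(1, 1), toxin = c(0, 1))
  full <- .firth_fit(X, k, n)
  ## profile penalized likelihood at toxin = 0: intercept re-optimized
  ## under the full-model Jeffreys penalty (keeps dimensions comparable)
  red <- optimize(function(b0) -.pen_ll(X, k, n, c(b0, 0)),
                  c(-30, 30), tol = 1e-10)
  se <- sqrt(diag(full$vcov))
  wald <- (full$coefficients[2L] / se[2L])^2
  plrt <- max(0, 2 * (full$pen_loglik - (-red$objective)))
  structure(list(
    coefficients = setNames(full$coefficients, c("(Intercept)", "toxin")),
    se = setNames(se, c("(Intercept)", "toxin")),
    vcov = full$vcov,
    wald_chisq = unname(wald), wald_p = unname(pchisq(wald, 1, lower.tail = FALSE)),
    plrt_chisq = unname(plrt), plrt_p = unname(pchisq(plrt, 1, lower.tail = FALSE)),
    pen_loglik = full$pen_loglik, converged = full$converged,
    iterations = full$iterations,
    counts = data.frame(arm = c("control", "toxin"), k = k, n = n)),
    class = "firth_glm")
}

#' @export
coef.firth_glm <- function(object, ...) object$coefficients

#' @export
vcov.firth_glm <- function(object, ...) object$vcov

#' @export
print.firth_glm <- function(x, ...) {
  cat("Firth bias-reduced binomial logistic fit (logit link)\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat(sprintf("toxin effect: Wald chi2 = %.3f (p = %.3g), penalized LRT chi2 = %.3f (p = %.3g)\n",
              x$wald_chisq, x$wald_p, x$plrt_chisq, x$plrt_p))
  invisible(x)
}

#' @export
summary.firth_glm <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se),
             wald_chisq = c(NA, object$wald_chisq),
             wald_p = c(NA, object$wald_p),
             plrt_chisq = c(NA, object$plrt_chisq),
             plrt_p = c(NA, object$plrt_p))
}

#' Binomial confidence interval for a survival proportion
#'
#' Clopper-Pearson exact interval by default; Wilson score interval by
#' flag.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return numeric vector `c(lo, hi)`.
#' @export
binomial_ci <- function(k, n, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  } else {
    z <- qnorm(1 - a / 2)
    ph <- k / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  c(lo = lo, hi = hi)
}

#' Tolerance call from survival at the 50 ug/g dose
#'
#' Category A (tolerant) is at least 10% absolute survival on diet with
#' 50 ug/g alpha-amanitin; category B (susceptible) is less than 10%.
#' The threshold is inclusive.
#'
#' @param species species labels.
#' @param proportion_at_50 survival proportions in `[0, 1]`.
#' @param cutoff tolerance threshold (default 0.10).
#' @return data frame `species`, `proportion`, `call` (`"A"`/`"B"`).
#' @export
classify_tolerance <- function(species, proportion_at_50, cutoff = 0.10) {
  stopifnot(length(species) == length(proportion_at_50),
            all(proportion_at_50 >= 0 & proportion_at_50 <= 1))
  data.frame(species = species, proportion = proportion_at_50,
             call = ifelse(proportion_at_50 >= cutoff, "A", "B"),
             stringsAsFactors = FALSE)
}

#' Per-species summary of a survival assay
#'
#' Pools vials within species and dose, fits the Firth model per species,
#' attaches the exact binomial confidence interval for toxin-arm survival
#' and the tolerance call.
#'
#' @param records vial-level survival records (several species allowed).
#' @param cutoff tolerance threshold (default 0.10).
#' @param level confidence level for the binomial interval.
#' @return data frame with one row per species.
#' @export
summarize_assay <- function(records, cutoff = 0.10, level = 0.95) {
  records <- validate_survival_records(records)
  out <- lapply(split(records, records$species), function(df) {
    ctrl <- df$dose == 0
    n0 <- sum(df$n_larvae[ctrl]); k0 <- sum(df$n_survived[ctrl])
    n1 <- sum(df$n_larvae[!ctrl]); k1 <- sum(df$n_survived[!ctrl])
    fit <- firth_logistic(df)
    ci <- binomial_ci(k1, n1, level)
    data.frame(species = df$species[1L],
               larvae_per_vial = round(median(df$n_larvae)),
               n_control = n0, surv_control = k0 / n0,
               n_toxin = n1, surv_toxin = k1 / n1,
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               slope = unname(coef(fit)["toxin"]),
               wald_chisq = fit$wald_chisq, wald_p = fit$wald_p,
               plrt_chisq = fit$plrt_chisq, plrt_p = fit$plrt_p,
               call = ifelse(k1 / n1 >= cutoff, "A", "B"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
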