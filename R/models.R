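#' Per-bar analysis table
#'
#' Long-format table with one row per (subject, piece, bar) joining the
#' baseline-differenced per-bar pupil diameter to its predictors. Duplicate
#' keys are rejected; rows with missing fields are kept here and dropped
#' (with a count) by the model fitters.
#'
#' @param df data frame with at least `subject`, `piece`, `bar`, `pupil`.
#' @return `df` with class `bar_table`.
#' @export
bar_table <- function(df) {
  req <- c("subject", "piece", "bar", "pupil")
  if (!all(req %in% names(df))) {
    stop("bar table needs columns ", paste(req, collapse = ", "))
  }
  key <- paste(df$subject, df$piece, df$bar)
  if (anyDuplicated(key)) stop("duplicate (subject, piece, bar) rows")
  df$bar <- as.integer(df$bar)
  class(df) <- unique(c("bar_table", class(df)))
  df
}

#' Mixed-model specification
#'
#' Describes the mixed-effects model: response, ordered fixed effects,
#' random-intercept factors, and the grouping within which residuals follow
#' an AR(1) process over bar number. Estimation is by maximum likelihood so
#' that likelihood-ratio and BIC comparisons across fixed-effect structures
#' are valid.
#'
#' @param fixed character vector of fixed-effect column names (may be empty
#'   for the null model).
#' @param response response column (default `"pupil"`).
#' @param random columns receiving crossed random intercepts (default
#'   `c("piece", "subject")`).
#' @param ar1_group columns whose interaction forms the AR(1) series grouping
#'   (default `c("piece", "subject")`).
#' @param bar integer time-index column for the AR(1) process (default
#'   `"bar"`); gaps from missing bars decay as `rho^gap`.
#' @export
model_spec <- function(fixed, response = "pupil",
                       random = c("piece", "subject"),
                       ar1_group = c("piece", "subject"), bar = "bar") {
  structure(list(response = response, fixed = as.character(fixed),
                 random = random, ar1_group = ar1_group, bar = bar),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rand <- paste(sprintf("(1|%s)", x$random), collapse = " + ")
  cat(sprintf("<model_spec> %s ~ %s + %s + ar1(%s + 0 | %s)\n", x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              rand, x$bar, paste(x$ar1_group, collapse = ":")))
  invisible(x)
}

#' Fit a linear mixed model with AR(1) serial correlation
#'
#' Gaussian mixed model, maximum likelihood, with crossed random intercepts
#' and an AR(1) residual process over bar number within each series group:
#' within group `g`, `cov(y_j, y_k)` includes
#' `sigma_ar^2 * rho^|bar_j - bar_k|` plus `sigma_e^2` on the diagonal.
#' Fitting is delegated to [glmmTMB::glmmTMB()]; standard errors come from
#' the observed information, `z = estimate/SE`, and two-sided p-values use
#' the normal reference.
#'
#' @param table a [bar_table()] (or plain data frame with the needed
#'   columns).
#' @param spec a [model_spec()].
#' @param fix optional list with elements `sigma_ar`, `rho`, `sigma_e` to
#'   hold the variance structure fixed (only supported when `spec$random` is
#'   empty; used for likelihood cross-checks).
#' @return object of class `lmm_fit`: `coefficients` (estimate, se, z, p,
#'   ci_lo, ci_hi), `varcomp` (`sigma_piece`, `sigma_subject`, `sigma_ar`,
#'   `rho`, `sigma_e`), `logLik`, `n`, `k`, `BIC`, `n_excluded`, `singular`,
#'   `spec`, and the underlying `model`.
#' @export
fit_lmm <- function(table, spec, fix = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  d <- as.data.frame(table)
  used <- unique(c(spec$response, spec$fixed, spec$random, spec$ar1_group,
                   spec$bar))
  missing_cols <- setdiff(used, names(d))
  if (length(missing_cols)) {
    stop("columns missing from table: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(d[used])
  n_excluded <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete rows to fit")

  bar <- d[[spec$bar]]
  d$.bar_f <- factor(bar, levels = seq(min(bar), max(bar)))
  d$.ar_g <- interaction(d[spec$ar1_group], drop = TRUE)
  for (r in spec$random) d[[r]] <- factor(d[[r]])

  # standardise fixed effects internally (predictor scales can differ by
  # orders of magnitude, which derails the optimizer); estimates and SEs
  # are transformed back exactly afterwards
  scl <- NULL
  if (length(spec$fixed)) {
    m <- vapply(spec$fixed, function(cn) mean(d[[cn]]), 0)
    s <- vapply(spec$fixed, function(cn) stats::sd(d[[cn]]), 0)
    s[!is.finite(s) | s == 0] <- 1
    for (j in seq_along(spec$fixed)) {
      cn <- spec$fixed[j]
      d[[cn]] <- (d[[cn]] - m[j]) / s[j]
    }
    scl <- list(m = m, s = s)
  }

  rhs <- c(if (length(spec$fixed)) spec$fixed else "1",
           sprintf("(1 | %s)", spec$random),
           "ar1(.bar_f + 0 | .ar_g)")
  form <- stats::reformulate(rhs, response = spec$response)

  args <- list(formula = form, data = d, REML = FALSE,
               control = glmmTMB::glmmTMBControl(rank_check = "adjust"))
  if (!is.null(fix)) {
    if (length(spec$random)) {
      stop("`fix` is only supported for models without random intercepts")
    }
    args$start <- list(theta = c(log(fix$sigma_ar),
                                 fix$rho / sqrt(1 - fix$rho^2)),
                       betad = log(fix$sigma_e))
    args$map <- list(theta = factor(c(NA, NA)), betad = factor(NA))
  }
  fit_healthy <- function(f) {
    conv <- f$fit$convergence
    is.finite(as.numeric(stats::logLik(f))) &&
      isTRUE(f$sdr$pdHess) && (is.null(conv) || conv == 0)
  }
  fit <- suppressWarnings(do.call(glmmTMB::glmmTMB, args))
  if (!fit_healthy(fit)) {
    # retry from the first solution with a larger iteration budget
    args2 <- args
    args2$control <- glmmTMB::glmmTMBControl(
      rank_check = "adjust",
      optCtrl = list(iter.max = 1000, eval.max = 1500))
    pf <- fit$fit$parfull
    args2$start <- utils::modifyList(
      if (is.null(args$start)) list() else args$start,
      list(beta = unname(pf[names(pf) == "beta"]),
           theta = unname(pf[names(pf) == "theta"])))
    refit <- try(suppressWarnings(do.call(glmmTMB::glmmTMB, args2)),
                 silent = TRUE)
    if (!inherits(refit, "try-error") &&
        (fit_healthy(refit) ||
           is.finite(as.numeric(stats::logLik(refit))))) {
      fit <- refit
    }
  }
  if (!fit_healthy(fit)) {
    # last resort: a BFGS pass from scratch
    args3 <- args
    args3$control <- glmmTMB::glmmTMBControl(
      rank_check = "adjust", optimizer = stats::optim,
      optArgs = list(method = "BFGS"))
    refit <- try(suppressWarnings(do.call(glmmTMB::glmmTMB, args3)),
                 silent = TRUE)
    if (!inherits(refit, "try-error") && fit_healthy(refit)) fit <- refit
  }
  conv <- fit$fit$convergence
  conv_ok <- is.null(conv) || conv == 0
  if (!is.finite(as.numeric(stats::logLik(fit))) ||
      (!conv_ok && !isTRUE(fit$sdr$pdHess))) {
    stop("mixed-model optimizer failed to converge: ", fit$fit$message)
  }
  if (!conv_ok || !isTRUE(fit$sdr$pdHess)) {
    warning("optimizer reported an imperfect solution (",
            if (!conv_ok) fit$fit$message else "non-PD information matrix",
            "); estimates retained, interpret with care")
  }

  co <- summary(fit)$coefficients$cond
  est <- co[, 1]
  se <- co[, 2]
  if (!is.null(scl)) {
    # exact back-transform from the standardised scale
    terms <- rownames(co)
    for (j in seq_along(spec$fixed)) {
      i <- match(spec$fixed[j], terms)
      if (!is.na(i)) {
        est[i] <- est[i] / scl$s[j]
        se[i] <- se[i] / scl$s[j]
      }
    }
    i0 <- match("(Intercept)", terms)
    if (!is.na(i0)) {
      a <- numeric(length(terms))
      a[i0] <- 1
      for (j in seq_along(spec$fixed)) {
        i <- match(spec$fixed[j], terms)
        if (!is.na(i) && is.finite(co[i, 1])) {
          est[i0] <- est[i0] - co[i, 1] * scl$m[j] / scl$s[j]
          a[i] <- -scl$m[j] / scl$s[j]
        }
      }
      V <- try(stats::vcov(fit)$cond, silent = TRUE)
      if (!inherits(V, "try-error") &&
          all(rownames(V) %in% terms)) {
        av <- a[match(rownames(V), terms)]
        se[i0] <- sqrt(as.numeric(t(av) %*% V %*% av))
      }
    }
  }
  coefs <- data.frame(term = rownames(co), estimate = est,
                      se = se, z = est / se,
                      p = 2 * stats::pnorm(-abs(est / se)),
                      row.names = NULL)
  coefs$ci_lo <- coefs$estimate - stats::qnorm(0.975) * coefs$se
  coefs$ci_hi <- coefs$estimate + stats::qnorm(0.975) * coefs$se

  vc <- glmmTMB::VarCorr(fit)$cond
  sd_of <- function(name) {
    if (name %in% names(vc)) unname(attr(vc[[name]], "stddev")[1]) else NA_real_
  }
  ar <- vc[[".ar_g"]]
  rho <- if (!is.null(ar) && nrow(ar) > 1L) {
    unname(attr(ar, "correlation")[1L, 2L])
  } else NA_real_
  varcomp <- list(sigma_piece = sd_of("piece"), sigma_subject = sd_of("subject"),
                  sigma_ar = if (!is.null(ar)) unname(attr(ar, "stddev")[1])
                             else NA_real_,
                  rho = rho, sigma_e = stats::sigma(fit))

  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  pd <- fit$sdr$pdHess
  re_sds <- c(varcomp$sigma_piece, varcomp$sigma_subject, varcomp$sigma_ar)
  singular <- isFALSE(pd) || any(re_sds < 1e-6, na.rm = TRUE)
  if (singular) warning("variance estimate on the boundary (singular fit)")

  structure(list(coefficients = coefs, varcomp = varcomp,
                 logLik = as.numeric(ll), n = n, k = k,
                 BIC = k * log(n) - 2 * as.numeric(ll),
                 n_excluded = n_excluded, singular = singular, spec = spec,
                 model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  print(x$spec)
  printCoefmat(
    `rownames<-`(as.matrix(x$coefficients[, c("estimate", "se", "z", "p")]),
                 x$coefficients$term),
    digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  v <- x$varcomp
  cat(sprintf("sigma_piece %.4g  sigma_subject %.4g  sigma_ar %.4g  rho %.3f  sigma_e %.4g\n",
              v$sigma_piece, v$sigma_subject, v$sigma_ar, v$rho, v$sigma_e))
  cat(sprintf("logLik %.3f  n %d  k %d  BIC %.2f  (%d rows excluded)\n",
              x$logLik, x$n, x$k, x$BIC, x$n_excluded))
  invisible(x)
}

#' Hierarchical predictor addition
#'
#' Starting from a null model (intercept + random effects + AR(1) only),
#' adds the given predictors one at a time in the supplied order (by
#' convention, decreasing absolute estimate size from a prior full-model
#' fit). Each row reports the likelihood-ratio chi-square (df = 1) of the
#' augmented model against its immediate predecessor, and the augmented
#' model's BIC. All fits are by maximum likelihood.
#'
#' @param table a [bar_table()].
#' @param spec a [model_spec()]; its `fixed` field is ignored in favour of
#'   `predictors`.
#' @param predictors character vector, in entry order.
#' @return data frame of class `comparison`: `predictor`, `chisq`, `df`,
#'   `p`, `BIC` — first row is the null model (BIC only).
#' @export
hierarchical_compare <- function(table, spec, predictors) {
  spec0 <- spec
  spec0$fixed <- character(0)
  prev <- fit_lmm(table, spec0)
  rows <- data.frame(predictor = "(null)", chisq = NA_real_, df = NA_integer_,
                     p = NA_real_, BIC = prev$BIC)
  acc <- character(0)
  for (p in predictors) {
    acc <- c(acc, p)
    sp <- spec
    sp$fixed <- acc
    cur <- fit_lmm(table, sp)
    chisq <- 2 * (cur$logLik - prev$logLik)
    if (chisq < -1e-6) {
      warning("logLik decreased when adding `", p,
              "` (possible convergence failure)")
    }
    chisq <- max(chisq, 0)
    rows <- rbind(rows, data.frame(
      predictor = p, chisq = chisq, df = 1L,
      p = stats::pchisq(chisq, df = 1, lower.tail = FALSE), BIC = cur$BIC))
    prev <- cur
  }
  class(rows) <- c("comparison", "data.frame")
  rows
}

#' Between-piece contrasts for one performer
#'
#' Fits, for each choice of base level, a model with piece as fixed effect,
#' piece as random intercept, and AR(1) over bar within piece, then collates
#' the full set of pairwise contrasts. With `P` pieces, bases `1..P-1` cover
#' all `P(P-1)/2` pairs. A contrast `(A, B)` is the fitted mean difference
#' `B - A`; significance is flagged at the Bonferroni-adjusted level.
#'
#' @param table a [bar_table()] restricted to one performer.
#' @param alpha significance level (default 0.008, Bonferroni for six
#'   contrasts).
#' @param response,bar column names (defaults `"pupil"`, `"bar"`).
#' @return data frame of class `contrast_result`: `performer`, `piece_a`,
#'   `piece_b`, `estimate`, `se`, `z`, `p`, `significant`.
#' @export
piece_contrasts <- function(table, alpha = 0.008, response = "pupil",
                            bar = "bar") {
  d <- as.data.frame(table)
  d <- d[stats::complete.cases(d[c(response, "piece", bar)]), ]
  pieces <- sort(unique(as.character(d$piece)))
  if (length(pieces) < 2L) stop("need at least 2 pieces for contrasts")
  performer <- if (length(unique(d$subject)) == 1L) {
    as.character(d$subject[1L])
  } else NA_character_
  b <- d[[bar]]
  d$.bar_f <- factor(b, levels = seq(min(b), max(b)))
  out <- NULL
  for (i in seq_len(length(pieces) - 1L)) {
    d$.piece_f <- stats::relevel(factor(d$piece, levels = pieces),
                                 ref = pieces[i])
    fit <- suppressWarnings(glmmTMB::glmmTMB(
      stats::reformulate(c(".piece_f", "(1 | .piece_f)",
                           "ar1(.bar_f + 0 | .piece_f)"),
                         response = response),
      data = d, REML = FALSE))
    co <- summary(fit)$coefficients$cond
    for (j in (i + 1L):length(pieces)) {
      term <- paste0(".piece_f", pieces[j])
      est <- co[term, 1]
      se <- co[term, 2]
      z <- est / se
      p <- 2 * stats::pnorm(-abs(z))
      out <- rbind(out, data.frame(
        performer = performer, piece_a = pieces[i], piece_b = pieces[j],
        estimate = est, se = se, z = z, p = p, significant = p < alpha,
        row.names = NULL))
    }
  }
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Wilcoxon signed-rank test with exact enumeration
#'
#' Paired two-sided test. Zero differences are dropped; ties in absolute
#' differences receive average ranks. `W` is the smaller of the positive-
#' and negative-rank sums. For `n <= 50` retained pairs the p-value is exact,
#' from the full distribution of the signed-rank sum over all `2^n` sign
#' patterns (computed by convolution, which also handles tied ranks); larger
#' samples use a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y paired numeric samples of equal length.
#' @return list of class `wilcoxon_result`: `W`, `V` (positive-rank sum),
#'   `p`, `n` (pairs retained), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; statistic undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  M <- n * (n + 1) / 2
  W <- min(V, M - V)
  if (n <= 50L) {
    # distribution of 2*V over 0..2M by convolution over ranks
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    tot <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(counts[seq_len(v2 + 1L)]) / tot
    p_ge <- sum(counts[(v2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- M / 2
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    zval <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(zval)))
    method <- "normal approximation"
  }
  structure(list(W = W, V = V, p = p, n = n, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: W = %g, p = %.4g (n = %d, %s)\n",
              x$W, x$p, x$n, x$method))
  invisible(x)
}
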