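#' All-subsets AICc model selection and model averaging
#'
#' Candidate sets are all subsets of the fixed-effect terms (including the
#' null model), each fitted with the same random-effect structure by
#' `lme4` (binomial GLMM via `glmer`, gaussian LMM via `lmer` with ML).
#' Models are ranked by the small-sample-corrected Akaike information
#' criterion, Akaike weights are computed, and per-term conditional
#' (natural) model-averaged estimates with adjusted standard errors and
#' relative variable importance (RVI) are reported.
#'
#' @name pcmc-modsel
NULL

#' All-subsets candidate specifications
#'
#' @param terms character vector of fixed-effect term names (1-10 terms;
#'   0 terms yields the null model alone).
#' @return list of character vectors, one per subset, `character(0)`
#'   first (the null model); `2^length(terms)` specs in total.
#' @examples
#' length(build_candidate_set(letters[1:5]))  # 32
#' @export
build_candidate_set <- function(terms) {
  terms <- unique(as.character(terms))
  if (length(terms) > 10L) stop("at most 10 terms supported", call. = FALSE)
  subsets <- list(character(0))
  for (tm in terms) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, tm)))
  }
  subsets[order(lengths(subsets))]
}

#' Small-sample-corrected Akaike information criterion
#'
#' \deqn{\mathrm{AICc} = -2\log L + 2k + \frac{2k(k+1)}{n-k-1}}
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (fixed coefficients including
#'   the intercept, plus variance components, plus the residual variance
#'   for gaussian models).
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(-101.56, 7, 175)  # 217.79
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one candidate model
#'
#' @param response response column name.
#' @param terms character vector of fixed-effect terms (possibly empty).
#' @param data model frame.
#' @param family `"binomial"` (glmer) or `"gaussian"` (lmer, ML).
#' @param random random-effects formula fragment, default
#'   `"(1 | dyad / victim)"` — victim nested in dyad, two variance
#'   components.
#' @return list: `terms`, `logLik`, `k` (from the fit's logLik df:
#'   fixed coefficients + variance components, + residual for gaussian),
#'   `n`, `coef` and `se` (named, fixed effects), `converged`, `message`.
#'   Non-converged fits carry `converged = FALSE` and are excluded (with
#'   a message) by [rank_and_weight()].
#' @export
fit_model <- function(response, terms, data, family = c("binomial", "gaussian"),
                      random = "(1 | dyad / victim)") {
  family <- match.arg(family)
  rhs <- paste(c(if (length(terms)) terms else "1", random), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch({
      if (family == "binomial") {
        lme4::glmer(fml, data = data, family = stats::binomial())
      } else {
        lme4::lmer(fml, data = data, REML = FALSE)
      }
    }, error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error") &&
      grepl("grouping factor|number of levels|> 1", conditionMessage(fit))) {
    # degenerate grouping (a single level): collapse to the fixed-effects fit
    fml0 <- stats::as.formula(paste(response, "~",
                                    if (length(terms)) paste(terms, collapse = " + ") else "1"))
    fit0 <- tryCatch(
      if (family == "binomial") stats::glm(fml0, data = data, family = stats::binomial())
      else stats::glm(fml0, data = data),
      error = function(e) e)
    if (!inherits(fit0, "error")) {
      ll <- stats::logLik(fit0)
      sm <- summary(fit0)$coefficients
      return(list(terms = terms, logLik = as.numeric(ll),
                  k = as.integer(attr(ll, "df")), n = nrow(data),
                  coef = stats::setNames(sm[, "Estimate"], rownames(sm)),
                  se = stats::setNames(sm[, "Std. Error"], rownames(sm)),
                  converged = fit0$converged %||% TRUE,
                  message = "random structure collapsed (single grouping level)"))
    }
  }
  if (inherits(fit, "error")) {
    return(list(terms = terms, logLik = NA_real_, k = NA_integer_, n = nrow(data),
                coef = NULL, se = NULL, converged = FALSE,
                message = conditionMessage(fit)))
  }
  ll <- stats::logLik(fit)
  sm <- summary(fit)$coefficients
  # singular (zero-variance) random effects are legitimate boundary fits;
  # only genuine optimizer failures disqualify a candidate
  all_msgs <- c(fit@optinfo$conv$lme4$messages %||% character(0), msgs)
  failed <- any(grepl("failed to converge|unable to evaluate|pwrssUpdate|Downdated",
                      all_msgs))
  list(terms = terms,
       logLik = as.numeric(ll),
       k = as.integer(attr(ll, "df")),
       n = nrow(data),
       coef = stats::setNames(sm[, "Estimate"], rownames(sm)),
       se = stats::setNames(sm[, "Std. Error"], rownames(sm)),
       converged = !failed,
       message = paste(all_msgs, collapse = "; "))
}

#' Fit the whole candidate set and rank it by AICc
#'
#' @inheritParams fit_model
#' @param terms all fixed-effect terms; every subset is fitted.
#' @param n_aicc sample size used in the AICc correction; defaults to
#'   `nrow(data)`.
#' @return object of class `pcmc_modsel`: `fits` (list from
#'   [fit_model()]), `table` (data.frame `model, df, logLik, aicc, delta,
#'   weight` over converged fits), `family`, `response`, `dropped`
#'   (non-converged model descriptions).
#' @export
ic_model_set <- function(response, terms, data, family = c("binomial", "gaussian"),
                         random = "(1 | dyad / victim)", n_aicc = nrow(data)) {
  family <- match.arg(family)
  specs <- build_candidate_set(terms)
  fits <- lapply(specs, function(s) fit_model(response, s, data, family, random))
  out <- rank_and_weight(fits, n_aicc)
  out$family <- family
  out$response <- response
  out
}

#' Rank fitted candidates: AICc, delta, Akaike weight
#'
#' \eqn{\Delta_i = \mathrm{AICc}_i - \min \mathrm{AICc}};
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}.
#'
#' @param fits list of fits from [fit_model()].
#' @param n_aicc sample size for the AICc correction.
#' @return `pcmc_modsel` object (see [ic_model_set()]).
#' @export
rank_and_weight <- function(fits, n_aicc) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$logLik), logical(1))
  dropped <- vapply(fits[!ok], function(f) {
    sprintf("{%s}: %s", paste(f$terms, collapse = "+"),
            if (nzchar(f$message)) f$message else "did not converge")
  }, character(1))
  if (length(dropped)) {
    message(length(dropped), " candidate model(s) excluded (non-convergence): ",
            paste(dropped, collapse = " | "))
  }
  fits <- fits[ok]
  if (length(fits) == 0L) stop("no successfully fitted candidate models", call. = FALSE)
  a <- vapply(fits, function(f) aicc(f$logLik, f$k, n_aicc), numeric(1))
  delta <- a - min(a)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = vapply(fits, function(f) if (length(f$terms)) paste(f$terms, collapse = " + ") else "(null)",
                   character(1)),
    df = vapply(fits, `[[`, integer(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    aicc = a, delta = delta, weight = w, stringsAsFactors = FALSE)
  ord <- order(tab$aicc)
  for (i in seq_along(fits)) {
    fits[[i]]$aicc <- a[i]; fits[[i]]$delta <- delta[i]; fits[[i]]$weight <- w[i]
  }
  out <- list(fits = fits[ord], table = tab[ord, , drop = FALSE], dropped = dropped,
              n_aicc = n_aicc)
  rownames(out$table) <- NULL
  class(out) <- "pcmc_modsel"
  out
}

#' @param x a `pcmc_modsel`.
#' @param max_delta truncate the printed ranking at this delta (default
#'   3; the full table stays in `x$table`).
#' @param ... unused.
#' @rdname ic_model_set
#' @export
print.pcmc_modsel <- function(x, max_delta = 3, ...) {
  tab <- x$table[x$table$delta <= max_delta, , drop = FALSE]
  tab$logLik <- round(tab$logLik, 2)
  tab$aicc <- round(tab$aicc, 2); tab$delta <- round(tab$delta, 2)
  tab$weight <- round(tab$weight, 2)
  cat(sprintf("candidate models (delta <= %g of %d fitted):\n", max_delta, nrow(x$table)))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Model-averaged estimates and relative variable importance
#'
#' Conditional (natural) averaging: each term is averaged over the models
#' that contain it, with those models' Akaike weights renormalized. The
#' adjusted standard error is the unconditional-variance estimator
#' \deqn{SE^*(\bar\beta) = \sum_i \tilde w_i
#'       \sqrt{SE_i^2 + (\beta_i - \bar\beta)^2},}
#' the z-value is \eqn{|\bar\beta|/SE^*} with a two-tailed normal p, and
#' the relative variable importance of a term is the sum of the
#' (unrenormalized) weights of the models containing it.
#'
#' @param modsel a `pcmc_modsel` from [ic_model_set()] /
#'   [rank_and_weight()].
#' @param full logical; `TRUE` switches to full (shrinkage) averaging,
#'   where models lacking a term contribute a zero coefficient.
#' @return object of class `pcmc_avg`; its `terms` element is a
#'   data.frame `term, estimate, adjusted_se, z, p, rvi`.
#' @export
model_average <- function(modsel, full = FALSE) {
  fits <- modsel$fits
  all_terms <- unique(unlist(lapply(fits, `[[`, "terms")))
  rows <- lapply(all_terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% f$terms, logical(1))
    if (!any(has)) return(NULL)
    # a factor term may appear in coef under a contrast name, e.g. "contextfeeding"
    coef_name <- function(f) {
      nm <- names(f$coef)
      hit <- nm[nm == tm | startsWith(nm, tm)]
      hit[1]
    }
    rvi <- sum(vapply(fits[has], `[[`, numeric(1), "weight"))
    betas <- vapply(fits[has], function(f) unname(f$coef[coef_name(f)]), numeric(1))
    ses <- vapply(fits[has], function(f) unname(f$se[coef_name(f)]), numeric(1))
    if (full) {
      w <- vapply(fits, `[[`, numeric(1), "weight")
      b_all <- ifelse(has, NA_real_, 0); s_all <- ifelse(has, NA_real_, 0)
      b_all[has] <- betas; s_all[has] <- ses
      bbar <- sum(w * b_all)
      se_star <- sum(w * sqrt(s_all^2 + (b_all - bbar)^2))
    } else {
      w <- vapply(fits[has], `[[`, numeric(1), "weight")
      w <- w / sum(w)
      bbar <- sum(w * betas)
      se_star <- sum(w * sqrt(ses^2 + (betas - bbar)^2))
    }
    z <- abs(bbar) / se_star
    data.frame(term = tm, estimate = bbar, adjusted_se = se_star, z = z,
               p = 2 * stats::pnorm(-z), rvi = rvi, stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  terms <- terms[order(-terms$rvi), , drop = FALSE]
  rownames(terms) <- NULL
  out <- list(terms = terms, full = full, n_models = length(fits))
  class(out) <- "pcmc_avg"
  out
}

#' @export
print.pcmc_avg <- function(x, ...) {
  cat(sprintf("model-averaged terms (%s averaging over %d models):\n",
              if (x$full) "full" else "conditional", x$n_models))
  tab <- x$terms
  tab$estimate <- signif(tab$estimate, 5); tab$adjusted_se <- signif(tab$adjusted_se, 5)
  tab$z <- round(tab$z, 3); tab$p <- signif(tab$p, 4); tab$rvi <- round(tab$rvi, 2)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pcmc_avg <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
summary.pcmc_avg <- function(object, ...) object$terms
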