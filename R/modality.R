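# Modality classification: beta-distribution MLE per event, sequential rule
# classification into seven modalities, spurious-bimodality correction, and
# cross-population modality dynamics.

#' Fit a beta distribution to PSI values by maximum likelihood
#'
#' Values are clipped to \eqn{[\epsilon, 1-\epsilon]} (the beta likelihood
#' is undefined at the boundaries) and the log-likelihood is maximized over
#' \eqn{\log\alpha, \log\beta} starting from the method-of-moments
#' estimates. When all values coincide after clipping, a degenerate
#' moment-matched fit is returned with a warning flag.
#'
#' @param x Non-missing PSI values on [0,1], length >= 2.
#' @param eps Clipping margin (default 1e-3).
#' @param max_iter Optimizer iteration cap (default 500).
#' @return Named numeric \code{c(alpha, beta)} with attributes
#'   \code{converged} and \code{degenerate}.
#' @export
fit_beta_mle <- function(x, eps = 1e-3, max_iter = 500) {
  stopifnot(length(x) >= 2, all(x >= 0 & x <= 1))
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x)
  v <- var(x)
  if (v < .Machine$double.eps) {
    # all values identical after clipping: spike at m; report a sharp
    # moment-matched fit rather than diverging
    scale <- 1e6
    out <- c(alpha = m * scale, beta = (1 - m) * scale)
    attr(out, "converged") <- FALSE
    attr(out, "degenerate") <- TRUE
    warning("constant PSI values after clipping; degenerate beta fit")
    return(out)
  }
  # method-of-moments start
  common <- m * (1 - m) / v - 1
  a0 <- max(m * common, 1e-3)
  b0 <- max((1 - m) * common, 1e-3)
  slx <- sum(log(x))
  sl1x <- sum(log1p(-x))
  n <- length(x)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -((a - 1) * slx + (b - 1) * sl1x - n * lbeta(a, b))
  }
  gr <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    dab <- digamma(a + b)
    da <- -(slx - n * (digamma(a) - dab)) * a
    db <- -(sl1x - n * (digamma(b) - dab)) * b
    c(da, db)
  }
  fit <- optim(log(c(a0, b0)), nll, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  out <- exp(fit$par)
  names(out) <- c("alpha", "beta")
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify a PSI distribution into a modality
#'
#' Rules are applied strictly in sequence on the fitted beta parameters:
#' \enumerate{
#'   \item bimodal when \eqn{\alpha < 0.5} or \eqn{\beta < 0.5};
#'   \item included when (\eqn{\alpha > 2} and \eqn{\beta < 1}) or
#'     \eqn{\alpha/\beta > 2};
#'   \item excluded when (\eqn{\beta > 2} and \eqn{\alpha < 1}) or
#'     \eqn{\beta/\alpha > 2};
#'   \item middle when \eqn{\alpha > 1}, \eqn{\beta > 1} and
#'     \eqn{\alpha \approx \beta} (relative tolerance \code{tau_eq});
#'   \item multimodal otherwise.
#' }
#' Included and excluded calls receive a sub-modality from the empirical
#' variance of the PSI values: primary below \code{var_threshold},
#' dispersed at or above it.
#'
#' @param alpha,beta Fitted beta shapes (> 0, finite).
#' @param sample_variance Empirical variance of the PSI values on [0,1].
#' @param tau_eq Relative tolerance for the middle rule's equality
#'   (default 0.05).
#' @param var_threshold Primary/dispersed variance cut (default 0.001).
#' @return List with \code{modality} and \code{sub_modality} ("none" unless
#'   included/excluded).
#' @export
classify_modality <- function(alpha, beta, sample_variance,
                              tau_eq = 0.05, var_threshold = 0.001) {
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop("non-finite beta parameters")
  }
  modality <- if (alpha < 0.5 || beta < 0.5) {
    "bimodal"
  } else if ((alpha > 2 && beta < 1) || alpha / beta > 2) {
    "included"
  } else if ((beta > 2 && alpha < 1) || beta / alpha > 2) {
    "excluded"
  } else if (alpha > 1 && beta > 1 &&
             abs(alpha - beta) <= tau_eq * max(alpha, beta)) {
    "middle"
  } else {
    "multimodal"
  }
  sub <- if (modality %in% c("included", "excluded")) {
    if (sample_variance < var_threshold) "primary" else "dispersed"
  } else "none"
  list(modality = modality, sub_modality = sub)
}

#' Distinguish true from spurious bimodality
#'
#' Spurious bimodal PSI distributions arise from all-or-none capture during
#' single-cell library amplification. A bimodal call is accepted as true
#' only when the two ends of the distribution are balanced: with
#' \eqn{p_{hi}} the fraction of cells above 0.75 and \eqn{p_{lo}} the
#' fraction below 0.25, the fold difference
#' \eqn{\max(p_{hi},p_{lo})/\min(p_{hi},p_{lo})} must be < 3 (an empty side
#' gives infinite fold and always fails) and the absolute difference
#' \eqn{|p_{hi}-p_{lo}|} must be < 0.50. False bimodals are reassigned to
#' included when the mean PSI exceeds 0.5 and excluded otherwise, and then
#' receive a primary/dispersed sub-modality from their variance.
#'
#' @param x Non-missing PSI values on [0,1] of an event classified bimodal.
#' @param var_threshold Primary/dispersed variance cut (default 0.001).
#' @return List: \code{is_true_bimodal}, \code{modality},
#'   \code{sub_modality}, \code{p_hi}, \code{p_lo}, \code{fold},
#'   \code{diff}.
#' @export
adjust_bimodality <- function(x, var_threshold = 0.001) {
  p_hi <- mean(x > 0.75)
  p_lo <- mean(x < 0.25)
  fold <- if (min(p_hi, p_lo) == 0) Inf else max(p_hi, p_lo) / min(p_hi, p_lo)
  d <- abs(p_hi - p_lo)
  true_bimodal <- is.finite(fold) && fold < 3 && d < 0.50
  if (true_bimodal) {
    return(list(is_true_bimodal = TRUE, modality = "bimodal",
                sub_modality = "none", p_hi = p_hi, p_lo = p_lo,
                fold = fold, diff = d))
  }
  modality <- if (mean(x) >= 0.5) "included" else "excluded"
  sub <- if (var(x) < var_threshold) "primary" else "dispersed"
  list(is_true_bimodal = FALSE, modality = modality, sub_modality = sub,
       p_hi = p_hi, p_lo = p_lo, fold = fold, diff = d)
}

#' Assign modalities to all eligible events
#'
#' Per eligible event: fit the beta distribution to the non-missing PSI
#' values, classify by the sequential rules, and (optionally) pass bimodal
#' calls through the spurious-bimodality correction. Pre- and
#' post-adjustment modalities are both recorded.
#'
#' @param psi Events x cells PSI matrix (NA = missing).
#' @param min_cells Eligibility floor on informative cells (default 25).
#' @param bimodal_adjust Apply the bimodality correction (default TRUE).
#' @param tau_eq,var_threshold Passed to [classify_modality()].
#' @return Data.frame: \code{event_id}, \code{alpha}, \code{beta},
#'   \code{variance}, \code{n_cells}, \code{modality}, \code{sub_modality},
#'   \code{pre_adjustment_modality}, \code{bimodal_adjusted}.
#' @export
assign_modalities <- function(psi, min_cells = 25, bimodal_adjust = TRUE,
                              tau_eq = 0.05, var_threshold = 0.001) {
  eligible <- psi_summary_filters(psi, min_cells = min_cells)
  out <- data.frame(event_id = character(), alpha = numeric(),
                    beta = numeric(), variance = numeric(),
                    n_cells = integer(), modality = character(),
                    sub_modality = character(),
                    pre_adjustment_modality = character(),
                    bimodal_adjusted = logical(), stringsAsFactors = FALSE)
  for (id in eligible) {
    x <- psi[id, ]
    x <- x[!is.na(x)]
    fit <- suppressWarnings(fit_beta_mle(x))
    v <- var(x)
    cl <- classify_modality(fit[["alpha"]], fit[["beta"]], v,
                            tau_eq = tau_eq, var_threshold = var_threshold)
    pre <- cl$modality
    adjusted <- FALSE
    if (bimodal_adjust && cl$modality == "bimodal") {
      adj <- adjust_bimodality(x, var_threshold = var_threshold)
      if (!adj$is_true_bimodal) {
        cl$modality <- adj$modality
        cl$sub_modality <- adj$sub_modality
        adjusted <- TRUE
      }
    }
    out <- rbind(out, data.frame(
      event_id = id, alpha = fit[["alpha"]], beta = fit[["beta"]],
      variance = v, n_cells = length(x), modality = cl$modality,
      sub_modality = cl$sub_modality, pre_adjustment_modality = pre,
      bimodal_adjusted = adjusted, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Classify modality dynamics between two cell populations
#'
#' For events called differentially spliced, the change of modality between
#' the populations is explicit when the five-class modality differs,
#' implicit when only the primary/dispersed sub-modality differs, and
#' restricted when neither differs despite the significant distribution
#' shift. Events lacking a modality call in either population are labeled
#' undefined.
#'
#' @param calls_g1,calls_g2 Modality tables from [assign_modalities()] for
#'   the two populations.
#' @param event_ids Events to classify (default: differentially spliced
#'   events present in either table).
#' @return Data.frame: \code{event_id}, \code{modality_g1},
#'   \code{modality_g2}, \code{sub_modality_g1}, \code{sub_modality_g2},
#'   \code{dynamics}.
#' @export
classify_modality_dynamics <- function(calls_g1, calls_g2,
                                       event_ids = NULL) {
  if (is.null(event_ids)) {
    event_ids <- union(calls_g1$event_id, calls_g2$event_id)
  }
  i1 <- match(event_ids, calls_g1$event_id)
  i2 <- match(event_ids, calls_g2$event_id)
  m1 <- calls_g1$modality[i1]; m2 <- calls_g2$modality[i2]
  s1 <- calls_g1$sub_modality[i1]; s2 <- calls_g2$sub_modality[i2]
  dynamics <- ifelse(is.na(m1) | is.na(m2), "undefined",
              ifelse(m1 != m2, "explicit",
              ifelse(s1 != s2, "implicit", "restricted")))
  data.frame(event_id = event_ids, modality_g1 = m1, modality_g2 = m2,
             sub_modality_g1 = s1, sub_modality_g2 = s2,
             dynamics = dynamics, stringsAsFactors = FALSE)
}
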