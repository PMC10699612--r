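#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted presence-background model
#'
#' One row per expanded basis term with its shrunken coefficient.
#'
#' @param x A `maxent_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @method tidy maxent_fit
#' @export
tidy.maxent_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of a fitted presence-background model
#'
#' @param x A `maxent_fit`.
#' @param ... Unused.
#' @return Tibble with counts, the number of nonzero terms, the background
#'   log-normalizer and the entropy of the fitted background distribution.
#' @method glance maxent_fit
#' @export
glance.maxent_fit <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$features), n_terms = length(x$beta),
                 k_nonzero = sum(x$beta != 0), log_z = x$logZ,
                 entropy = x$entropy)
}

#' Tidy an RSFSA result
#'
#' The variable ranking (one row per variable).
#'
#' @param x An `rsfsa_result`.
#' @param ... Unused.
#' @return The `rsfsa_ranking` tibble.
#' @method tidy rsfsa_result
#' @export
tidy.rsfsa_result <- function(x, ...) tibble::as_tibble(x$ranking)

#' One-row summary of an RSFSA result
#'
#' @param x An `rsfsa_result`.
#' @param ... Unused.
#' @return Tibble with the selected size and criterion, ensemble size and
#'   mean held-out metrics over the ensemble members.
#' @method glance rsfsa_result
#' @export
glance.rsfsa_result <- function(x, ...) {
  m <- x$ensemble$metrics
  tibble::tibble(size = x$stage1$size, criterion = x$stage1$criterion,
                 fallback = x$stage1$fallback,
                 n_members = length(x$ensemble$models),
                 mean_auc_psa = mean(m$auc_psa),
                 mean_auc_diff = mean(m$auc_psa_diff),
                 mean_tss_psa = mean(m$tss_psa))
}
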